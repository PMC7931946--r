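# Physicochemical descriptors and the rule filters used to compare cohorts
# and relate promiscuity to properties. MW, Crippen-type clogP and Ertl TPSA
# come from the structure-perception backend; counts and the pKa/logS
# estimates are computed on the heavy-atom graph.

.PKA_TABLE <- list(
  basic = c(aliphatic_amine = 10.6, aniline = 4.6, imidazole = 7.0,
            pyridine = 5.2),
  acidic = c(carboxylic_acid = 4.2, sulfonic_acid = -1.0,
             phosphonic_acid = 2.0, phenol = 10.0)
)

.rotatableBonds <- function(mol) {
  g <- mol@graph
  b <- g$bonds
  if (nrow(b) == 0) return(0L)
  el <- g$atoms$element
  deg <- g$atoms$degree
  nb <- .neighborList(g)
  bord <- .bondOrderMatrixLookup(g)
  isAmideBond <- function(i, j) {
    # C-N single bond where the C is double-bonded to O
    for (p in list(c(i, j), c(j, i))) {
      c_ <- p[1]; n_ <- p[2]
      if (el[c_] == "C" && el[n_] == "N") {
        dblO <- any(vapply(nb[[c_]], function(k)
          k != n_ && el[k] == "O" &&
            identical(unname(bord[paste(min(c_, k), max(c_, k), sep = ":")]), 2L),
          logical(1)))
        if (dblO) return(TRUE)
      }
    }
    FALSE
  }
  sum(vapply(seq_len(nrow(b)), function(k) {
    i <- b$from[k]; j <- b$to[k]
    b$order[k] == 1L && !b$aromatic[k] && !b$inRing[k] &&
      deg[i] >= 2L && deg[j] >= 2L && !isAmideBond(i, j)
  }, logical(1)))
}

.sp3Carbons <- function(mol) {
  g <- mol@graph
  el <- g$atoms$element
  multi <- rep(FALSE, nrow(g$atoms))
  b <- g$bonds
  if (nrow(b) > 0) {
    hit <- b$order > 1L | b$aromatic
    multi[unique(c(b$from[hit], b$to[hit]))] <- TRUE
  }
  sum(el == "C" & !g$atoms$aromatic & !multi)
}

.estimatePKa <- function(mol, labels = assignFeatures(mol)) {
  g <- mol@graph
  atoms <- g$atoms
  el <- atoms$element
  nb <- .neighborList(g)
  bord <- .bondOrderMatrixLookup(g)
  getOrd <- function(i, j) unname(bord[paste(min(i, j), max(i, j), sep = ":")])

  basic <- numeric(0); acidic <- numeric(0)
  hasP <- vapply(labels, function(l) "P" %in% l, logical(1))
  for (i in which(el == "N")) {
    if (atoms$aromatic[i]) {
      if (atoms$nH[i] == 0) {
        # pyridine-type aromatic N; adjacent aromatic N-H marks an
        # imidazole/azole-like pattern with a higher representative value
        nearNH <- any(el == "N" & atoms$aromatic & atoms$nH >= 1 &
                        g$dist[i, ] >= 1 & g$dist[i, ] <= 2)
        basic <- c(basic, if (nearNH) .PKA_TABLE$basic[["imidazole"]]
                          else .PKA_TABLE$basic[["pyridine"]])
      }
    } else if (hasP[i]) {
      basic <- c(basic, .PKA_TABLE$basic[["aliphatic_amine"]])
    } else {
      allSingle <- length(nb[[i]]) == 0 ||
        all(vapply(nb[[i]], function(j) identical(getOrd(i, j), 1L), logical(1)))
      aromNbr <- length(nb[[i]]) > 0 && any(atoms$aromatic[nb[[i]]])
      if (allSingle && aromNbr) {
        # aniline-type unless amide nitrogen
        isAmide <- any(vapply(nb[[i]], function(j) {
          el[j] == "C" && any(vapply(nb[[j]], function(k)
            k != i && el[k] %in% c("O", "S") && identical(getOrd(j, k), 2L),
            logical(1)))
        }, logical(1)))
        if (!isAmide) basic <- c(basic, .PKA_TABLE$basic[["aniline"]])
      }
    }
  }
  for (i in which(el == "O")) {
    donorOrAnion <- atoms$nH[i] >= 1 || atoms$charge[i] < 0
    if (!donorOrAnion) next
    for (j in nb[[i]]) {
      if (!identical(getOrd(i, j), 1L)) next
      dblO <- any(vapply(nb[[j]], function(k)
        k != i && el[k] == "O" && identical(getOrd(j, k), 2L), logical(1)))
      if (el[j] == "C" && dblO) acidic <- c(acidic, .PKA_TABLE$acidic[["carboxylic_acid"]])
      if (el[j] == "S" && dblO) acidic <- c(acidic, .PKA_TABLE$acidic[["sulfonic_acid"]])
      if (el[j] == "P" && dblO) acidic <- c(acidic, .PKA_TABLE$acidic[["phosphonic_acid"]])
      if (el[j] == "C" && atoms$aromatic[j] && !dblO && atoms$nH[i] >= 1)
        acidic <- c(acidic, .PKA_TABLE$acidic[["phenol"]])
    }
  }
  list(basic = if (length(basic)) max(basic) else NA_real_,
       acidic = if (length(acidic)) min(acidic) else NA_real_)
}

#' Compute the physicochemical property profile of a molecule
#'
#' MW includes implicit hydrogens; clogP is a Crippen-type atom-contribution
#' estimate and TPSA the Ertl fragment-contribution value. HBD/HBA are the
#' donor/acceptor atom counts of the pharmacophore feature table. Rotatable
#' bonds are single, non-ring, non-terminal, non-amide bonds. pKa values are
#' representative pattern-table estimates (most basic and most acidic site);
#' logS is an ESOL-type linear estimate:
#' 0.16 - 0.63 clogP - 0.0062 MW + 0.066 nRot - 0.74 (aromatic fraction).
#'
#' @param mol a [Molecule-class].
#' @return one-row data.frame: mol_id, MW, clogP, TPSA, HBD, HBA,
#'   n_rotatable, n_sp3_carbon, pKa_basic, pKa_acidic, logS.
#' @export
computeProperties <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  labels <- assignFeatures(mol)
  hbd <- sum(vapply(labels, function(l) "D" %in% l, logical(1)))
  hba <- sum(vapply(labels, function(l) "A" %in% l, logical(1)))
  nrot <- .rotatableBonds(mol)
  mw <- mol@graph$mw
  clogp <- mol@graph$logp
  aromProp <- mean(mol@graph$atoms$aromatic)
  pka <- .estimatePKa(mol, labels)
  logS <- 0.16 - 0.63 * clogp - 0.0062 * mw + 0.066 * nrot - 0.74 * aromProp
  data.frame(
    mol_id = molId(mol),
    MW = mw, clogP = clogp, TPSA = mol@graph$tpsa,
    HBD = hbd, HBA = hba,
    n_rotatable = nrot, n_sp3_carbon = .sp3Carbons(mol),
    pKa_basic = pka$basic, pKa_acidic = pka$acidic,
    logS = logS,
    stringsAsFactors = FALSE)
}

#' Property profiles for a set of molecules
#' @param molecules a [MoleculeSet-class] or list of [Molecule-class].
#' @param path optional TSV output path.
#' @return data.frame, one row per molecule.
#' @export
propertyProfiles <- function(molecules, path = NULL) {
  if (is(molecules, "MoleculeSet")) molecules <- molecules@molecules
  df <- do.call(rbind, lapply(molecules, computeProperties))
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

# internal: the global property block appended to FPD+SHED for the QSAR-style
# classifiers
.sarGlobalProps <- function(mol) {
  labels <- assignFeatures(mol)
  c(MW = mol@graph$mw,
    clogP = mol@graph$logp,
    TPSA = mol@graph$tpsa,
    HBD = sum(vapply(labels, function(l) "D" %in% l, logical(1))),
    HBA = sum(vapply(labels, function(l) "A" %in% l, logical(1))),
    nRot = .rotatableBonds(mol),
    nSp3 = .sp3Carbons(mol),
    aromProp = mean(mol@graph$atoms$aromatic))
}

#' Classify a property profile against the 3/75 rule, Ro5 and the pKa window
#'
#' 3/75 bins use inclusive boundaries exactly as the rule is stated
#' (compliant = clogP <= 3 and TPSA >= 75). Ro5 violations are counted as
#' MW >= 500, clogP >= 5, HBD > 5, HBA > 10 (boundary conventions exposed via
#' \code{ro5Bounds}). \code{pka_7_10} is TRUE when the basic pKa lies in
#' [7, 10].
#'
#' @param profile one row of [computeProperties()] output (or a list with the
#'   same fields).
#' @param ro5Bounds named list overriding the four Ro5 cutoffs.
#' @return data.frame with \code{rule_3_75_bin}, \code{compliant_3_75},
#'   \code{ro5_violations}, \code{pka_7_10}.
#' @export
classifyRules <- function(profile,
                          ro5Bounds = list(MW = 500, clogP = 5, HBD = 5, HBA = 10)) {
  lowLogP <- profile$clogP <= 3
  highTPSA <- profile$TPSA >= 75
  bin <- if (highTPSA && lowLogP) "TPSA>=75 & clogP<=3"
         else if (!highTPSA && !lowLogP) "TPSA<75 & clogP>3"
         else if (highTPSA && !lowLogP) "TPSA>=75 & clogP>3"
         else "TPSA<75 & clogP<=3"
  viol <- sum(profile$MW >= ro5Bounds$MW,
              profile$clogP >= ro5Bounds$clogP,
              profile$HBD > ro5Bounds$HBD,
              profile$HBA > ro5Bounds$HBA)
  pka710 <- !is.na(profile$pKa_basic) &&
    profile$pKa_basic >= 7 && profile$pKa_basic <= 10
  data.frame(
    mol_id = if (!is.null(profile$mol_id)) profile$mol_id else NA_character_,
    rule_3_75_bin = bin,
    compliant_3_75 = highTPSA && lowLogP,
    ro5_violations = as.integer(viol),
    pka_7_10 = pka710,
    stringsAsFactors = FALSE)
}

.MW_BINS <- c(-Inf, 200, 300, 500, 700, Inf)
.MW_BIN_LABELS <- c("<200", "200-300", "300-500", "500-700", ">700")

#' Cross-tabulate off-target counts against property bins
#'
#' Counts each compound's consensus-passing, non-training predicted
#' interactions and distributes them over MW bins (<200, 200-300, 300-500,
#' 500-700, >700), TPSA bins of width 50 and clogP bins of width 1 (top bin
#' >= 7), reporting the percentage of all predicted off-targets per bin.
#'
#' @param predictions prediction data.frame (from [predictTargets()] /
#'   [classifyInteractions()]) with \code{mol_id}, \code{consensus_pass},
#'   \code{provenance}.
#' @param profiles data.frame from [propertyProfiles()].
#' @return list of three data.frames (\code{MW}, \code{TPSA}, \code{clogP}),
#'   each with bin, n_offtargets, percent; plus \code{n_missing_profile}.
#' @export
promiscuityProfile <- function(predictions, profiles) {
  offt <- predictions[predictions$consensus_pass &
                        predictions$provenance != "training_set", , drop = FALSE]
  counts <- table(offt$mol_id)
  ids <- names(counts)
  missing <- setdiff(ids, profiles$mol_id)
  ids <- setdiff(ids, missing)
  prof <- profiles[match(ids, profiles$mol_id), ]
  nOff <- as.integer(counts[ids])

  binTable <- function(values, breaks, labels) {
    bin <- cut(values, breaks = breaks, labels = labels, right = FALSE)
    tot <- vapply(split(nOff, bin), sum, numeric(1))
    tot[is.na(tot)] <- 0
    pct <- if (sum(tot) > 0) 100 * tot / sum(tot) else tot * 0
    data.frame(bin = labels, n_offtargets = as.integer(tot),
               percent = as.numeric(pct), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  tpsaBreaks <- c(seq(0, 250, by = 50), Inf)
  tpsaLabels <- c(paste(head(tpsaBreaks, -2), tpsaBreaks[2:(length(tpsaBreaks) - 1)],
                        sep = "-"), ">=250")
  logpBreaks <- c(-Inf, seq(0, 7, by = 1), Inf)
  logpLabels <- c("<0", paste(0:6, 1:7, sep = "-"), ">=7")
  list(
    MW = binTable(prof$MW, .MW_BINS, .MW_BIN_LABELS),
    TPSA = binTable(prof$TPSA, tpsaBreaks, tpsaLabels),
    clogP = binTable(prof$clogP, logpBreaks, logpLabels),
    n_missing_profile = length(missing))
}
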