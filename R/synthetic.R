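# Desk-scale chemogenomics fixtures with known ground truth: chemotype
# series built from a packaged scaffold library with enumerated decorations,
# planted cross-activities, decoys, withheld queries, and recovery metrics.

# scaffold library: each entry carries one "%s" substitution site on a ring
# carbon; decorating with any fragment below yields a valid SMILES
.SCAFFOLDS <- c(
  # protonatable amines
  "CCN(CC)CCOc1ccc(%s)cc1",
  "CN1CCN(CC1)c1ccc(%s)cc1",
  "CN(C)CCCc1ccc(%s)cc1",
  "C1CCN(CC1)Cc1ccc(%s)cc1",
  "CNCCc1ccc(%s)cc1OC",
  "CC(N)Cc1ccc(%s)cc1",
  "OCCN1CCC(CC1)c1ccc(%s)cc1",
  "CN1CCC(CC1)Oc1ccc(%s)cc1",
  "NCCCOc1ccc(%s)cc1C",
  "C1CN(CCO1)Cc1ccc(%s)cc1",
  "CCNCC(O)c1ccc(%s)cc1",
  "CN(C)CCOC(=O)c1ccc(%s)cc1",
  "NCCc1c[nH]c2ccc(%s)cc12",
  "CCN1CCCC1Cc1ccc(%s)cc1",
  "CN(C)Cc1ccc(%s)cc1OC",
  # carboxylic and other acids
  "OC(=O)Cc1ccc(%s)cc1OC",
  "OC(=O)c1ccc(Oc2ccc(%s)cc2)cc1",
  "CC(C(=O)O)c1ccc(%s)cc1",
  "OC(=O)c1cc2cc(%s)ccc2[nH]1",
  "NS(=O)(=O)c1ccc(%s)cc1OC",
  "CC(=O)Nc1cc(%s)ccc1C(O)=O",
  "OC(=O)CSc1ccc(%s)cc1",
  "OC(=O)CCc1ccc(%s)cc1C",
  "OC(=O)c1ccc(CNC(C)=O)cc1%s",
  "OC(=O)COc1ccc(%s)cc1Cl",
  "OS(=O)(=O)Cc1ccc(%s)cc1",
  "OC(=O)c1ccc(-c2ccc(%s)cc2)cc1",
  "CC(O)(C(O)=O)c1ccc(%s)cc1",
  "OC(=O)CN(C)c1ccc(%s)cc1",
  "OC(=O)c1cc(%s)ccc1NC(C)=O",
  # aromatics and heteroaromatics
  "c1ccc2[nH]c(-c3ccc(%s)cc3)cc2c1",
  "c1cc(%s)ccc1-c1nc2ccccc2o1",
  "c1cc(%s)ccc1-c1nc2ccccc2s1",
  "Cc1ccc(-c2ccc(%s)cc2)cc1O",
  "c1cc(%s)ccc1-c1ccnc2ccccc12",
  "COc1ccc(-c2cc3ccccc3[nH]2)cc1%s",
  "c1cc(%s)ccc1Oc1ccccc1C",
  "Cc1n[nH]c(-c2ccc(%s)cc2)c1C",
  "c1cc(%s)ccc1-c1csc(C)n1",
  "c1cc(%s)ccc1Cn1ccnc1",
  "COc1cc(%s)ccc1-c1ccccc1",
  "c1cc(%s)ccc1CCc1ccccc1O",
  "Cc1oc2ccccc2c1Cc1ccc(%s)cc1",
  "c1cc(%s)ccc1Sc1ccccc1N",
  "Cc1ccc2oc(-c3ccc(%s)cc3)cc2c1",
  # neutral cores: amides, ethers, ureas, sulfones
  "CC(=O)Nc1ccc(%s)cc1OC",
  "O=C(Nc1ccc(%s)cc1)c1ccccc1",
  "COc1cc(%s)ccc1CNC(C)=O",
  "O=C(N1CCCC1)c1ccc(%s)cc1",
  "O=S(=O)(N)c1ccc(%s)cc1C",
  "CCOC(=O)Nc1ccc(%s)cc1",
  "O=C(NC)c1ccc(Oc2ccc(%s)cc2)cc1",
  "CNC(=O)Cc1ccc(%s)cc1OC",
  "O=C(NCCO)c1ccc(%s)cc1",
  "CC(=O)N1CCC(CC1)c1ccc(%s)cc1",
  "O=C(Nc1ccc(%s)cc1)NC1CC1",
  "COCCOc1ccc(%s)cc1C",
  "CS(=O)(=O)c1ccc(%s)cc1OC",
  "O=C1CCCN1c1ccc(%s)cc1")

# decoration fragments: small alkyl/halogen substituents, valid as "(%s)"
# ring branches. Deliberately conservative — they perturb the 2-D structure
# without adding pharmacophore features, so members of one chemotype are
# near-duplicates in descriptor space (the property the recovery invariants
# are built on)
.DECORATIONS <- c(
  "C", "CC", "CCC", "C(C)C", "CCCC", "C(C)(C)C", "CC(C)C", "CCCCC",
  "F", "Cl", "Br", "I", "CF", "CCl", "CBr", "CI",
  "C(F)(F)F", "CCF", "CCCl", "CCBr", "C=C", "CC=C", "C#C", "CCCF")

#' Default synthetic study specification
#'
#' The packaged defaults are the study conditions used throughout the test
#' suite: 8 targets in 4 families (one chemotype each, 20 actives per
#' chemotype), each chemotype planted onto its family partner target at
#' fraction 0.3, 60 decoys, 20\% of each chemotype withheld as queries,
#' seed 17.
#'
#' @param nTargets number of targets (one chemotype each).
#' @param nFamilies number of target families (targets assigned contiguously).
#' @param activesPerChemotype chemotype series length.
#' @param crossFraction fraction of each chemotype's members planted onto the
#'   family-partner off-target (0 disables planting).
#' @param decoyCount number of unannotated decoy compounds.
#' @param withholdFraction fraction of each chemotype withheld as queries.
#' @param seed RNG seed for the member subsets.
#' @return a validated spec list; \code{plantedCrossActivities} is a
#'   data.frame (chemotype, off_target, fraction).
#' @export
syntheticSpec <- function(nTargets = 8L, nFamilies = 4L,
                          activesPerChemotype = 20L, crossFraction = 0.3,
                          decoyCount = 60L, withholdFraction = 0.2,
                          seed = 17L) {
  stopifnot(nTargets >= 1, nFamilies >= 1, nFamilies <= nTargets,
            activesPerChemotype >= 1, decoyCount >= 0,
            crossFraction >= 0, crossFraction <= 1,
            withholdFraction >= 0, withholdFraction < 1)
  tids <- sprintf("T%02d", seq_len(nTargets))
  fam <- sprintf("FAM%d", ceiling(seq_len(nTargets) / (nTargets / nFamilies)))
  planted <- NULL
  if (crossFraction > 0) {
    rows <- list()
    for (i in seq_len(nTargets)) {
      partners <- setdiff(which(fam == fam[i]), i)
      if (length(partners))
        rows[[length(rows) + 1L]] <- data.frame(
          chemotype = tids[i], off_target = tids[partners[1]],
          fraction = crossFraction, stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, rows)
  }
  list(nTargets = nTargets, targetIds = tids, families = fam,
       activesPerChemotype = as.integer(activesPerChemotype),
       plantedCrossActivities = planted,
       decoyCount = as.integer(decoyCount),
       withholdFraction = withholdFraction, seed = as.integer(seed))
}

#' Generate a synthetic reference database with known ground truth
#'
#' Each target gets one chemotype: a scaffold from the packaged library
#' decorated with enumerated fragments. Members are active on their primary
#' target; planted cross-activities copy the stated fraction of members onto
#' the off-target; decoys (remaining scaffold/decoration combinations) carry
#' no annotation; a stated fraction of each chemotype is withheld from the
#' database as queries. Fully deterministic under the spec seed.
#'
#' @param spec a [syntheticSpec()] list.
#' @return list with \code{db} (a [ReferenceDatabase-class]) and \code{truth}
#'   (a [GroundTruth-class]).
#' @export
generateReferenceDb <- function(spec = syntheticSpec()) {
  n <- spec$activesPerChemotype
  if (spec$nTargets > length(.SCAFFOLDS) ||
      n > length(.DECORATIONS))
    stop("scaffold library exhausted: at most ", length(.SCAFFOLDS),
         " targets and ", length(.DECORATIONS), " actives per chemotype")
  nDecoyScaffolds <- length(.SCAFFOLDS) - spec$nTargets
  if (spec$decoyCount > nDecoyScaffolds * length(.DECORATIONS))
    stop("scaffold library exhausted: at most ",
         nDecoyScaffolds * length(.DECORATIONS), " decoys available")
  set.seed(spec$seed)

  compounds <- list()
  interRows <- list()
  truthRows <- list()
  withheldRows <- list()
  for (i in seq_len(spec$nTargets)) {
    t <- spec$targetIds[i]
    scaf <- .SCAFFOLDS[i]
    members <- sprintf("%s_%02d", t, seq_len(n))
    smi <- vapply(seq_len(n), function(j)
      sprintf(scaf, .DECORATIONS[j]), character(1))
    plantRow <- if (!is.null(spec$plantedCrossActivities))
      spec$plantedCrossActivities[spec$plantedCrossActivities$chemotype == t, ]
      else NULL
    plantedIdx <- integer(0)
    if (!is.null(plantRow) && nrow(plantRow) == 1)
      plantedIdx <- sort(sample(n, round(plantRow$fraction * n)))
    withheldIdx <- sort(sample(n, round(spec$withholdFraction * n)))

    for (j in seq_len(n)) {
      mid <- members[j]
      if (j %in% withheldIdx) {
        withheldRows[[length(withheldRows) + 1L]] <-
          data.frame(mol_id = mid, smiles = smi[j], stringsAsFactors = FALSE)
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          mol_id = mid, target_id = t, kind = "primary",
          stringsAsFactors = FALSE)
        if (j %in% plantedIdx)
          truthRows[[length(truthRows) + 1L]] <- data.frame(
            mol_id = mid, target_id = plantRow$off_target,
            kind = "planted_off_target", stringsAsFactors = FALSE)
        next
      }
      compounds[[mid]] <- parseMolecule(smi[j], mid)
      interRows[[length(interRows) + 1L]] <- data.frame(
        mol_id = mid, target_id = t, label = "active",
        potency_uM = NA_real_, stringsAsFactors = FALSE)
      if (j %in% plantedIdx)
        interRows[[length(interRows) + 1L]] <- data.frame(
          mol_id = mid, target_id = plantRow$off_target, label = "active",
          potency_uM = NA_real_, stringsAsFactors = FALSE)
    }
  }

  # decoys: remaining scaffolds x decorations, in library order, unannotated
  k <- 0L
  for (si in seq.int(spec$nTargets + 1L, length.out = nDecoyScaffolds)) {
    for (dj in seq_along(.DECORATIONS)) {
      if (k >= spec$decoyCount) break
      k <- k + 1L
      mid <- sprintf("DCY_%03d", k)
      compounds[[mid]] <- parseMolecule(sprintf(.SCAFFOLDS[si],
                                                .DECORATIONS[dj]), mid)
    }
    if (k >= spec$decoyCount) break
  }

  canon <- vapply(compounds, smiles, character(1))
  if (anyDuplicated(canon))
    stop("scaffold library produced duplicate canonical SMILES: ",
         paste(names(canon)[duplicated(canon)], collapse = ", "))

  inter <- do.call(rbind, interRows)
  inter <- inter[order(inter$target_id, inter$mol_id), ]
  rownames(inter) <- NULL
  tids <- sort(unique(inter$target_id))
  actives <- lapply(tids, function(t)
    sort(inter$mol_id[inter$target_id == t]))
  names(actives) <- tids
  inactives <- stats::setNames(rep(list(character(0)), length(tids)), tids)
  targets <- data.frame(
    target_id = tids,
    target_family = spec$families[match(tids, spec$targetIds)],
    stringsAsFactors = FALSE)
  db <- new("ReferenceDatabase", compounds = compounds, targets = targets,
            actives = actives, inactives = inactives, interactions = inter,
            aliases = character(0))
  truth <- new("GroundTruth",
               interactions = do.call(rbind, truthRows),
               withheld = do.call(rbind, withheldRows))
  list(db = db, truth = truth)
}

#' Build the query set from a ground truth
#'
#' Parses the withheld molecules and returns them with their expected
#' (query, target) pairs, asserting no leakage: no query's canonical SMILES
#' occurs among the database compounds.
#'
#' @param truth a [GroundTruth-class].
#' @param db the emitted [ReferenceDatabase-class] (leakage check).
#' @return list with \code{queries} (list of [Molecule-class]) and
#'   \code{expected} (data.frame mol_id, target_id, kind).
#' @export
generateQuerySet <- function(truth, db) {
  queries <- lapply(seq_len(nrow(truth@withheld)), function(r)
    parseMolecule(truth@withheld$smiles[r], truth@withheld$mol_id[r]))
  dbCanon <- vapply(db@compounds, smiles, character(1))
  qCanon <- vapply(queries, smiles, character(1))
  leak <- qCanon %in% dbCanon
  if (any(leak))
    stop("leakage: withheld query present in the database: ",
         paste(truth@withheld$mol_id[leak], collapse = ", "))
  list(queries = queries, expected = truth@interactions)
}

#' Evaluate recovery of expected interactions
#'
#' Compares a prediction table (from [predictTargets()]) against the expected
#' pairs: ensemble recall of primary targets, capture of planted off-targets,
#' overall capture rate, precision of the consensus-passing set, per-method
#' recall among expected pairs (method score at or above tau) and the
#' all-six fraction — the same arithmetic as the cohort report.
#'
#' @param predictionTable data.frame from [predictTargets()].
#' @param expected data.frame (mol_id, target_id, kind) from
#'   [generateQuerySet()].
#' @param tau method-score threshold for per-method recall.
#' @return list of metrics.
#' @export
evaluateRecovery <- function(predictionTable, expected, tau = 0.6) {
  pass <- predictionTable[predictionTable$consensus_pass, , drop = FALSE]
  predKey <- paste(pass$mol_id, pass$target_id)
  expKey <- paste(expected$mol_id, expected$target_id)
  hit <- expKey %in% predKey

  primary <- expected$kind == "primary"
  planted <- expected$kind == "planted_off_target"
  recallPrimary <- if (any(primary)) mean(hit[primary]) else NA_real_
  capturePlanted <- if (any(planted)) mean(hit[planted]) else NA_real_
  capture <- if (length(expKey)) mean(hit) else NA_real_
  precision <- if (length(predKey)) mean(predKey %in% expKey) else NA_real_

  # per-method recall over all expected pairs present in the full table
  idx <- match(expKey, paste(predictionTable$mol_id,
                             predictionTable$target_id))
  methodRecall <- vapply(.METHODS, function(m) {
    s <- predictionTable[[m]][idx]
    mean(!is.na(s) & s >= tau)
  }, numeric(1))
  allSix <- mean(vapply(seq_along(expKey), function(r) {
    if (is.na(idx[r])) return(FALSE)
    s <- unlist(predictionTable[idx[r], .METHODS])
    all(!is.na(s) & s >= tau)
  }, logical(1)))

  list(recall_primary = recallPrimary,
       capture_planted = capturePlanted,
       capture_rate = capture,
       precision = precision,
       n_expected = length(expKey),
       n_predicted = length(predKey),
       method_recall = methodRecall,
       all_six_fraction = allSix)
}
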