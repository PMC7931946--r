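# Hashed circular substructure fingerprint (Morgan-style neighborhoods) and
# bitset Tanimoto. Hashing is a plain 31-polynomial over the integers mod
# 2^31 - 1: deterministic across platforms (exact in double arithmetic).

.HASH_MOD <- 2147483647

.hashInts <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% .HASH_MOD)) %% .HASH_MOD
  h
}

#' Compute a hashed circular fingerprint
#'
#' Initial atom identifiers hash element, heavy degree, hydrogen count,
#' formal charge, aromaticity and ring membership; each iteration rehashes an
#' atom's identifier with its (bond-order, neighbor-identifier) pairs in
#' canonical order. Identifiers from all radii 0..\code{radius} are folded
#' onto \code{nbits} bits.
#'
#' @param mol a [Molecule-class].
#' @param nbits fingerprint width (default 2048).
#' @param radius neighborhood radius (default 2; 3 gives larger shells).
#' @return sorted integer vector of set bit positions (0-based), with
#'   attribute \code{nbits}.
#' @export
computeFingerprint <- function(mol, nbits = 2048L, radius = 2L) {
  g <- mol@graph
  atoms <- g$atoms
  n <- nrow(atoms)
  nb <- .neighborList(g)
  bord <- .bondOrderMatrixLookup(g)
  getOrd <- function(i, j) {
    o <- unname(bord[paste(min(i, j), max(i, j), sep = ":")])
    if (is.na(o)) 0L else o
  }
  ids <- vapply(seq_len(n), function(i)
    .hashInts(c(atoms$Z[i], atoms$degree[i], atoms$nH[i],
                atoms$charge[i] + 10L, as.integer(atoms$aromatic[i]),
                as.integer(atoms$inRing[i]))), numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    newIds <- numeric(n)
    for (i in seq_len(n)) {
      if (length(nb[[i]]) == 0) { newIds[i] <- .hashInts(c(r, ids[i])); next }
      pairs <- lapply(nb[[i]], function(j) c(getOrd(i, j), ids[j]))
      ord <- order(vapply(pairs, `[`, numeric(1), 1),
                   vapply(pairs, `[`, numeric(1), 2))
      newIds[i] <- .hashInts(c(r, ids[i], unlist(pairs[ord])))
    }
    ids <- newIds
    all_ids <- c(all_ids, ids)
  }
  bits <- sort(unique(as.integer(all_ids %% nbits)))
  attr(bits, "nbits") <- as.integer(nbits)
  bits
}

#' Tanimoto coefficient between two bitset fingerprints
#'
#' \code{|A & B| / |A | B|}. Two empty fingerprints have similarity 0,
#' flagged via the \code{degenerate} attribute.
#'
#' @param a,b fingerprints from [computeFingerprint()].
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ni <- length(intersect(a, b))
  nu <- length(a) + length(b) - ni
  ni / nu
}

# Descriptor bundle for one molecule, computed once and reused by the
# predictors (SIM/SEA/SAR/MLM feature spaces and the reduced graph for
# subgraph mining).
.descriptorBundle <- function(mol, config) {
  labels <- assignFeatures(mol)
  list(
    fpd = computeFPD(mol, L = config$L, featureSet = config$featureSet),
    shed = computeSHED(mol, L = config$L, featureSet = config$featureSet),
    phrag = computePHRAG(mol, featureSet = config$featureSet),
    fp = computeFingerprint(mol, nbits = config$fpBits, radius = config$fpRadius),
    reduced = .atomLabelStrings(labels, config$featureSet),
    props = .sarGlobalProps(mol)
  )
}

.descriptorSet <- function(mols, config) {
  out <- lapply(mols, .descriptorBundle, config = config)
  names(out) <- vapply(mols, molId, character(1))
  out
}

#' Export a descriptor matrix for a set of molecules
#'
#' One row per molecule: the FPD frequencies, SHED entropies and the global
#' property block used by the QSAR-style methods.
#'
#' @param molecules a [MoleculeSet-class] or list of [Molecule-class].
#' @param config an [otsaConfig()] list.
#' @param path optional TSV output path.
#' @return the matrix, invisibly if \code{path} is given.
#' @export
descriptorMatrix <- function(molecules, config = otsaConfig(), path = NULL) {
  if (is(molecules, "MoleculeSet")) molecules <- molecules@molecules
  rows <- lapply(molecules, function(m) {
    c(computeFPD(m, L = config$L, featureSet = config$featureSet),
      stats::setNames(computeSHED(m, L = config$L, featureSet = config$featureSet),
                      paste0("SHED_", .featurePairs(config$featureSet))),
      .sarGlobalProps(m))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(molecules, molId, character(1))
  if (!is.null(path)) {
    utils::write.table(data.frame(mol_id = rownames(mat), mat,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(mat))
  }
  mat
}
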