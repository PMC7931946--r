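# Feature-pair distribution (FPD) and Shannon-entropy (SHED) descriptors.
# Both are built from the same raw object: counts of pharmacophore feature
# pairs by topological (bond-count) distance, capped at L bonds.

# Raw feature-pair x distance counts. Rows: feature pairs ("A:D", ...),
# columns: distances 1..L (distances beyond L pool into bin L). Same-atom
# feature co-occurrences are excluded (only atom pairs i < j count).
.fpdCounts <- function(mol, L = 10L, featureSet = "six",
                       labels = assignFeatures(mol)) {
  pairs <- .featurePairs(featureSet)
  keep <- .featureUniverse(featureSet)
  counts <- matrix(0, nrow = length(pairs), ncol = L,
                   dimnames = list(pairs, as.character(seq_len(L))))
  n <- mol@atomCount
  if (n >= 2) {
    D <- mol@graph$dist
    for (i in seq_len(n - 1L)) {
      li <- intersect(labels[[i]], keep)
      if (!length(li)) next
      for (j in (i + 1L):n) {
        d <- D[i, j]
        if (!is.finite(d) || d < 1) next
        lj <- intersect(labels[[j]], keep)
        if (!length(lj)) next
        db <- min(d, L)
        for (f in li) for (g in lj) {
          key <- paste(min(f, g), max(f, g), sep = ":")
          counts[key, db] <- counts[key, db] + 1
        }
      }
    }
  }
  counts
}

#' Compute the feature-pair distribution descriptor
#'
#' A fixed-length vector indexed by (feature pair, topological distance bin):
#' for every atom pair i < j at bond distance d and every feature f on i and
#' g on j, bin (\{f,g\}, min(d, L)) is incremented; counts are then
#' normalized to frequencies. A molecule with no labeled atom pair yields the
#' all-zero vector, flagged \code{featureless}.
#'
#' @param mol a [Molecule-class].
#' @param L distance cap in bonds (default 10; overflow pools into bin L).
#' @param featureSet "six" (21 pairs) or "four" (10 pairs).
#' @return named numeric vector of length \code{npairs * L}, entries summing
#'   to 1 unless featureless; attribute \code{featureless} is TRUE/FALSE.
#' @export
computeFPD <- function(mol, L = 10L, featureSet = "six") {
  counts <- .fpdCounts(mol, L = L, featureSet = featureSet)
  v <- as.vector(t(counts))
  names(v) <- as.vector(t(outer(rownames(counts), colnames(counts), paste, sep = "|")))
  tot <- sum(v)
  featureless <- tot == 0
  if (!featureless) v <- v / tot
  attr(v, "featureless") <- featureless
  v
}

#' Compute Shannon-entropy descriptors over feature-pair distance profiles
#'
#' One entropy (nats) per feature pair: with q the pair's distance
#' distribution renormalized over d = 1..L, H = -sum(q log q). An empty or
#' single-distance (point-mass) profile has entropy 0; the maximum is log(L).
#'
#' @inheritParams computeFPD
#' @return named numeric vector, one entry per feature pair, each in
#'   [0, log(L)].
#' @export
computeSHED <- function(mol, L = 10L, featureSet = "six") {
  counts <- .fpdCounts(mol, L = L, featureSet = featureSet)
  apply(counts, 1, function(row) {
    s <- sum(row)
    if (s == 0) return(0)
    q <- row[row > 0] / s
    -sum(q * log(q))
  })
}

#' Euclidean distance between two entropy-descriptor vectors
#'
#' @param a,b equal-length SHED vectors (as from [computeSHED()]).
#' @return non-negative number; 0 iff a == b.
#' @export
shedDistance <- function(a, b) {
  if (length(a) != length(b))
    stop("SHED dimension mismatch: ", length(a), " vs ", length(b))
  sqrt(sum((a - b)^2))
}
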