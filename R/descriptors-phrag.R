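# Pharmacophoric fragments: feature-label sequences read off shortest paths
# of 2..7 atoms, collected as a multiset and compared by multiset Tanimoto.

#' Compute the pharmacophoric fragment multiset
#'
#' For every atom pair at topological distance 1..6 bonds (2..7 atoms), the
#' per-atom feature label strings along every shortest path between them form
#' a fragment. A fragment reads the same regardless of atom numbering: the
#' lexicographically smaller of its two reading directions is stored.
#' Featureless atoms contribute the placeholder label \code{"0"}.
#'
#' @param mol a [Molecule-class].
#' @param featureSet "six" or "four".
#' @return named integer vector: fragment string -> multiplicity.
#' @export
computePHRAG <- function(mol, featureSet = "six") {
  labels <- .atomLabelStrings(assignFeatures(mol), featureSet)
  n <- mol@atomCount
  frags <- character(0)
  if (n >= 2) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(mol@graph$bonds) > 0)
      g <- igraph::add_edges(g, rbind(mol@graph$bonds$from, mol@graph$bonds$to))
    D <- mol@graph$dist
    for (i in seq_len(n - 1L)) {
      targets <- which(D[i, ] >= 1 & D[i, ] <= 6 & seq_len(n) > i)
      if (!length(targets)) next
      asp <- igraph::all_shortest_paths(g, from = i, to = targets)$vpaths
      for (p in asp) {
        idx <- as.integer(p)
        fwd <- paste(labels[idx], collapse = "-")
        rev_ <- paste(labels[rev(idx)], collapse = "-")
        frags <- c(frags, if (fwd <= rev_) fwd else rev_)
      }
    }
  }
  if (!length(frags)) {
    out <- integer(0)
  } else {
    tab <- table(frags)
    out <- stats::setNames(as.integer(tab), names(tab))
  }
  out
}

#' Multiset Tanimoto similarity between two fragment multisets
#'
#' \code{sum(min counts) / sum(max counts)} over the union of fragments.
#' Self-similarity is 1 for any molecule with at least one fragment; a
#' featureless (empty) multiset is defined to have similarity 0 against
#' everything, flagged via the \code{degenerate} attribute.
#'
#' @param a,b fragment multisets from [computePHRAG()].
#' @return similarity in [0, 1].
#' @export
phragSimilarity <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  keys <- union(names(a), names(b))
  av <- stats::setNames(rep(0L, length(keys)), keys); av[names(a)] <- a
  bv <- stats::setNames(rep(0L, length(keys)), keys); bv[names(b)] <- b
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}
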