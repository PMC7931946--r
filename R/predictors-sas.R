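# Similarity-active-subgraph mining. Molecules are reduced to labeled graphs
# (atoms -> pharmacophore label strings, edges -> bonds); per target, the
# miner grows label paths breadth-first from the most frequent labeled edges
# and keeps the smallest paths present in at least fA of the actives and at
# most fB of a size-matched background sample.

# reduced graph = list(labels = character, nb = adjacency list)
.reducedGraph <- function(mol, featureSet = "six") {
  list(labels = .atomLabelStrings(assignFeatures(mol), featureSet),
       nb = .neighborList(mol@graph))
}

# does the reduced graph contain a simple path with this label sequence
# (either reading direction)?
.containsLabelPath <- function(red, labseq) {
  n <- length(red$labels)
  if (length(labseq) > n) return(FALSE)
  dfs <- function(pos, node, used) {
    if (pos == length(labseq)) return(TRUE)
    for (nxt in red$nb[[node]]) {
      if (!used[nxt] && red$labels[nxt] == labseq[pos + 1L]) {
        used[nxt] <- TRUE
        if (dfs(pos + 1L, nxt, used)) return(TRUE)
        used[nxt] <- FALSE
      }
    }
    FALSE
  }
  target <- labseq
  for (dir in 1:2) {
    starts <- which(red$labels == target[1])
    for (s in starts) {
      used <- rep(FALSE, n); used[s] <- TRUE
      if (dfs(1L, s, used)) return(TRUE)
    }
    if (length(labseq) == 1L || identical(labseq, rev(labseq))) break
    target <- rev(labseq)
  }
  FALSE
}

.canonicalSeq <- function(s) {
  fwd <- paste(s, collapse = "-")
  bwd <- paste(rev(s), collapse = "-")
  if (fwd <= bwd) s else rev(s)
}

.seqCoverage <- function(reds, labseq) {
  mean(vapply(reds, .containsLabelPath, logical(1), labseq = labseq))
}

# mine up to maxKeep minimal label paths for one target
.mineSAS <- function(activeReds, bgReds, fA, fB, maxLen = 7L, maxKeep = 3L,
                     frontierCap = 200L) {
  # frequent labeled edges as seeds
  edgeSets <- lapply(activeReds, function(r) {
    e <- character(0)
    for (i in seq_along(r$nb)) for (j in r$nb[[i]]) if (j > i) {
      a <- r$labels[i]; b <- r$labels[j]
      e <- c(e, paste(min(a, b), max(a, b), sep = "\r"))
    }
    unique(e)
  })
  freq <- table(unlist(edgeSets)) / length(activeReds)
  seeds <- names(freq)[freq >= fA]
  if (!length(seeds)) return(list())
  seeds <- seeds[order(-freq[seeds], seeds)]
  frontier <- lapply(strsplit(seeds, "\r", fixed = TRUE), .canonicalSeq)

  labelUniverse <- sort(unique(unlist(lapply(activeReds, `[[`, "labels"))))
  accepted <- list()
  seen <- character(0)
  while (length(frontier) > 0 && length(frontier[[1]]) <= maxLen) {
    keys <- vapply(frontier, paste, character(1), collapse = "-")
    dup <- duplicated(keys) | keys %in% seen
    frontier <- frontier[!dup]; keys <- keys[!dup]
    seen <- c(seen, keys)
    if (!length(frontier)) break
    cov <- vapply(frontier, .seqCoverage, numeric(1), reds = activeReds)
    frontier <- frontier[cov >= fA]; cov <- cov[cov >= fA]
    if (!length(frontier)) break
    bg <- vapply(frontier, .seqCoverage, numeric(1), reds = bgReds)
    hit <- bg <= fB
    for (i in which(hit)) {
      accepted[[length(accepted) + 1L]] <- list(
        labels = frontier[[i]],
        pattern = paste(frontier[[i]], collapse = "-"),
        coverage = cov[i], bgFrac = bg[i],
        specificity = 1 - bg[i])
    }
    if (length(accepted) >= maxKeep) break
    if (length(frontier) > frontierCap) {
      ord <- order(-cov)[seq_len(frontierCap)]
      frontier <- frontier[ord]
    }
    # breadth-first growth: extend every surviving path by one labeled atom
    nxt <- list()
    for (s in frontier) {
      if (length(s) >= maxLen) next
      for (lab in labelUniverse) {
        nxt[[length(nxt) + 1L]] <- .canonicalSeq(c(s, lab))
        nxt[[length(nxt) + 1L]] <- .canonicalSeq(c(lab, s))
      }
    }
    frontier <- nxt
  }
  if (!length(accepted)) return(list())
  ord <- order(vapply(accepted, function(x) length(x$labels), integer(1)),
               vapply(accepted, function(x) x$bgFrac, numeric(1)),
               vapply(accepted, function(x) x$pattern, character(1)))
  accepted[ord][seq_len(min(maxKeep, length(accepted)))]
}
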