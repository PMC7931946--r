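# Pharmacophore feature typing on the heavy-atom graph. Six recognition
# elements: hydrogen-bond donor (D) and acceptor (A), hydrophobe (H),
# aromatic (R), positively (P) and negatively (N) ionizable. An atom may
# carry several labels; labels are a deterministic function of the canonical
# molecule.

.neighborList <- function(graph) {
  n <- nrow(graph$atoms)
  nb <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds$from[k]; j <- graph$bonds$to[k]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

.bondOrderMatrixLookup <- function(graph) {
  # order keyed "i:j" with i<j; aromatic bonds coded 4
  b <- graph$bonds
  if (nrow(b) == 0) return(character(0))
  lo <- pmin(b$from, b$to); hi <- pmax(b$from, b$to)
  ord <- ifelse(b$aromatic, 4L, b$order)
  stats::setNames(ord, paste(lo, hi, sep = ":"))
}

#' Assign pharmacophore feature labels to every atom
#'
#' Pattern table (config-free, minimal): \strong{D} = N or O bearing at least
#' one hydrogen; \strong{A} = any O, or N that is not an amide/nitro nitrogen,
#' not positively charged and not an aromatic N-H; \strong{H} = carbon bonded
#' only to carbons; \strong{R} = aromatic atom; \strong{P} = protonatable
#' nitrogen (non-aromatic, all single bonds, not amide, not bonded to an
#' aromatic atom) or any positively charged N; \strong{N} = acidic oxygen of a
#' carboxylic/sulfonic/phosphonic group (or its deprotonated form).
#'
#' @param mol a [Molecule-class].
#' @return list of character vectors, one per atom, each sorted; possibly
#'   empty (featureless atoms are allowed).
#' @examples
#' assignFeatures(parseMolecule("CCO"))  # O carries D and A; carbons H
#' @export
assignFeatures <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  g <- mol@graph
  atoms <- g$atoms
  n <- nrow(atoms)
  nb <- .neighborList(g)
  bord <- .bondOrderMatrixLookup(g)
  getOrd <- function(i, j) unname(bord[paste(min(i, j), max(i, j), sep = ":")])

  el <- atoms$element
  isAmideN <- function(i) {
    # N bonded to a carbon that is double-bonded to O or S
    any(vapply(nb[[i]], function(j) {
      el[j] == "C" && any(vapply(nb[[j]], function(k)
        k != i && el[k] %in% c("O", "S") && identical(getOrd(j, k), 2L),
        logical(1)))
    }, logical(1)))
  }
  isNitroN <- function(i) {
    os <- nb[[i]][el[nb[[i]]] == "O"]
    length(os) >= 2 && any(vapply(os, function(k)
      identical(getOrd(i, k), 2L) || atoms$charge[k] < 0, logical(1)))
  }
  isAcidO <- function(i) {
    if (el[i] != "O") return(FALSE)
    if (atoms$nH[i] < 1 && atoms$charge[i] >= 0) return(FALSE)
    any(vapply(nb[[i]], function(j) {
      el[j] %in% c("C", "S", "P") &&
        any(vapply(nb[[j]], function(k)
          k != i && el[k] == "O" && identical(getOrd(j, k), 2L), logical(1)))
    }, logical(1)))
  }

  labels <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- character(0)
    if (atoms$aromatic[i]) lab <- c(lab, "R")
    if (el[i] == "C" && (length(nb[[i]]) == 0 || all(el[nb[[i]]] == "C")))
      lab <- c(lab, "H")
    if (el[i] %in% c("N", "O") && atoms$nH[i] >= 1)
      lab <- c(lab, "D")
    if (el[i] == "O") {
      lab <- c(lab, "A")
    } else if (el[i] == "N" && atoms$charge[i] <= 0 &&
               !isAmideN(i) && !isNitroN(i) &&
               !(atoms$aromatic[i] && atoms$nH[i] >= 1)) {
      lab <- c(lab, "A")
    }
    if (el[i] == "N") {
      allSingle <- length(nb[[i]]) == 0 ||
        all(vapply(nb[[i]], function(j) identical(getOrd(i, j), 1L), logical(1)))
      protonatable <- !atoms$aromatic[i] && allSingle && !isAmideN(i) &&
        !isNitroN(i) &&
        (length(nb[[i]]) == 0 || !any(atoms$aromatic[nb[[i]]]))
      if (atoms$charge[i] > 0 || protonatable) lab <- c(lab, "P")
    }
    if (isAcidO(i)) lab <- c(lab, "N")
    labels[[i]] <- sort(unique(lab))
  }
  labels
}

.featureUniverse <- function(featureSet = "six") {
  if (featureSet == "four") c("A", "D", "H", "R") else c("A", "D", "H", "N", "P", "R")
}

.featurePairs <- function(featureSet = "six") {
  f <- .featureUniverse(featureSet)
  pairs <- character(0)
  for (i in seq_along(f)) for (j in i:length(f))
    pairs <- c(pairs, paste(f[i], f[j], sep = ":"))
  pairs
}

# Per-atom label string used by the reduced graphs of the subgraph miner and
# by pharmacophore fragments; "0" marks a featureless atom.
.atomLabelStrings <- function(labels, featureSet = "six") {
  keep <- .featureUniverse(featureSet)
  vapply(labels, function(l) {
    l <- intersect(l, keep)
    if (length(l) == 0) "0" else paste(sort(l), collapse = "")
  }, character(1))
}
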