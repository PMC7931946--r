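# OpenBabel access layer. ChemmineOB ships the full SWIG bindings but exports
# only a file-oriented surface, so the string-level calls go through its
# namespace directly. Everything downstream of this file works on the plain
# heavy-atom graph extracted here.

.obns <- local({
  ns <- NULL
  function() {
    if (is.null(ns)) ns <<- asNamespace("ChemmineOB")
    ns
  }
})

# Parse a single SMILES into an OBMol reference, or NULL if unparseable.
.obRead <- function(smiles, format = "smi") {
  ob <- .obns()
  conv <- ob$OBConversion()
  if (!ob$OBConversion_SetInFormat(conv, format)) stop("openbabel: bad format ", format)
  mol <- ob$OBMol()
  ok <- tryCatch(ob$OBConversion_ReadString(conv, mol, smiles),
                 error = function(e) FALSE)
  if (!isTRUE(ok) || ob$OBMol_NumAtoms(mol) < 1) return(NULL)
  mol
}

# Canonical SMILES; "i" drops stereo and isotope annotations on output.
.obCanonicalSmiles <- function(mol, stripStereo = TRUE) {
  ob <- .obns()
  conv <- ob$OBConversion()
  ob$OBConversion_SetOutFormat(conv, "can")
  if (stripStereo)
    ob$OBConversion_AddOption(conv, "i", ob$OBConversion_OUTOPTIONS_get(), "")
  out <- ob$OBConversion_WriteString(conv, mol)
  sub("[[:space:]].*$", "", sub("^[[:space:]]+", "", out))
}

.ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na",
  "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr",
  "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe")

.elementSymbol <- function(z) {
  ifelse(z >= 1 & z <= length(.ELEMENTS), .ELEMENTS[pmax(z, 1)], paste0("Z", z))
}

# Extract the heavy-atom graph (atom table, bond table) from an OBMol parsed
# without explicit hydrogens: implicit H counts live on the atoms.
.obGraph <- function(mol) {
  ob <- .obns()
  n <- ob$OBMol_NumAtoms(mol)
  z <- integer(n); arom <- logical(n); chg <- integer(n)
  nh <- integer(n); ring <- logical(n); hyb <- integer(n); deg <- integer(n)
  for (i in seq_len(n)) {
    a <- ob$OBMol_GetAtom(mol, i)
    z[i] <- ob$OBAtom_GetAtomicNum(a)
    arom[i] <- ob$OBAtom_IsAromatic(a)
    chg[i] <- ob$OBAtom_GetFormalCharge(a)
    nh[i] <- ob$OBAtom_GetImplicitHCount(a) + ob$OBAtom_ExplicitHydrogenCount(a)
    ring[i] <- ob$OBAtom_IsInRing(a)
    hyb[i] <- ob$OBAtom_GetHyb(a)
    deg[i] <- ob$OBAtom_GetHvyDegree(a)
  }
  nb <- ob$OBMol_NumBonds(mol)
  from <- integer(nb); to <- integer(nb); ord <- integer(nb)
  barom <- logical(nb); bring <- logical(nb)
  if (nb > 0) for (i in seq_len(nb)) {
    b <- ob$OBMol_GetBond(mol, i - 1L)
    from[i] <- ob$OBBond_GetBeginAtomIdx(b)
    to[i] <- ob$OBBond_GetEndAtomIdx(b)
    ord[i] <- ob$OBBond_GetBondOrder(b)
    barom[i] <- ob$OBBond_IsAromatic(b)
    bring[i] <- ob$OBBond_IsInRing(b)
  }
  list(
    atoms = data.frame(
      element = .elementSymbol(z), Z = z, aromatic = arom, charge = chg,
      nH = nh, inRing = ring, hyb = hyb, degree = deg,
      stringsAsFactors = FALSE),
    bonds = data.frame(from = from, to = to, order = ord,
                       aromatic = barom, inRing = bring)
  )
}

.obDescriptor <- function(mol, name) {
  ob <- .obns()
  d <- ob$OBDescriptor_FindType(name)
  ob$OBDescriptor_Predict(d, mol)
}

# Topological (bond-count) distance matrix via breadth-first search.
.topoDistances <- function(nAtoms, bonds) {
  g <- igraph::make_empty_graph(n = nAtoms, directed = FALSE)
  if (nrow(bonds) > 0)
    g <- igraph::add_edges(g, rbind(bonds$from, bonds$to))
  d <- igraph::distances(g)
  storage.mode(d) <- "double"
  d
}

#' Canonicalize a SMILES string
#'
#' Returns the canonical SMILES of the largest fragment with stereochemistry
#' and isotope labels removed. The mapping is idempotent and independent of
#' input atom ordering, so any two SMILES denoting the same 2-D graph —
#' including enantiomer pairs — collapse to one canonical form.
#'
#' @param smiles a single SMILES string.
#' @return canonical stereo-stripped SMILES (character scalar).
#' @examples
#' canonicalize("OCC") == canonicalize("CCO")
#' canonicalize("C[C@@H](N)C(=O)O") == canonicalize("C[C@H](N)C(=O)O")
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- .obRead(smiles)
  if (is.null(mol))
    stop("unparseable SMILES: '", smiles, "'")
  .obns()$OBMol_StripSalts(mol, 0L)
  .obCanonicalSmiles(mol, stripStereo = TRUE)
}

#' Parse a SMILES string into a Molecule
#'
#' Canonicalizes (largest fragment, stereo and isotopes stripped), then
#' re-parses the canonical form so the stored heavy-atom graph is a pure
#' function of the canonical SMILES: every descriptor computed downstream is
#' invariant to the input's atom order and stereo annotations by construction.
#'
#' @param smiles a single SMILES string.
#' @param molId identifier to attach.
#' @return a [Molecule-class] object.
#' @export
parseMolecule <- function(smiles, molId = "mol") {
  can <- canonicalize(smiles)
  mol <- .obRead(can)
  if (is.null(mol)) stop("internal: canonical SMILES failed to re-parse: ", can)
  graph <- .obGraph(mol)
  graph$dist <- .topoDistances(nrow(graph$atoms), graph$bonds)
  graph$mw <- .obns()$OBMol_GetMolWt(mol)
  graph$tpsa <- .obDescriptor(mol, "TPSA")
  graph$logp <- .obDescriptor(mol, "logP")
  new("Molecule",
      molId = as.character(molId),
      smilesInput = smiles,
      smilesCanonical = can,
      atomCount = nrow(graph$atoms),
      graph = graph)
}
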