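#' @import methods
NULL

#' Molecule: a parsed, canonicalized 2-D chemical structure
#'
#' Holds the canonical stereo-stripped SMILES together with the heavy-atom
#' graph used by every descriptor. Stereo descriptors and isotopes are removed
#' before canonicalization, so the two enantiomers of a chiral compound map to
#' the same \code{Molecule} — the whole framework is deliberately 2-D and
#' stereo-blind. Salts and mixtures are reduced to their largest fragment at
#' parse time.
#'
#' @slot molId character identifier.
#' @slot smilesInput the SMILES string as supplied.
#' @slot smilesCanonical canonical stereo-stripped SMILES of the largest fragment.
#' @slot atomCount heavy-atom count (implicit hydrogens are never vertices).
#' @slot graph internal list: \code{atoms} and \code{bonds} data frames, the
#'   topological distance matrix \code{dist}, and cached whole-molecule
#'   properties (\code{mw}, \code{tpsa}, \code{logp}).
#' @exportClass Molecule
setClass("Molecule",
  representation(
    molId = "character",
    smilesInput = "character",
    smilesCanonical = "character",
    atomCount = "integer",
    graph = "list"
  )
)

setValidity("Molecule", function(object) {
  msg <- character()
  if (length(object@molId) != 1L || !nzchar(object@molId))
    msg <- c(msg, "molId must be a single non-empty string")
  if (object@atomCount < 1L)
    msg <- c(msg, "atomCount must be >= 1")
  if (!all(c("atoms", "bonds", "dist") %in% names(object@graph)))
    msg <- c(msg, "graph must contain atoms, bonds and dist")
  if (length(msg)) msg else TRUE
})

#' MoleculeSet: an ordered collection of molecules plus its parse report
#'
#' Returned by [readMoleculeTable()]. Unparseable records are never silently
#' dropped: each appears in the parse report with its line (or record) number
#' and the reason it was skipped.
#'
#' @slot molecules list of [Molecule-class] objects, in file order.
#' @slot parseReport data.frame with columns \code{line}, \code{input},
#'   \code{status}, \code{note}.
#' @exportClass MoleculeSet
setClass("MoleculeSet",
  representation(molecules = "list", parseReport = "data.frame")
)

setValidity("MoleculeSet", function(object) {
  if (!all(vapply(object@molecules, is, logical(1), "Molecule")))
    return("all elements must be Molecule objects")
  ids <- vapply(object@molecules, function(m) m@molId, character(1))
  if (anyDuplicated(ids)) return("duplicate mol_id in MoleculeSet")
  TRUE
})

#' ReferenceDatabase: the chemogenomics training corpus
#'
#' Per-target active (and optional inactive) ligand sets over a deduplicated
#' compound table. Compounds are deduplicated by canonical SMILES (first id
#' wins; later ids are recorded as aliases). Targets left with no actives
#' after loading are dropped.
#'
#' @slot compounds named list of [Molecule-class], keyed by mol_id.
#' @slot targets data.frame with columns \code{target_id}, \code{target_family}.
#' @slot actives named list: target_id -> character vector of active mol_ids.
#' @slot inactives named list: target_id -> character vector of inactive mol_ids.
#' @slot interactions data.frame: \code{mol_id}, \code{target_id},
#'   \code{label}, \code{potency_uM}.
#' @slot aliases named character: duplicate id -> retained id.
#' @exportClass ReferenceDatabase
setClass("ReferenceDatabase",
  representation(
    compounds = "list",
    targets = "data.frame",
    actives = "list",
    inactives = "list",
    interactions = "data.frame",
    aliases = "character"
  )
)

setValidity("ReferenceDatabase", function(object) {
  msg <- character()
  tids <- object@targets$target_id
  if (!setequal(names(object@actives), tids))
    msg <- c(msg, "actives must be keyed by the target table")
  if (any(lengths(object@actives[tids]) == 0L))
    msg <- c(msg, "every retained target must have >= 1 active")
  for (t in tids) {
    if (length(intersect(object@actives[[t]], object@inactives[[t]])))
      msg <- c(msg, paste0("target ", t, ": actives and inactives overlap"))
  }
  bad <- setdiff(object@interactions$mol_id, names(object@compounds))
  if (length(bad))
    msg <- c(msg, paste0("interactions reference unknown compounds: ",
                         paste(head(bad, 5), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' TruthTable: known (compound, target) interactions from prior evidence
#'
#' Used to split consensus-passing predictions into previously confirmed and
#' genuinely new interactions. Duplicate pairs collapse at load time.
#'
#' @slot pairs data.frame with columns \code{mol_id}, \code{target_id},
#'   \code{source}.
#' @exportClass TruthTable
setClass("TruthTable", representation(pairs = "data.frame"))

setValidity("TruthTable", function(object) {
  key <- paste(object@pairs$mol_id, object@pairs$target_id)
  if (anyDuplicated(key)) return("duplicate (mol_id, target_id) pairs")
  TRUE
})

#' ExpressionMatrix: target expression across tissues
#'
#' A non-negative target-by-tissue matrix (TPM-like units, taken as given)
#' used to retain only predicted off-targets expressed in a tissue of
#' interest.
#'
#' @slot values numeric matrix, rownames = target ids, colnames = tissues.
#' @slot species character.
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(values = "matrix", species = "character")
)

setValidity("ExpressionMatrix", function(object) {
  if (any(object@values < 0)) return("expression values must be >= 0")
  if (anyDuplicated(colnames(object@values))) return("tissue names must be unique")
  TRUE
})

#' MethodModel: one fitted ligand-centric target-prediction method
#'
#' @slot methodId one of SAS, SAR, SIM, SEA, MLM, XPI.
#' @slot state method-specific fitted state.
#' @slot dbFingerprint hash of the reference database the model was fitted on.
#' @slot seed integer seed used for any stochastic fitting step.
#' @exportClass MethodModel
setClass("MethodModel",
  representation(
    methodId = "character",
    state = "list",
    dbFingerprint = "character",
    seed = "integer"
  )
)

setValidity("MethodModel", function(object) {
  if (!object@methodId %in% c("SAS", "SAR", "SIM", "SEA", "MLM", "XPI"))
    return("unknown methodId")
  TRUE
})

#' OTSAModel: the six fitted methods over one reference database
#'
#' @slot db the [ReferenceDatabase-class] the methods were fitted on.
#' @slot methods named list of [MethodModel-class] (SAS, SAR, SIM, SEA, MLM, XPI).
#' @slot config the configuration list used ([otsaConfig()]).
#' @slot descriptors cached per-compound descriptor tables for the database.
#' @exportClass OTSAModel
setClass("OTSAModel",
  representation(
    db = "ReferenceDatabase",
    methods = "list",
    config = "list",
    descriptors = "list"
  )
)

#' GroundTruth: planted interactions and withheld queries of a synthetic run
#'
#' @slot interactions data.frame with columns \code{mol_id},
#'   \code{target_id}, \code{kind} (primary or planted_off_target).
#' @slot withheld data.frame with columns \code{mol_id}, \code{smiles} — the
#'   query compounds never emitted into the reference database.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(interactions = "data.frame", withheld = "data.frame")
)

setValidity("GroundTruth", function(object) {
  bad <- setdiff(object@interactions$kind,
                 c("primary", "planted_off_target"))
  if (length(bad)) return("unknown interaction kind")
  key <- paste(object@interactions$mol_id, object@interactions$target_id)
  if (anyDuplicated(key)) return("duplicate ground-truth pairs")
  TRUE
})

#' OTSAReport: ranked predictions plus cohort summary arithmetic
#'
#' @slot predictions data.frame of consensus-passing interaction predictions
#'   (one row per compound-target pair), ranked within compound.
#' @slot summary list of cohort statistics (totals, provenance split,
#'   per-method coverage, all-six fraction, mean interactions per compound).
#' @exportClass OTSAReport
setClass("OTSAReport",
  representation(predictions = "data.frame", summary = "list")
)
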