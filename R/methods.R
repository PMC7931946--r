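#' @rdname Molecule-class
#' @export
setMethod("molId", "Molecule", function(x) x@molId)

#' @rdname Molecule-class
#' @export
setMethod("smiles", "Molecule", function(x) x@smilesCanonical)

#' @rdname Molecule-class
#' @export
setMethod("atomCount", "Molecule", function(x) x@atomCount)

setMethod("show", "Molecule", function(object) {
  cat("Molecule", object@molId, ":", object@smilesCanonical,
      sprintf("(%d heavy atoms)\n", object@atomCount))
})

#' @rdname MoleculeSet-class
#' @export
setMethod("molId", "MoleculeSet", function(x)
  vapply(x@molecules, function(m) m@molId, character(1)))

#' @rdname MoleculeSet-class
#' @export
setMethod("smiles", "MoleculeSet", function(x)
  vapply(x@molecules, function(m) m@smilesCanonical, character(1)))

#' @rdname MoleculeSet-class
#' @export
setMethod("parseReport", "MoleculeSet", function(x) x@parseReport)

#' @rdname MoleculeSet-class
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@molecules))

#' @rdname MoleculeSet-class
#' @param i index.
#' @export
setMethod("[[", "MoleculeSet", function(x, i) x@molecules[[i]])

setMethod("show", "MoleculeSet", function(object) {
  skipped <- sum(object@parseReport$status == "skipped")
  cat("MoleculeSet with", length(object@molecules), "molecules",
      sprintf("(%d record(s) skipped at parse)\n", skipped))
})

#' @rdname ReferenceDatabase-class
#' @export
setMethod("targetIds", "ReferenceDatabase", function(x) x@targets$target_id)

#' @rdname ReferenceDatabase-class
#' @param target a target id.
#' @export
setMethod("activeLigands", "ReferenceDatabase", function(x, target) {
  if (!target %in% names(x@actives)) stop("unknown target: ", target)
  x@actives[[target]]
})

setMethod("show", "ReferenceDatabase", function(object) {
  cat("ReferenceDatabase:", length(object@compounds), "compounds,",
      nrow(object@targets), "targets,",
      nrow(object@interactions), "interactions\n")
  fam <- table(object@targets$target_family)
  cat("  families:", paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MethodModel", function(object) {
  cat("MethodModel", object@methodId, "fitted on db",
      substr(object@dbFingerprint, 1, 8), "\n")
})

setMethod("show", "OTSAModel", function(object) {
  cat("OTSAModel with methods:", paste(names(object@methods), collapse = ", "), "\n")
  show(object@db)
})

#' @rdname OTSAReport-class
#' @export
setMethod("predictions", "OTSAReport", function(x) x@predictions)

#' @rdname OTSAReport-class
#' @export
setMethod("cohortSummary", "OTSAReport", function(x) x@summary)

setMethod("show", "OTSAReport", function(object) {
  s <- object@summary
  cat("OTSAReport:", s$n_compounds, "compounds,",
      s$total_interactions, "consensus interactions",
      sprintf("(training %d / confirmed %d / new %d), %.1f per compound\n",
              s$training_set, s$confirmed, s$new,
              s$mean_interactions_per_compound))
})
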