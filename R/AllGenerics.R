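#' @rdname Molecule-class
#' @param object,x an object.
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))

#' @rdname Molecule-class
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @rdname Molecule-class
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname MoleculeSet-class
#' @export
setGeneric("parseReport", function(x) standardGeneric("parseReport"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("activeLigands", function(x, target) standardGeneric("activeLigands"))

#' @rdname OTSAReport-class
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname OTSAReport-class
#' @export
setGeneric("cohortSummary", function(x) standardGeneric("cohortSummary"))
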