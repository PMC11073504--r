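#' @rdname AbundanceMatrix-class
#' @param x an object.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname GeneSetCollection-class
#' @param x an object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' @rdname GrowthTable-class
#' @param x an object.
#' @export
setGeneric("divisionRate", function(x) standardGeneric("divisionRate"))

#' @rdname GrowthTable-class
#' @export
setGeneric("inhibition", function(x) standardGeneric("inhibition"))

#' @rdname CorrelationMatrix-class
#' @param x an object.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname TaskStats-class
#' @param x an object.
#' @export
setGeneric("deltaTable", function(x) standardGeneric("deltaTable"))

#' @rdname TaskStats-class
#' @export
setGeneric("rangeTable", function(x) standardGeneric("rangeTable"))

#' @rdname TaskStats-class
#' @export
setGeneric("signConvention", function(x) standardGeneric("signConvention"))

#' @rdname SyntheticTruth-class
#' @param x an object.
#' @export
setGeneric("deltaProxy", function(x) standardGeneric("deltaProxy"))
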