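#' Construct a GrowthTable
#'
#' @param divisionRate named numeric vector of per-cell nominal division
#'   rates (names are the cell identifiers).
#' @param inhibition optional cells x drugs numeric matrix of maximum growth
#'   inhibition values; missing measurements are `NA` and are never imputed.
#'   Row names must equal the cells of `divisionRate`.
#'
#' @return a \linkS4class{GrowthTable}.
#' @export
GrowthTable <- function(divisionRate, inhibition = NULL) {
    divisionRate <- unlist(divisionRate)
    if (is.null(inhibition)) {
        inhibition <- matrix(numeric(0), nrow = length(divisionRate), ncol = 0,
                             dimnames = list(names(divisionRate), NULL))
    }
    inhibition <- as.matrix(inhibition)
    storage.mode(inhibition) <- "double"
    new("GrowthTable", divisionRate = divisionRate, inhibition = inhibition)
}

#' @rdname GrowthTable-class
#' @aliases divisionRate inhibition
#' @export
setMethod("divisionRate", "GrowthTable", function(x) x@divisionRate)

#' @rdname GrowthTable-class
#' @export
setMethod("inhibition", "GrowthTable", function(x) x@inhibition)

#' @rdname GrowthTable-class
#' @export
setMethod("cellIds", "GrowthTable", function(x) names(x@divisionRate))

setMethod("show", "GrowthTable", function(object) {
    cat(sprintf("GrowthTable: %d cells, %d drugs (%d missing inhibition values)\n",
                length(object@divisionRate), ncol(object@inhibition),
                sum(is.na(object@inhibition))))
})
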