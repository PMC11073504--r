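#' Construct an AbundanceMatrix
#'
#' Wraps a genes x cells matrix of non-negative abundances (RPKM-like for
#' mRNA, MS-intensity-like for protein) into a validated
#' \linkS4class{AbundanceMatrix}.
#'
#' @param values numeric matrix, genes in rows (row names = gene identifiers),
#'   cells in columns (column names = cell identifiers). All values must be
#'   finite and non-negative.
#' @param modality `"mRNA"` or `"protein"`.
#'
#' @return an \linkS4class{AbundanceMatrix}.
#' @examples
#' m <- matrix(c(1, 2, 4, 2, 2, 5), nrow = 3,
#'             dimnames = list(c("TP53", "MYC", "EGFR"), c("CL01", "CL02")))
#' am <- AbundanceMatrix(m, "mRNA")
#' geneIds(am)
#' @export
AbundanceMatrix <- function(values, modality = c("mRNA", "protein")) {
    modality <- match.arg(modality)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(assays = list(abundance = values))
    new("AbundanceMatrix", se, modality = modality)
}

#' @rdname AbundanceMatrix-class
#' @aliases modality geneIds cellIds abundances
#' @export
setMethod("modality", "AbundanceMatrix", function(x) x@modality)

#' @rdname AbundanceMatrix-class
#' @export
setMethod("geneIds", "AbundanceMatrix", function(x) rownames(x))

#' @rdname AbundanceMatrix-class
#' @export
setMethod("cellIds", "AbundanceMatrix", function(x) colnames(x))

#' @rdname AbundanceMatrix-class
#' @export
setMethod("abundances", "AbundanceMatrix",
    function(x) assay(x, "abundance"))

setMethod("show", "AbundanceMatrix", function(object) {
    cat(sprintf("AbundanceMatrix (%s): %d genes x %d cells\n",
                object@modality, nrow(object), ncol(object)))
    v <- assay(object, "abundance")
    cat(sprintf("  abundance range: [%.3g, %.3g]\n", min(v), max(v)))
    cat("  cells:", paste(head(colnames(object), 5), collapse = ", "),
        if (ncol(object) > 5) "..." else "", "\n")
})
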