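## Central S4 classes. Validity methods enforce the structural invariants the
## analysis relies on; constructors live next to the accessors in the
## per-class files.

#' AbundanceMatrix: genes x cells abundances for one modality
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay named `"abundance"` (non-negative, finite, RPKM-like for mRNA or
#' MS-intensity-like for protein) with unique gene row names and cell column
#' names, plus the modality label.
#'
#' @slot modality either `"mRNA"` or `"protein"`.
#' @export
setClass("AbundanceMatrix",
    contains = "SummarizedExperiment",
    representation(modality = "character"))

setValidity("AbundanceMatrix", function(object) {
    msg <- character()
    if (length(object@modality) != 1L ||
        !object@modality %in% c("mRNA", "protein"))
        msg <- c(msg, "modality must be one of 'mRNA', 'protein'")
    if (!"abundance" %in% assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    if (nrow(object) < 1L || ncol(object) < 1L)
        msg <- c(msg, "at least one gene and one cell are required")
    gid <- rownames(object); cid <- colnames(object)
    if (is.null(gid) || anyDuplicated(gid) || any(!nzchar(gid)))
        msg <- c(msg, "gene identifiers must be unique and non-empty")
    if (is.null(cid) || anyDuplicated(cid) || any(!nzchar(cid)))
        msg <- c(msg, "cell identifiers must be unique and non-empty")
    if ("abundance" %in% assayNames(object)) {
        v <- assay(object, "abundance")
        if (!is.numeric(v) || any(!is.finite(v)))
            msg <- c(msg, "abundances must be finite numbers")
        else if (any(v < 0))
            msg <- c(msg, "abundances must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' GeneSetCollection: named gene sets over a gene universe
#'
#' @slot sets named list of character vectors (unique, non-empty members).
#' @slot universe character vector of all gene identifiers the sets are
#'   defined over (at least the union of the members).
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    s <- object@sets
    if (length(s)) {
        if (is.null(names(s)) || anyDuplicated(names(s)) ||
            any(!nzchar(names(s))))
            msg <- c(msg, "set names must be unique and non-empty")
        if (!all(vapply(s, is.character, logical(1))))
            msg <- c(msg, "set members must be character vectors")
        else {
            if (any(vapply(s, length, integer(1)) < 1L))
                msg <- c(msg, "every set must have at least one member")
            if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
                msg <- c(msg, "set members must be deduplicated")
            if (!all(unlist(s, use.names = FALSE) %in% object@universe))
                msg <- c(msg, "all members must belong to the universe")
        }
    }
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe must not contain duplicates")
    if (length(msg)) msg else TRUE
})

#' GrowthTable: per-cell division rates and cells x drugs growth inhibition
#'
#' @slot divisionRate named numeric, one nominal division rate per cell.
#' @slot inhibition numeric matrix (cells x drugs) of maximum growth
#'   inhibition values; missing measurements stay `NA`, never imputed.
#' @export
setClass("GrowthTable",
    representation(divisionRate = "numeric", inhibition = "matrix"))

setValidity("GrowthTable", function(object) {
    msg <- character()
    cid <- names(object@divisionRate)
    if (is.null(cid) || anyDuplicated(cid) || any(!nzchar(cid)))
        msg <- c(msg, "cell identifiers must be unique and non-empty")
    if (any(!is.finite(object@divisionRate)))
        msg <- c(msg, "division rates must be finite")
    inh <- object@inhibition
    if (length(inh)) {
        if (!identical(rownames(inh), cid))
            msg <- c(msg, "inhibition rows must match the division-rate cells")
        if (is.null(colnames(inh)) || anyDuplicated(colnames(inh)))
            msg <- c(msg, "drug identifiers must be unique")
        if (!is.numeric(inh) || any(is.infinite(inh)))
            msg <- c(msg, "inhibition values must be numeric (NA allowed)")
    }
    if (length(msg)) msg else TRUE
})

#' CorrelationMatrix: cells x cells mRNA-protein correlations
#'
#' Entry (i, j) is the correlation of cell i's mRNA profile with cell j's
#' protein profile over the shared genes; the diagonal holds the "same cell"
#' correlations. Entries from constant profiles are `NA` (flagged undefined,
#' never silently zero).
#'
#' @slot values numeric matrix in \[-1, 1\] (or `NA`).
#' @slot method `"pearson"` or `"spearman"`.
#' @slot nGenesUsed number of shared genes the correlations are based on.
#' @export
setClass("CorrelationMatrix",
    representation(values = "matrix", method = "character",
                   nGenesUsed = "integer"))

setValidity("CorrelationMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    else if (any(abs(v) > 1 + 1e-8, na.rm = TRUE))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (!object@method %in% c("pearson", "spearman"))
        msg <- c(msg, "method must be 'pearson' or 'spearman'")
    if (length(msg)) msg else TRUE
})

#' RankedList: one cell's gene products ordered by abundance
#'
#' @slot cellId,modality identifiers of the profile the ranking came from.
#' @slot genes gene identifiers in descending abundance order (ties broken
#'   by ascending gene identifier, deterministically).
#' @slot scores abundances aligned to `genes`, non-increasing.
#' @export
setClass("RankedList",
    representation(cellId = "character", modality = "character",
                   genes = "character", scores = "numeric"))

setValidity("RankedList", function(object) {
    msg <- character()
    if (length(object@genes) != length(object@scores))
        msg <- c(msg, "genes and scores must be aligned")
    if (length(object@genes) < 3L)
        msg <- c(msg, "a ranked list needs at least 3 genes")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "genes must be unique")
    if (is.unsorted(-object@scores))
        msg <- c(msg, "scores must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' CohortParams: parameters of the synthetic paired cohort
#'
#' See [cohortParams()] for the meaning, units and defaults of each field.
#' @export
setClass("CohortParams",
    representation(
        nCells = "integer", nGenes = "integer", nHallmarks = "integer",
        hallmarkSizes = "integer",
        couplingHallmark = "numeric", couplingBackground = "numeric",
        transcriptionOffset = "numeric", offsetSd = "numeric",
        translationSelectivity = "numeric",
        divisionSlope = "numeric", divisionIntercept = "numeric",
        divisionNoiseSd = "numeric",
        nDrugs = "integer",
        muMean = "numeric", muSd = "numeric", noiseSdRange = "numeric",
        proteinBaseline = "numeric",
        seed = "integer"))

setValidity("CohortParams", function(object) {
    bad <- function(x) length(x) != 1L || !is.finite(x)
    msg <- character()
    for (f in c("nCells", "nGenes", "nHallmarks", "nDrugs"))
        if (bad(slot(object, f)) || slot(object, f) < 1L)
            msg <- c(msg, sprintf("%s must be a count >= 1", f))
    for (f in c("couplingHallmark", "couplingBackground"))
        if (bad(slot(object, f)) || slot(object, f) < 0 ||
            slot(object, f) > 1)
            msg <- c(msg, sprintf("%s must lie in [0, 1]", f))
    if (!length(msg) && object@couplingHallmark < object@couplingBackground)
        msg <- c(msg, "couplingHallmark must be >= couplingBackground")
    if (bad(object@translationSelectivity) ||
        object@translationSelectivity < 0 || object@translationSelectivity > 1)
        msg <- c(msg, "translationSelectivity must lie in [0, 1]")
    if (length(object@hallmarkSizes) != object@nHallmarks)
        msg <- c(msg, "hallmarkSizes must have one entry per hallmark")
    else if (any(object@hallmarkSizes < 1L) ||
             any(object@hallmarkSizes > object@nGenes))
        msg <- c(msg, "hallmarkSizes must lie in [1, nGenes]")
    for (f in c("offsetSd", "divisionNoiseSd", "muSd"))
        if (bad(slot(object, f)) || slot(object, f) < 0)
            msg <- c(msg, sprintf("%s must be a non-negative number", f))
    if (length(object@noiseSdRange) != 2L ||
        any(object@noiseSdRange < 0) || diff(object@noiseSdRange) < 0)
        msg <- c(msg, "noiseSdRange must be an increasing pair of non-negative numbers")
    if (bad(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: generating parameters behind one synthetic cohort
#'
#' @slot geneCoupling named numeric, the per-gene target same-cell Pearson
#'   correlation between the log mRNA and log protein abundances.
#' @slot setOffsets hallmarks x cells matrix of transcription offsets (log2).
#' @slot affectedSets names of the hallmarks whose transcription offset is
#'   not propagated to the protein side (the decoupled "tasks").
#' @slot divisionSlope,divisionIntercept the linear division-rate model.
#' @slot seed master seed used for generation.
#' @export
setClass("SyntheticTruth",
    representation(geneCoupling = "numeric", setOffsets = "matrix",
                   affectedSets = "character", divisionSlope = "numeric",
                   divisionIntercept = "numeric", seed = "integer"))

#' TaskStats: enrichment difference and range statistics
#'
#' @slot delta data.frame with columns `cell_id`, `set_name`, `nes_mrna`,
#'   `nes_protein`, `delta` (the signed NES difference under the stated
#'   convention).
#' @slot range data.frame with columns `cell_id`, `modality`, `range`
#'   (max NES - min NES over the hallmarks of that ranked list).
#' @slot signConvention `"mrna_minus_protein"` or `"protein_minus_mrna"`.
#' @export
setClass("TaskStats",
    representation(delta = "data.frame", range = "data.frame",
                   signConvention = "character"))

setValidity("TaskStats", function(object) {
    msg <- character()
    if (!object@signConvention %in%
        c("mrna_minus_protein", "protein_minus_mrna"))
        msg <- c(msg, "unknown sign convention")
    need <- c("cell_id", "set_name", "delta")
    if (!all(need %in% names(object@delta)))
        msg <- c(msg, "delta table must have cell_id, set_name, delta")
    if (!all(c("cell_id", "modality", "range") %in% names(object@range)))
        msg <- c(msg, "range table must have cell_id, modality, range")
    else if (any(object@range$range < 0, na.rm = TRUE))
        msg <- c(msg, "ranges must be non-negative")
    if (length(msg)) msg else TRUE
})
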