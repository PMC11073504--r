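## TSV / GMT readers and writers. All files are tab-delimited UTF-8 with '.'
## as the decimal mark; gene identifiers are matched by exact string equality
## after whitespace trimming (no symbol/alias resolution).

#' Read an abundance matrix from TSV
#'
#' Expects a header row of cell identifiers with a leading `gene_id` column.
#' Genes containing any non-numeric entry are dropped with a logged count;
#' duplicated gene identifiers, negative values and empty matrices are
#' format errors.
#'
#' @param path path to a tab-delimited file.
#' @param modality `"mRNA"` or `"protein"`.
#' @return an \linkS4class{AbundanceMatrix}.
#' @seealso [writeAbundance()]
#' @export
readAbundance <- function(path, modality = c("mRNA", "protein")) {
    modality <- match.arg(modality)
    if (!file.exists(path))
        stop("abundance file not found: ", path, call. = FALSE)
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", quote = "")
    if (nrow(raw) == 0L || ncol(raw) < 2L)
        stop("empty abundance matrix in ", path, call. = FALSE)
    genes <- trimws(raw[[1L]])
    if (anyDuplicated(genes))
        stop(sprintf("duplicate gene ID '%s' in %s",
                     genes[duplicated(genes)][1L], path), call. = FALSE)
    cells <- trimws(colnames(raw)[-1L])
    vals <- suppressWarnings(
        vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
    vals <- matrix(vals, nrow = nrow(raw),
                   dimnames = list(genes, cells))
    bad <- rowSums(is.na(vals)) > 0L
    if (any(bad)) {
        message(sprintf("readAbundance: dropped %d gene(s) with non-numeric entries",
                        sum(bad)))
        vals <- vals[!bad, , drop = FALSE]
    }
    if (nrow(vals) == 0L)
        stop("no genes with numeric values in ", path, call. = FALSE)
    neg <- which(vals < 0, arr.ind = TRUE)
    if (nrow(neg) > 0L)
        stop(sprintf("negative abundance for gene '%s' in cell '%s' (%s)",
                     rownames(vals)[neg[1L, 1L]], colnames(vals)[neg[1L, 2L]],
                     path), call. = FALSE)
    AbundanceMatrix(vals, modality)
}

#' Write an abundance matrix to TSV
#'
#' Values are written on the linear scale, rounded to `digits` decimals
#' (RPKM-like convention).
#'
#' @param x an \linkS4class{AbundanceMatrix}.
#' @param path output path.
#' @param digits decimals kept in the file (default 2).
#' @return `path`, invisibly.
#' @export
writeAbundance <- function(x, path, digits = 2L) {
    stopifnot(is(x, "AbundanceMatrix"))
    v <- round(abundances(x), digits)
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTsv(df, path)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB-convention lines: set name, description, then
#' tab-separated members. Members are deduplicated with a warning; duplicate
#' set names and member-less lines are format errors; an empty file yields an
#' empty collection with a warning.
#'
#' @param path path to a GMT file.
#' @param universe optional gene universe; defaults to the union of members.
#' @return a \linkS4class{GeneSetCollection}.
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path, universe = NULL) {
    if (!file.exists(path))
        stop("GMT file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
        warning("empty GMT file: ", path, call. = FALSE)
        return(GeneSetCollection(list(), universe))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(fields, function(f) trimws(f[1L]), character(1))
    if (anyDuplicated(nm))
        stop(sprintf("duplicate set name '%s' in %s",
                     nm[duplicated(nm)][1L], path), call. = FALSE)
    short <- vapply(fields, length, integer(1)) < 3L
    if (any(short))
        stop(sprintf("GMT line %d has no members in %s",
                     which(short)[1L], path), call. = FALSE)
    sets <- lapply(fields, function(f) trimws(f[-(1:2)]))
    names(sets) <- nm
    GeneSetCollection(sets, universe)
}

#' Write gene sets to a GMT file
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @param descriptions optional per-set description column (recycled `"na"`).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(x, path, descriptions = NULL) {
    stopifnot(is(x, "GeneSetCollection"))
    s <- geneSets(x)
    if (is.null(descriptions)) descriptions <- rep("na", length(s))
    lines <- vapply(seq_along(s), function(i)
        paste(c(names(s)[i], descriptions[i], s[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a growth table from TSV
#'
#' Expects columns `cell_id`, `division_rate`, then one column per drug.
#' Blank inhibition cells are kept as `NA`; a non-numeric division rate or a
#' missing `division_rate` column is a format error.
#'
#' @param path path to a tab-delimited file.
#' @return a \linkS4class{GrowthTable}.
#' @seealso [writeGrowth()]
#' @export
readGrowth <- function(path) {
    if (!file.exists(path))
        stop("growth file not found: ", path, call. = FALSE)
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", quote = "")
    if (!all(c("cell_id", "division_rate") %in% colnames(raw)))
        stop("growth table must have 'cell_id' and 'division_rate' columns",
             call. = FALSE)
    cells <- trimws(raw$cell_id)
    rate <- suppressWarnings(as.numeric(raw$division_rate))
    if (any(is.na(rate)))
        stop(sprintf("non-numeric division rate for cell '%s' in %s",
                     cells[is.na(rate)][1L], path), call. = FALSE)
    names(rate) <- cells
    drugCols <- setdiff(colnames(raw), c("cell_id", "division_rate"))
    inh <- NULL
    if (length(drugCols)) {
        inh <- vapply(raw[drugCols], function(col) {
            col <- trimws(col)
            col[!nzchar(col)] <- NA_character_
            suppressWarnings(as.numeric(col))
        }, numeric(nrow(raw)))
        inh <- matrix(inh, nrow = nrow(raw),
                      dimnames = list(cells, drugCols))
    }
    GrowthTable(rate, inh)
}

#' Write a growth table to TSV
#'
#' @param x a \linkS4class{GrowthTable}.
#' @param path output path.
#' @param digits decimals kept in the file (default 4).
#' @return `path`, invisibly.
#' @export
writeGrowth <- function(x, path, digits = 4L) {
    stopifnot(is(x, "GrowthTable"))
    df <- data.frame(cell_id = cellIds(x),
                     division_rate = round(divisionRate(x), digits),
                     stringsAsFactors = FALSE)
    if (ncol(inhibition(x)) > 0L)
        df <- cbind(df, round(inhibition(x), digits))
    .writeTsv(df, path)
}

#' Write a synthetic-cohort truth object to JSON
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
    stopifnot(is(truth, "SyntheticTruth"))
    obj <- list(
        seed = truth@seed,
        division_slope = truth@divisionSlope,
        division_intercept = truth@divisionIntercept,
        affected_sets = truth@affectedSets,
        set_offsets = as.data.frame(truth@setOffsets),
        gene_coupling = as.list(truth@geneCoupling))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

# deterministic TSV writer shared by all outputs
.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}
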