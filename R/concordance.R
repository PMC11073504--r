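## mRNA-protein concordance: cross-correlation of every cell's mRNA profile
## with every cell's protein profile, same-cell versus other-cell contrasts,
## hallmark-restricted correlations, and the hallmark-versus-random-set
## comparison.

.transformAbundance <- function(v, transform) {
    switch(transform,
           log2p1 = log2(v + 1),
           none = v,
           stop("unknown transform: ", transform, call. = FALSE))
}

# one-row test-summary data.frame, the common currency of the test results
.testSummary <- function(name, statistic, df, p, direction) {
    data.frame(statistic_name = name, statistic = unname(statistic),
               df = if (length(df) == 1L) unname(df) else paste(df, collapse = ","),
               p_value = unname(p), direction = direction,
               stringsAsFactors = FALSE)
}

#' Cross-correlate mRNA and protein profiles across cells
#'
#' Entry (i, j) of the result is the correlation of cell i's mRNA vector with
#' cell j's protein vector over the genes shared by both modalities (exact
#' identifier match); the diagonal holds the same-cell correlations. Pearson
#' correlations are computed on `log2(x + 1)`-transformed abundances by
#' default (raw linear abundances are outlier-dominated); Spearman uses raw
#' values, being rank-invariant. Constant profiles give flagged `NA` entries.
#'
#' @param mrna,protein \linkS4class{AbundanceMatrix} objects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param genes optional gene subset to restrict the correlation to.
#' @param transform transform applied before Pearson correlation:
#'   `"log2p1"` (default) or `"none"`. Ignored for Spearman.
#'
#' @return a \linkS4class{CorrelationMatrix}.
#' @export
crossCorrelation <- function(mrna, protein,
                             method = c("pearson", "spearman"),
                             genes = NULL,
                             transform = c("log2p1", "none")) {
    method <- match.arg(method)
    transform <- match.arg(transform)
    stopifnot(is(mrna, "AbundanceMatrix"), is(protein, "AbundanceMatrix"))
    shared <- intersect(geneIds(mrna), geneIds(protein))
    dropped <- length(union(geneIds(mrna), geneIds(protein))) - length(shared)
    if (dropped > 0L)
        message(sprintf("crossCorrelation: %d gene(s) absent from one modality dropped",
                        dropped))
    if (!is.null(genes)) shared <- intersect(shared, genes)
    if (length(shared) < 3L)
        stop("fewer than 3 shared genes after intersection", call. = FALSE)
    A <- abundances(mrna)[shared, , drop = FALSE]
    B <- abundances(protein)[shared, , drop = FALSE]
    if (method == "pearson") {
        A <- .transformAbundance(A, transform)
        B <- .transformAbundance(B, transform)
        vals <- suppressWarnings(cor(A, B))
    } else {
        vals <- suppressWarnings(cor(A, B, method = "spearman"))
    }
    new("CorrelationMatrix", values = vals, method = method,
        nGenesUsed = length(shared))
}

#' @rdname CorrelationMatrix-class
#' @aliases corValues
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@values)

setMethod("show", "CorrelationMatrix", function(object) {
    d <- diag(object@values)
    o <- object@values[row(object@values) != col(object@values)]
    cat(sprintf("CorrelationMatrix (%s, %d genes): %d x %d cells\n",
                object@method, object@nGenesUsed,
                nrow(object@values), ncol(object@values)))
    cat(sprintf("  same-cell mean %.3f, other-cell mean %.3f\n",
                mean(d, na.rm = TRUE), mean(o, na.rm = TRUE)))
})

#' Contrast same-cell and other-cell correlations
#'
#' Splits a \linkS4class{CorrelationMatrix} into its diagonal ("same cell")
#' and all off-diagonal ("other cells") entries and compares the two groups
#' with an unequal-variance (Welch) two-sample t-test and a one-sided
#' Kolmogorov-Smirnov test of whether the same-cell correlations are
#' stochastically larger (statistic D+, the supremum of the other-cell ECDF
#' above the same-cell ECDF).
#'
#' @param corr a \linkS4class{CorrelationMatrix} with at least 2 cells.
#' @return a list of two one-row data.frames, `welch` and `ks`, with columns
#'   `statistic_name`, `statistic`, `df`, `p_value`, `direction`. A matrix
#'   with zero variance in both groups yields flagged `NA` statistics.
#' @export
sameVsOther <- function(corr) {
    stopifnot(is(corr, "CorrelationMatrix"))
    v <- corValues(corr)
    if (nrow(v) < 2L || ncol(v) < 2L)
        stop("at least 2 cells are needed to contrast same vs other",
             call. = FALSE)
    d <- diag(v)[!is.na(diag(v))]
    o <- v[row(v) != col(v)]
    o <- o[!is.na(o)]
    if (length(d) < 2L || length(o) < 2L)
        stop("both groups need at least 2 defined correlations",
             call. = FALSE)
    welch <- tryCatch({
        tt <- t.test(d, o, var.equal = FALSE)
        .testSummary("welch_t", tt$statistic, tt$parameter, tt$p.value,
                     "two_sided")
    }, error = function(e)
        .testSummary("welch_t", NA_real_, NA_real_, NA_real_, "two_sided"))
    ks <- ecdfCompare(d, o, alternative = "greater")
    list(welch = welch, ks = ks)
}

#' Per-hallmark same-cell correlations
#'
#' Recomputes the same-cell mRNA-protein correlation of every cell restricted
#' to each gene set's members (intersected with the shared universe). A
#' (set, cell) pair with fewer than 3 usable genes is flagged `NA`.
#'
#' @inheritParams crossCorrelation
#' @param sets a \linkS4class{GeneSetCollection}.
#' @return data.frame with columns `set_name`, `cell_id`, `r`, `n_genes`.
#' @export
setwiseCorrelation <- function(mrna, protein, sets,
                               method = c("pearson", "spearman"),
                               transform = c("log2p1", "none")) {
    method <- match.arg(method)
    transform <- match.arg(transform)
    stopifnot(is(sets, "GeneSetCollection"))
    shared <- intersect(geneIds(mrna), geneIds(protein))
    cells <- intersect(cellIds(mrna), cellIds(protein))
    A <- abundances(mrna)[shared, cells, drop = FALSE]
    B <- abundances(protein)[shared, cells, drop = FALSE]
    if (method == "pearson") {
        A <- .transformAbundance(A, transform)
        B <- .transformAbundance(B, transform)
    } else {
        A <- apply(A, 2L, rank); B <- apply(B, 2L, rank)
        rownames(A) <- rownames(B) <- shared
    }
    out <- lapply(names(geneSets(sets)), function(nm) {
        members <- intersect(geneSets(sets)[[nm]], shared)
        if (length(members) < 3L)
            return(data.frame(set_name = nm, cell_id = cells, r = NA_real_,
                              n_genes = length(members),
                              stringsAsFactors = FALSE))
        a <- A[members, , drop = FALSE]; b <- B[members, , drop = FALSE]
        r <- vapply(seq_along(cells), function(i)
            suppressWarnings(cor(a[, i], b[, i])), numeric(1))
        data.frame(set_name = nm, cell_id = cells, r = r,
                   n_genes = length(members), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Compare hallmark correlations against a random gene set
#'
#' For each hallmark, a two-sample Wilcoxon rank-sum test of its per-cell
#' same-cell correlations against the random set's (exact enumeration when
#' both groups have at most 12 values and no ties, normal approximation with
#' continuity correction otherwise), plus a one-way ANOVA of the correlations
#' on set membership with the random set as the reference level.
#'
#' @param setwise data.frame from [setwiseCorrelation()] over the hallmarks.
#' @param randomCorrs numeric vector of the random set's per-cell same-cell
#'   correlations (e.g. the relevant rows of a second [setwiseCorrelation()]
#'   call, or `r` for a set from [sampleRandomSet()]).
#' @param alternative direction of the per-hallmark rank-sum test:
#'   `"greater"` (default; hallmark correlations larger), `"two_sided"` or
#'   `"less"`.
#' @return a list: `wilcoxon`, a data.frame with one row per hallmark
#'   (`set_name`, `statistic_name`, `statistic` = W, `p_value`,
#'   `direction`), and `anova`, a one-row test summary with the F statistic
#'   and its degrees of freedom.
#' @export
hallmarkVsRandom <- function(setwise, randomCorrs,
                             alternative = c("greater", "two_sided", "less")) {
    alternative <- match.arg(alternative)
    randomCorrs <- randomCorrs[!is.na(randomCorrs)]
    if (length(randomCorrs) < 2L)
        stop("the random set needs at least 2 defined correlations",
             call. = FALSE)
    alt <- sub("two_sided", "two.sided", alternative, fixed = TRUE)
    setsv <- split(setwise$r, setwise$set_name)
    wil <- do.call(rbind, lapply(names(setsv), function(nm) {
        x <- setsv[[nm]][!is.na(setsv[[nm]])]
        if (length(x) < 2L)
            stop("hallmark '", nm, "' has fewer than 2 defined correlations",
                 call. = FALSE)
        exact <- length(x) <= 12L && length(randomCorrs) <= 12L
        wt <- suppressWarnings(
            wilcox.test(x, randomCorrs, alternative = alt, exact = exact,
                        correct = TRUE))
        data.frame(set_name = nm, statistic_name = "wilcoxon_W",
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   direction = alternative, stringsAsFactors = FALSE)
    }))
    df <- rbind(
        data.frame(set_name = "random", r = randomCorrs,
                   stringsAsFactors = FALSE),
        setwise[!is.na(setwise$r), c("set_name", "r")])
    df$set_name <- stats::relevel(factor(df$set_name), ref = "random")
    fit <- lm(r ~ set_name, data = df)
    an <- anova(fit)
    aov <- .testSummary("anova_F", an$`F value`[1L],
                        c(an$Df[1L], an$Df[2L]), an$`Pr(>F)`[1L],
                        "two_sided")
    list(wilcoxon = wil, anova = aov)
}
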