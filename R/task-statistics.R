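## The two decoupling statistics: the per-(cell, hallmark) difference between
## mRNA- and protein-based normalized enrichment scores (delta), tested per
## hallmark against a bootstrap difference-of-means null, and the per-(cell,
## modality) range of enrichment across the hallmarks.

#' Per-(cell, set) NES difference between modalities
#'
#' @param recordsMrna,recordsProtein enrichment records (data.frames from
#'   [gseaPreranked()] / [enrichAllCells()]) for the mRNA and protein ranked
#'   lists; both must cover the same (cell, set) pairs -- pairs present in
#'   only one input are kept with a flagged `NA` delta.
#' @param signConvention `"mrna_minus_protein"` (default; positive =
#'   transcription-favored) or `"protein_minus_mrna"`.
#' @return data.frame with columns `cell_id`, `set_name`, `nes_mrna`,
#'   `nes_protein`, `delta`.
#' @export
enrichmentDelta <- function(recordsMrna, recordsProtein,
                            signConvention = c("mrna_minus_protein",
                                               "protein_minus_mrna")) {
    signConvention <- match.arg(signConvention)
    a <- recordsMrna[c("cell_id", "set_name", "nes")]
    b <- recordsProtein[c("cell_id", "set_name", "nes")]
    names(a)[3L] <- "nes_mrna"; names(b)[3L] <- "nes_protein"
    m <- merge(a, b, by = c("cell_id", "set_name"), all = TRUE, sort = TRUE)
    if (!any(stats::complete.cases(m)))
        stop("no overlapping (cell, set) pairs between the two record sets",
             call. = FALSE)
    nMissing <- sum(!stats::complete.cases(m))
    if (nMissing > 0L)
        message(sprintf("enrichmentDelta: %d (cell, set) pair(s) missing in one modality flagged",
                        nMissing))
    m$delta <- if (signConvention == "mrna_minus_protein")
        m$nes_mrna - m$nes_protein else m$nes_protein - m$nes_mrna
    m
}

#' Bootstrap test of the mean enrichment difference of one hallmark
#'
#' The observed statistic is the mean difference MD = mean(mRNA scores) -
#' mean(protein scores) across cells. The null pools both modalities' scores
#' (exchangeability under "no modality effect"), draws two samples of
#' `sampleSize` with replacement, and records their difference of means,
#' `nBoot` times. The p-value is `(1 + #{|null| >= |MD|}) / (nBoot + 1)` --
#' the add-one correction keeps it strictly positive.
#'
#' @param scoresMrna,scoresProtein per-cell NES values of one hallmark for
#'   the two modalities.
#' @param nBoot number of bootstrap draws (>= 1000; default 10000).
#' @param sampleSize size of each resample; defaults to the number of cells
#'   on the mRNA side.
#' @param seed integer seed; deterministic given the seed.
#' @return a list: `observed_md`, `null_draws`, `p_value`, `n_boot`,
#'   `sample_size`, `seed`.
#' @export
bootstrapDeltaTest <- function(scoresMrna, scoresProtein, nBoot = 10000L,
                               sampleSize = NULL, seed) {
    scoresMrna <- scoresMrna[!is.na(scoresMrna)]
    scoresProtein <- scoresProtein[!is.na(scoresProtein)]
    if (!length(scoresMrna) || !length(scoresProtein))
        stop("both score pools must be non-empty", call. = FALSE)
    if (nBoot < 1000L) stop("nBoot must be >= 1000", call. = FALSE)
    if (is.null(sampleSize)) sampleSize <- length(scoresMrna)
    sampleSize <- as.integer(sampleSize)
    nBoot <- as.integer(nBoot)
    obs <- mean(scoresMrna) - mean(scoresProtein)
    pool <- c(scoresMrna, scoresProtein)
    if (max(pool) - min(pool) == 0 && abs(obs) > 0)
        stop("constant pooled scores cannot produce a nonzero observed difference",
             call. = FALSE)
    null <- withr::with_seed(as.integer(seed), {
        draws <- matrix(sample(pool, 2L * sampleSize * nBoot, replace = TRUE),
                        nrow = 2L * sampleSize)
        colMeans(draws[seq_len(sampleSize), , drop = FALSE]) -
            colMeans(draws[-seq_len(sampleSize), , drop = FALSE])
    })
    p <- (1 + sum(abs(null) >= abs(obs))) / (nBoot + 1)
    list(observed_md = obs, null_draws = null, p_value = p,
         n_boot = nBoot, sample_size = sampleSize, seed = as.integer(seed))
}

#' Range of enrichment of one ranked list
#'
#' The difference between the highest and the lowest NES across the hallmark
#' sets of one (cell, modality) ranked list; always non-negative, invariant
#' to adding a constant to all scores, and unchanged by sets whose NES lies
#' strictly between the current extremes.
#'
#' @param nes numeric vector of NES values (at least one; `NA`s dropped).
#' @return a single non-negative number.
#' @export
enrichmentRange <- function(nes) {
    nes <- nes[!is.na(nes)]
    if (!length(nes)) stop("at least one NES value is required", call. = FALSE)
    max(nes) - min(nes)
}

#' Assemble the delta and range statistics of a cohort
#'
#' @inheritParams enrichmentDelta
#' @return a \linkS4class{TaskStats}.
#' @export
taskStatistics <- function(recordsMrna, recordsProtein,
                           signConvention = c("mrna_minus_protein",
                                              "protein_minus_mrna")) {
    signConvention <- match.arg(signConvention)
    delta <- enrichmentDelta(recordsMrna, recordsProtein, signConvention)
    both <- rbind(recordsMrna, recordsProtein)
    grp <- split(both, list(both$cell_id, both$modality), drop = TRUE)
    rng <- do.call(rbind, lapply(grp, function(g)
        data.frame(cell_id = g$cell_id[1L], modality = g$modality[1L],
                   range = if (all(is.na(g$nes))) NA_real_
                           else enrichmentRange(g$nes),
                   stringsAsFactors = FALSE)))
    rownames(rng) <- NULL
    rng <- rng[order(rng$modality, rng$cell_id), ]
    new("TaskStats", delta = delta, range = rng,
        signConvention = signConvention)
}

#' @rdname TaskStats-class
#' @aliases deltaTable rangeTable signConvention
#' @export
setMethod("deltaTable", "TaskStats", function(x) x@delta)

#' @rdname TaskStats-class
#' @export
setMethod("rangeTable", "TaskStats", function(x) x@range)

#' @rdname TaskStats-class
#' @export
setMethod("signConvention", "TaskStats", function(x) x@signConvention)

setMethod("show", "TaskStats", function(object) {
    cat(sprintf("TaskStats (%s): %d (cell, set) deltas, %d ranges\n",
                object@signConvention, nrow(object@delta),
                nrow(object@range)))
    cat(sprintf("  mean delta %.3f; mean range %.3f\n",
                mean(object@delta$delta, na.rm = TRUE),
                mean(object@range$range, na.rm = TRUE)))
})
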