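## Preranked gene-set enrichment. Gene products are ranked per cell and
## modality by abundance; a weighted Kolmogorov-Smirnov running sum measures
## the concentration of each hallmark at the top or bottom of the list. The
## null is built by gene-label permutation (random member sets of equal size
## from the ranked universe) -- the only permutation scheme available when a
## single profile exists per (cell, modality). Enrichment scores are
## normalized by the mean positive and negative null scores separately, and
## false discovery is controlled by Benjamini-Hochberg across the sets of one
## ranked list.

#' Rank the gene products of one cell
#'
#' Orders genes by descending abundance; ties are broken by ascending gene
#' identifier (C-locale, deterministic across runs). Genes with missing
#' values are excluded with a logged count.
#'
#' @param x an \linkS4class{AbundanceMatrix} or a genes x cells numeric
#'   matrix with dimnames.
#' @param cell cell identifier (must exist in `x`).
#' @param modality modality label recorded in the result; taken from `x`
#'   when it is an \linkS4class{AbundanceMatrix}.
#' @return a \linkS4class{RankedList}.
#' @examples
#' m <- matrix(c(5, 3, 9), dimnames = list(c("A", "B", "C"), "CL01"))
#' rankProducts(m, "CL01")
#' @export
setGeneric("rankProducts",
    function(x, cell, modality = "mRNA") standardGeneric("rankProducts"))

#' @rdname rankProducts
#' @export
setMethod("rankProducts", "AbundanceMatrix", function(x, cell, modality) {
    .rankProducts(abundances(x), cell, modality(x))
})

#' @rdname rankProducts
#' @export
setMethod("rankProducts", "matrix", function(x, cell, modality) {
    .rankProducts(x, cell, modality)
})

.rankProducts <- function(values, cell, modality) {
    if (!cell %in% colnames(values))
        stop("unknown cell: ", cell, call. = FALSE)
    v <- values[, cell]
    genes <- rownames(values)
    keep <- !is.na(v)
    if (any(!keep))
        message(sprintf("rankProducts: %d gene(s) with missing values excluded",
                        sum(!keep)))
    v <- v[keep]; genes <- genes[keep]
    if (length(v) < 3L)
        stop("fewer than 3 genes with defined values for cell ", cell,
             call. = FALSE)
    ord <- order(-v, genes, method = "radix")
    new("RankedList", cellId = cell, modality = modality,
        genes = genes[ord], scores = unname(v[ord]))
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list accumulating `|score|^exponent / N_R` at each
#' set member (N_R = the sum of member weights) and `-1/(N - N_hit)` at each
#' non-member. The enrichment score is the signed extreme deviation of the
#' running sum, in \[-1, 1\]: +1 when all members occupy the top of the list,
#' -1 when they occupy the bottom. With `exponent = 0` the statistic reduces
#' to the classic unweighted Kolmogorov-Smirnov form. Scores are
#' `scoreTransform`-ed before weighting (default `log2(x + 1)`: with
#' `exponent = 1`, weights on the raw linear scale would let the single most
#' abundant product dominate the sum; ranks are unaffected either way).
#'
#' @param ranked a \linkS4class{RankedList}.
#' @param members character vector of member gene identifiers; at least one
#'   member and one non-member must be present in the list.
#' @param exponent weighting exponent p (default 1, the established
#'   preranked default).
#' @param scoreTransform `"log2p1"` (default) or `"none"`.
#' @return a list with `es` (the enrichment score) and `position` (1-based
#'   rank at which the extreme deviation is attained).
#' @examples
#' rl <- new("RankedList", cellId = "c", modality = "mRNA",
#'           genes = paste0("g", 1:5), scores = c(5, 4, 3, 2, 1))
#' enrichmentScore(rl, c("g1", "g3"), exponent = 1,
#'                 scoreTransform = "none")$es  # 2/3
#' @export
enrichmentScore <- function(ranked, members, exponent = 1,
                            scoreTransform = c("log2p1", "none")) {
    scoreTransform <- match.arg(scoreTransform)
    stopifnot(is(ranked, "RankedList"))
    pos <- which(ranked@genes %in% members)
    n <- length(ranked@genes)
    if (length(pos) < 1L)
        stop("no set member present in the ranked list", call. = FALSE)
    if (length(pos) >= n)
        stop("set covers the whole ranked list (degenerate)", call. = FALSE)
    w <- .esWeights(ranked@scores, exponent, scoreTransform)
    res <- .cppEnrichmentScore(w, as.integer(pos))
    list(es = unname(res[1L]), position = as.integer(res[2L]))
}

.esWeights <- function(scores, exponent, scoreTransform) {
    s <- .transformAbundance(abs(scores), scoreTransform)
    if (exponent == 0) rep(1, length(s)) else s^exponent
}

#' Preranked gene-set enrichment with a permutation null
#'
#' For every set: the observed enrichment score; a null of `nPerm` scores
#' from random equal-size member sets drawn from the ranked universe; the
#' normalized enrichment score NES = ES / mean(|null ES| of the same sign);
#' the one-tailed permutation p-value
#' `p = (1 + #same-sign null with |ES_null| >= |ES|) / (1 + #same-sign null)`;
#' and the Benjamini-Hochberg q-value across the sets of this ranked list.
#' Sets with fewer than `minSize` members in the list (or none outside it)
#' are flagged (`NA` statistics) and excluded from the BH adjustment.
#'
#' @inheritParams enrichmentScore
#' @param sets a \linkS4class{GeneSetCollection} (or named list of character
#'   vectors).
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param minSize minimum effective set size (default 5).
#' @param keepNull if `TRUE`, attach the per-set null ES draws as the
#'   `"null"` attribute of the result.
#' @return data.frame with one row per set: `cell_id`, `modality`,
#'   `set_name`, `size_effective`, `es`, `nes`, `p_value`, `fdr_q`,
#'   `n_perm`, `seed`. `sign(nes) == sign(es)` whenever `es != 0`.
#' @export
gseaPreranked <- function(ranked, sets, nPerm = 1000L, seed,
                          exponent = 1, minSize = 5L,
                          scoreTransform = c("log2p1", "none"),
                          keepNull = FALSE) {
    scoreTransform <- match.arg(scoreTransform)
    stopifnot(is(ranked, "RankedList"))
    if (nPerm < 100L) stop("nPerm must be >= 100", call. = FALSE)
    setList <- if (is(sets, "GeneSetCollection")) geneSets(sets) else sets
    stopifnot(is.list(setList), !is.null(names(setList)))
    n <- length(ranked@genes)
    w <- .esWeights(ranked@scores, exponent, scoreTransform)
    nulls <- vector("list", length(setList))
    rows <- withr::with_seed(as.integer(seed), {
        lapply(seq_along(setList), function(i) {
            pos <- which(ranked@genes %in% setList[[i]])
            m <- length(pos)
            if (m < minSize || m >= n)  # flagged: too small or degenerate
                return(data.frame(set_name = names(setList)[i],
                                  size_effective = m, es = NA_real_,
                                  nes = NA_real_, p_value = NA_real_,
                                  stringsAsFactors = FALSE))
            es <- unname(.cppEnrichmentScore(w, as.integer(pos))[1L])
            null <- .cppPermutationES(w, m, as.integer(nPerm))
            if (keepNull) nulls[[i]] <<- null
            sameSign <- if (es >= 0) null[null >= 0] else null[null < 0]
            nes <- if (length(sameSign) && mean(abs(sameSign)) > 0)
                es / mean(abs(sameSign)) else NA_real_
            p <- (1 + sum(abs(sameSign) >= abs(es))) / (1 + length(sameSign))
            data.frame(set_name = names(setList)[i], size_effective = m,
                       es = es, nes = nes, p_value = p,
                       stringsAsFactors = FALSE)
        })
    })
    out <- do.call(rbind, rows)
    out$fdr_q <- NA_real_
    ok <- !is.na(out$p_value)
    out$fdr_q[ok] <- p.adjust(out$p_value[ok], method = "BH")
    out <- data.frame(cell_id = ranked@cellId, modality = ranked@modality,
                      out, n_perm = as.integer(nPerm),
                      seed = as.integer(seed), stringsAsFactors = FALSE)
    if (keepNull) {
        names(nulls) <- names(setList)
        attr(out, "null") <- nulls
    }
    out
}

#' Enrichment records for every cell of both modalities
#'
#' Convenience wrapper running [rankProducts()] + [gseaPreranked()] over all
#' cells of the two abundance matrices. Per-list seeds are derived from
#' `seed` by fixed offsets, so the result is reproducible without per-cell
#' seed bookkeeping.
#'
#' @inheritParams gseaPreranked
#' @param mrna,protein \linkS4class{AbundanceMatrix} objects.
#' @return data.frame of stacked [gseaPreranked()] records.
#' @export
enrichAllCells <- function(mrna, protein, sets, nPerm = 1000L, seed,
                           exponent = 1, minSize = 5L,
                           scoreTransform = c("log2p1", "none")) {
    scoreTransform <- match.arg(scoreTransform)
    seed <- as.integer(seed)
    mats <- list(mrna, protein)
    res <- list(); k <- 0L
    for (mat in mats) {
        for (cell in cellIds(mat)) {
            k <- k + 1L
            rl <- rankProducts(mat, cell)
            res[[k]] <- gseaPreranked(rl, sets, nPerm = nPerm,
                                      seed = seed + k, exponent = exponent,
                                      minSize = minSize,
                                      scoreTransform = scoreTransform)
        }
    }
    do.call(rbind, res)
}
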