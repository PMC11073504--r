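## Associations of the decoupling statistics with cell growth: pooled and
## per-hallmark Pearson correlations, the hallmark-fixed-factor linear model
## of division rate on the enrichment difference, and ECDF comparisons.

#' Pearson association between paired vectors
#'
#' Pearson correlation with its two-sided t-based p-value; pairs with a
#' missing value in either variable are dropped. A constant predictor or
#' response yields a flagged undefined record (`NA` statistics), never an
#' error.
#'
#' @param predictor,response numeric vectors of equal length.
#' @param predictorName,responseName labels recorded in the result.
#' @param hallmark optional hallmark name for per-hallmark results.
#' @return one-row data.frame: `predictor`, `response`, `hallmark`, `pcc`,
#'   `p_value`, `n`.
#' @export
correlate <- function(predictor, response, predictorName = "delta",
                      responseName = "division_rate", hallmark = NA_character_) {
    stopifnot(length(predictor) == length(response))
    keep <- stats::complete.cases(predictor, response)
    x <- predictor[keep]; y <- response[keep]
    if (length(x) < 3L)
        stop("fewer than 3 complete pairs", call. = FALSE)
    rec <- data.frame(predictor = predictorName, response = responseName,
                      hallmark = hallmark, pcc = NA_real_,
                      p_value = NA_real_, n = length(x),
                      stringsAsFactors = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(rec)
    ct <- cor.test(x, y, method = "pearson")
    rec$pcc <- unname(ct$estimate)
    rec$p_value <- ct$p.value
    rec
}

#' Hallmark-fixed-factor model of division rate on the enrichment difference
#'
#' Ordinary least squares of the division rate on the per-(cell, hallmark)
#' delta with one intercept per hallmark and a common slope (the "fixed
#' effect" of decoupling on growth). A mixed model is not attempted: a
#' handful of cells times ten hallmarks cannot support random-effect
#' estimation, and a single common slope is the estimand.
#'
#' @param deltaTable data.frame with columns `cell_id`, `set_name`, `delta`
#'   (e.g. [deltaTable()] of a \linkS4class{TaskStats}, or any per-(cell,
#'   set) predictor table with those columns).
#' @param growth a \linkS4class{GrowthTable}.
#' @return one-row data.frame: `estimate` (the common slope), `std_error`,
#'   `p_value`, `df`, `model = "pooled_fixed_effect"`, `n`.
#' @export
fixedEffectModel <- function(deltaTable, growth) {
    stopifnot(is(growth, "GrowthTable"))
    df <- deltaTable[!is.na(deltaTable$delta), ]
    df$division_rate <- divisionRate(growth)[df$cell_id]
    df <- df[!is.na(df$division_rate), ]
    if (length(unique(df$set_name)) < 2L || length(unique(df$cell_id)) < 3L)
        stop("need at least 2 hallmarks and 3 cells", call. = FALSE)
    df$set_name <- factor(df$set_name)
    fit <- lm(division_rate ~ set_name + delta, data = df)
    cf <- summary(fit)$coefficients
    if (anyNA(coef(fit)) || !"delta" %in% rownames(cf))
        stop("rank-deficient design: delta is collinear with the hallmark factor",
             call. = FALSE)
    data.frame(estimate = cf["delta", "Estimate"],
               std_error = cf["delta", "Std. Error"],
               p_value = cf["delta", "Pr(>|t|)"],
               df = fit$df.residual, model = "pooled_fixed_effect",
               n = nrow(df), stringsAsFactors = FALSE)
}

#' Per-hallmark linear models of division rate on the delta
#'
#' One ordinary-least-squares slope per hallmark; hallmarks with fewer than
#' 3 cells with a defined delta are skipped with a warning.
#'
#' @inheritParams fixedEffectModel
#' @return data.frame with one row per fitted hallmark: `hallmark`,
#'   `estimate`, `std_error`, `p_value`, `df`, `model = "per_hallmark"`, `n`.
#' @export
perHallmarkEffects <- function(deltaTable, growth) {
    stopifnot(is(growth, "GrowthTable"))
    df <- deltaTable[!is.na(deltaTable$delta), ]
    df$division_rate <- divisionRate(growth)[df$cell_id]
    df <- df[!is.na(df$division_rate), ]
    out <- lapply(split(df, df$set_name), function(g) {
        if (nrow(g) < 3L) {
            warning(sprintf("hallmark '%s' skipped: only %d cell(s) with a defined delta",
                            g$set_name[1L], nrow(g)), call. = FALSE)
            return(NULL)
        }
        fit <- lm(division_rate ~ delta, data = g)
        cf <- summary(fit)$coefficients
        if (!"delta" %in% rownames(cf)) {
            warning(sprintf("hallmark '%s' skipped: constant delta",
                            g$set_name[1L]), call. = FALSE)
            return(NULL)
        }
        data.frame(hallmark = g$set_name[1L],
                   estimate = cf["delta", "Estimate"],
                   std_error = cf["delta", "Std. Error"],
                   p_value = cf["delta", "Pr(>|t|)"],
                   df = fit$df.residual, model = "per_hallmark",
                   n = nrow(g), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Compare two samples' empirical cumulative distribution functions
#'
#' Kolmogorov-Smirnov statistic as the supremum difference of the two ECDFs,
#' with the asymptotic p-value. `alternative = "greater"` tests whether
#' `a` tends to be larger than `b` (statistic D+ = sup of ECDF(b) above
#' ECDF(a)); `"less"` the reverse; `"two_sided"` uses the absolute supremum.
#' Because the standard statistic lives in \[0, 1\], the scaled variant
#' `sqrt(n*m/(n+m)) * D` is also reported.
#'
#' @param a,b numeric samples (each at least 2 values).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return one-row data.frame: `statistic_name = "ks_D"`, `statistic` (D in
#'   \[0, 1\]), `scaled_statistic`, `df` (`NA`; none defined), `p_value`,
#'   `direction`.
#' @export
ecdfCompare <- function(a, b, alternative = c("two_sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("both samples need at least 2 values", call. = FALSE)
    ## stats::ks.test's "greater" means ECDF(x) above ECDF(y), i.e. x
    ## stochastically SMALLER; swap arguments so our "greater" means
    ## "a tends to be larger".
    kt <- suppressWarnings(switch(alternative,
        two_sided = ks.test(a, b, alternative = "two.sided"),
        greater = ks.test(b, a, alternative = "greater"),
        less = ks.test(a, b, alternative = "greater")))
    d <- unname(kt$statistic)
    n <- length(a); m <- length(b)
    out <- .testSummary("ks_D", d, NA_real_, kt$p.value, alternative)
    out$scaled_statistic <- sqrt(n * m / (n + m)) * d
    out
}
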