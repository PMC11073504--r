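# Independent brute-force / textbook-formula oracles. These implementations
# deliberately share no code with the package: literal loops and the formulas
# as printed in statistics texts.

# running-sum enrichment score by walking every position of the ranked list
oracleES <- function(genes, scores, members, exponent = 1) {
    w <- if (exponent == 0) rep(1, length(scores)) else abs(scores)^exponent
    hit <- genes %in% members
    nr <- sum(w[hit])
    nmiss <- sum(!hit)
    run <- 0
    maxv <- 0
    minv <- 0
    for (i in seq_along(genes)) {
        run <- run + if (hit[i]) w[i] / nr else -1 / nmiss
        if (run > maxv) maxv <- run
        if (run < minv) minv <- run
    }
    # exact magnitude ties resolve to the positive extreme (the package's
    # documented convention); the epsilon absorbs float drift from the
    # interleaved accumulation order
    if (maxv >= -minv - 1e-9 * max(maxv, -minv, 1)) maxv else minv
}

# Welch two-sample t with Satterthwaite degrees of freedom
oracleWelch <- function(x, y) {
    vx <- stats::var(x) / length(x)
    vy <- stats::var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 /
        (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# one-way ANOVA F from between/within sums of squares
oracleF <- function(values, groups) {
    g <- split(values, groups)
    grand <- mean(values)
    ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                      numeric(1)))
    ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
    (ssb / (length(g) - 1)) / (ssw / (length(values) - length(g)))
}

# simple OLS slope
oracleSlope <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# pooled fixed-factor common slope by within-group demeaning (Frisch-Waugh)
oraclePooledSlope <- function(x, y, groups) {
    num <- den <- 0
    for (g in unique(groups)) {
        i <- groups == g
        num <- num + sum((x[i] - mean(x[i])) * (y[i] - mean(y[i])))
        den <- den + sum((x[i] - mean(x[i]))^2)
    }
    num / den
}

# Pearson r from the covariance formula plus the t-based p-value
oraclePearson <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# KS statistic as the supremum ECDF difference enumerated at all data points;
# "greater" means sample a tends to be larger (ECDF of b lies above)
oracleKS <- function(a, b, alternative = "two_sided") {
    pts <- sort(unique(c(a, b)))
    fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
    fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
    switch(alternative,
           two_sided = max(abs(fa - fb)),
           greater = max(fb - fa),
           less = max(fa - fb))
}
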