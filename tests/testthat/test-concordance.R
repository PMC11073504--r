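test_that("self-correlation and affine invariance behave as Pearson demands", {
    set.seed(1)
    v <- matrix(runif(40, 1, 50), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:4)))
    m <- AbundanceMatrix(v, "mRNA")
    pSame <- AbundanceMatrix(v, "protein")
    expect_equal(unname(diag(corValues(crossCorrelation(m, pSame)))),
                 rep(1, 4), tolerance = 1e-12)
    pAff <- AbundanceMatrix(2 * v + 3, "protein")
    ccA <- crossCorrelation(m, pAff, transform = "none")
    ccM <- crossCorrelation(m, AbundanceMatrix(v, "protein"),
                            transform = "none")
    expect_equal(corValues(ccA), corValues(ccM), tolerance = 1e-12)
    expect_equal(unname(diag(corValues(ccA))), rep(1, 4), tolerance = 1e-12)
})

test_that("single-cell correlation matches the covariance-formula oracle", {
    m <- makeAbundance(matrix(c(1, 2, 4), ncol = 1), "mRNA",
                       genes = c("a", "b", "c"), cells = "CL01")
    p <- makeAbundance(matrix(c(2, 2, 5), ncol = 1), "protein",
                       genes = c("a", "b", "c"), cells = "CL01")
    cc <- crossCorrelation(m, p, transform = "none")
    expect_equal(corValues(cc)[1, 1],
                 oraclePearson(c(1, 2, 4), c(2, 2, 5))$r,
                 tolerance = 1e-12)
})

test_that("genes absent from one modality are dropped and row permutation is immaterial", {
    set.seed(2)
    v <- matrix(runif(30, 1, 9), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10),
                                c("c1", "c2", "c3")))
    m <- AbundanceMatrix(v, "mRNA")
    p <- AbundanceMatrix(v[c(1:8), ] + 1, "protein")
    expect_message(cc <- crossCorrelation(m, p), "2 gene")
    perm <- sample(1:8)
    pPerm <- AbundanceMatrix((v[1:8, ] + 1)[perm, ], "protein")
    expect_equal(corValues(crossCorrelation(m, pPerm)), corValues(cc),
                 tolerance = 1e-12)
    expect_error(crossCorrelation(m, AbundanceMatrix(v[1:2, ], "protein")),
                 "fewer than 3 shared genes")
})

test_that("Spearman equals Pearson on rank-transformed vectors", {
    set.seed(3)
    v1 <- matrix(sample(1:100, 60), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 c("c1", "c2", "c3")))
    v2 <- matrix(sample(1:100, 60), nrow = 20, dimnames = dimnames(v1))
    m <- AbundanceMatrix(v1, "mRNA"); p <- AbundanceMatrix(v2, "protein")
    sp <- corValues(crossCorrelation(m, p, method = "spearman"))
    manual <- cor(apply(v1, 2, rank), apply(v2, 2, rank))
    expect_equal(sp, manual, tolerance = 1e-12)
})

test_that("constant profiles are flagged undefined, not silent zeros", {
    v <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("c1", "c2")))
    m <- AbundanceMatrix(v, "mRNA")
    p <- AbundanceMatrix(v, "protein")
    cc <- corValues(crossCorrelation(m, p, transform = "none"))
    expect_true(all(is.na(cc[, "c2"])))
    expect_false(anyNA(cc[, "c1"][1]))
})

test_that("sameVsOther separates groups and matches the Welch oracle", {
    set.seed(4)
    n <- 6
    v <- matrix(runif(n * n, 0.05, 0.15), n, n,
                dimnames = list(paste0("c", 1:n), paste0("c", 1:n)))
    diag(v) <- runif(n, 0.85, 0.95)
    cm <- new("CorrelationMatrix", values = v, method = "pearson",
              nGenesUsed = 100L)
    res <- sameVsOther(cm)
    expect_gt(res$welch$statistic, 10)
    expect_equal(res$ks$statistic, 1.0)

    d <- diag(v); o <- v[row(v) != col(v)]
    orc <- oracleWelch(d, o)
    expect_equal(res$welch$statistic, orc$t, tolerance = 1e-12)
    expect_equal(res$welch$df, orc$df, tolerance = 1e-12)
    expect_equal(res$welch$p_value, orc$p, tolerance = 1e-12)
})

test_that("sameVsOther p-values are calibrated when the groups share a distribution", {
    set.seed(5)
    ps <- replicate(400, {
        v <- matrix(runif(144, -0.5, 0.5), 12, 12)
        sameVsOther(new("CorrelationMatrix", values = v,
                        method = "pearson",
                        nGenesUsed = 10L))$welch$p_value
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("setwise correlation restricted to the whole universe equals the diagonal", {
    co <- smallCohort(seed = 12)
    all <- GeneSetCollection(list(everything = geneIds(co$mrna)))
    sw <- setwiseCorrelation(co$mrna, co$protein, all)
    cc <- crossCorrelation(co$mrna, co$protein)
    expect_equal(sw$r, unname(diag(corValues(cc))), tolerance = 1e-12)
})

test_that("sets below 3 usable members are flagged undefined", {
    co <- smallCohort(seed = 13)
    tiny <- GeneSetCollection(list(pair = geneIds(co$mrna)[1:2]))
    sw <- setwiseCorrelation(co$mrna, co$protein, tiny)
    expect_true(all(is.na(sw$r)))
    expect_identical(unique(sw$n_genes), 2L)
})

test_that("sampleRandomSet is a seeded uniform draw without replacement", {
    u <- sprintf("g%03d", 1:50)
    expect_setequal(sampleRandomSet(u, n = 50, seed = 1), u)
    expect_identical(sampleRandomSet(u, n = 10, seed = 3),
                     sampleRandomSet(u, n = 10, seed = 3))
    expect_false(identical(sampleRandomSet(u, n = 10, seed = 3),
                           sampleRandomSet(u, n = 10, seed = 4)))
    expect_error(sampleRandomSet(u, n = 0, seed = 1), "count >= 1")
    expect_error(sampleRandomSet(u, n = 51, seed = 1), "exceeds")
})

test_that("hallmarkVsRandom detects no effect when groups coincide", {
    r <- seq(0.1, 0.41, by = 0.01)
    sw <- data.frame(set_name = "h1", cell_id = seq_along(r), r = r)
    res <- hallmarkVsRandom(sw, r, alternative = "two_sided")
    expect_lt(res$anova$statistic, 1e-10)
    expect_gt(res$wilcoxon$p_value[1], 0.95)
})

test_that("ANOVA F matches the sum-of-squares oracle on a small fixture", {
    hall <- c(0.30, 0.40, 0.35)
    rand <- c(0.10, 0.20, 0.12)
    sw <- data.frame(set_name = "h1", cell_id = 1:3, r = hall)
    res <- hallmarkVsRandom(sw, rand)
    expect_equal(res$anova$statistic,
                 oracleF(c(rand, hall), rep(c("r", "h"), each = 3)),
                 tolerance = 1e-10)
})

test_that("a 0.2 shift is detected by the one-sided rank-sum test", {
    set.seed(6)
    rand <- runif(32, 0, 0.3)
    sw <- data.frame(set_name = "h1", cell_id = 1:32, r = rand + 0.2)
    res <- hallmarkVsRandom(sw, rand, alternative = "greater")
    expect_lt(res$wilcoxon$p_value[1], 0.01)
})

test_that("the same-vs-other gap grows with the coupling strength", {
    gaps <- vapply(c(0.2, 0.45, 0.7), function(cp) {
        mean(vapply(1:20, function(i) {
            co <- smallCohort(seed = 7000 + i + round(1000 * cp),
                              couplingHallmark = cp,
                              couplingBackground = cp)
            v <- corValues(crossCorrelation(co$mrna, co$protein))
            mean(diag(v)) - mean(v[row(v) != col(v)])
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(gaps) > 0))
})
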