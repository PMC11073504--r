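test_that("correlate recovers perfect linearity and matches the t oracle", {
    x <- 1:10
    expect_equal(correlate(x, 2 * x)$pcc, 1, tolerance = 1e-12)
    set.seed(20)
    a <- runif(5); b <- runif(5)
    got <- correlate(a, b)
    want <- oraclePearson(a, b)
    expect_equal(got$pcc, want$r, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    expect_identical(got$n, 5L)
})

test_that("correlate flags constants, drops incomplete pairs, errors when too few", {
    rec <- correlate(rep(1, 5), rnorm(5))
    expect_true(is.na(rec$pcc) && is.na(rec$p_value))
    rec2 <- correlate(c(1, 2, 3, NA, 5), c(2, 4, NA, 8, 10))
    expect_identical(rec2$n, 3L)
    expect_error(correlate(c(1, NA, NA), c(1, 2, 3)), "fewer than 3")
})

test_that("correlate is invariant to positive affine transforms", {
    set.seed(21)
    x <- rnorm(20); y <- rnorm(20)
    base <- correlate(x, y)
    tr <- correlate(3 * x + 7, 0.5 * y - 2)
    expect_equal(tr$pcc, base$pcc, tolerance = 1e-12)
    expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
})

test_that("correlate p-values are uniform under independence", {
    set.seed(22)
    ps <- replicate(400, correlate(rnorm(15), rnorm(15))$p_value)
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("fixedEffectModel recovers a noiseless slope and matches the oracle", {
    cells <- sprintf("c%02d", 1:8)
    sets <- c("h1", "h2", "h3")
    dt <- expand.grid(cell_id = cells, set_name = sets,
                      stringsAsFactors = FALSE)
    set.seed(23)
    # a delta shared across hallmarks within each cell plus an exactly
    # linear response recovers the slope without error
    dt2 <- dt
    dt2$delta <- rep(rnorm(8), times = 3)   # identical delta across sets
    div2 <- setNames(-2 * dt2$delta[1:8] + 5, cells)
    fe <- suppressWarnings(fixedEffectModel(dt2, GrowthTable(div2)))
    expect_equal(fe$estimate, -2, tolerance = 1e-10)

    set.seed(24)
    dt$delta <- rnorm(nrow(dt))
    div <- setNames(rnorm(8, 1), cells)
    fe2 <- fixedEffectModel(dt, GrowthTable(div))
    expect_equal(fe2$estimate,
                 oraclePooledSlope(dt$delta, div[dt$cell_id], dt$set_name),
                 tolerance = 1e-10)
})

test_that("a delta constant within every hallmark is rank-deficient", {
    cells <- sprintf("c%02d", 1:6)
    dt <- expand.grid(cell_id = cells, set_name = c("h1", "h2"),
                      stringsAsFactors = FALSE)
    dt$delta <- ifelse(dt$set_name == "h1", 0.3, 0.9)
    div <- setNames(rnorm(6), cells)
    expect_error(fixedEffectModel(dt, GrowthTable(div)), "rank-deficient")
})

test_that("per-hallmark slopes match OLS and skip undersized hallmarks", {
    cells <- sprintf("c%02d", 1:4)
    dt <- rbind(
        data.frame(cell_id = cells, set_name = "h1",
                   delta = c(0.1, 0.4, 0.2, 0.8)),
        data.frame(cell_id = cells[1:2], set_name = "h2",
                   delta = c(0.5, 0.7)))
    div <- setNames(c(1.2, 0.7, 1.0, 0.3), cells)
    expect_warning(ph <- perHallmarkEffects(dt, GrowthTable(div)),
                   "h2.*skipped|skipped.*h2")
    expect_identical(nrow(ph), 1L)
    expect_equal(ph$estimate,
                 oracleSlope(c(0.1, 0.4, 0.2, 0.8), div),
                 tolerance = 1e-10)

    # exactly linear data: every per-hallmark slope equals the pooled slope
    dt2 <- expand.grid(cell_id = cells, set_name = c("h1", "h2"),
                       stringsAsFactors = FALSE)
    dt2$delta <- rep(c(0.2, 0.5, 0.9, 0.4), times = 2)
    div2 <- setNames(3 - 1.5 * c(0.2, 0.5, 0.9, 0.4), cells)
    ph2 <- suppressWarnings(perHallmarkEffects(dt2, GrowthTable(div2)))
    fe <- suppressWarnings(fixedEffectModel(dt2, GrowthTable(div2)))
    expect_equal(ph2$estimate, rep(fe$estimate, 2), tolerance = 1e-10)
    expect_equal(unique(ph2$estimate), -1.5, tolerance = 1e-10)
})

test_that("ecdfCompare matches brute-force supremum enumeration", {
    expect_equal(ecdfCompare(1:5, 1:5)$statistic, 0, tolerance = 1e-15)
    expect_equal(ecdfCompare(6:10, 1:5, alternative = "greater")$statistic,
                 1.0, tolerance = 1e-15)
    set.seed(25)
    for (i in 1:20) {
        a <- round(runif(5, 0, 10), 2)
        b <- round(runif(5, 0, 10), 2)
        for (alt in c("two_sided", "greater", "less")) {
            got <- ecdfCompare(a, b, alternative = alt)
            expect_equal(got$statistic, oracleKS(a, b, alt),
                         tolerance = 1e-12)
            expect_equal(got$scaled_statistic,
                         sqrt(25 / 10) * got$statistic, tolerance = 1e-12)
        }
    }
    expect_error(ecdfCompare(1, 1:5), "at least 2")
})
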