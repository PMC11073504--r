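test_that("ranking is descending with deterministic identifier tie-breaks", {
    m <- makeAbundance(matrix(c(5, 3, 9), ncol = 1), "mRNA",
                       genes = c("A", "B", "C"), cells = "CL01")
    rl <- rankProducts(m, "CL01")
    expect_identical(rl@genes, c("C", "A", "B"))
    tie <- matrix(c(5, 5, 1), ncol = 1,
                  dimnames = list(c("B", "A", "Z"), "CL01"))
    expect_identical(rankProducts(tie, "CL01")@genes, c("A", "B", "Z"))
    expect_error(rankProducts(m, "CL99"), "unknown cell")
    allNa <- matrix(NA_real_, 3, 1,
                    dimnames = list(c("A", "B", "C"), "CL01"))
    expect_error(suppressMessages(rankProducts(allNa, "CL01")),
                 "fewer than 3 genes")
    someNa <- matrix(c(1, NA, 3, 4), ncol = 1,
                     dimnames = list(c("A", "B", "C", "D"), "CL01"))
    expect_message(rl2 <- rankProducts(someNa, "CL01"), "1 gene")
    expect_identical(rl2@genes, c("D", "C", "A"))
})

test_that("the worked running-sum example gives ES = 2/3 at position 3", {
    rl <- makeRanked(c(5, 4, 3, 2, 1))
    res <- enrichmentScore(rl, c("g1", "g3"), exponent = 1,
                           scoreTransform = "none")
    expect_equal(res$es, 2 / 3, tolerance = 1e-12)
    expect_identical(res$position, 3L)
})

test_that("extreme concentrations reach ES of exactly +1 and -1", {
    rl <- makeRanked(10:1, genes = sprintf("g%02d", 1:10))
    expect_equal(enrichmentScore(rl, rl@genes[1:3])$es, 1.0,
                 tolerance = 1e-12)
    expect_equal(enrichmentScore(rl, rl@genes[8:10])$es, -1.0,
                 tolerance = 1e-12)
    expect_error(enrichmentScore(rl, rl@genes), "whole ranked list")
    expect_error(enrichmentScore(rl, c("absent1", "absent2")), "no set member")
})

test_that("enrichment score equals brute-force enumeration on 500 random cases", {
    set.seed(42)
    for (i in 1:500) {
        n <- sample(5:20, 1)
        case <- randomCase(n)
        expo <- sample(c(0, 1, 1.5), 1)
        got <- enrichmentScore(case$ranked, case$members, exponent = expo,
                               scoreTransform = "none")$es
        want <- oracleES(case$ranked@genes, case$ranked@scores,
                         case$members, exponent = expo)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("exponent 0 reduces to the classic unweighted KS form", {
    set.seed(43)
    for (i in 1:50) {
        case <- randomCase(sample(8:20, 1))
        got <- enrichmentScore(case$ranked, case$members, exponent = 0)$es
        # direct ECDF-difference computation: hit vs miss cumulative fractions
        hit <- case$ranked@genes %in% case$members
        dev <- cumsum(hit) / sum(hit) - cumsum(!hit) / sum(!hit)
        want <- dev[which.max(abs(dev))]
        if (abs(max(dev)) == abs(min(dev))) want <- max(dev)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
    skip_if_not_installed("fgsea")
    set.seed(44)
    for (i in 1:50) {
        case <- randomCase(sample(10:40, 1), maxSet = 8)
        got <- enrichmentScore(case$ranked, case$members, exponent = 1,
                               scoreTransform = "none")$es
        stats <- setNames(case$ranked@scores, case$ranked@genes)
        want <- fgsea::calcGseaStat(stats,
                                    which(names(stats) %in% case$members),
                                    gseaParam = 1)
        expect_equal(got, want, tolerance = 1e-10)
    }
})

test_that("gseaPreranked is deterministic and respects its invariants", {
    set.seed(45)
    co <- smallCohort(seed = 21)
    rl <- rankProducts(co$mrna, cellIds(co$mrna)[1])
    a <- gseaPreranked(rl, co$geneSets, nPerm = 200, seed = 77)
    b <- gseaPreranked(rl, co$geneSets, nPerm = 200, seed = 77)
    expect_identical(a, b)
    ok <- !is.na(a$nes) & a$es != 0
    expect_true(all(sign(a$nes[ok]) == sign(a$es[ok])))
    # BH keeps the p-value ordering within the list
    ord <- order(a$p_value)
    expect_true(all(diff(a$fdr_q[ord]) >= -1e-12))
    expect_error(gseaPreranked(rl, co$geneSets, nPerm = 50, seed = 1),
                 "nPerm")
})

test_that("sets outside the ranked universe are flagged and excluded from BH", {
    rl <- makeRanked(20:1, genes = sprintf("g%02d", 1:20))
    sets <- list(inside = rl@genes[c(2, 5, 7, 9, 11, 15)],
                 outside = sprintf("x%02d", 1:6))
    rec <- gseaPreranked(rl, sets, nPerm = 100, seed = 5)
    expect_true(is.na(rec$es[rec$set_name == "outside"]))
    expect_true(is.na(rec$fdr_q[rec$set_name == "outside"]))
    expect_false(is.na(rec$fdr_q[rec$set_name == "inside"]))
})

test_that("NES normalization centres the same-sign null on 1", {
    set.seed(46)
    genes <- sprintf("g%04d", 1:800)
    rl <- makeRanked(round(runif(800, 0.5, 1.5), 3), genes = genes)
    sets <- list(S = sample(genes, 60))
    # exponent 0: the unweighted null takes both signs freely
    a <- gseaPreranked(rl, sets, nPerm = 1000, seed = 11, exponent = 0,
                       keepNull = TRUE)
    b <- gseaPreranked(rl, sets, nPerm = 1000, seed = 12, exponent = 0,
                       keepNull = TRUE)
    nullA <- attr(a, "null")$S
    nullB <- attr(b, "null")$S
    # null draws of one run, normalized by the other run's same-sign mean
    posNES <- nullA[nullA > 0] / mean(nullB[nullB > 0])
    expect_lt(abs(mean(posNES) - 1), 0.05)
    negNES <- nullA[nullA < 0] / mean(abs(nullB[nullB < 0]))
    expect_lt(abs(mean(negNES) + 1), 0.05)
})

test_that("with exponent 0 the NES is exactly invariant to positive scaling", {
    genes <- sprintf("g%03d", 1:100)
    set.seed(47)
    sc <- sort(runif(100, 1, 9), decreasing = TRUE)
    sets <- list(S = sample(genes, 12))
    r1 <- gseaPreranked(makeRanked(sc, genes = genes), sets, nPerm = 100,
                        seed = 3, exponent = 0)
    r2 <- gseaPreranked(makeRanked(5 * sc, genes = genes), sets,
                        nPerm = 100, seed = 3, exponent = 0)
    expect_equal(r1$es, r2$es, tolerance = 1e-15)
    expect_equal(r1$nes, r2$nes, tolerance = 1e-15)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-15)
})

test_that("enrichAllCells stacks reproducible per-cell records", {
    co <- smallCohort(seed = 22, nCells = 3, nGenes = 300)
    a <- enrichAllCells(co$mrna, co$protein, co$geneSets, nPerm = 100,
                        seed = 9)
    b <- enrichAllCells(co$mrna, co$protein, co$geneSets, nPerm = 100,
                        seed = 9)
    expect_identical(a, b)
    expect_setequal(unique(a$modality), c("mRNA", "protein"))
    expect_identical(nrow(a), 2L * 3L * 10L)
})
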