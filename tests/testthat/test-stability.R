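# The stability score should reward low intragroup noise and low
# intergroup drift; these tests probe it through planted simulations
# and analytic edge cases rather than formula-by-formula equality.

test_that("a constant gene attains the minimal stability value", {
    set.seed(42)
    n <- 30
    grp <- rep(c("A", "B"), each = n)
    m <- rbind(
        FLAT = rep(20, 2 * n),
        N1 = 22 + rnorm(2 * n, sd = 0.5),
        N2 = 24 + rnorm(2 * n, sd = 0.8),
        N3 = 26 + rnorm(2 * n, sd = 0.3) + rep(c(0, 1), each = n))
    colnames(m) <- paste0("s", seq_len(2 * n))
    x <- CtExperiment(m, grp)
    rep1 <- assessStability(x, rownames(m))
    expect_equal(bestSingle(rep1), "FLAT")
    s <- singleStability(rep1)
    expect_true(all(s$stability >= 0))
    expect_equal(s$gene[which.min(s$stability)], "FLAT")
})

test_that("stability is invariant to global Ct shifts and group relabeling", {
    sim <- simulateCtData(nGroups = 3, nPerGroup = 15, nTargets = 2,
        nHousekeeping = 4, missingRate = 0, seed = 5)
    x <- sim$ct
    cand <- paste0("HK", 1:4)
    r0 <- assessStability(x, cand)
    xs <- CtExperiment(ctValues(x) + 7.5, sampleGroups(x), collapsed = TRUE)
    r1 <- assessStability(xs, cand)
    expect_equal(singleStability(r1)$stability,
        singleStability(r0)$stability, tolerance = 1e-10)
    relab <- c(Group1 = "zebra", Group2 = "ant", Group3 = "mole")
    xr <- CtExperiment(ctValues(x), unname(relab[sampleGroups(x)]),
        collapsed = TRUE)
    r2 <- assessStability(xr, cand)
    expect_equal(sort(singleStability(r2)$stability),
        sort(singleStability(r0)$stability), tolerance = 1e-10)
    expect_equal(pairStability(r2)$stability, pairStability(r0)$stability,
        tolerance = 1e-10)
})

test_that("stability ranking matches planted (|d| + sigma) ranking", {
    # five genes with well-separated planted intergroup deviations and
    # noise levels, both increasing with gene index. The shifts sum to
    # zero across the candidates, so the gene-by-group centering leaves
    # the planted deviations identifiable (a shift common to all
    # candidates is unidentifiable by construction of the model).
    sds <-    c(0.10, 0.20, 0.30, 0.40, 0.50)
    shifts <- c(0.00, 0.60, -1.20, -1.80, 2.40)  # group B minus group A
    n <- 50
    hits <- 0
    for (rep in 1:200) {
        set.seed(9000 + rep)
        m <- t(vapply(1:5, function(i) {
            c(20 + i + rnorm(n, sd = sds[i]),
              20 + i + shifts[i] + rnorm(n, sd = sds[i]))
        }, numeric(2 * n)))
        rownames(m) <- paste0("g", 1:5)
        colnames(m) <- paste0("s", seq_len(2 * n))
        x <- CtExperiment(m, rep(c("A", "B"), each = n))
        s <- singleStability(assessStability(x, rownames(m)))
        if (identical(order(s$stability), 1:5)) hits <- hits + 1
    }
    expect_gte(hits / 200, 0.95)
})

test_that("added noise and injected group shifts worsen stability", {
    worseNoise <- 0
    worseShift <- 0
    n <- 25
    for (rep in 1:100) {
        set.seed(500 + rep)
        base <- t(vapply(1:4, function(i) 20 + i + rnorm(2 * n, sd = 0.3),
            numeric(2 * n)))
        rownames(base) <- paste0("g", 1:4)
        colnames(base) <- paste0("s", seq_len(2 * n))
        grp <- rep(c("A", "B"), each = n)
        s0 <- singleStability(assessStability(
            CtExperiment(base, grp), rownames(base)))
        noisy <- base
        noisy["g1", ] <- noisy["g1", ] + rnorm(2 * n, sd = 0.6)
        s1 <- singleStability(assessStability(
            CtExperiment(noisy, grp), rownames(base)))
        if (s1$stability[1] > s0$stability[1]) worseNoise <- worseNoise + 1
        shifted <- base
        shifted["g1", grp == "B"] <- shifted["g1", grp == "B"] + 1
        s2 <- singleStability(assessStability(
            CtExperiment(shifted, grp), rownames(base)))
        if (s2$stability[1] > s0$stability[1]) worseShift <- worseShift + 1
    }
    expect_gte(worseNoise / 100, 0.9)
    expect_gte(worseShift / 100, 0.95)
})

test_that("pair stability is symmetric and can beat both singles", {
    sim <- simulateCtData(nGroups = 2, nPerGroup = 20, nTargets = 2,
        nHousekeeping = 4, missingRate = 0, seed = 21)
    repk <- assessStability(sim$ct, paste0("HK", 1:4))
    p <- pairStability(repk)
    key1 <- paste(pmin(p$geneA, p$geneB), pmax(p$geneA, p$geneB))
    expect_false(anyDuplicated(key1) > 0)
    expect_equal(nrow(p), choose(4, 2))

    # two genes constant within groups with opposite group shifts:
    # their average cancels the intergroup deviation
    n <- 12
    m <- rbind(
        UP = rep(c(20, 21), each = n),
        DOWN = rep(c(25, 24), each = n),
        NOISY = 22 + rep(c(0, 0.2), each = n) +
            rep(c(0.05, -0.05), n))
    colnames(m) <- paste0("s", seq_len(2 * n))
    x <- CtExperiment(m, rep(c("A", "B"), each = n))
    r <- assessStability(x, rownames(m))
    s <- singleStability(r); p <- pairStability(r)
    pud <- p$stability[p$geneA == "DOWN" & p$geneB == "UP" |
                       p$geneA == "UP" & p$geneB == "DOWN"]
    expect_lt(pud, s$stability[s$gene == "UP"])
    expect_lt(pud, s$stability[s$gene == "DOWN"])
})

test_that("groups with too few complete samples are dropped with a warning", {
    m <- rbind(HKa = c(20, 20.1, 20.2, NA, 21),
               HKb = c(22, 22.2, 22.1, 22.3, NA))
    colnames(m) <- paste0("s", 1:5)
    x <- CtExperiment(m, c("A", "A", "A", "B", "B"))
    expect_warning(r <- assessStability(x, c("HKa", "HKb")), "dropped")
    expect_identical(r@groupsUsed, "A")
    expect_true(all(is.finite(singleStability(r)$stability)))
})

test_that("housekeeping selection follows the user-list policy", {
    sim <- simulateCtData(nGroups = 4, nPerGroup = 40, nTargets = 6,
        nHousekeeping = 5, missingRate = 0.02, seed = 31)
    x <- sim$ct
    # >= 2 genes: best pair among them
    hk <- selectHousekeeping(x, paste0("HK", 1:5))
    expect_length(hk, 2)
    expect_s4_class(attr(hk, "report"), "StabilityReport")
    expect_identical(sort(as.character(hk)),
        bestPair(attr(hk, "report")))
    # exactly one gene: used as-is
    expect_identical(selectHousekeeping(x, "HK3"), "HK3")
    # unknown gene
    expect_error(selectHousekeeping(x, c("HK1", "NOPE")), "unknown")
    # no list: all genes, with a warning
    expect_warning(hk2 <- selectHousekeeping(x), "all genes")
    expect_length(hk2, 2)
    # fewer than two candidates for the report itself
    expect_error(assessStability(x, "HK1"), "at least 2")
    expect_error(assessStability(x, c("HK1", "NOPE")), "not in table")
})
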