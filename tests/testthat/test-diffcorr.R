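test_that("method choice routes on per-gene normality with override", {
    set.seed(61)
    m <- rbind(T1 = rnorm(40), T2 = rnorm(40))
    norm <- makeNormMat(m, rep(c("A", "B"), each = 20))
    expect_identical(chooseCorrMethod(norm), "pearson")
    m2 <- rbind(T1 = rnorm(160), T2 = c(rnorm(80)^2, rnorm(80)))
    norm2 <- makeNormMat(m2, rep(c("A", "B"), each = 80))
    expect_identical(chooseCorrMethod(norm2), "spearman")
    expect_identical(chooseCorrMethod(norm2, override = "pearson"),
        "pearson")
})

test_that("correlation matrices are symmetric, gated, and unit-diagonal", {
    set.seed(62)
    base <- rnorm(30)
    m <- rbind(T1 = base, T2 = base + rnorm(30, sd = 0.2),
        T3 = rnorm(30), T4 = rnorm(30))
    norm <- makeNormMat(m, rep("A", 30))
    gc <- correlationMatrix(norm, "A", "spearman", alpha = 0.05)
    expect_equal(gc@r, t(gc@r))
    expect_equal(unname(diag(gc@r)), rep(1, 4))
    expect_equal(unname(diag(gatedR(gc))), rep(1, 4))
    expect_gt(gc@r["T1", "T2"], 0.8)
    expect_equal(gatedR(gc)["T1", "T2"], gc@r["T1", "T2"])
    # wherever p > alpha the gated coefficient is zero
    off <- upper.tri(gc@r)
    expect_true(all(gatedR(gc)[off][gc@p[off] > 0.05] == 0))
    expect_error(correlationMatrix(norm, "ghost"), "unknown group")
})

test_that("a sizeable but non-significant correlation is gated to zero", {
    # n = 4, monotone except one swap: spearman r = 0.8 with p = 0.33
    m <- rbind(T1 = c(1, 2, 3, 4), T2 = c(1, 3, 2, 4), T3 = c(2, 1, 4, 3))
    norm <- makeNormMat(m, rep("A", 4))
    gc <- correlationMatrix(norm, "A", "spearman", alpha = 0.05)
    expect_equal(gc@r["T1", "T2"], 0.8)
    expect_gt(gc@p["T1", "T2"], 0.05)
    expect_equal(gatedR(gc)["T1", "T2"], 0)
    # a perfectly monotone pair at n = 5 survives the gate
    m5 <- rbind(T1 = 1:5, T2 = c(2, 4, 6, 8, 10), T3 = c(5, 1, 4, 2, 3))
    gc5 <- correlationMatrix(makeNormMat(m5, rep("A", 5)), "A",
        "spearman", alpha = 0.05)
    expect_equal(gc5@r["T1", "T2"], 1)
    expect_equal(gatedR(gc5)["T1", "T2"], 1)
})

test_that("raising alpha never decreases the gated-entry count", {
    set.seed(63)
    m <- matrix(rnorm(8 * 25), nrow = 8,
        dimnames = list(paste0("T", 1:8), NULL))
    m[2, ] <- m[1, ] + rnorm(25, sd = 0.4)
    m[4, ] <- -m[3, ] + rnorm(25, sd = 0.6)
    norm <- makeNormMat(m, rep("A", 25))
    counts <- vapply(c(0.001, 0.01, 0.05, 0.2, 1), function(a) {
        gc <- correlationMatrix(norm, "A", "spearman", alpha = a)
        sum(gatedR(gc)[upper.tri(gc@r)] != 0)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("dR-val obeys its range and the worked arithmetic", {
    expect_equal(drValue(0.43, -0.48), 0.91)
    expect_equal(drValue(0.7, 0.7), 0)
    expect_equal(drValue(1, -1), 2)
    expect_error(drValue(1.2, 0), "\\[-1, 1\\]")
    set.seed(64)
    ra <- runif(200, -1, 1); rb <- runif(200, -1, 1)
    dv <- drValue(ra, rb)
    expect_true(all(dv >= 0 & dv <= 2))
    expect_equal(dv, drValue(rb, ra))   # group symmetry
})

test_that("drval tables cover reference pairs and rank planted flips first", {
    set.seed(65)
    n <- 60
    z <- rnorm(n)
    mkGroup <- function(rho) {
        t1 <- z
        t2 <- rho * z + sqrt(1 - rho^2) * rnorm(n)
        rbind(T1 = t1, T2 = t2, T3 = rnorm(n), T4 = rnorm(n))
    }
    mA <- mkGroup(0.9); mB <- mkGroup(-0.9); mC <- mkGroup(0.85)
    norm <- makeNormMat(cbind(mA, mB, mC),
        rep(c("A", "B", "C"), each = n))
    corrs <- lapply(c("A", "B", "C"), function(g)
        correlationMatrix(norm, g, "spearman", 0.05))
    names(corrs) <- c("A", "B", "C")
    dt <- drvalTable(corrs, reference = "A")
    # (n_groups - 1) comparisons x choose(4, 2) gene pairs
    expect_equal(nrow(dt), 2 * choose(4, 2))
    expect_setequal(unique(paste(dt$groupA, dt$groupB)), c("A B", "A C"))
    expect_true(all(dt$dRval >= 0 & dt$dRval <= 2, na.rm = TRUE))
    # planted flip tops the ranking; same-sign comparison stays low
    expect_setequal(c(dt$geneA[1], dt$geneB[1]), c("T1", "T2"))
    expect_identical(dt$groupB[1], "B")
    ac <- dt[dt$groupB == "C" & dt$geneA == "T1" & dt$geneB == "T2", ]
    expect_lt(ac$dRval, 0.3)
    # full pair set on request
    dtAll <- drvalTable(corrs, reference = "A", allPairs = TRUE)
    expect_equal(nrow(dtAll), 3 * choose(4, 2))
    # identical matrices give all-zero dR
    dt0 <- drvalTable(list(A = corrs$A, B = corrs$A), "A")
    expect_true(all(dt0$dRval[dt0$complete] == 0))
    expect_error(drvalTable(corrs, "ghost"), "reference")
})

test_that("spearman p equals the exhaustive permutation oracle for n <= 6", {
    set.seed(66)
    for (n in 4:6) for (rep in 1:5) {
        xv <- sample(seq(1, 50), n); yv <- sample(seq(51, 99), n)
        m <- rbind(T1 = xv, T2 = yv, T3 = rnorm(n))
        norm <- makeNormMat(m, rep("A", n))
        st <- pairScatterStats(norm, "T1", "T2", "A", "spearman")
        expect_equal(st$p, spearmanOracle(xv, yv), tolerance = 1e-9,
            info = sprintf("n=%d rep=%d", n, rep))
        expect_equal(st$r, cor(xv, yv, method = "spearman"),
            tolerance = 1e-12)
    }
})

test_that("scatter statistics report raw correlations and trend lines", {
    m <- rbind(T1 = c(1, 2, 3, 4, 5), T2 = c(10, 8, 6, 4, 2))
    norm <- makeNormMat(m, rep("A", 5))
    st <- pairScatterStats(norm, "T1", "T2", "A", "pearson")
    expect_equal(st$r, -1)
    expect_equal(st$slope, -2)
    expect_equal(st$intercept, 12)
    stSelf <- pairScatterStats(norm, "T1", "T1", "A", "spearman")
    expect_equal(stSelf$r, 1)
    tiny <- makeNormMat(rbind(T1 = c(1, 2, NA), T2 = c(1, 2, 3)),
        rep("A", 3))
    expect_error(pairScatterStats(tiny, "T1", "T2", "A"), "complete pairs")
})
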