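test_that("KS normality check matches a brute-force statistic and calls", {
    # values placed at normal quantiles: statistic small, p large
    n <- 50
    q <- qnorm((seq_len(n) - 0.5) / n)
    norm <- makeNorm1(A = q, B = rnorm(10))
    pv <- normalityByGroup(norm, "G", "A")
    expect_gt(pv[["A"]], 0.5)

    # brute-force D against the plug-in normal, vs the ks.test statistic
    y <- sort(q)
    Fy <- pnorm(y, mean(y), sd(y))
    D <- max(pmax(abs(seq_len(n) / n - Fy), abs((seq_len(n) - 1) / n - Fy)))
    expect_equal(unname(ks.test(y, "pnorm", mean(y), sd(y))$statistic), D,
        tolerance = 1e-12)

    # strongly right-skewed draws reject normality
    set.seed(77)
    skew <- rnorm(100)^2
    norm2 <- makeNorm1(A = skew)
    expect_lt(normalityByGroup(norm2, "G", "A")[["A"]], 0.05)

    # too-small group: missing p plus warning
    norm3 <- makeNorm1(A = c(1, 2), B = c(1, 2, 3, 2.5))
    expect_warning(p3 <- normalityByGroup(norm3, "G"), "fewer than 3")
    expect_true(is.na(p3[["A"]]))
    expect_false(is.na(p3[["B"]]))
})

test_that("test routing follows the any-group-fails rule with override", {
    expect_identical(routeTest(c(0.005, 0.2, 0.009, 0.001)), "mann-whitney")
    expect_identical(routeTest(c(0.3, 0.9, 0.05)), "student-t")
    expect_identical(routeTest(c(0.001, NA)), "mann-whitney")
    expect_identical(routeTest(c(0.001, 0.2), override = "student-t"),
        "student-t")
    expect_error(routeTest(c(NA_real_, NA_real_)), "no finite")
})

test_that("Mann-Whitney exact p matches hand-enumerated cases and group symmetry holds", {
    norm <- makeNorm1(lo = c(1, 2, 3), hi = c(4, 5, 6))
    cmp <- compareGroups(norm, "G", "lo", "hi", "mann-whitney")
    expect_equal(cmp$pValue, 0.1)                  # 2/20 assignments
    expect_equal(cmp$nA, 3); expect_equal(cmp$nB, 3)

    # identical data in both groups: FC = 1, p = 1
    same <- makeNorm1(A = c(1, 2, 3), B = c(1, 2, 3))
    for (tt in c("mann-whitney", "student-t")) {
        cmp2 <- compareGroups(same, "G", "A", "B", tt)
        expect_equal(cmp2$foldChange, 1)
        expect_equal(cmp2$pValue, 1)
    }

    # FC antisymmetry: FC_ab * FC_ba = 1, same p
    set.seed(15)
    norm3 <- makeNorm1(A = rnorm(9), B = rnorm(11) + 0.8)
    ab <- compareGroups(norm3, "G", "A", "B", "mann-whitney")
    ba <- compareGroups(norm3, "G", "B", "A", "mann-whitney")
    expect_equal(ab$foldChange * ba$foldChange, 1)
    expect_equal(ab$pValue, ba$pValue)

    # medians -3 vs -4 give FC = 2 under the adopted definition
    norm4 <- makeNorm1(A = c(-4, -3, -2), B = c(-5, -4, -3))
    expect_equal(compareGroups(norm4, "G", "A", "B",
        "mann-whitney")$foldChange, 2)

    expect_error(compareGroups(norm, "G", "lo", "lo", "mann-whitney"),
        "different")
    few <- makeNorm1(A = 1, B = c(1, 2))
    expect_error(compareGroups(few, "G", "A", "B", "mann-whitney"), "A")
})

test_that("Mann-Whitney p agrees with exhaustive enumeration up to n = 8", {
    set.seed(99)
    for (na in 2:6) for (nb in 2:(8 - na)) {
        if (nb < 2) next
        a <- runif(na); b <- runif(nb) + 0.3
        norm <- makeNorm1(A = a, B = b)
        got <- compareGroups(norm, "G", "A", "B", "mann-whitney")$pValue
        expect_equal(got, mwOracle(a, b), tolerance = 1e-12,
            info = sprintf("na=%d nb=%d", na, nb))
    }
})

test_that("pairwise tables enumerate group pairs with the reference second", {
    sim <- simulateCtData(nGroups = 4, nPerGroup = 10, nTargets = 3,
        nHousekeeping = 2, missingRate = 0, seed = 8)
    norm <- deltaCt(sim$ct, c("HK1", "HK2"))
    tab <- pairwiseTable(norm, "T01", reference = "Group2",
        test = "mann-whitney")
    expect_equal(nrow(tab), choose(4, 2))
    withRef <- tab$groupA == "Group2" | tab$groupB == "Group2"
    expect_true(all(tab$groupB[withRef] == "Group2"))
    tab2 <- pairwiseTable(norm, "T01", reference = "Group1",
        groups = c("Group1", "Group3"), test = "student-t")
    expect_equal(nrow(tab2), 1)
    expect_error(pairwiseTable(norm, "T01", reference = "Group9"),
        "not among")
    # auto routing picks a valid test
    tab3 <- suppressWarnings(pairwiseTable(norm, "T01",
        reference = "Group1", test = "auto"))
    expect_true(all(tab3$test %in% c("mann-whitney", "student-t")))
})

test_that("significance stars follow the scheme and are monotone", {
    expect_identical(pStars(0.03), "*")
    expect_identical(pStars(0.05), "ns")
    expect_identical(pStars(1e-4), "****")
    expect_identical(pStars(0.01), "**")       # boundary: strongest label
    expect_identical(pStars(0.001), "***")
    expect_true(is.na(pStars(NA_real_)))
    expect_error(pStars(1.2), "0, 1")
    grid <- sort(c(10^seq(-6, 0, length.out = 40), 1e-4, 1e-3, 0.01, 0.05))
    lv <- c("ns" = 0, "*" = 1, "**" = 2, "***" = 3, "****" = 4)
    ranks <- unname(lv[pStars(grid)])
    expect_true(all(diff(ranks) <= 0))         # larger p, never stronger
})
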