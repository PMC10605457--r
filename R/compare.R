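#' Per-group normality assessment
#'
#' One-sample Kolmogorov-Smirnov test of each group's -deltaCt values
#' for one gene against a normal distribution with that group's sample
#' mean and standard deviation (plug-in parameters, no Lilliefors
#' correction). Groups with fewer than 3 non-missing values get a
#' missing p-value with a warning.
#'
#' @param x a [NormalizedSet-class].
#' @param gene gene name.
#' @param groups group labels to assess (default: all groups present).
#' @param groupVar grouping variable in `colData`.
#' @return Named numeric vector of two-sided p-values, one per group.
#' @export
normalityByGroup <- function(x, gene, groups = NULL, groupVar = "group") {
    stopifnot(is(x, "NormalizedSet"))
    if (!gene %in% rownames(x)) stop("unknown gene: ", gene)
    grp <- as.character(colData(x)[[groupVar]])
    if (is.null(groups)) groups <- sort(unique(grp[!is.na(grp)]))
    unknown <- setdiff(groups, grp)
    if (length(unknown))
        stop("unknown group(s): ", paste(unknown, collapse = ", "))
    v <- negDeltaCt(x)[gene, ]
    out <- vapply(groups, function(g) {
        y <- v[!is.na(v) & grp == g & !is.na(grp)]
        if (length(y) < 3) return(NA_real_)
        s <- stats::sd(y)
        if (s == 0) return(0)  # degenerate: constant values are non-normal
        suppressWarnings(
            stats::ks.test(y, "pnorm", mean(y), s)$p.value)
    }, numeric(1))
    if (anyNA(out))
        warning("group(s) with fewer than 3 values: normality p missing for ",
            paste(groups[is.na(out)], collapse = ", "), call. = FALSE)
    out
}

#' Route to a parametric or nonparametric test
#'
#' Chooses the two-group test from the per-group normality p-values: if
#' any group rejects normality at alpha = 0.05 the Mann-Whitney test is
#' used, otherwise the Student t-test. An explicit `override` always
#' wins, letting users force either test.
#'
#' @param normalityP numeric vector of per-group KS p-values (at least
#'   one finite value required unless `override` is given).
#' @param override optional `"mann-whitney"` or `"student-t"`.
#' @param alpha per-group normality threshold (default 0.05).
#' @return `"mann-whitney"` or `"student-t"`.
#' @export
routeTest <- function(normalityP, override = NULL, alpha = 0.05) {
    if (!is.null(override))
        return(match.arg(override, c("mann-whitney", "student-t")))
    if (all(!is.finite(normalityP)))
        stop("no finite normality p-value; cannot route the test")
    if (any(normalityP < alpha, na.rm = TRUE)) "mann-whitney" else "student-t"
}

#' Compare one gene between two groups
#'
#' Two-sided comparison of a gene's -deltaCt between two groups with the
#' Mann-Whitney test (exact when the combined sample size is <= 25 and
#' there are no ties; tie- and continuity-corrected normal approximation
#' otherwise) or the classical equal-variance Student t-test. The fold
#' change is `2^(median_a - median_b)`, a linear-scale fold consistent
#' with the Livak scale, so swapping the groups inverts it.
#'
#' @param x a [NormalizedSet-class].
#' @param gene gene name.
#' @param groupA,groupB distinct group labels (each with >= 2
#'   non-missing values).
#' @param test `"mann-whitney"` or `"student-t"`.
#' @param groupVar grouping variable.
#' @return One-row data.frame: `gene`, `groupA`, `groupB`, `nA`, `nB`,
#'   `medianA`, `medianB`, `foldChange`, `pValue`, `test`, `stars`.
#' @export
compareGroups <- function(x, gene, groupA, groupB,
                          test = c("mann-whitney", "student-t"),
                          groupVar = "group") {
    stopifnot(is(x, "NormalizedSet"))
    test <- match.arg(test)
    if (identical(groupA, groupB))
        stop("groupA and groupB must be different")
    if (!gene %in% rownames(x)) stop("unknown gene: ", gene)
    grp <- as.character(colData(x)[[groupVar]])
    v <- negDeltaCt(x)[gene, ]
    a <- v[!is.na(v) & grp %in% groupA]
    b <- v[!is.na(v) & grp %in% groupB]
    if (length(a) < 2) stop("fewer than 2 values in group ", groupA)
    if (length(b) < 2) stop("fewer than 2 values in group ", groupB)
    p <- .twoGroupP(a, b, test)
    ma <- stats::median(a); mb <- stats::median(b)
    data.frame(gene = gene, groupA = groupA, groupB = groupB,
        nA = length(a), nB = length(b), medianA = ma, medianB = mb,
        foldChange = 2^(ma - mb), pValue = p, test = test,
        stars = pStars(p), row.names = NULL)
}

.twoGroupP <- function(a, b, test) {
    if (test == "mann-whitney") {
        ties <- anyDuplicated(c(a, b)) > 0
        exact <- (length(a) + length(b) <= 25) && !ties
        suppressWarnings(
            stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    } else {
        if (stats::sd(c(a, b)) == 0) return(1)  # all values identical
        stats::t.test(a, b, var.equal = TRUE)$p.value
    }
}

#' All pairwise group comparisons for one gene
#'
#' One [compareGroups()] record per unordered pair among the selected
#' groups; in pairs containing the reference group, the reference is
#' listed as `groupB` (so fold changes read as "versus reference").
#' With `test = "auto"` the test is routed once from the per-group
#' normality assessment over the selected groups.
#'
#' @param x a [NormalizedSet-class].
#' @param gene gene name.
#' @param reference reference group label (must be among `groups`).
#' @param groups group labels to compare (default: all; >= 2 required).
#' @param test `"auto"`, `"mann-whitney"`, or `"student-t"`.
#' @param groupVar grouping variable.
#' @return data.frame of comparison records, one per group pair.
#' @export
pairwiseTable <- function(x, gene, reference, groups = NULL,
                          test = c("auto", "mann-whitney", "student-t"),
                          groupVar = "group") {
    test <- match.arg(test)
    grp <- as.character(colData(x)[[groupVar]])
    if (is.null(groups)) groups <- sort(unique(grp[!is.na(grp)]))
    if (length(groups) < 2) stop("need at least 2 groups")
    if (!reference %in% groups)
        stop("reference group '", reference, "' not among selected groups")
    if (test == "auto") {
        np <- suppressWarnings(
            normalityByGroup(x, gene, groups, groupVar = groupVar))
        test <- routeTest(np)
    }
    cmb <- utils::combn(sort(groups), 2)
    out <- lapply(seq_len(ncol(cmb)), function(i) {
        a <- cmb[1, i]; b <- cmb[2, i]
        if (a == reference) { a <- cmb[2, i]; b <- reference }
        compareGroups(x, gene, a, b, test = test, groupVar = groupVar)
    })
    do.call(rbind, out)
}

#' Significance stars
#'
#' Maps p-values to the asterisk scheme used throughout the package:
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p <= 0.01, `***` for
#' p <= 0.001, `****` for p <= 0.0001 (the strongest applicable label
#' wins at scheme boundaries). Missing p gives a missing label; p
#' outside \[0, 1\] is an error. Smaller p never yields a weaker label.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of labels.
#' @examples
#' pStars(c(0.03, 0.05, 1e-4))   # "*", "ns", "****"
#' @export
pStars <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    vapply(p, function(pp) {
        if (is.na(pp)) return(NA_character_)
        if (pp <= 1e-4) "****"
        else if (pp <= 1e-3) "***"
        else if (pp <= 0.01) "**"
        else if (pp < 0.05) "*"
        else "ns"
    }, character(1))
}
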