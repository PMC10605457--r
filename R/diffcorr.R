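#' Choose the correlation method for a differential-correlation run
#'
#' One method is used for the whole run so that dR-val compares like
#' with like: Pearson if every gene passes the per-group normality
#' check (KS, alpha = 0.05) in every selected group, Spearman
#' otherwise. An explicit override always wins. Groups too small for a
#' normality p (fewer than 3 values) do not count against normality.
#'
#' @param x a [NormalizedSet-class].
#' @param groups group labels entering the run (default: all).
#' @param override optional `"pearson"` or `"spearman"`.
#' @param alpha normality threshold per gene and group.
#' @param groupVar grouping variable.
#' @return `"pearson"` or `"spearman"`.
#' @export
chooseCorrMethod <- function(x, groups = NULL, override = NULL,
                             alpha = 0.05, groupVar = "group") {
    if (!is.null(override))
        return(match.arg(override, c("pearson", "spearman")))
    grp <- as.character(colData(x)[[groupVar]])
    if (is.null(groups)) groups <- sort(unique(grp[!is.na(grp)]))
    for (g in rownames(x)) {
        np <- suppressWarnings(
            normalityByGroup(x, g, groups, groupVar = groupVar))
        if (any(np < alpha, na.rm = TRUE)) return("spearman")
    }
    "pearson"
}

# Correlation of two vectors on pairwise-complete observations.
# Spearman p: exact permutation null for n <= 9 without ties, otherwise
# the t-distribution approximation; Pearson p: t-distribution.
.corPair <- function(xv, yv, method) {
    ok <- !is.na(xv) & !is.na(yv)
    n <- sum(ok)
    if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n))
    xv <- xv[ok]; yv <- yv[ok]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
        return(list(r = NA_real_, p = NA_real_, n = n))
    if (method == "spearman") {
        ties <- anyDuplicated(xv) > 0 || anyDuplicated(yv) > 0
        ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman",
            exact = (n <= 9 && !ties)))
    } else {
        ct <- stats::cor.test(xv, yv, method = "pearson")
    }
    list(r = unname(ct$estimate), p = min(1, ct$p.value), n = n)
}

#' Per-group correlation matrix with significance gating
#'
#' Full symmetric correlation and p-value matrices over the target
#' genes within one group, on pairwise-complete observations, plus the
#' gated matrix in which each coefficient with `p > alpha` is set to
#' zero: a non-significant p-value is taken to show no correlation
#' regardless of the coefficient's magnitude. Pairs with fewer than 3
#' complete observations get missing `r` (gated to 0 and flagged by
#' `n < 3`).
#'
#' @param x a [NormalizedSet-class].
#' @param group group label (>= 3 samples).
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha gating threshold on the correlation p-value.
#' @param groupVar grouping variable.
#' @return A [GroupCorrelation-class].
#' @export
correlationMatrix <- function(x, group, method = c("spearman", "pearson"),
                              alpha = 0.05, groupVar = "group") {
    stopifnot(is(x, "NormalizedSet"))
    method <- match.arg(method)
    grp <- as.character(colData(x)[[groupVar]])
    if (!group %in% grp) stop("unknown group: ", group)
    m <- negDeltaCt(x)[, grp %in% group, drop = FALSE]
    if (ncol(m) < 3) stop("group ", group, " has fewer than 3 samples")
    k <- nrow(m)
    genes <- rownames(m)
    r <- p <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
    nmat <- tcrossprod(!is.na(m) * 1L)
    for (i in seq_len(k)) {
        vi <- m[i, ]
        if (sum(!is.na(vi)) >= 3) { r[i, i] <- 1; p[i, i] <- 0 }
        for (j in if (i < k) (i + 1):k else integer(0)) {
            cp <- .corPair(vi, m[j, ], method)
            r[i, j] <- r[j, i] <- cp$r
            p[i, j] <- p[j, i] <- cp$p
        }
    }
    gated <- r
    gated[is.na(r) | is.na(p) | p > alpha] <- 0
    diag(gated)[!is.na(diag(r))] <- 1
    new("GroupCorrelation", group = group, method = method,
        r = r, p = p, n = nmat, alpha = alpha, rGated = gated)
}

#' The dR-val statistic
#'
#' Absolute difference of two (significance-gated) correlation
#' coefficients of the same gene pair in two groups:
#' `dRval = |r_groupA - r_groupB|`, ranging 0 (no change in the
#' correlation profile) to 2 (complete flip from perfect positive to
#' perfect negative correlation or vice versa).
#'
#' @param rA,rB correlation coefficients in \[-1, 1\] (vectorized).
#' @return `|rA - rB|`.
#' @examples
#' drValue(0.43, -0.48)   # 0.91
#' @export
drValue <- function(rA, rB) {
    if (any(abs(rA) > 1, na.rm = TRUE) || any(abs(rB) > 1, na.rm = TRUE))
        stop("correlation coefficients must lie in [-1, 1]")
    abs(rA - rB)
}

#' Differential-correlation table over group pairs
#'
#' For each pair of groups containing the reference group (or the full
#' set of n(n-1)/2 group pairs with `allPairs = TRUE`) and every
#' unordered gene pair, the dR-val of the gated correlation
#' coefficients. Gene pairs whose coefficient is missing in either
#' group (fewer than 3 complete observations) are kept with missing
#' dR-val and `complete = FALSE`, and sort last.
#'
#' @param corrs named list of [GroupCorrelation-class] objects sharing
#'   genes, method, and alpha (one per group).
#' @param reference reference group label (must be in `names(corrs)`).
#' @param allPairs compute every group pair instead of reference-only.
#' @return data.frame `geneA`, `geneB`, `groupA`, `groupB`, `rGatedA`,
#'   `rGatedB`, `dRval`, `complete`, sorted by `dRval` descending.
#' @export
drvalTable <- function(corrs, reference, allPairs = FALSE) {
    stopifnot(length(corrs) >= 2)
    if (is.null(names(corrs)))
        names(corrs) <- vapply(corrs, function(z) z@group, character(1))
    if (!reference %in% names(corrs))
        stop("reference group '", reference, "' not among computed groups")
    methods <- unique(vapply(corrs, function(z) z@method, character(1)))
    alphas <- unique(vapply(corrs, function(z) z@alpha, numeric(1)))
    if (length(methods) > 1 || length(alphas) > 1)
        stop("all GroupCorrelation objects must share method and alpha")
    genes <- rownames(corrs[[1]]@r)
    if (!all(vapply(corrs, function(z) identical(rownames(z@r), genes),
                    logical(1))))
        stop("all GroupCorrelation objects must cover the same genes")
    gp <- if (allPairs) utils::combn(names(corrs), 2)
        else rbind(reference, setdiff(names(corrs), reference))
    ut <- which(upper.tri(corrs[[1]]@r), arr.ind = TRUE)
    out <- lapply(seq_len(ncol(gp)), function(i) {
        ga <- gp[1, i]; gb <- gp[2, i]
        ca <- corrs[[ga]]; cb <- corrs[[gb]]
        ok <- !is.na(ca@r[ut]) & !is.na(cb@r[ut])
        data.frame(
            geneA = genes[ut[, 1]], geneB = genes[ut[, 2]],
            groupA = ga, groupB = gb,
            rGatedA = ca@rGated[ut], rGatedB = cb@rGated[ut],
            dRval = ifelse(ok, abs(ca@rGated[ut] - cb@rGated[ut]), NA_real_),
            complete = ok, row.names = NULL)
    })
    out <- do.call(rbind, out)
    out[order(-out$dRval, out$geneA, out$geneB, na.last = TRUE), ]
}

#' Per-group scatter statistics for one gene pair
#'
#' Raw (ungated) correlation coefficient, p-value and pairwise-complete
#' count per group for two genes, plus the least-squares trend line
#' (slope and intercept of geneY on geneX) for plotting.
#'
#' @param x a [NormalizedSet-class].
#' @param geneX,geneY gene names (X and Y axes).
#' @param groups group labels (typically two).
#' @param method `"pearson"` or `"spearman"`.
#' @param groupVar grouping variable.
#' @return data.frame `group`, `r`, `p`, `n`, `slope`, `intercept`.
#' @export
pairScatterStats <- function(x, geneX, geneY, groups,
                             method = c("spearman", "pearson"),
                             groupVar = "group") {
    stopifnot(is(x, "NormalizedSet"))
    method <- match.arg(method)
    for (g in c(geneX, geneY))
        if (!g %in% rownames(x)) stop("unknown gene: ", g)
    grp <- as.character(colData(x)[[groupVar]])
    m <- negDeltaCt(x)
    rows <- lapply(groups, function(g) {
        sel <- !is.na(grp) & grp == g
        if (!any(sel)) stop("unknown group: ", g)
        xv <- m[geneX, sel]; yv <- m[geneY, sel]
        ok <- !is.na(xv) & !is.na(yv)
        if (sum(ok) < 3)
            stop("group ", g, " has fewer than 3 complete pairs")
        if (geneX == geneY) {
            cp <- list(r = 1, p = 0, n = sum(ok))
        } else {
            cp <- .corPair(xv, yv, method)
        }
        fit <- stats::lm.fit(cbind(1, xv[ok]), yv[ok])$coefficients
        data.frame(group = g, r = cp$r, p = cp$p, n = cp$n,
            slope = unname(fit[2]), intercept = unname(fit[1]),
            row.names = NULL)
    })
    do.call(rbind, rows)
}
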