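#' Housekeeping-gene stability (model-based variance decomposition)
#'
#' Scores candidate housekeeping genes, singly and in unordered pairs,
#' with a NormFinder-type stability value computed directly from Ct
#' values (already a log2-scale quantity), restricted to samples that
#' carry a label of the chosen grouping variable. Lower stability means
#' a more stable gene.
#'
#' The model decomposes, within each group, each candidate's Ct into a
#' gene effect, a sample effect and residual noise. Two-way centering
#' within the group removes the gene and sample effects; per-gene
#' intragroup variances are estimated from the residuals with an
#' unbiasedness correction (negative estimates truncated to zero). The
#' gene-by-group interaction of the group means (the intergroup
#' deviation `d`) is shrunken empirically toward zero in proportion to
#' its sampling variance. A gene's stability is the group average of
#' `|d_shrunken| + sqrt(posterior variance of d + sigma^2/n)`; with a
#' single group it reduces to `sqrt(sigma^2)` (intragroup variation
#' only). Pair stability applies the same combination rule to the
#' pairwise-averaged deviations `(d_i + d_j)/2` and variances
#' `(sigma2_i + sigma2_j)/4`, so a pair whose members deviate in
#' opposite directions can be more stable than either member.
#'
#' Missing values: within each group only samples complete for all
#' candidates enter (the two-way centering needs a rectangular matrix);
#' a group with fewer than 2 complete samples is dropped for the whole
#' computation with a warning, keeping the candidate set comparable.
#'
#' @param x a collapsed [CtExperiment-class].
#' @param candidates character vector of >= 2 candidate gene names.
#' @param groupVar name of the `colData` column holding the grouping
#'   labels (default the primary `"group"`).
#' @return A [StabilityReport-class] with per-gene and per-pair
#'   stability values and the selected best single gene / best pair
#'   (ties broken lexicographically).
#' @references Andersen CL, Jensen JL, Orntoft TF (2004). Normalization
#'   of real-time quantitative RT-PCR data: a model-based variance
#'   estimation approach. Cancer Research 64(15):5245-50.
#' @export
assessStability <- function(x, candidates, groupVar = "group") {
    stopifnot(is(x, "CtExperiment"))
    if (length(candidates) < 2)
        stop("need at least 2 candidate housekeeping genes")
    missing_g <- setdiff(candidates, rownames(x))
    if (length(missing_g))
        stop("candidate gene(s) not in table: ",
             paste(missing_g, collapse = ", "))
    candidates <- sort(unique(candidates))
    fit <- .stabilityModel(x, candidates, groupVar)
    single <- data.frame(gene = candidates,
        stability = vapply(candidates, function(g) .combineStability(
            fit$d[g, ], fit$vard[g, ], fit$sigma2[g, ],
            fit$n, fit$gamma2), numeric(1)),
        row.names = NULL)
    cp <- utils::combn(candidates, 2)
    pairs <- data.frame(geneA = cp[1, ], geneB = cp[2, ],
        stability = NA_real_, row.names = NULL)
    for (i in seq_len(ncol(cp))) {
        a <- cp[1, i]; b <- cp[2, i]
        pairs$stability[i] <- .combineStability(
            (fit$d[a, ] + fit$d[b, ]) / 2,
            (fit$vard[a, ] + fit$vard[b, ]) / 4,
            (fit$sigma2[a, ] + fit$sigma2[b, ]) / 4,
            fit$n, fit$gamma2)
    }
    bi <- which.min(single$stability)   # candidates sorted: first = lexicographic
    bp <- which.min(pairs$stability)
    new("StabilityReport",
        single = single, pairs = pairs,
        bestSingle = single$gene[bi],
        bestPair = sort(c(pairs$geneA[bp], pairs$geneB[bp])),
        groupsUsed = fit$groups, nPerGroup = fit$n)
}

# Fit the per-group variance decomposition over the candidate matrix.
# Returns per gene x group: sigma2 (intragroup variance), d (intergroup
# deviation), vard (sampling variance of d), plus the shrinkage scale.
.stabilityModel <- function(x, candidates, groupVar) {
    if (!groupVar %in% colnames(colData(x)))
        stop("unknown grouping variable: ", groupVar)
    grp <- as.character(colData(x)[[groupVar]])
    keep <- !is.na(grp) & nzchar(trimws(grp))
    if (!any(keep)) stop("no samples carry a '", groupVar, "' label")
    ct <- ctValues(x)[candidates, keep, drop = FALSE]
    grp <- trimws(grp[keep])
    k <- length(candidates)
    levs <- sort(unique(grp))
    dropped <- character(0)
    mats <- list()
    for (g in levs) {
        m <- ct[, grp == g, drop = FALSE]
        complete <- colSums(is.na(m)) == 0
        if (sum(complete) < 2) { dropped <- c(dropped, g); next }
        mats[[g]] <- m[, complete, drop = FALSE]
    }
    if (length(dropped))
        warning("group(s) dropped for stability (fewer than 2 complete ",
            "samples): ", paste(dropped, collapse = ", "), call. = FALSE)
    if (!length(mats))
        stop("no group has at least 2 complete samples for all candidates")
    G <- length(mats)
    n <- vapply(mats, ncol, integer(1))
    sigma2 <- matrix(NA_real_, k, G, dimnames = list(candidates, names(mats)))
    gmean <- sigma2
    for (g in names(mats)) {
        m <- mats[[g]]
        ng <- ncol(m)
        z <- m - rowMeans(m) - rep(colMeans(m), each = k) + mean(m)
        rv <- rowSums(z^2) / (ng - 1)
        if (k >= 3) {
            S <- k / (k - 1) * sum(rv)
            sigma2[, g] <- pmax(0, (rv - S / k^2) * k / (k - 2))
        } else {
            # two candidates: the shared residual variance cannot be
            # apportioned between them; assign it symmetrically
            sigma2[, g] <- pmax(0, 2 * rv)
        }
        gmean[, g] <- rowMeans(m)
    }
    if (G >= 2) {
        d <- gmean - rowMeans(gmean) -
            rep(colMeans(gmean), each = k) + mean(gmean)
        vard <- sweep((1 - 2 / k) * sigma2 +
            rep(colSums(sigma2), each = k) / k^2, 2, n, `/`)
        gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - mean(vard))
    } else {
        d <- matrix(0, k, 1, dimnames = dimnames(gmean))
        vard <- d
        gamma2 <- 0
    }
    list(sigma2 = sigma2, d = d, vard = vard, gamma2 = gamma2,
        n = n, groups = names(mats))
}

# Single-gene combination rule applied to one gene's (or one pair's
# averaged) per-group deviations and variances; arguments are vectors
# over the groups used.
.combineStability <- function(d, vard, sigma2, n, gamma2) {
    if (length(n) == 1)
        return(sqrt(sigma2[[1]]))        # single group: intragroup only
    shrink <- gamma2 / (gamma2 + vard)
    shrink[!is.finite(shrink)] <- 0      # gamma2 = 0 and vard = 0
    dtil <- d * shrink
    postvar <- vard * shrink
    se <- sqrt(postvar + sigma2 / n)
    mean(abs(dtil) + se)
}

#' Select the housekeeping normalizer set
#'
#' Implements the normalizer-selection policy: a user list with exactly
#' one gene is used as-is (the single-housekeeping workflow); a list of
#' two or more genes is scored with [assessStability()] and the best
#' pair is chosen; with no list at all, every gene in the table is
#' treated as a candidate (allowed but discouraged -- a warning is
#' issued, since target genes can masquerade as stable).
#'
#' @param x a collapsed [CtExperiment-class].
#' @param userList optional character vector of candidate housekeeping
#'   genes.
#' @param groupVar grouping variable for the stability computation.
#' @return Character vector of chosen normalizer gene names; when a
#'   stability computation was run, the [StabilityReport-class] is
#'   attached as attribute `"report"`.
#' @export
selectHousekeeping <- function(x, userList = NULL, groupVar = "group") {
    stopifnot(is(x, "CtExperiment"))
    if (!is.null(userList)) {
        unknown <- setdiff(userList, rownames(x))
        if (length(unknown))
            stop("unknown housekeeping gene(s): ",
                 paste(unknown, collapse = ", "))
        if (length(userList) == 1) return(userList)
        candidates <- userList
    } else {
        warning("no housekeeping list supplied; evaluating all genes as ",
            "candidates (results may be misleading)", call. = FALSE)
        candidates <- rownames(x)
    }
    report <- assessStability(x, candidates, groupVar = groupVar)
    out <- bestPair(report)
    attr(out, "report") <- report
    out
}
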