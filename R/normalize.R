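#' Livak normalization to -deltaCt
#'
#' For each sample, the normalizer (housekeeping) Ct values are averaged
#' arithmetically (the arithmetic mean of Ct corresponds to the
#' geometric mean of the underlying linear quantities) and each target
#' gene's -deltaCt is computed as `-(Ct_target - mean(Ct_housekeeping))`.
#' Normalizer genes are removed from the target set, and a -deltaCt is
#' missing whenever the target Ct or any normalizer Ct is missing for
#' that sample. Adding a constant to every Ct value leaves all -deltaCt
#' unchanged.
#'
#' @param x a collapsed [CtExperiment-class].
#' @param normalizers character vector of housekeeping gene names (e.g.
#'   from [selectHousekeeping()]); must be non-empty and present in `x`.
#' @param excludeGenes further genes to drop from the target set,
#'   typically the full housekeeping candidate list (a candidate that
#'   lost the stability contest is still a reference gene, not a
#'   target); default none beyond the normalizers themselves.
#' @return A [NormalizedSet-class] of target genes; if `normalizers`
#'   carries a `"report"` attribute (as returned by
#'   [selectHousekeeping()]) it is stored in `metadata(x)$stability`.
#' @references Livak KJ, Schmittgen TD (2001). Analysis of relative gene
#'   expression data using real-time quantitative PCR and the
#'   2^(-ddCt) method. Methods 25(4):402-8.
#' @examples
#' ct <- matrix(c(25, 20, 22), 3, 1,
#'              dimnames = list(c("tgt", "hk1", "hk2"), "s1"))
#' x <- CtExperiment(ct, "A", collapsed = TRUE)
#' negDeltaCt(deltaCt(x, c("hk1", "hk2")))   # -4
#' @export
deltaCt <- function(x, normalizers, excludeGenes = character(0)) {
    stopifnot(is(x, "CtExperiment"))
    normalizers <- as.character(normalizers)
    if (!length(normalizers)) stop("normalizer set must not be empty")
    unknown <- setdiff(c(normalizers, excludeGenes), rownames(x))
    if (length(unknown))
        stop("normalizer gene(s) not in table: ",
             paste(unknown, collapse = ", "))
    ct <- ctValues(x)
    hk <- ct[normalizers, , drop = FALSE]
    hkMean <- colMeans(hk)               # NA if any normalizer Ct missing
    targets <- setdiff(rownames(ct), c(normalizers, excludeGenes))
    if (!length(targets)) stop("no target genes left after removing normalizers")
    nd <- -(ct[targets, , drop = FALSE] -
        matrix(hkMean, length(targets), ncol(ct), byrow = TRUE))
    cd <- colData(x)
    out <- NormalizedSet(nd, group = as.character(cd$group),
        housekeeping = normalizers,
        sampleData = as.data.frame(cd[, setdiff(colnames(cd), "group"),
                                      drop = FALSE]))
    colnames(out) <- colnames(x)
    if (!is.null(attr(normalizers, "report")))
        metadata(out)$stability <- attr(normalizers, "report")
    out
}

#' Relative expression 2^(-ddCt) against a reference group
#'
#' Rescales one gene's -deltaCt values to fold units relative to a
#' reference group: each sample's 2^(-deltaCt) is divided by the
#' reference group's median on that same linear scale, so the median of
#' the returned values over the reference group is exactly 1 for any
#' reference size, a sample sitting at the reference median maps to 1,
#' and a sample one -deltaCt unit above it maps to 2. (Centering on the
#' linear scale rather than subtracting the log-scale median matters
#' only for even-sized reference groups, where a median does not
#' commute through the exponential.)
#'
#' @param x a [NormalizedSet-class].
#' @param gene target gene name.
#' @param referenceGroup reference group label (>= 1 non-missing value
#'   required).
#' @param groupVar grouping variable (default primary `"group"`).
#' @return data.frame with columns `sample`, `group`, `relExpr`.
#' @export
relativeExpression <- function(x, gene, referenceGroup, groupVar = "group") {
    stopifnot(is(x, "NormalizedSet"))
    if (!gene %in% rownames(x)) stop("unknown gene: ", gene)
    grp <- as.character(colData(x)[[groupVar]])
    if (!referenceGroup %in% grp)
        stop("reference group '", referenceGroup, "' not found")
    v <- negDeltaCt(x)[gene, ]
    ref <- v[grp == referenceGroup]
    if (all(is.na(ref)))
        stop("reference group has no non-missing values for ", gene)
    m <- stats::median(2^ref, na.rm = TRUE)
    data.frame(sample = colnames(x), group = grp,
        relExpr = 2^v / m, row.names = NULL)
}
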