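#' Benjamini-Hochberg adjustment with missing values
#'
#' Step-up false-discovery-rate adjustment over the non-missing
#' p-values; missing entries stay missing and do not count toward the
#' number of tests. Output is order-preserving, elementwise >= the
#' input, and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjustBH <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Genome-wide two-group screen (volcano table)
#'
#' Compares every target gene between two groups with one chosen test,
#' collects counts, medians, fold change, log2 fold change and p-value
#' per gene, and adjusts the p-values by Benjamini-Hochberg across all
#' genes of the run. Genes with fewer than 2 non-missing values in
#' either group get missing p-values (excluded from the adjustment) and
#' are flagged `tested = FALSE`. Classification columns are added by
#' [classifyGenes()].
#'
#' @param x a [NormalizedSet-class].
#' @param groupA,groupB two distinct group labels.
#' @param test `"mann-whitney"` or `"student-t"`.
#' @param groupVar grouping variable.
#' @return data.frame with one row per target gene: `gene`, `test`,
#'   `nA`, `nB`, `medianA`, `medianB`, `foldChange`, `log2FoldChange`,
#'   `pValue`, `pAdjusted`, `tested`.
#' @export
volcanoTable <- function(x, groupA, groupB,
                         test = c("mann-whitney", "student-t"),
                         groupVar = "group") {
    stopifnot(is(x, "NormalizedSet"))
    test <- match.arg(test)
    if (identical(groupA, groupB))
        stop("groupA and groupB must be different")
    grp <- as.character(colData(x)[[groupVar]])
    m <- negDeltaCt(x)
    rows <- lapply(rownames(m), function(g) {
        v <- m[g, ]
        a <- v[!is.na(v) & grp %in% groupA]
        b <- v[!is.na(v) & grp %in% groupB]
        if (length(a) < 2 || length(b) < 2)
            return(data.frame(gene = g, test = test,
                nA = length(a), nB = length(b),
                medianA = NA_real_, medianB = NA_real_,
                foldChange = NA_real_, log2FoldChange = NA_real_,
                pValue = NA_real_, tested = FALSE))
        ma <- stats::median(a); mb <- stats::median(b)
        data.frame(gene = g, test = test, nA = length(a), nB = length(b),
            medianA = ma, medianB = mb, foldChange = 2^(ma - mb),
            log2FoldChange = ma - mb,
            pValue = .twoGroupP(a, b, test), tested = TRUE)
    })
    out <- do.call(rbind, rows)
    out$pAdjusted <- adjustBH(out$pValue)
    out[c("gene", "test", "nA", "nB", "medianA", "medianB", "foldChange",
          "log2FoldChange", "pValue", "pAdjusted", "tested")]
}

#' Classify genes by fold-change and p thresholds
#'
#' Adds a `class` column to a volcano table: `significant` when
#' `|log2FC| > log2(fcThreshold)` AND the chosen p-value `< pThreshold`
#' (both strict, so a gene sitting exactly at a threshold is not
#' called), `fc_only` / `p_only` when only one condition holds, `ns`
#' otherwise. Untested genes (missing p) are classed `ns`. A `label`
#' flag marks significant genes for plot labeling.
#'
#' @param tab a data.frame from [volcanoTable()].
#' @param fcThreshold fold-change threshold (>= 1), in fold units.
#' @param pThreshold p-value threshold in (0, 1\].
#' @param useAdjusted use `pAdjusted` instead of raw `pValue`.
#' @return `tab` with `class` and `label` columns.
#' @export
classifyGenes <- function(tab, fcThreshold = 2, pThreshold = 1e-4,
                          useAdjusted = FALSE) {
    stopifnot(fcThreshold >= 1, pThreshold > 0, pThreshold <= 1)
    p <- if (useAdjusted) tab$pAdjusted else tab$pValue
    fcPass <- !is.na(tab$log2FoldChange) &
        abs(tab$log2FoldChange) > log2(fcThreshold)
    pPass <- !is.na(p) & p < pThreshold
    tab$class <- ifelse(fcPass & pPass, "significant",
        ifelse(fcPass, "fc_only", ifelse(pPass, "p_only", "ns")))
    tab$label <- tab$class == "significant"
    tab
}
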