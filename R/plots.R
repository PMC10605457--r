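#' @importFrom ggplot2 ggplot aes geom_boxplot geom_jitter geom_point
#'   geom_hline geom_vline geom_abline geom_text annotate facet_wrap
#'   labs theme_bw theme element_text scale_color_manual ggsave
NULL

#' Expression boxplot with significance stars
#'
#' Boxplot of one gene per group, on the -deltaCt scale or as
#' 2^(-ddCt) relative to the reference group, annotated with the
#' asterisk label of each group's comparison against the reference.
#'
#' @param x a [NormalizedSet-class].
#' @param gene gene name.
#' @param reference reference group label.
#' @param groups groups to plot (default all).
#' @param scale `"negDeltaCt"` or `"relative"` (2^(-ddCt), reference
#'   median 1).
#' @param test routing as in [pairwiseTable()].
#' @param groupVar grouping variable.
#' @return A ggplot object.
#' @export
plotExpressionBox <- function(x, gene, reference, groups = NULL,
                              scale = c("negDeltaCt", "relative"),
                              test = "auto", groupVar = "group") {
    scale <- match.arg(scale)
    grp <- as.character(colData(x)[[groupVar]])
    if (is.null(groups)) groups <- sort(unique(grp[!is.na(grp)]))
    tab <- pairwiseTable(x, gene, reference, groups, test = test,
        groupVar = groupVar)
    ref <- tab[tab$groupB == reference, ]
    stars <- stats::setNames(ref$stars, ref$groupA)
    if (scale == "relative") {
        df <- relativeExpression(x, gene, reference, groupVar)
        df <- df[df$group %in% groups, ]
        df$y <- df$relExpr
        ylab <- sprintf("%s relative expression (2^-ddCt, %s = 1)",
            gene, reference)
    } else {
        v <- negDeltaCt(x)[gene, ]
        df <- data.frame(group = grp, y = v)[grp %in% groups, ]
        ylab <- sprintf("%s expression (-dCt)", gene)
    }
    df <- df[!is.na(df$y), ]
    ann <- data.frame(group = names(stars), lab = unname(stars))
    top <- max(df$y, na.rm = TRUE)
    ggplot(df, aes(x = group, y = y)) +
        geom_boxplot(outlier.shape = NA) +
        geom_jitter(width = 0.15, alpha = 0.35, size = 0.7) +
        geom_text(data = ann, aes(x = group, label = lab),
            y = top + 0.06 * abs(top), size = 4) +
        labs(x = groupVar, y = ylab,
            subtitle = sprintf("vs %s, %s", reference, tab$test[1])) +
        theme_bw()
}

#' Volcano plot
#'
#' log2 fold change against -log10 p for a classified volcano table;
#' significant genes are labeled.
#'
#' @param tab output of [classifyGenes()].
#' @param useAdjusted plot adjusted instead of raw p-values.
#' @return A ggplot object.
#' @export
plotVolcano <- function(tab, useAdjusted = FALSE) {
    tab <- tab[!is.na(tab$pValue), ]
    tab$mlp <- -log10(if (useAdjusted) tab$pAdjusted else tab$pValue)
    cols <- c(ns = "grey60", fc_only = "forestgreen",
        p_only = "steelblue", significant = "firebrick")
    p <- ggplot(tab, aes(x = log2FoldChange, y = mlp,
            color = class)) +
        geom_point(size = 1.4) +
        scale_color_manual(values = cols) +
        labs(x = "log2 fold change",
            y = if (useAdjusted) "-log10 adjusted p" else "-log10 p",
            color = NULL) +
        theme_bw()
    lab <- tab[tab$label, ]
    if (nrow(lab))
        p <- p + geom_text(data = lab, aes(label = gene),
            vjust = -0.6, size = 2.6, show.legend = FALSE)
    p
}

#' Differential-correlation dot plot
#'
#' dR-val of every gene pair, one panel per group comparison, sorted by
#' pair index; the static counterpart of an interactive hover plot (the
#' sorted table from [drvalTable()] carries the identities).
#'
#' @param tab output of [drvalTable()].
#' @return A ggplot object.
#' @export
plotDrDotplot <- function(tab) {
    tab <- tab[tab$complete, ]
    tab$comparison <- paste(tab$groupA, "vs", tab$groupB)
    tab$idx <- stats::ave(tab$dRval, tab$comparison,
        FUN = function(z) seq_along(z))
    ggplot(tab, aes(x = idx, y = dRval)) +
        geom_point(alpha = 0.5, size = 0.8) +
        facet_wrap(~comparison) +
        labs(x = "gene pair (sorted by dR-val)", y = "dR-val") +
        theme_bw()
}

#' Two-panel scatter plot for one gene pair
#'
#' -deltaCt of one gene against the other, one panel per group, each
#' with its least-squares trend line and the correlation r / p
#' annotation from [pairScatterStats()].
#'
#' @param x a [NormalizedSet-class].
#' @param geneX,geneY gene names.
#' @param groups two group labels.
#' @param method correlation method.
#' @param groupVar grouping variable.
#' @return A ggplot object.
#' @export
plotPairScatter <- function(x, geneX, geneY, groups,
                            method = c("spearman", "pearson"),
                            groupVar = "group") {
    method <- match.arg(method)
    st <- pairScatterStats(x, geneX, geneY, groups, method, groupVar)
    grp <- as.character(colData(x)[[groupVar]])
    m <- negDeltaCt(x)
    df <- data.frame(group = grp, xv = m[geneX, ], yv = m[geneY, ])
    df <- df[df$group %in% groups & !is.na(df$xv) & !is.na(df$yv), ]
    st$lab <- sprintf("r = %.2f, p = %.3g", st$r, st$p)
    ggplot(df, aes(x = xv, y = yv)) +
        geom_point(alpha = 0.6, size = 1) +
        geom_abline(data = st,
            aes(slope = slope, intercept = intercept),
            color = "firebrick") +
        geom_text(data = st, aes(label = lab),
            x = min(df$xv), y = max(df$yv), hjust = 0, vjust = 1,
            size = 3, inherit.aes = FALSE) +
        facet_wrap(~group) +
        labs(x = sprintf("%s (-dCt)", geneX),
             y = sprintf("%s (-dCt)", geneY)) +
        theme_bw()
}

#' Export a figure at publication resolution
#'
#' Writes a ggplot to a raster file at 600 dots per inch.
#'
#' @param plot a ggplot object.
#' @param path output path (extension selects the device, e.g. `.png`).
#' @param width,height size in inches.
#' @param dpi resolution (default 600).
#' @return `path`, invisibly.
#' @export
exportFigure <- function(plot, path, width = 7, height = 5, dpi = 600) {
    if (is.null(plot)) stop("nothing to export")
    ggsave(path, plot = plot, width = width, height = height, dpi = dpi)
    invisible(path)
}
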