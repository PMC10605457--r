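utils::globalVariables(c("group", "y", "lab", "log2FoldChange", "mlp",
    "class", "gene", "idx", "dRval", "xv", "yv", "slope", "intercept"))

#' Run the full analysis pipeline
#'
#' Ties the stages together: read (or accept) a Ct table, collapse
#' technical replicates, select the housekeeping normalizers, normalize
#' to -deltaCt, and run any requested analyses (gene-wise expression
#' comparison, volcano screen, differential correlation, pair scatter).
#' Every output table is written as CSV with a provenance header (tool
#' version, parameters); figures are written as 600-dpi PNG. The run is
#' deterministic for a fixed input and configuration.
#'
#' @param config a list with elements: `input` (path, or a
#'   [CtExperiment-class] directly), `layout`, `filetype`,
#'   `housekeeping` (character vector, or NULL for all-gene candidate
#'   scoring), `groupVar` (default "group"), `reference` (reference
#'   group; default first group), `test` ("auto"/"mann-whitney"/
#'   "student-t"), `gene` (genes for expression analysis; default
#'   none), `volcano` (list(groupA, groupB) or NULL), `diffcorr`
#'   (TRUE/FALSE), `corrMethod` ("auto"/"pearson"/"spearman"), `alpha`
#'   (gating threshold, default 0.05), `fcThreshold`, `pThreshold`,
#'   `useAdjusted`, `figures` (logical, default TRUE), `outputDir`.
#' @return Invisibly, a list with the [NormalizedSet-class], the
#'   [StabilityReport-class] (if computed), and the paths written.
#' @export
runPipeline <- function(config) {
    cfg <- utils::modifyList(list(layout = "auto", filetype = "auto",
        housekeeping = NULL, groupVar = "group", reference = NULL,
        test = "auto", gene = character(0), volcano = NULL,
        diffcorr = FALSE, corrMethod = "auto", alpha = 0.05,
        fcThreshold = 2, pThreshold = 1e-4, useAdjusted = FALSE,
        figures = TRUE, outputDir = "ctflow-out"), config)
    if (is.null(cfg$input)) stop("config$input is required")
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)

    x <- if (is(cfg$input, "CtExperiment")) cfg$input
        else readCtTable(cfg$input, cfg$layout, cfg$filetype)
    if (!cfg$groupVar %in% colnames(colData(x)))
        stop("unknown grouping variable: ", cfg$groupVar)
    x <- collapseReplicates(x)

    hk <- selectHousekeeping(x, cfg$housekeeping, groupVar = "group")
    message("normalizers: ", paste(hk, collapse = ", "))
    report <- attr(hk, "report")
    if (!is.null(report)) {
        paths <- c(paths,
            .writeTable(singleStability(report),
                file.path(cfg$outputDir, "stability_single.csv"), cfg),
            .writeTable(pairStability(report),
                file.path(cfg$outputDir, "stability_pairs.csv"), cfg))
    }
    norm <- deltaCt(x, hk, excludeGenes = cfg$housekeeping)
    ndPath <- file.path(cfg$outputDir, "normalized_negDeltaCt.csv")
    writeNormalized(norm, ndPath)
    paths <- c(paths, ndPath)

    grpAll <- sort(unique(as.character(colData(norm)[[cfg$groupVar]])))
    if (is.null(cfg$reference)) cfg$reference <- grpAll[1]

    for (g in cfg$gene) {
        tab <- pairwiseTable(norm, g, cfg$reference, grpAll,
            test = cfg$test, groupVar = cfg$groupVar)
        paths <- c(paths, .writeTable(tab,
            file.path(cfg$outputDir, paste0("expression_", g, ".csv")), cfg))
        if (cfg$figures)
            paths <- c(paths, exportFigure(
                plotExpressionBox(norm, g, cfg$reference, grpAll,
                    test = cfg$test, groupVar = cfg$groupVar),
                file.path(cfg$outputDir, paste0("boxplot_", g, ".png"))))
    }

    if (!is.null(cfg$volcano)) {
        vt <- volcanoTable(norm, cfg$volcano[[1]], cfg$volcano[[2]],
            test = if (cfg$test %in% c("mann-whitney", "student-t"))
                cfg$test else "mann-whitney",
            groupVar = cfg$groupVar)
        vt <- classifyGenes(vt, cfg$fcThreshold, cfg$pThreshold,
            cfg$useAdjusted)
        paths <- c(paths, .writeTable(vt,
            file.path(cfg$outputDir, "volcano.csv"), cfg))
        if (cfg$figures)
            paths <- c(paths, exportFigure(plotVolcano(vt, cfg$useAdjusted),
                file.path(cfg$outputDir, "volcano.png")))
    }

    if (isTRUE(cfg$diffcorr)) {
        method <- if (cfg$corrMethod == "auto")
            chooseCorrMethod(norm, grpAll, groupVar = cfg$groupVar)
            else cfg$corrMethod
        corrs <- lapply(grpAll, function(g)
            correlationMatrix(norm, g, method, cfg$alpha, cfg$groupVar))
        names(corrs) <- grpAll
        dt <- drvalTable(corrs, cfg$reference)
        paths <- c(paths, .writeTable(dt,
            file.path(cfg$outputDir, "diffcorr.csv"), cfg))
        if (cfg$figures)
            paths <- c(paths, exportFigure(plotDrDotplot(dt),
                file.path(cfg$outputDir, "diffcorr.png")))
    }

    invisible(list(normalized = norm, stability = report,
        housekeeping = as.character(hk), paths = paths))
}

# CSV with provenance header lines prefixed '#'
.writeTable <- function(df, path, cfg) {
    con <- file(path, "w")
    on.exit(close(con))
    keep <- !vapply(cfg, function(z) is.null(z) || is.object(z) ||
        is.list(z) && length(z) > 2, logical(1))
    prm <- vapply(cfg[keep], function(z)
        paste(as.character(unlist(z)), collapse = " "), character(1))
    writeLines(c(
        paste0("# ctflow ", as.character(utils::packageVersion("ctflow"))),
        paste0("# ", names(prm), ": ", prm)), con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    path
}
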