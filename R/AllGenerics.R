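#' Accessors
#'
#' Small accessor generics for the package's classes: `ctValues()` and
#' `negDeltaCt()` return the assay matrices, `sampleGroups()` the primary
#' group labels, `geneNames()` the row (gene) names, `housekeeping()` the
#' normalizer set of a [NormalizedSet-class], `bestSingle()`/`bestPair()`
#' the selected genes of a [StabilityReport-class], and `gatedR()` the
#' significance-gated correlation matrix of a [GroupCorrelation-class].
#'
#' @param x an object of the documented class.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))
#' @rdname accessors
#' @export
setGeneric("negDeltaCt", function(x) standardGeneric("negDeltaCt"))
#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("housekeeping", function(x) standardGeneric("housekeeping"))
#' @rdname accessors
#' @export
setGeneric("bestSingle", function(x) standardGeneric("bestSingle"))
#' @rdname accessors
#' @export
setGeneric("bestPair", function(x) standardGeneric("bestPair"))
#' @rdname accessors
#' @export
setGeneric("singleStability", function(x) standardGeneric("singleStability"))
#' @rdname accessors
#' @export
setGeneric("pairStability", function(x) standardGeneric("pairStability"))
#' @rdname accessors
#' @export
setGeneric("gatedR", function(x) standardGeneric("gatedR"))

#' @rdname accessors
setMethod("ctValues", "CtExperiment", function(x) assay(x, "ct"))
#' @rdname accessors
setMethod("negDeltaCt", "NormalizedSet", function(x) assay(x, "negDeltaCt"))
#' @rdname accessors
setMethod("sampleGroups", "SummarizedExperiment",
    function(x) as.character(colData(x)$group))
#' @rdname accessors
setMethod("geneNames", "SummarizedExperiment", function(x) rownames(x))
#' @rdname accessors
setMethod("housekeeping", "NormalizedSet", function(x) x@housekeeping)
#' @rdname accessors
setMethod("bestSingle", "StabilityReport", function(x) x@bestSingle)
#' @rdname accessors
setMethod("bestPair", "StabilityReport", function(x) x@bestPair)
#' @rdname accessors
setMethod("singleStability", "StabilityReport", function(x) x@single)
#' @rdname accessors
setMethod("pairStability", "StabilityReport", function(x) x@pairs)
#' @rdname accessors
setMethod("gatedR", "GroupCorrelation", function(x) x@rGated)

setMethod("show", "CtExperiment", function(object) {
    grp <- sampleGroups(object)
    cat("CtExperiment:", nrow(object), "genes x", ncol(object), "samples",
        if (object@collapsed) "(replicates collapsed)" else "(raw rows)", "\n")
    cat("  groups:", paste(sprintf("%s (n=%d)", names(table(grp)), table(grp)),
        collapse = ", "), "\n")
    extra <- setdiff(colnames(colData(object)), "group")
    if (length(extra))
        cat("  secondary variables:", paste(extra, collapse = ", "), "\n")
    cat("  missing Ct cells:", sum(is.na(ctValues(object))), "\n")
})

setMethod("show", "NormalizedSet", function(object) {
    cat("NormalizedSet: -deltaCt for", nrow(object), "target genes x",
        ncol(object), "samples\n")
    cat("  normalizers:", paste(object@housekeeping, collapse = ", "), "\n")
    cat("  groups:", paste(unique(sampleGroups(object)), collapse = ", "), "\n")
})

setMethod("show", "StabilityReport", function(object) {
    cat("StabilityReport over", nrow(object@single), "candidates,",
        length(object@groupsUsed), "groups\n")
    cat("  best single:", object@bestSingle,
        sprintf("(stability %.4f)\n", min(object@single$stability)))
    if (nrow(object@pairs))
        cat("  best pair:", paste(object@bestPair, collapse = " + "),
            sprintf("(stability %.4f)\n", min(object@pairs$stability)))
})

setMethod("show", "GroupCorrelation", function(object) {
    cat("GroupCorrelation for group", object@group, "-", object@method,
        "correlation,", nrow(object@r), "genes\n")
    off <- object@rGated[upper.tri(object@rGated)]
    cat(sprintf("  alpha = %g; %d of %d gene pairs pass the gate\n",
        object@alpha, sum(off != 0), length(off)))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", nrow(object@groupMeans), "target genes,",
        ncol(object@groupMeans), "groups, seed", object@seed, "\n")
    cat("  housekeeping candidates:", paste(object@hkGenes, collapse = ", "), "\n")
    if (nrow(object@corrPairs))
        cat("  planted correlation targets:", nrow(object@corrPairs), "\n")
})
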