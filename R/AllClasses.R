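#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData colData<-
NULL

#' CtExperiment: raw cycle-threshold values with sample annotation
#'
#' A container for a qPCR experiment recorded as cycle-threshold (Ct)
#' values. Genes are rows, samples are columns (the Bioconductor
#' convention); the single assay is named `"ct"`. `colData` carries the
#' mandatory primary `group` label and any number of secondary
#' categorical variables joined from sample metadata. Sample identifiers
#' are the column names; before [collapseReplicates()] they may repeat
#' (technical replicates share the identifier and the group label).
#'
#' Ct values are PCR cycles: finite, nonnegative, typically 10-40.
#' Missing measurements (blank cells, "Undetermined", ">40" in input
#' files) are stored as `NA`.
#'
#' @slot collapsed logical scalar; `TRUE` once technical replicates have
#'   been collapsed, after which sample identifiers are unique.
#' @export
setClass("CtExperiment",
    contains = "SummarizedExperiment",
    representation(collapsed = "logical"),
    prototype(collapsed = FALSE)
)

.validCtExperiment <- function(object) {
    msg <- character(0)
    if (!"ct" %in% names(assays(object)))
        msg <- c(msg, "assay 'ct' is required")
    else {
        ct <- assay(object, "ct")
        if (!is.numeric(ct))
            msg <- c(msg, "Ct values must be numeric")
        else {
            bad <- ct[!is.na(ct)]
            if (any(!is.finite(bad)) || any(bad < 0))
                msg <- c(msg, "Ct values must be finite and nonnegative (or NA)")
        }
    }
    if (is.null(rownames(object)) || anyNA(rownames(object)) ||
        any(!nzchar(rownames(object))))
        msg <- c(msg, "gene names must be non-empty")
    else if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene names must be unique")
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        grp <- as.character(colData(object)$group)
        if (anyNA(grp) || any(!nzchar(trimws(grp))))
            msg <- c(msg, "every sample needs a non-empty primary group")
    }
    if (is.null(colnames(object)) || any(!nzchar(colnames(object))))
        msg <- c(msg, "sample identifiers must be non-empty")
    if (isTRUE(object@collapsed) && anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique after replicate collapsing")
    if (length(msg)) msg else TRUE
}
setValidity("CtExperiment", .validCtExperiment)

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of Ct values, genes in rows, samples in
#'   columns; dimnames required.
#' @param group character vector of primary group labels, one per sample.
#' @param sampleData optional data.frame of further per-sample
#'   categorical variables (secondary variables).
#' @param collapsed logical; set `TRUE` when the columns are already one
#'   row per biological sample.
#' @return A [CtExperiment-class] object.
#' @examples
#' ct <- matrix(c(20, 21, 25, 26), 2, 2,
#'              dimnames = list(c("ACTB", "TP53"), c("s1", "s2")))
#' CtExperiment(ct, group = c("A", "B"))
#' @export
CtExperiment <- function(ct, group, sampleData = NULL, collapsed = FALSE) {
    ct <- as.matrix(ct)
    cd <- DataFrame(group = trimws(as.character(group)))
    if (!is.null(sampleData) && ncol(as.data.frame(sampleData)) > 0) {
        stopifnot(nrow(sampleData) == ncol(ct))
        cd <- cbind(cd, DataFrame(sampleData))
    }
    se <- SummarizedExperiment(assays = list(ct = ct), colData = cd)
    new("CtExperiment", se, collapsed = collapsed)
}

#' NormalizedSet: -deltaCt values for target genes
#'
#' Livak-normalized expression: for each sample the mean Ct of the
#' housekeeping (normalizer) genes is subtracted from each target gene's
#' Ct and the sign flipped, so higher values mean higher expression on a
#' log2 scale. Normalizer genes are excluded from the rows. A -deltaCt
#' is `NA` iff the target Ct or any required housekeeping Ct is missing
#' for that sample. The stability report (if normalizers were chosen
#' automatically) travels in `metadata(x)$stability`.
#'
#' @slot housekeeping character vector of normalizer gene names used.
#' @export
setClass("NormalizedSet",
    contains = "SummarizedExperiment",
    representation(housekeeping = "character")
)

.validNormalizedSet <- function(object) {
    msg <- character(0)
    if (!"negDeltaCt" %in% names(assays(object)))
        msg <- c(msg, "assay 'negDeltaCt' is required")
    if (any(object@housekeeping %in% rownames(object)))
        msg <- c(msg, "normalizer genes must not appear among target genes")
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (length(msg)) msg else TRUE
}
setValidity("NormalizedSet", .validNormalizedSet)

#' Construct a NormalizedSet
#'
#' Usually produced by [deltaCt()]; the constructor is exported for
#' round-tripping written tables.
#'
#' @param negDeltaCt numeric matrix of -deltaCt values, target genes in
#'   rows, samples in columns.
#' @param group primary group label per sample.
#' @param housekeeping names of the normalizer genes that were used.
#' @param sampleData optional extra per-sample columns.
#' @return A [NormalizedSet-class].
#' @export
NormalizedSet <- function(negDeltaCt, group, housekeeping = character(0),
                          sampleData = NULL) {
    m <- as.matrix(negDeltaCt)
    cd <- DataFrame(group = as.character(group))
    if (!is.null(sampleData) && ncol(as.data.frame(sampleData)) > 0)
        cd <- cbind(cd, DataFrame(sampleData))
    se <- SummarizedExperiment(assays = list(negDeltaCt = m), colData = cd)
    new("NormalizedSet", se, housekeeping = as.character(housekeeping))
}

#' StabilityReport: housekeeping-gene stability values
#'
#' Model-based stability values for candidate housekeeping genes, singly
#' and in unordered pairs. Lower values mean more stable genes. The best
#' single gene and best pair minimize the respective stability value
#' (ties broken lexicographically).
#'
#' @slot single data.frame with columns `gene`, `stability`.
#' @slot pairs data.frame with columns `geneA`, `geneB`, `stability`.
#' @slot bestSingle character scalar.
#' @slot bestPair character vector of length 2 (sorted).
#' @slot groupsUsed group labels that entered the computation.
#' @slot nPerGroup integer vector (named by group) of complete samples used.
#' @export
setClass("StabilityReport",
    representation(
        single = "data.frame",
        pairs = "data.frame",
        bestSingle = "character",
        bestPair = "character",
        groupsUsed = "character",
        nPerGroup = "integer"
    )
)

.validStabilityReport <- function(object) {
    msg <- character(0)
    s <- object@single$stability
    p <- object@pairs$stability
    if (length(s) && (any(!is.finite(s)) || any(s < 0)))
        msg <- c(msg, "single stability values must be finite and >= 0")
    if (length(p) && (any(!is.finite(p)) || any(p < 0)))
        msg <- c(msg, "pair stability values must be finite and >= 0")
    if (length(s) && length(object@bestSingle) &&
        abs(min(s) - s[match(object@bestSingle, object@single$gene)]) > 1e-12)
        msg <- c(msg, "bestSingle must attain the minimal single stability")
    if (length(msg)) msg else TRUE
}
setValidity("StabilityReport", .validStabilityReport)

#' GroupCorrelation: per-group gene-gene correlation with p-gating
#'
#' Symmetric correlation (`r`) and p-value matrices over target genes
#' within one group, on pairwise-complete observations, plus the gated
#' matrix `rGated` in which every coefficient whose p-value exceeds
#' `alpha` is set to zero (a non-significant correlation is treated as
#' no correlation regardless of its magnitude). Entries with fewer than
#' 3 pairwise-complete observations have `NA` in `r` and 0 in `rGated`.
#'
#' @slot group group label.
#' @slot method "pearson" or "spearman".
#' @slot r,p,n numeric matrices (n = pairwise-complete counts).
#' @slot alpha significance threshold used for gating.
#' @slot rGated gated coefficient matrix.
#' @export
setClass("GroupCorrelation",
    representation(
        group = "character",
        method = "character",
        r = "matrix",
        p = "matrix",
        n = "matrix",
        alpha = "numeric",
        rGated = "matrix"
    )
)

.validGroupCorrelation <- function(object) {
    msg <- character(0)
    r <- object@r; p <- object@p; g <- object@rGated
    if (!isTRUE(all.equal(r, t(r), check.attributes = FALSE)))
        msg <- c(msg, "r must be symmetric")
    rr <- r[!is.na(r)]
    if (length(rr) && any(rr < -1 - 1e-8 | rr > 1 + 1e-8))
        msg <- c(msg, "r must lie in [-1, 1]")
    gate <- !is.na(p) & p > object@alpha
    if (any(g[gate] != 0))
        msg <- c(msg, "rGated must be zero wherever p > alpha")
    if (length(msg)) msg else TRUE
}
setValidity("GroupCorrelation", .validGroupCorrelation)

#' SyntheticTruth: planted parameters of a generated Ct dataset
#'
#' Records everything the generator planted so downstream recovery can
#' be scored: per-target group means on the -deltaCt scale, the
#' housekeeping candidates with their noise and intergroup shifts,
#' per-group correlation targets for designated gene pairs, and the
#' missingness/replicate scheme.
#'
#' @slot groupMeans matrix (target gene x group) of planted -deltaCt means.
#' @slot hkGenes housekeeping candidate names.
#' @slot hkSD,hkShift per-candidate intragroup SD and intergroup shift span (Ct units).
#' @slot corrPairs data.frame `geneA`, `geneB`, `group`, `r` of planted correlations.
#' @slot targetSD intragroup SD of target genes (-deltaCt units).
#' @slot missingRate,replicateRate fractions in [0, 1].
#' @slot seed integer seed used.
#' @export
setClass("SyntheticTruth",
    representation(
        groupMeans = "matrix",
        hkGenes = "character",
        hkSD = "numeric",
        hkShift = "numeric",
        corrPairs = "data.frame",
        targetSD = "numeric",
        missingRate = "numeric",
        replicateRate = "numeric",
        seed = "integer"
    )
)

.validSyntheticTruth <- function(object) {
    msg <- character(0)
    if (nrow(object@corrPairs) &&
        any(abs(object@corrPairs$r) > 1))
        msg <- c(msg, "planted correlations must lie in [-1, 1]")
    if (any(object@hkSD <= 0) || any(object@targetSD <= 0))
        msg <- c(msg, "planted SDs must be > 0")
    if (length(msg)) msg else TRUE
}
setValidity("SyntheticTruth", .validSyntheticTruth)
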