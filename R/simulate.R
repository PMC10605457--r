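#' Simulate a Ct dataset with planted ground truth
#'
#' Generates a seeded qPCR Ct table emulating the structure of a
#' large-scale (single-cell style) experiment: stable and unstable
#' housekeeping candidates, target genes with planted per-group mean
#' shifts on the -deltaCt scale, designated gene pairs with planted
#' per-group correlations, a per-sample loading effect common to all
#' genes, sporadic completely-at-random missingness, and optional
#' technical replicates.
#'
#' Signals are planted on the -deltaCt scale and mapped to Ct by
#' subtracting them from a fixed per-gene baseline and adding the
#' per-sample loading, so Livak normalization against the stable
#' housekeeping genes inverts the construction in the noise-free limit.
#' The first two housekeeping candidates are planted stable (small SD,
#' zero intergroup shift); later candidates get larger SDs and
#' intergroup shifts, so the stable pair is the ground-truth best pair.
#'
#' @param nGroups,nPerGroup number of groups and samples per group.
#' @param nTargets,nHousekeeping number of target genes and housekeeping
#'   candidates.
#' @param groupMeans optional nTargets x nGroups matrix of planted
#'   -deltaCt group means (default all zero; rownames become gene
#'   names).
#' @param corrPairs optional data.frame `geneA`, `geneB`, `group`, `r`
#'   of planted within-group correlations (a gene may appear in at most
#'   one pair).
#' @param targetSD intragroup SD of target genes in -deltaCt units
#'   (recycled per gene).
#' @param hkSD,hkShift per-candidate intragroup SD and intergroup shift
#'   (Ct units; the shift is applied in the candidate's own group,
#'   cycling through the groups, so shifted candidates do not cancel
#'   each other); defaults plant candidates 1-2 stable and the rest
#'   increasingly unstable.
#' @param loadingSD SD of the per-sample loading common to all genes.
#' @param missingRate,replicateRate fraction of missing Ct cells, and
#'   fraction of samples measured twice as technical replicates.
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with `ct` (a [CtExperiment-class]) and `truth` (a
#'   [SyntheticTruth-class]).
#' @export
simulateCtData <- function(nGroups = 2, nPerGroup = 80, nTargets = 20,
                           nHousekeeping = 5, groupMeans = NULL,
                           corrPairs = NULL, targetSD = 0.5,
                           hkSD = NULL, hkShift = NULL,
                           loadingSD = 0.8, missingRate = 0.02,
                           replicateRate = 0, seed = 1L) {
    stopifnot(nGroups >= 1, nPerGroup >= 2, nTargets >= 1,
        nHousekeeping >= 1, missingRate >= 0, missingRate < 1,
        replicateRate >= 0, replicateRate <= 1)
    set.seed(as.integer(seed))
    groups <- paste0("Group", seq_len(nGroups))
    if (is.null(groupMeans)) {
        groupMeans <- matrix(0, nTargets, nGroups,
            dimnames = list(sprintf("T%02d", seq_len(nTargets)), groups))
    } else {
        groupMeans <- as.matrix(groupMeans)
        stopifnot(nrow(groupMeans) == nTargets, ncol(groupMeans) == nGroups)
        if (is.null(rownames(groupMeans)))
            rownames(groupMeans) <- sprintf("T%02d", seq_len(nTargets))
        colnames(groupMeans) <- groups
    }
    tnames <- rownames(groupMeans)
    if (is.null(hkSD))
        hkSD <- rep_len(c(0.15, 0.15, 0.35, 0.45, 0.40), nHousekeeping)
    else hkSD <- rep_len(hkSD, nHousekeeping)
    if (is.null(hkShift))
        hkShift <- rep_len(c(0, 0, 0.3, 0.6, 0.45), nHousekeeping)
    else hkShift <- rep_len(hkShift, nHousekeeping)
    hknames <- paste0("HK", seq_len(nHousekeeping))
    targetSD <- rep_len(targetSD, nTargets)
    if (is.null(corrPairs))
        corrPairs <- data.frame(geneA = character(0), geneB = character(0),
            group = character(0), r = numeric(0))
    if (nrow(corrPairs)) {
        stopifnot(all(c(corrPairs$geneA, corrPairs$geneB) %in% tnames),
            all(corrPairs$group %in% groups))
        if (any(abs(corrPairs$r) > 1))
            stop("infeasible correlation structure: |r| > 1")
        up <- unique(corrPairs[c("geneA", "geneB")])
        if (any(table(c(up$geneA, up$geneB)) > 1))
            stop("a gene may appear in at most one planted pair")
    }

    nS <- nGroups * nPerGroup
    grp <- rep(groups, each = nPerGroup)
    sid <- paste0(grp, "_S", sprintf("%03d", sequence(rep(nPerGroup, nGroups))))
    loading <- stats::rnorm(nS, 0, loadingSD)

    # target signal on the -deltaCt scale
    E <- matrix(stats::rnorm(nTargets * nS), nTargets, nS,
        dimnames = list(tnames, NULL))
    for (i in seq_len(nrow(corrPairs))) {
        a <- corrPairs$geneA[i]; b <- corrPairs$geneB[i]
        cols <- which(grp == corrPairs$group[i])
        rr <- corrPairs$r[i]
        E[b, cols] <- rr * E[a, cols] + sqrt(1 - rr^2) * E[b, cols]
    }
    X <- groupMeans[, match(grp, groups), drop = FALSE] + E * targetSD

    baseCt <- stats::runif(nTargets, 22, 30)
    ctTargets <- baseCt - X + matrix(loading, nTargets, nS, byrow = TRUE)

    hkBase <- stats::runif(nHousekeeping, 18, 22)
    # each unstable candidate drifts in its own group (shifts that are
    # collinear across candidates would cancel in the gene-by-group
    # interaction and be invisible to any stability score)
    ownGroup <- ((seq_len(nHousekeeping) - 1L) %% nGroups) + 1L
    ctHK <- matrix(NA_real_, nHousekeeping, nS,
        dimnames = list(hknames, NULL))
    for (c in seq_len(nHousekeeping)) {
        shift <- hkShift[c] * (grp == groups[ownGroup[c]])
        ctHK[c, ] <- hkBase[c] + shift + loading +
            stats::rnorm(nS, 0, hkSD[c])
    }

    ct <- rbind(ctHK, ctTargets)
    ct <- pmax(ct, 0)                    # Ct values are nonnegative cycles
    if (missingRate > 0)
        ct[stats::runif(length(ct)) < missingRate] <- NA_real_
    colnames(ct) <- sid

    if (replicateRate > 0) {
        idx <- which(stats::runif(nS) < replicateRate)
        if (length(idx)) {
            repCt <- ct[, idx, drop = FALSE] +
                matrix(stats::rnorm(nrow(ct) * length(idx), 0, 0.05),
                    nrow(ct))
            colnames(repCt) <- sid[idx]
            ct <- cbind(ct, repCt)
            grp <- c(grp, grp[idx])
        }
    }

    truth <- new("SyntheticTruth", groupMeans = groupMeans,
        hkGenes = hknames, hkSD = hkSD, hkShift = hkShift,
        corrPairs = corrPairs, targetSD = targetSD,
        missingRate = missingRate, replicateRate = replicateRate,
        seed = as.integer(seed))
    list(ct = CtExperiment(ct, group = grp,
            collapsed = replicateRate == 0),
        truth = truth)
}

# 49 filler human gene symbols for the worked-example-scale emulation
.fillerGenes <- c(
    "MYC", "EGFR", "KRAS", "BRAF", "PTEN", "RB1", "CCND1", "CDK4", "CDK6",
    "CDKN1A", "CDKN2A", "MDM2", "BAX", "BCL2", "CASP3", "CASP8", "BIRC5",
    "VEGFA", "KDR", "FGF2", "FGFR1", "PDGFRB", "MET", "ERBB2", "ESR1",
    "PGR", "AR", "STAT3", "JAK2", "NFKB1", "RELA", "TGFB1", "SMAD4",
    "WNT1", "CTNNB1", "GSK3B", "NOTCH1", "HES1", "DLL1", "SNAI2",
    "TWIST1", "ZEB1", "VIM", "CDH1", "MMP2", "MMP9", "TIMP1", "ITGB1",
    "SPARC")

#' Synthetic emulation of a 68-gene, 328-sample reference experiment
#'
#' A fully synthetic dataset (no measured data) emulating a large-scale
#' qPCR study design: 4 groups of 82 samples, 63 target genes and 5
#' housekeeping candidates named A-E, with a planted ground truth
#' mirroring the qualitative findings such a study reports. Candidates
#' B and E are planted as the stable pair (small SD, no intergroup
#' shift); A, C and D drift between groups. Twelve target genes are
#' differentially expressed between Group1 and Group2 (TP53, CDH2, FOS
#' and SESN2 up in Group1; SOD2, SRC, HIF1A, CMBL, PCNA, SERPINE2,
#' ALDH3A1 and SNAI1 up in Group2); AKT1 is raised in Group3 (strongly)
#' and Group4 (modestly) relative to Group1; and the PCNA-KDM5B pair is
#' planted with correlation +0.43 in Group1 and -0.48 in Group3. About
#' 2% of cells are missing at random.
#'
#' @param seed integer seed.
#' @return list with `ct` and `truth`, as [simulateCtData()].
#' @export
exampleCtData <- function(seed = 104L) {
    groups <- paste0("Group", 1:4)
    named <- c("AKT1", "TP53", "CDH2", "FOS", "SESN2", "SOD2", "SRC",
        "HIF1A", "CMBL", "PCNA", "SERPINE2", "ALDH3A1", "SNAI1", "KDM5B")
    tnames <- c(named, .fillerGenes)
    stopifnot(length(tnames) == 63)
    gm <- matrix(0, 63, 4, dimnames = list(tnames, groups))
    upG1 <- c(TP53 = 2.2, CDH2 = 1.8, FOS = 2.6, SESN2 = 1.6)
    upG2 <- c(SOD2 = 2.0, SRC = 1.7, HIF1A = 2.4, CMBL = 1.9, PCNA = 2.1,
        SERPINE2 = 1.6, ALDH3A1 = 2.3, SNAI1 = 1.8)
    gm[names(upG1), "Group1"] <- upG1
    gm[names(upG2), "Group2"] <- upG2
    gm["AKT1", c("Group3", "Group4")] <- c(1.5, 0.5)
    cp <- data.frame(geneA = "PCNA", geneB = "KDM5B",
        group = c("Group1", "Group3"), r = c(0.43, -0.48))
    sim <- simulateCtData(nGroups = 4, nPerGroup = 82, nTargets = 63,
        nHousekeeping = 5, groupMeans = gm, corrPairs = cp,
        targetSD = 1, hkSD = c(0.35, 0.18, 0.5, 0.3, 0.18),
        hkShift = c(0.3, 0, 0.45, 0.6, 0), loadingSD = 0.8,
        missingRate = 0.02, replicateRate = 0, seed = seed)
    hkMap <- c(HK1 = "A", HK2 = "B", HK3 = "C", HK4 = "D", HK5 = "E")
    sim$ct <- renameGenes(sim$ct, hkMap)
    sim$truth@hkGenes <- unname(hkMap[sim$truth@hkGenes])
    sim
}

#' Write a CtExperiment to disk
#'
#' Writes the Ct table in wide (sample, group, one column per gene) or
#' long (sample, group, gene, Ct) layout as CSV or TSV; missing Ct
#' values become blank cells. The written file round-trips through
#' [readCtTable()].
#'
#' @param x a [CtExperiment-class].
#' @param path output path.
#' @param layout `"wide"` or `"long"`.
#' @param filetype `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeCtTable <- function(x, path, layout = c("wide", "long"),
                         filetype = c("csv", "tsv")) {
    stopifnot(is(x, "CtExperiment"))
    layout <- match.arg(layout)
    filetype <- match.arg(filetype)
    ct <- ctValues(x)
    if (layout == "wide") {
        df <- data.frame(sample = colnames(x), group = sampleGroups(x),
            t(ct), check.names = FALSE)
    } else {
        df <- data.frame(
            sample = rep(colnames(x), each = nrow(ct)),
            group = rep(sampleGroups(x), each = nrow(ct)),
            gene = rep(rownames(ct), times = ncol(ct)),
            ct = as.vector(ct))
    }
    sep <- if (filetype == "csv") "," else "\t"
    utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
        quote = FALSE)
    invisible(path)
}
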