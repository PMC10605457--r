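# Fixtures built in code: tiny Ct tables and normalized sets.

makeCt <- function(values, genes, samples, groups, collapsed = TRUE) {
    m <- matrix(values, nrow = length(genes),
        dimnames = list(genes, samples))
    CtExperiment(m, group = groups, collapsed = collapsed)
}

# NormalizedSet with one value vector per group for a single gene
makeNorm1 <- function(..., gene = "G") {
    vals <- list(...)
    v <- unlist(vals)
    grp <- rep(names(vals), vapply(vals, length, integer(1)))
    m <- matrix(v, nrow = 1,
        dimnames = list(gene, paste0("s", seq_along(v))))
    NormalizedSet(m, group = grp)
}

# NormalizedSet from a genes x samples matrix plus group labels
makeNormMat <- function(m, groups) {
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    NormalizedSet(m, group = groups)
}

# all permutations of 1..n (n small), as a matrix with one row per
# permutation; used by the exhaustive-enumeration oracles
permutations <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- permutations(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        cbind(i, matrix(rest[sub], nrow(sub)))
    }))
}

# exhaustive two-sided Mann-Whitney p by enumerating group assignments
mwOracle <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled); na <- length(a)
    uStat <- function(idx) {
        ra <- rank(pooled)[idx]
        sum(ra) - na * (na + 1) / 2
    }
    u0 <- uStat(seq_len(na))
    center <- na * (n - na) / 2
    idxs <- utils::combn(n, na)
    us <- apply(idxs, 2, uStat)
    mean(abs(us - center) >= abs(u0 - center) - 1e-9)
}

# exhaustive two-sided Spearman permutation p (no ties assumed)
spearmanOracle <- function(x, y) {
    r0 <- stats::cor(x, y, method = "spearman")
    perms <- permutations(length(y))
    rs <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "spearman"))
    mean(abs(rs) >= abs(r0) - 1e-9)
}

# brute-force BH step-up: adj_i = min over ranks j >= rank(i) of m*p_j/j
bhOracle <- function(p) {
    m <- length(p)
    r <- rank(p, ties.method = "first")
    vapply(seq_len(m), function(i) {
        min(1, min(vapply(seq_len(m), function(j)
            if (r[j] >= r[i]) m * p[j] / r[j] else Inf, numeric(1))))
    }, numeric(1))
}
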