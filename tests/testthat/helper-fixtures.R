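# shared fixture builders and independent oracles for the test suite

# adjusted Rand index from the contingency-table formula (independent of
# any clustering code under test)
ari <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    maxidx <- (sumi + sumj) / 2
    if (maxidx == expected) return(as.numeric(sumij == maxidx))
    (sumij - expected) / (maxidx - expected)
}

# perfect two-block indicator matrix: `rows` indicator rows over two
# sample blocks of size `blockSize`
twoBlockIndicators <- function(blockSize, rows = 3L) {
    X <- do.call(rbind, lapply(seq_len(rows), function(i) {
        r <- rep(c(1, 0), each = blockSize)
        if (i %% 2 == 0) 1 - r else r
    }))
    colnames(X) <- paste0("s", seq_len(2L * blockSize))
    X
}

# write a SEG-format fixture and return its path
writeSegFixture <- function(rows, path = tempfile(fileext = ".seg")) {
    header <- "Sample\tChromosome\tStart\tEnd\tSegment_Mean"
    writeLines(c(header, rows), path)
    path
}

# brute-force pairwise AUC oracle (Mann-Whitney identity by explicit
# pair counting; ties contribute 1/2)
aucBruteForce <- function(values, positive) {
    pos <- values[positive]
    neg <- values[!positive]
    mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# brute-force k-sample log-rank chi-square from explicit risk tables
logrankBruteForce <- function(time, event, groups) {
    g <- factor(groups)
    k <- nlevels(g)
    etimes <- sort(unique(time[event == 1]))
    O <- E <- numeric(k)
    V <- matrix(0, k, k)
    for (t0 in etimes) {
        at <- time >= t0
        n <- sum(at)
        if (n < 2) next
        nj <- sapply(levels(g), function(l) sum(at & g == l))
        dj <- sapply(levels(g), function(l)
            sum(at & g == l & time == t0 & event == 1))
        d <- sum(dj)
        if (d == 0) next
        O <- O + dj
        E <- E + d * nj / n
        for (j in seq_len(k)) for (l in seq_len(k)) {
            V[j, l] <- V[j, l] + d * (n - d) / (n - 1) *
                (nj[j] / n) * ((j == l) - nj[l] / n)
        }
    }
    u <- (O - E)[-k]
    drop(t(u) %*% solve(V[-k, -k, drop = FALSE]) %*% u)
}

# exact Fisher p for a 2x2 table by enumerating all tables with the
# observed margins (two-sided by probability mass)
fisher2x2Enumerate <- function(tab) {
    a <- tab[1, 1]
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
    probs <- dhyper(lo:hi, c1, n - c1, r1)
    pObs <- dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# small preprocessed platform set with planted subgroups, for
# pipeline-level tests at a modest size
smallStudy <- function(seed, n = 120L) {
    sim <- simulateMultiomics(syntheticConfig(n_samples = n, seed = seed))
    list(sim = sim, platforms = preprocessPlatforms(sim))
}
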