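test_that("feature sub-clustering recovers anti-correlated blocks", {
    set.seed(21)
    base <- rnorm(30)
    # block A follows `base`, block B follows `-base`: within-block
    # correlation +1, between-block -1
    m <- rbind(t(replicate(4, base)), t(replicate(4, -base)))
    rownames(m) <- paste0("f", 1:8)
    colnames(m) <- paste0("s", 1:30)
    sc <- subclusterFeatures(m, 2)
    expect_equal(length(unique(sc$assignment[1:4])), 1L)
    expect_equal(length(unique(sc$assignment[5:8])), 1L)
    expect_false(sc$assignment[1] == sc$assignment[5])
})

test_that("sub-clustering honours k bounds", {
    m <- matrix(rnorm(12), 3, 4,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
    expect_equal(sort(unname(subclusterFeatures(m, 3)$assignment)), 1:3)
    expect_error(subclusterFeatures(m, 4), "exceeds")
    expect_error(subclusterFeatures(m, 1), "at least 2")
})

test_that("indicator rows enforce the minimum-group-size NA rule", {
    set.seed(31)
    # 23 samples splitting 14 vs 9: the smaller group is under 10 -> all NA
    m1 <- rbind(c(rnorm(14, 0), rnorm(9, 5)),
                c(rnorm(14, 0), rnorm(9, 5)),
                c(rnorm(14, 0), rnorm(9, 5)))
    rownames(m1) <- paste0("f", 1:3); colnames(m1) <- paste0("s", 1:23)
    r1 <- indicatorFromSubcluster(m1, rownames(m1), minGroupSize = 10)
    expect_true(all(is.na(r1$labels)))

    # 40 samples splitting 20 vs 20: rule not triggered, labels 0/1
    m2 <- rbind(c(rnorm(20, 0), rnorm(20, 5)),
                c(rnorm(20, 0), rnorm(20, 5)))
    rownames(m2) <- paste0("f", 1:2); colnames(m2) <- paste0("s", 1:40)
    r2 <- indicatorFromSubcluster(m2, rownames(m2), minGroupSize = 10)
    expect_false(anyNA(r2$labels))
    expect_setequal(unique(r2$labels), c(0, 1))
})

test_that("indicator orientation labels the higher-mean group 1", {
    m <- rbind(rep(c(1, -1), each = 20), rep(c(1, -1), each = 20))
    rownames(m) <- c("a", "b"); colnames(m) <- paste0("s", 1:40)
    r <- indicatorFromSubcluster(m, c("a", "b"), minGroupSize = 10)
    expect_equal(unname(r$labels[1:20]), rep(1, 20))
    expect_equal(unname(r$labels[21:40]), rep(0, 20))
})

test_that("indicators are invariant to sample order and positive scaling", {
    set.seed(41)
    m <- rbind(c(rnorm(15, 0), rnorm(15, 4)), c(rnorm(15, 0), rnorm(15, 4)))
    rownames(m) <- c("a", "b"); colnames(m) <- paste0("s", 1:30)
    r0 <- indicatorFromSubcluster(m, c("a", "b"), minGroupSize = 5)
    perm <- sample(30)
    rPerm <- indicatorFromSubcluster(m[, perm], c("a", "b"), minGroupSize = 5)
    expect_equal(rPerm$labels[colnames(m)], r0$labels)
    rScale <- indicatorFromSubcluster(m * 7, c("a", "b"), minGroupSize = 5)
    expect_equal(rScale$labels, r0$labels)
})

test_that("COC assembly orders rows by platform and counts them", {
    mkRow <- function(p, i, ids) structure(
        list(platform = p, subcluster = i,
             labels = setNames(rep(c(0, 1), length.out = length(ids)), ids)),
        class = "IndicatorRow")
    ids <- paste0("s", 1:5)
    rows <- list(mkRow("METH", 1L, ids), mkRow("CNV", 2L, ids),
                 mkRow("CNV", 1L, ids), mkRow("MRNA", 1L, ids))
    coc <- assembleCOCMatrix(rows)
    expect_equal(dim(coc), c(4L, 5L))
    expect_equal(indicatorInfo(coc)$platform,
                 c("CNV", "CNV", "MRNA", "METH"))
    expect_equal(indicatorInfo(coc)$subcluster[1:2], 1:2)

    bad <- list(mkRow("CNV", 1L, c("A", "B", "C")),
                mkRow("MRNA", 1L, c("B", "C", "D")))
    expect_error(assembleCOCMatrix(bad), "inconsistent sample set")
})

test_that("row count equals the sum of per-platform sub-cluster counts", {
    st <- smallStudy(seed = 55, n = 60)
    counts <- c(CNV = 2L, MRNA = 2L, MIRNA = 2L, METH = 2L)
    rows <- unlist(lapply(names(counts), function(nm)
        platformIndicators(st$platforms[[nm]], counts[[nm]],
                           minGroupSize = 5)), recursive = FALSE)
    coc <- assembleCOCMatrix(rows)
    expect_equal(nrow(coc), sum(counts))
})

test_that("NA-tolerant binary distance matches hand-counted mismatches", {
    X <- rbind(c(1, 0, NA), c(0, 0, 1), c(1, 1, 1), c(NA, 0, 0))
    colnames(X) <- c("a", "b", "c")
    d <- binaryIndicatorDist(X)
    # a vs b: rows 1-3 observed for both -> mismatches 1,0,0 -> 1/3
    expect_equal(d["a", "b"], 1 / 3)
    # a vs c: rows 2,3 observed (row 1 NA in c... row4 NA in a) -> rows 2,3:
    # (0 vs 1), (1 vs 1) -> 1/2
    expect_equal(d["a", "c"], 1 / 2)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 3))
})

test_that("consensus invariants hold across k and seed", {
    set.seed(61)
    X <- matrix(rbinom(10 * 30, 1, 0.5), 10, 30,
                dimnames = list(NULL, paste0("s", 1:30)))
    X[sample(length(X), 20)] <- NA
    for (k in c(2, 4)) for (seed in c(1, 99)) {
        r <- consensusCluster(X, k, reps = 30, sampleFraction = 0.8,
                              seed = seed)
        cm <- consensusMatrix(r)
        expect_equal(cm, t(cm))
        expect_equal(unname(diag(cm)), rep(1, 30))
        expect_true(all(cm >= 0 & cm <= 1))
        expect_equal(length(unique(subgroupLabels(r))), k)
    }
})

test_that("consensus with full sampling equals the single-partition co-membership", {
    X <- twoBlockIndicators(10)
    r <- consensusCluster(X, 2, reps = 5, sampleFraction = 1, seed = 3)
    # oracle: one deterministic partition of the full cohort
    D <- binaryIndicatorDist(X)
    cl <- cutree(hclust(as.dist(D), method = "average"), k = 2)
    expect_equal(unname(consensusMatrix(r)),
                 unname(outer(cl, cl, "==") * 1))
    expect_true(all(consensusMatrix(r) %in% c(0, 1)))
})

test_that("perfectly separated blocks give a 0/1 consensus and exact labels", {
    X <- twoBlockIndicators(15)
    r <- consensusCluster(X, 2, reps = 40, sampleFraction = 0.8, seed = 5)
    cm <- consensusMatrix(r)
    blockA <- 1:15; blockB <- 16:30
    expect_true(all(cm[blockA, blockA] == 1))
    expect_true(all(cm[blockB, blockB] == 1))
    expect_true(all(cm[blockA, blockB] == 0))
    lab <- subgroupLabels(r)
    expect_equal(length(unique(lab[blockA])), 1L)
    expect_equal(length(unique(lab[blockB])), 1L)
    expect_false(lab[1] == lab[16])
})

test_that("all-NA rows never change the consensus labels", {
    X <- twoBlockIndicators(12)
    Xna <- rbind(X, rep(NA_real_, ncol(X)))
    r1 <- consensusCluster(X, 2, reps = 25, sampleFraction = 0.8, seed = 7)
    r2 <- consensusCluster(Xna, 2, reps = 25, sampleFraction = 0.8, seed = 7)
    expect_equal(subgroupLabels(r1), subgroupLabels(r2))
    expect_equal(consensusMatrix(r1), consensusMatrix(r2))
})

test_that("consensus clustering rejects degenerate inputs", {
    X <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "only"))
    expect_error(consensusCluster(X, 2, reps = 5), "exceeds")
})

test_that("delta-area elbow picks the true block count and flags flat data", {
    X <- twoBlockIndicators(60)
    res <- lapply(2:5, function(k)
        consensusCluster(X, k, reps = 50, sampleFraction = 0.8, seed = k))
    expect_equal(as.integer(selectKDeltaArea(res)), 2L)

    set.seed(71)
    R <- matrix(rbinom(20 * 60, 1, 0.5), 20, 60,
                dimnames = list(NULL, paste0("s", 1:60)))
    resR <- lapply(2:7, function(k)
        consensusCluster(R, k, reps = 50, sampleFraction = 0.8, seed = k))
    expect_warning(kR <- selectKDeltaArea(resR), "no stable elbow")
    expect_equal(as.integer(kR), 2L)

    expect_warning(k1 <- selectKDeltaArea(res[1]), "single")
    expect_equal(as.integer(k1), 2L)
})

test_that("five planted subgroups are recovered by the delta-area elbow", {
    st <- smallStudy(seed = 77, n = 120)
    cc <- cocaConfig(reps = 60)
    fs <- finalizeSubgroups(st$platforms,
                            c(CNV = 8, MRNA = 10, MIRNA = 6, METH = 10),
                            cc, seed = 2)
    expect_equal(fs$k, 5L)
    truth <- trueLabels(st$sim)[names(fs$labels)]
    expect_gte(ari(fs$labels, truth), 0.9)
    # the helper ARI agrees with the independent mclust implementation
    expect_equal(ari(fs$labels, truth),
                 mclust::adjustedRandIndex(fs$labels, truth))
})
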