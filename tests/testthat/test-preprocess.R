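test_that("gene-level CNV equals explicit base-pair-weighted segment means", {
    # two samples so the SD filter has something to act on; filter disabled
    # via a tiny threshold to test the averaging in isolation
    cfg <- preprocessConfig(cnv_sd_min = 1e-9)
    segs <- data.frame(
        sample = c("A", "A", "B", "B"),
        chrom = "1",
        start = c(1L, 501L, 1L, 251L),
        end = c(500L, 2000L, 250L, 1000L),
        seg_mean = c(1.0, 0.0, 2.0, 0.4))
    genes <- GenomicRanges::GRanges("1", IRanges::IRanges(1, 1000))
    names(genes) <- "G1"
    out <- assayValues(geneLevelCNV(segs, genes, cfg))
    # sample A: 500 bp at 1.0 + 500 bp at 0.0 -> 0.5
    expect_equal(out["G1", "A"], 0.5)
    # sample B: 250 bp at 2.0 + 750 bp at 0.4 -> (500 + 300) / 1000 = 0.8
    expect_equal(out["G1", "B"], 0.8)
})

test_that("a gene inside one segment inherits its segment mean; clipping at the bound", {
    cfg <- preprocessConfig(cnv_sd_min = 1e-9)
    segs <- data.frame(sample = rep(c("A", "B"), each = 2),
                       chrom = "2", start = c(1L, 5001L),
                       end = c(5000L, 9000L),
                       seg_mean = c(0.8, 2.7, -0.3, -3.1))
    genes <- GenomicRanges::GRanges("2", IRanges::IRanges(c(100, 6000),
                                                          c(400, 6400)))
    names(genes) <- c("IN1", "IN2")
    out <- assayValues(geneLevelCNV(segs, genes, cfg))
    expect_equal(out["IN1", "A"], 0.8)
    expect_equal(out["IN2", "A"], 2.0)    # 2.7 clipped to the +2 bound
    expect_equal(out["IN2", "B"], -2.0)   # -3.1 clipped to the -2 bound
})

test_that("CNV SD filter drops flat genes and preprocessing is idempotent", {
    cfg <- preprocessConfig()
    segs <- do.call(rbind, lapply(1:6, function(i) data.frame(
        sample = paste0("S", i), chrom = "1",
        start = c(1L, 1001L), end = c(1000L, 2000L),
        seg_mean = c(ifelse(i <= 3, 1.5, -1.5), 0.01 * i))))
    genes <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 1001),
                                                          c(1000, 2000)))
    names(genes) <- c("VAR", "FLAT")
    out <- geneLevelCNV(segs, genes, cfg)
    expect_equal(featureIDs(out), "VAR")  # FLAT has SD < 0.2
    # clipping is idempotent: feeding scores back through changes nothing
    v <- assayValues(out)
    v2 <- pmin(pmax(v, -2), 2)
    expect_identical(v, v2)
})

test_that("genes without segment coverage in some sample are dropped with warning", {
    cfg <- preprocessConfig(cnv_sd_min = 1e-9)
    segs <- data.frame(sample = c("A", "B"), chrom = "1",
                       start = c(1L, 1L), end = c(1000L, 400L),
                       seg_mean = c(1, -1))
    genes <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 600),
                                                          c(300, 900)))
    names(genes) <- c("COVERED", "HALF")   # HALF has no segment in B
    expect_warning(out <- geneLevelCNV(segs, genes, cfg), "coverage")
    expect_equal(featureIDs(out), "COVERED")
})

test_that("methylation preprocessing drops NA loci and keeps top-SD sites", {
    set.seed(3)
    m <- matrix(runif(5 * 6), 5, 6,
                dimnames = list(paste0("cg", 1:5), paste0("s", 1:6)))
    m[2, 4] <- NA
    x <- PlatformMatrix(m, "METH")
    out <- prepMethylation(x, preprocessConfig(meth_top_n = 2))
    expect_false("cg2" %in% featureIDs(out))
    expect_equal(nrow(out), 2L)
    sds <- apply(m[-2, ], 1, sd)
    expect_setequal(featureIDs(out), names(sort(sds, decreasing = TRUE))[1:2])
    expect_false(anyNA(assayValues(out)))
})

test_that("top-N tie-break is deterministic by feature ID", {
    m <- rbind(zzz = c(0, 1, 0, 1), aaa = c(1, 0, 1, 0),
               mmm = c(0.4, 0.6, 0.5, 0.5))
    colnames(m) <- paste0("s", 1:4)
    x <- PlatformMatrix(m, "METH")
    out1 <- prepMethylation(x, preprocessConfig(meth_top_n = 1))
    out2 <- prepMethylation(PlatformMatrix(m[c(3, 1, 2), ], "METH"),
                            preprocessConfig(meth_top_n = 1))
    # zzz and aaa tie on SD; the lexicographically smaller ID wins either way
    expect_equal(featureIDs(out1), "aaa")
    expect_equal(featureIDs(out2), "aaa")
})

test_that("expression preprocessing floors log2 values and drops undetected genes", {
    m <- rbind(low = c(2^-30, 2^-30, 2^-30, 2),
               mid = c(2^-5, 2^-5, 32, 2^-5),
               gap = c(1, 2, NA, 4),
               top = c(1, 1024, 1, 1024))
    colnames(m) <- paste0("s", 1:4)
    out <- prepExpression(PlatformMatrix(m, "MRNA"), preprocessConfig())
    v <- assayValues(out)
    expect_false("gap" %in% rownames(v))      # undetected in one sample
    expect_equal(v["low", 1], -26)            # log2 = -30 floored
    expect_equal(v["mid", 1], -5)             # above the floor: identity
    expect_equal(min(v), -26)
})

test_that("miRNA preprocessing floors at 0 and keeps exactly top-N", {
    set.seed(5)
    m <- matrix(2^rnorm(100 * 4, mean = 4, sd = 2), 100, 4,
                dimnames = list(sprintf("mir%03d", 1:100), paste0("s", 1:4)))
    m[1, ] <- c(0.5, 8, 0.5, 8)   # RPM 0.5 -> log2 = -1 -> floored to 0
    out <- prepMirna(PlatformMatrix(m, "MIRNA"), preprocessConfig())
    v <- assayValues(out)
    expect_equal(nrow(v), 80L)
    expect_equal(v["mir001", 1], 0)
    expect_equal(v["mir001", 2], 3)
    expect_true(all(v >= 0))
})

test_that("SD-based feature selection is invariant to sample column order", {
    set.seed(7)
    m <- matrix(rnorm(30 * 8), 30, 8,
                dimnames = list(paste0("f", 1:30), paste0("s", 1:8)))
    x1 <- PlatformMatrix(2^m, "MRNA")
    x2 <- PlatformMatrix(2^m[, sample(8)], "MRNA")
    cfg <- preprocessConfig(mrna_top_n = 10)
    expect_setequal(featureIDs(prepExpression(x1, cfg)),
                    featureIDs(prepExpression(x2, cfg)))
})

test_that("mutation matrix construction is dense, idempotent and validated", {
    calls <- data.frame(gene = c("TP53", "TP53", "CTNNB1"),
                        sample = c("S1", "S1", "S2"))
    out <- buildMutationMatrix(calls, samples = c("S1", "S2", "S3"))
    v <- assayValues(out)
    expect_equal(v["TP53", ], c(S1 = 1, S2 = 0, S3 = 0))  # duplicate call once
    expect_equal(v["CTNNB1", "S2"], 1)
    expect_equal(dim(v), c(2L, 3L))
    expect_equal(dim(buildMutationMatrix(data.frame(), c("S1")))[1], 0L)
    expect_error(buildMutationMatrix(data.frame(gene = "G", sample = "S9"),
                                     c("S1")), "unknown sample")
})
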