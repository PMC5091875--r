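test_that("the generator is bit-deterministic given its seed", {
    cfg <- syntheticConfig(n_samples = 40, seed = 101)
    s1 <- simulateMultiomics(cfg)
    s2 <- simulateMultiomics(cfg)
    expect_identical(assayValues(platformMatrix(s1, "MRNA")),
                     assayValues(platformMatrix(s2, "MRNA")))
    expect_identical(s1@segments, s2@segments)
    expect_identical(clinicalTable(s1), clinicalTable(s2))
    expect_identical(trueLabels(s1), trueLabels(s2))
    s3 <- simulateMultiomics(syntheticConfig(n_samples = 40, seed = 102))
    expect_false(identical(assayValues(platformMatrix(s1, "MRNA")),
                           assayValues(platformMatrix(s3, "MRNA"))))
})

test_that("generated data satisfy the preprocessing invariants", {
    sim <- simulateMultiomics(syntheticConfig(n_samples = 60, seed = 103))
    pp <- preprocessPlatforms(sim)
    expect_true(all(abs(assayValues(pp$CNV)) <= 2))
    beta <- assayValues(pp$METH)
    expect_true(all(beta >= 0 & beta <= 1))
    expect_false(anyNA(beta))
    expect_true(all(assayValues(pp$MRNA) >= -26))
    expect_true(all(assayValues(pp$MIRNA) >= 0))
    mut <- assayValues(platformMatrix(sim, "MUT"))
    expect_true(all(mut %in% c(0, 1)))
    # shared sample universe
    expect_setequal(sampleIDs(pp$CNV), names(trueLabels(sim)))
})

test_that("per-block two-group splits recover subgroup unions at 3-SD effects", {
    cfg <- syntheticConfig(n_samples = 100, effect = 3, seed = 107)
    sim <- simulateMultiomics(cfg)
    pp <- preprocessPlatforms(sim)
    truth <- trueLabels(sim)
    # the first marker block of the mRNA platform shifts subgroup 1 only:
    # its indicator should isolate S1 almost perfectly
    rows <- platformIndicators(pp$MRNA, 10, minGroupSize = 5)
    inS1 <- as.numeric(truth[sampleIDs(pp$MRNA)] == "S1")
    agree <- vapply(rows, function(r) {
        if (all(is.na(r$labels))) return(0)
        mean(r$labels == inS1)
    }, numeric(1))
    expect_gte(max(agree), 0.95)
})

test_that("zero effect produces no recoverable subgroup structure", {
    cfg <- syntheticConfig(n_samples = 100, effect = 0, seed = 109,
                           log_hazard_offsets = rep(0, 5))
    sim <- simulateMultiomics(cfg)
    pp <- preprocessPlatforms(sim)
    cc <- cocaConfig(reps = 30, subgroup_range = 2:5)
    fs <- suppressWarnings(finalizeSubgroups(
        pp, c(CNV = 8, MRNA = 10, MIRNA = 6, METH = 10), cc, seed = 3))
    truth <- trueLabels(sim)[names(fs$labels)]
    expect_lt(abs(ari(fs$labels, truth)), 0.1)
})

test_that("block effect sizes match the configuration", {
    # n = 500 so the empirical shift is within 3 standard errors
    cfg <- syntheticConfig(n_samples = 500, seed = 113)
    sim <- simulateMultiomics(cfg)
    truth <- trueLabels(sim)
    m <- log2(assayValues(platformMatrix(sim, "MRNA")))
    spec <- cfg$platforms$MRNA
    # first marker block shifts S1 by effect (in log2 units)
    ids <- colnames(m)
    block1 <- grep("^gene_b1_", rownames(m))
    shifted <- colMeans(m[block1, truth[ids] == "S1"], na.rm = TRUE)
    rest <- colMeans(m[block1, truth[ids] != "S1"], na.rm = TRUE)
    est <- mean(shifted) - mean(rest)
    se <- sqrt(var(shifted) / length(shifted) + var(rest) / length(rest))
    expect_lt(abs(est - spec$effect), 3 * se)
})

test_that("survival simulation respects hazards and censoring settings", {
    cfg0 <- syntheticConfig(n_samples = 100, censoring_rate = 0, seed = 127)
    surv0 <- simulateSurvival(rep(1:5, 20), cfg0)
    expect_true(all(surv0$event == 1))

    # hazard ratio 4 between two groups of 50: power above 95%
    cfgHR <- syntheticConfig(seed = 131)
    hits <- vapply(1:40, function(i) {
        withr::with_seed(1000 + i, {
            g <- rep(c(1, 3), each = 50)   # offsets 1.4 vs 0: HR ~ 4
            s <- simulateSurvival(g, cfgHR)
            logrankTest(s$time, s$event, g)$p_value < 0.05
        })
    }, logical(1))
    expect_gte(mean(hits), 0.95)

    # equal offsets: p-values roughly uniform
    cfg0h <- syntheticConfig(log_hazard_offsets = rep(0, 5), seed = 137)
    ps <- vapply(1:60, function(i) {
        withr::with_seed(2000 + i, {
            g <- sample(1:5, 150, replace = TRUE)
            s <- simulateSurvival(g, cfg0h)
            logrankTest(s$time, s$event, g)$p_value
        })
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("mutation enrichment biases the designated subgroup genes", {
    cfg <- syntheticConfig(n_samples = 400, seed = 139)
    sim <- simulateMultiomics(cfg)
    mut <- assayValues(platformMatrix(sim, "MUT"))
    truth <- trueLabels(sim)[colnames(mut)]
    # gene MUTG01 is enriched in subgroup 1
    inRate <- mean(mut["MUTG01", truth == "S1"])
    outRate <- mean(mut["MUTG01", truth != "S1"])
    expect_gt(inRate, outRate + 0.15)
})

test_that("invalid configurations are rejected", {
    expect_error(syntheticConfig(proportions = c(0.5, 0.5)), "proportions")
    expect_error(syntheticConfig(censoring_rate = 1), "censoring")
    expect_error(syntheticConfig(baseline_hazard = 0), "baseline")
    expect_error(syntheticConfig(log_hazard_offsets = 1:3), "offsets")
})
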