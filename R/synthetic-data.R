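#' Configuration of the synthetic multi-omics generator
#'
#' Defines the simulated study: sample size, planted subgroup
#' structure, per-platform feature-block architecture, survival
#' hazards, mutation enrichment and clinical covariate biases. The
#' defaults describe the study conditions the pipeline is designed
#' for: 250 samples in 5 unequally sized subgroups, feature blocks
#' whose subgroup-specific mean shifts are 2 total-SD units, a 4-fold
#' hazard ratio between the extreme subgroups with 30% censoring, and
#' subgroup-biased mutation rates and clinical covariates.
#'
#' Each platform entry specifies \code{n_blocks} feature blocks of
#' \code{block_size} features, a shared within-block noise SD
#' (\code{block_sd}, inducing within-block correlation), an
#' independent per-feature noise SD (\code{feature_sd}), a baseline
#' level and the subgroup shift (\code{effect}, in units of the total
#' noise SD). The first \code{n_subgroups} blocks of every platform
#' each shift exactly one subgroup (guaranteeing that every subgroup
#' is marked on every platform); remaining blocks shift a random
#' proper subset of subgroups.
#'
#' @param n_samples number of samples.
#' @param n_subgroups number of planted subgroups.
#' @param proportions subgroup proportions (sum to 1).
#' @param effect subgroup mean shift in total-SD units, applied to all
#'   platforms (0 = no planted structure).
#' @param cnv,meth,mrna,mirna per-platform architecture overrides
#'   (lists with any of \code{n_blocks}, \code{block_size},
#'   \code{block_sd}, \code{feature_sd}, \code{baseline},
#'   \code{effect}).
#' @param baseline_hazard baseline event rate per day.
#' @param log_hazard_offsets per-subgroup log-hazard offsets (0 = no
#'   survival difference); the default spans log(4).
#' @param censoring_rate expected fraction censored, in [0, 1).
#' @param mutation_genes number of simulated genes in the mutation
#'   matrix.
#' @param mutation_baseline per-gene background mutation probability.
#' @param mutation_enrichment rate multiplier for each subgroup's
#'   enriched genes (two genes per subgroup, probability capped at
#'   0.95); 1 = no enrichment.
#' @param covariate_bias list of per-subgroup probabilities for the
#'   biased clinical covariates (\code{female}, \code{alcohol},
#'   \code{afp_high}, \code{stage_high}); each must have
#'   \code{n_subgroups} entries.
#' @param na_fraction fraction of methylation loci and mRNA genes
#'   carrying one missing cell (exercises the NA-handling rules).
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(n_samples = 250L, n_subgroups = 5L,
                            proportions = c(0.12, 0.32, 0.26, 0.18, 0.12),
                            effect = 2,
                            cnv = list(), meth = list(), mrna = list(),
                            mirna = list(),
                            baseline_hazard = 1 / 500,
                            log_hazard_offsets = c(1.4, 0.4, 0, 0.4, 0.7),
                            censoring_rate = 0.3,
                            mutation_genes = 30L,
                            mutation_baseline = 0.08,
                            mutation_enrichment = 6,
                            covariate_bias = list(
                                female = c(0.20, 0.35, 0.30, 0.55, 0.60),
                                alcohol = c(0.60, 0.35, 0.25, 0.20, 0.60),
                                afp_high = c(0.60, 0.45, 0.25, 0.60, 0.50),
                                stage_high = c(0.80, 0.50, 0.45, 0.60, 0.85)),
                            na_fraction = 0.02,
                            seed = 1L) {
    G <- as.integer(n_subgroups)
    if (length(proportions) != G || abs(sum(proportions) - 1) > 1e-8)
        stop("'proportions' must have one entry per subgroup and sum to 1")
    if (length(log_hazard_offsets) != G)
        stop("'log_hazard_offsets' needs one entry per subgroup")
    if (censoring_rate < 0 || censoring_rate >= 1)
        stop("'censoring_rate' must lie in [0, 1)")
    if (baseline_hazard <= 0) stop("'baseline_hazard' must be positive")
    if (effect < 0) stop("'effect' must be nonnegative")
    for (nm in names(covariate_bias)) {
        pr <- covariate_bias[[nm]]
        if (length(pr) != G || any(pr < 0) || any(pr > 1))
            stop("covariate bias '", nm, "' must be ", G,
                 " probabilities in [0, 1]")
    }
    defaults <- list(
        CNV = list(n_blocks = 8L, block_size = 15L, block_sd = 0.25,
                   feature_sd = 0.25, baseline = 0, effect = NULL),
        METH = list(n_blocks = 10L, block_size = 20L, block_sd = 0.6,
                    feature_sd = 0.8, baseline = 0, effect = NULL),
        MRNA = list(n_blocks = 10L, block_size = 20L, block_sd = 0.6,
                    feature_sd = 0.8, baseline = 5, effect = NULL),
        MIRNA = list(n_blocks = 6L, block_size = 10L, block_sd = 0.6,
                     feature_sd = 0.8, baseline = 4, effect = NULL))
    user <- list(CNV = cnv, METH = meth, MRNA = mrna, MIRNA = mirna)
    platforms <- lapply(names(defaults), function(nm)
        utils::modifyList(defaults[[nm]], user[[nm]]))
    names(platforms) <- names(defaults)
    for (nm in names(platforms)) {
        p <- platforms[[nm]]
        # effect is expressed in units of the total per-feature noise SD
        if (is.null(p$effect))
            platforms[[nm]]$effect <-
                effect * sqrt(p$block_sd^2 + p$feature_sd^2)
        if (p$n_blocks < G)
            stop("platform ", nm, " needs at least ", G,
                 " blocks (one marker block per subgroup)")
    }
    structure(list(n_samples = as.integer(n_samples), n_subgroups = G,
                   proportions = proportions, effect = effect,
                   platforms = platforms,
                   baseline_hazard = baseline_hazard,
                   log_hazard_offsets = log_hazard_offsets,
                   censoring_rate = censoring_rate,
                   mutation_genes = as.integer(mutation_genes),
                   mutation_baseline = mutation_baseline,
                   mutation_enrichment = mutation_enrichment,
                   covariate_bias = covariate_bias,
                   na_fraction = na_fraction,
                   seed = as.integer(seed)),
              class = "SyntheticConfig")
}

# which subgroups each block shifts: the first G blocks mark one
# subgroup each; later blocks mark a random nonempty proper subset
.blockTargets <- function(n_blocks, G) {
    targets <- lapply(seq_len(G), function(gz) gz)
    extra <- n_blocks - G
    if (extra > 0)
        targets <- c(targets, lapply(seq_len(extra), function(i) {
            size <- sample.int(G - 1L, 1L)
            sort(sample.int(G, size))
        }))
    targets
}

# block-structured Gaussian scores: per sample s and block b,
# score = baseline + effect * [subgroup(s) in targets(b)] + N(0, block_sd);
# features add independent N(0, feature_sd)
.blockMatrix <- function(g, spec, G, prefix) {
    n <- length(g)
    targets <- .blockTargets(spec$n_blocks, G)
    rowsPer <- spec$block_size
    vals <- matrix(NA_real_, spec$n_blocks * rowsPer, n)
    blockScore <- matrix(NA_real_, spec$n_blocks, n)
    for (b in seq_len(spec$n_blocks)) {
        shift <- spec$effect * as.numeric(g %in% targets[[b]])
        blockScore[b, ] <- spec$baseline + shift + rnorm(n, 0, spec$block_sd)
        rows <- (b - 1L) * rowsPer + seq_len(rowsPer)
        vals[rows, ] <- rep(blockScore[b, ], each = rowsPer) +
            rnorm(rowsPer * n, 0, spec$feature_sd)
    }
    rownames(vals) <- paste0(prefix, rep(seq_len(spec$n_blocks),
                                         each = rowsPer), "_",
                             rep(seq_len(rowsPer), spec$n_blocks))
    list(values = vals, blockScore = blockScore, targets = targets)
}

# sprinkle one missing cell into a fraction of the rows
.addNA <- function(m, frac) {
    nr <- nrow(m)
    hit <- which(runif(nr) < frac)
    for (i in hit) m[i, sample.int(ncol(m), 1L)] <- NA_real_
    m
}

#' Simulate survival times with subgroup-specific hazards
#'
#' Event times are exponential with rate
#' \code{baseline_hazard * exp(offset[subgroup])}; independent
#' exponential censoring is tuned so the expected censored fraction
#' equals \code{censoring_rate} within each subgroup.
#'
#' @param labels subgroup labels (integer 1..G or factor).
#' @param config a \code{\link{syntheticConfig}}.
#' @return data.frame with \code{time} (days) and \code{event}
#'   (1 = death, 0 = censored), one row per label.
#' @export
simulateSurvival <- function(labels, config) {
    if (config$baseline_hazard <= 0)
        stop("'baseline_hazard' must be positive")
    g <- as.integer(labels)
    rate <- config$baseline_hazard * exp(config$log_hazard_offsets[g])
    tt <- rexp(length(g), rate)
    cr <- config$censoring_rate
    if (cr > 0) {
        crate <- rate * cr / (1 - cr)
        cc <- rexp(length(g), crate)
    } else {
        cc <- rep(Inf, length(g))
    }
    data.frame(time = pmax(pmin(tt, cc), 1e-3),
               event = as.integer(tt <= cc))
}

#' Simulate a complete multi-omics study with planted subgroups
#'
#' Draws subgroup memberships, builds four block-structured platforms
#' (CNV emitted as per-sample segment records over a bundled gene
#' model so the genomic-overlap path is exercised; methylation squashed
#' into beta values through a logistic map; mRNA and miRNA emitted on
#' the linear scale so the log2/floor preprocessing applies), a binary
#' mutation matrix with subgroup-enriched genes, clinical covariates
#' with subgroup biases, and survival with subgroup-specific hazards.
#' Fully deterministic given the configuration (including its seed).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{SyntheticMultiOmics}.
#' @export
simulateMultiomics <- function(config = syntheticConfig()) {
    stopifnot(inherits(config, "SyntheticConfig"))
    withr::with_seed(config$seed, .simulateMultiomics(config))
}

.simulateMultiomics <- function(config) {
    n <- config$n_samples
    G <- config$n_subgroups
    ids <- sprintf("S%03d", seq_len(n))
    g <- sample(rep(seq_len(G),
                    times = diff(round(cumsum(c(0, config$proportions)) * n))))
    # guard against a rounding-empty subgroup
    for (gz in seq_len(G))
        if (!any(g == gz)) g[sample.int(n, 1L)] <- gz
    names(g) <- ids

    ## CNV: block scores -> two segments per block per sample
    cnvSpec <- config$platforms$CNV
    cnvTargets <- .blockTargets(cnvSpec$n_blocks, G)
    geneWidth <- 5000L; geneGap <- 5000L
    gpb <- cnvSpec$block_size
    blockSpan <- gpb * (geneWidth + geneGap)
    geneDf <- do.call(rbind, lapply(seq_len(cnvSpec$n_blocks), function(b)
        data.frame(gene = sprintf("GENE_B%d_%d", b, seq_len(gpb)),
                   chrom = as.character(b),
                   start = (seq_len(gpb) - 1L) * (geneWidth + geneGap) + 1L,
                   end = (seq_len(gpb) - 1L) * (geneWidth + geneGap) + geneWidth,
                   stringsAsFactors = FALSE)))
    genes <- GenomicRanges::GRanges(geneDf$chrom,
                                    IRanges::IRanges(geneDf$start, geneDf$end))
    names(genes) <- geneDf$gene
    half <- (gpb %/% 2L) * (geneWidth + geneGap)
    segs <- vector("list", cnvSpec$n_blocks)
    for (b in seq_len(cnvSpec$n_blocks)) {
        shift <- cnvSpec$effect * as.numeric(g %in% cnvTargets[[b]])
        score <- cnvSpec$baseline + shift + rnorm(n, 0, cnvSpec$block_sd)
        segs[[b]] <- data.frame(
            sample = rep(ids, 2L),
            chrom = as.character(b),
            start = rep(c(1L, half + 1L), each = n),
            end = rep(c(half, blockSpan), each = n),
            seg_mean = c(score + rnorm(n, 0, cnvSpec$feature_sd),
                         score + rnorm(n, 0, cnvSpec$feature_sd)),
            stringsAsFactors = FALSE)
    }
    segments <- do.call(rbind, segs)

    ## methylation: logistic squash keeps beta semantics in [0, 1]
    methRaw <- .blockMatrix(g, config$platforms$METH, G, "cg_")
    beta <- 1 / (1 + exp(-methRaw$values))
    beta <- .addNA(beta, config$na_fraction)
    colnames(beta) <- ids
    meth <- PlatformMatrix(beta, kind = "METH", state = "raw")

    ## mRNA / miRNA emitted on the linear scale
    mrnaRaw <- .blockMatrix(g, config$platforms$MRNA, G, "gene_b")
    mrnaVals <- .addNA(2^mrnaRaw$values, config$na_fraction)
    colnames(mrnaVals) <- ids
    mrna <- PlatformMatrix(mrnaVals, kind = "MRNA", state = "raw")

    mirnaRaw <- .blockMatrix(g, config$platforms$MIRNA, G, "hsa-mir-b")
    mirnaVals <- 2^mirnaRaw$values
    colnames(mirnaVals) <- ids
    mirna <- PlatformMatrix(mirnaVals, kind = "MIRNA", state = "raw")

    ## mutation matrix: two enriched genes per subgroup
    M <- config$mutation_genes
    rate <- matrix(config$mutation_baseline, M, G)
    for (gz in seq_len(G)) {
        enriched <- ((gz - 1L) * 2L) %% M + c(1L, 2L)
        rate[enriched, gz] <- pmin(0.95,
            config$mutation_baseline * config$mutation_enrichment)
    }
    mut <- matrix(rbinom(M * n, 1L, rate[, g]), M, n,
                  dimnames = list(sprintf("MUTG%02d", seq_len(M)), ids))
    mutCalls <- which(mut == 1L, arr.ind = TRUE)
    mutation <- buildMutationMatrix(
        data.frame(gene = rownames(mut)[mutCalls[, 1L]],
                   sample = ids[mutCalls[, 2L]]),
        samples = ids)

    ## clinical covariates with subgroup biases
    bias <- config$covariate_bias
    female <- rbinom(n, 1L, bias$female[g]) == 1L
    alcohol <- rbinom(n, 1L, bias$alcohol[g]) == 1L
    afpHigh <- rbinom(n, 1L, bias$afp_high[g]) == 1L
    stageHigh <- rbinom(n, 1L, bias$stage_high[g]) == 1L
    surv <- simulateSurvival(g, config)
    clinical <- data.frame(
        sample_id = ids,
        time = surv$time, event = surv$event,
        gender = ifelse(female, "Female", "Male"),
        alcohol = ifelse(alcohol, "YES", "NO"),
        afp = ifelse(afpHigh, round(exp(runif(n, log(21), log(2000)))),
                     round(runif(n, 1, 20), 1)),
        ajcc_t = as.character(ifelse(stageHigh,
                                     sample(2:4, n, replace = TRUE), 1L)),
        child_pugh = sample(c("Low(1)", "High(>1)"), n, replace = TRUE,
                            prob = c(0.85, 0.15)),
        hcv = sample(c("Yes", "No"), n, replace = TRUE, prob = c(0.8, 0.2)),
        vascular_invasion = sample(c("YES", "NO"), n, replace = TRUE,
                                   prob = c(0.35, 0.65)),
        stringsAsFactors = FALSE)
    clinical$afp_class <- classifyAFP(clinical$afp)
    clinical$stage_class <- classifyStage(clinical$ajcc_t)

    new("SyntheticMultiOmics", segments = segments, genes = genes,
        meth = meth, mrna = mrna, mirna = mirna, mutation = mutation,
        clinical = clinical,
        trueLabels = setNames(factor(g, levels = seq_len(G),
                                     labels = paste0("S", seq_len(G))),
                              ids),
        config = unclass(config))
}

#' Preprocess every platform of a synthetic (or assembled) study
#'
#' Applies the platform-specific preprocessing: gene-level CNV
#' averaging with clipping and SD filtering, methylation NA-drop and
#' top-variance selection, and the log2/floor/top-variance pathway for
#' mRNA and miRNA.
#'
#' @param sim a \linkS4class{SyntheticMultiOmics}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return named list of preprocessed \linkS4class{PlatformMatrix}
#'   objects (\code{CNV}, \code{MRNA}, \code{MIRNA}, \code{METH}).
#' @export
preprocessPlatforms <- function(sim, config = preprocessConfig()) {
    list(CNV = geneLevelCNV(sim@segments, sim@genes, config),
         MRNA = prepExpression(platformMatrix(sim, "MRNA"), config),
         MIRNA = prepMirna(platformMatrix(sim, "MIRNA"), config),
         METH = prepMethylation(platformMatrix(sim, "METH"), config))
}
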