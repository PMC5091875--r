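#' Configuration for the survival-guided sub-cluster search
#'
#' Grid ranges default to the full search space of the method: 2-15
#' sub-clusters for CNV, mRNA and methylation, 2-7 for miRNA, and 2-7
#' candidate subgroup counts. \code{budget} caps how many grid
#' combinations are evaluated (seeded random subsample of the grid);
#' \code{NULL} means exhaustive. Consensus-clustering repetitions and
#' sample fraction default to the conventional 1000 / 0.8; desk-scale
#' runs typically lower \code{reps}.
#'
#' @param cnv_range,mrna_range,mirna_range,meth_range integer vectors of
#'   candidate sub-cluster counts per platform.
#' @param subgroup_range integer vector of candidate subgroup counts.
#' @param min_group_size smallest admissible group in a binary split
#'   (smaller splits become all-NA rows).
#' @param p_threshold log-rank significance threshold for storing a
#'   combination.
#' @param reps,sample_fraction consensus-clustering resampling settings.
#' @param stability_threshold relative delta-area threshold for
#'   \code{\link{selectKDeltaArea}}.
#' @param budget maximum number of grid combinations to evaluate
#'   (\code{NULL} = exhaustive).
#' @param bh_correct apply Benjamini-Hochberg correction across grid
#'   points before calling significance (off by default).
#' @param cluster_method feature sub-clustering method, see
#'   \code{\link{subclusterFeatures}}.
#' @param distance indicator distance, see
#'   \code{\link{binaryIndicatorDist}}.
#' @return a list of class \code{"COCAConfig"}.
#' @export
cocaConfig <- function(cnv_range = 2:15, mrna_range = 2:15,
                       mirna_range = 2:7, meth_range = 2:15,
                       subgroup_range = 2:7, min_group_size = 10L,
                       p_threshold = 0.05, reps = 1000L,
                       sample_fraction = 0.8, stability_threshold = 0.05,
                       budget = NULL, bh_correct = FALSE,
                       cluster_method = "hclust", distance = "hamming") {
    stopifnot(all(cnv_range >= 2), all(mrna_range >= 2),
              all(mirna_range >= 2), all(meth_range >= 2),
              all(subgroup_range >= 2), min_group_size >= 1,
              p_threshold > 0, p_threshold < 1, reps >= 1,
              sample_fraction > 0, sample_fraction <= 1)
    structure(list(cnv_range = as.integer(cnv_range),
                   mrna_range = as.integer(mrna_range),
                   mirna_range = as.integer(mirna_range),
                   meth_range = as.integer(meth_range),
                   subgroup_range = as.integer(subgroup_range),
                   min_group_size = as.integer(min_group_size),
                   p_threshold = p_threshold, reps = as.integer(reps),
                   sample_fraction = sample_fraction,
                   stability_threshold = stability_threshold,
                   budget = budget, bh_correct = bh_correct,
                   cluster_method = cluster_method, distance = distance),
              class = "COCAConfig")
}

# intersect the sample universes of the platforms (and optionally a
# clinical table) and subset every matrix to it, preserving first-seen order
.harmoniseSamples <- function(platforms, clinical = NULL) {
    ids <- Reduce(intersect, lapply(platforms, sampleIDs))
    if (!is.null(clinical)) ids <- intersect(ids, clinical$sample_id)
    if (length(ids) == 0L)
        stop("the platforms (and clinical table) share no samples")
    lapply(platforms, function(p)
        PlatformMatrix(assayValues(p)[, ids, drop = FALSE],
                       kind = platformKind(p), state = matrixState(p),
                       params = p@params))
}

# indicator rows for one combination of per-platform counts, with a
# per-(platform, k) cache: sub-clustering and splitting depend only on
# the platform matrix and k, so the grid reuses them
.comboRows <- function(platforms, counts, config, seed, cache) {
    rows <- list()
    for (nm in names(counts)) {
        key <- paste0(nm, "_", counts[[nm]])
        if (is.null(cache[[key]]))
            cache[[key]] <- platformIndicators(
                platforms[[nm]], counts[[nm]],
                minGroupSize = config$min_group_size, seed = seed,
                method = config$cluster_method)
        rows <- c(rows, cache[[key]])
    }
    rows
}

#' Survival-guided grid search over per-platform sub-cluster counts
#'
#' For every evaluated combination of per-platform sub-cluster counts,
#' the features of each platform are sub-clustered, each sub-cluster is
#' binarised into a 0/1/NA sample indicator, the indicators are stacked
#' into the cluster-of-clusters matrix, samples are consensus-clustered
#' into each candidate subgroup count, and the subgroups are scored by
#' the k-sample log-rank test. Combinations whose subgroups separate
#' survival at \code{p_threshold} are flagged significant; the rest are
#' discarded by downstream selection. Classifications containing a
#' subgroup smaller than \code{min_group_size} are recorded as
#' untested (\code{logrank_p = NA}, not significant): a subgroup below
#' the minimum split size is not a usable subtyping, and near-empty
#' groups invalidate the log-rank chi-square approximation. Evaluation order, any random grid
#' subsampling, and consensus resampling are all seed-deterministic.
#'
#' @param platforms named list of preprocessed
#'   \linkS4class{PlatformMatrix} objects; names identify the platforms
#'   (\code{CNV}, \code{MRNA}, \code{MIRNA}, \code{METH}).
#' @param clinical data.frame with \code{sample_id}, \code{time},
#'   \code{event}.
#' @param config a \code{\link{cocaConfig}}.
#' @param seed integer seed.
#' @return data.frame of grid points with per-platform counts,
#'   \code{k_subgroups}, \code{logrank_p} and \code{significant}.
#' @export
survivalGuidedGridSearch <- function(platforms, clinical,
                                     config = cocaConfig(), seed = 1L) {
    platforms <- .harmoniseSamples(platforms, clinical)
    ids <- sampleIDs(platforms[[1L]])
    clin <- clinical[match(ids, clinical$sample_id), ]
    ranges <- list(CNV = config$cnv_range, MRNA = config$mrna_range,
                   MIRNA = config$mirna_range, METH = config$meth_range)
    ranges <- ranges[names(ranges) %in% names(platforms)]
    grid <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
    if (!is.null(config$budget) && config$budget < nrow(grid))
        grid <- withr::with_seed(as.integer(seed),
            grid[sample.int(nrow(grid), config$budget), , drop = FALSE])
    cache <- new.env(parent = emptyenv())
    out <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        counts <- as.list(grid[i, , drop = FALSE])
        rows <- .comboRows(platforms, counts, config, seed, cache)
        coc <- assembleCOCMatrix(rows, sampleUniverse = ids)
        pts <- lapply(config$subgroup_range, function(ks) {
            cr <- consensusCluster(coc, ks, reps = config$reps,
                                   sampleFraction = config$sample_fraction,
                                   seed = as.integer(seed) + ks,
                                   distance = config$distance)
            lab <- subgroupLabels(cr)[ids]
            # a classification with a subgroup below the minimum group
            # size is not a usable subtyping and the log-rank chi-square
            # approximation degenerates for near-empty groups: such
            # points are recorded as untested (p = NA, not significant)
            p <- if (min(table(lab)) < config$min_group_size) NA_real_
                 else logrankTest(clin$time, clin$event, lab)$p_value
            data.frame(as.data.frame(counts), k_subgroups = ks,
                       logrank_p = p)
        })
        out[[i]] <- do.call(rbind, pts)
    }
    res <- do.call(rbind, out)
    names(res)[seq_along(ranges)] <- paste0("k_", tolower(names(ranges)))
    res$significant <- if (config$bh_correct)
        !is.na(res$logrank_p) &
            p.adjust(res$logrank_p, "BH") < config$p_threshold
    else !is.na(res$logrank_p) & res$logrank_p < config$p_threshold
    rownames(res) <- NULL
    res
}

#' Select per-platform sub-cluster counts by recurrence
#'
#' Among the significant grid points, takes for each platform
#' independently the most recurrent sub-cluster count; ties are broken
#' toward the smaller count (reported via a message).
#'
#' @param points data.frame from
#'   \code{\link{survivalGuidedGridSearch}}.
#' @return named integer vector of selected counts, one per platform
#'   column (\code{k_cnv}, \code{k_mrna}, ...).
#' @export
recurrenceModeSelect <- function(points) {
    sig <- points[points$significant, , drop = FALSE]
    if (nrow(sig) == 0L)
        stop("no significant grid point; widen the grid, raise the ",
             "p threshold, or check the survival data")
    cols <- grep("^k_(?!subgroups)", names(points), perl = TRUE, value = TRUE)
    sel <- vapply(cols, function(cl) {
        tb <- table(sig[[cl]])
        best <- names(tb)[tb == max(tb)]
        if (length(best) > 1L)
            message("tie for ", cl, " between counts ",
                    paste(best, collapse = ", "),
                    "; choosing the smaller")
        min(as.integer(best))
    }, integer(1))
    names(sel) <- cols
    sel
}

#' Final subgroup calling at the selected sub-cluster counts
#'
#' Rebuilds the cluster-of-clusters matrix at the selected per-platform
#' sub-cluster counts, consensus-clusters the samples at every
#' candidate subgroup count, and picks the count at the elbow of the
#' consensus-CDF delta-area curve.
#'
#' @param platforms named list of preprocessed
#'   \linkS4class{PlatformMatrix} objects.
#' @param counts named integer vector or list of selected sub-cluster
#'   counts; names must match \code{names(platforms)} (a
#'   \code{\link{recurrenceModeSelect}} result with \code{k_cnv}-style
#'   names is also accepted).
#' @param config a \code{\link{cocaConfig}}.
#' @param seed integer seed.
#' @return list with \code{k} (chosen subgroup count), \code{labels}
#'   (named subgroup assignment), \code{result} (the chosen
#'   \linkS4class{ConsensusResult}), \code{deltaArea}, \code{results}
#'   (all candidates) and \code{coc} (the assembled
#'   \linkS4class{COCMatrix}).
#' @export
finalizeSubgroups <- function(platforms, counts, config = cocaConfig(),
                              seed = 1L) {
    counts <- as.list(counts)
    names(counts) <- toupper(sub("^k_", "", names(counts)))
    if (!all(names(platforms) %in% names(counts)))
        stop("no sub-cluster count supplied for platform(s): ",
             paste(setdiff(names(platforms), names(counts)), collapse = ", "))
    counts <- counts[names(platforms)]
    platforms <- .harmoniseSamples(platforms)
    ids <- sampleIDs(platforms[[1L]])
    cache <- new.env(parent = emptyenv())
    rows <- .comboRows(platforms, counts, config, seed, cache)
    coc <- assembleCOCMatrix(rows, sampleUniverse = ids)
    results <- lapply(config$subgroup_range, function(ks)
        consensusCluster(coc, ks, reps = config$reps,
                         sampleFraction = config$sample_fraction,
                         seed = as.integer(seed) + ks,
                         distance = config$distance))
    chosen <- selectKDeltaArea(results, config$stability_threshold)
    res <- results[[match(as.integer(chosen), config$subgroup_range)]]
    list(k = as.integer(chosen), labels = subgroupLabels(res),
         result = res, deltaArea = attr(chosen, "deltaArea"),
         results = results, coc = coc)
}

#' Leave-one-out cross-validated subgroup assignment accuracy
#'
#' For each sample, subgroup centroids are recomputed on the indicator
#' matrix without it, the sample is assigned to the nearest centroid
#' under the NA-tolerant mean absolute difference, and the assignment
#' is compared with its label. Samples in singleton subgroups are
#' skipped with a warning (their centroid would be empty) and the
#' denominator adjusted.
#'
#' @param x \linkS4class{COCMatrix} or 0/1/NA matrix.
#' @param labels named subgroup assignment covering the samples.
#' @return proportion of correctly re-assigned samples, with attribute
#'   \code{"n"} = number of samples scored.
#' @export
loocvAccuracy <- function(x, labels) {
    X <- if (is(x, "COCMatrix")) indicatorMatrix(x) else x
    ids <- colnames(X)
    labels <- labels[ids]
    if (anyNA(labels)) stop("labels must cover every sample")
    if (length(unique(labels)) < 2L)
        stop("need at least 2 subgroups")
    sizes <- table(labels)
    single <- names(sizes)[sizes < 2L]
    if (length(single))
        warning("singleton subgroup(s) skipped in LOOCV: ",
                paste(single, collapse = ", "))
    score <- !(labels %in% single)
    correct <- logical(0)
    groups <- sort(unique(labels[score]))
    for (i in which(score)) {
        cen <- vapply(groups, function(gz) {
            cols <- setdiff(which(labels == gz), i)
            rowMeans(X[, cols, drop = FALSE], na.rm = TRUE)
        }, numeric(nrow(X)))
        cen <- matrix(cen, nrow = nrow(X))
        xi <- X[, i]
        d <- vapply(seq_along(groups), function(j) {
            ok <- !is.na(xi) & !is.na(cen[, j])
            if (!any(ok)) return(Inf)
            mean(abs(xi[ok] - cen[ok, j]))
        }, numeric(1))
        correct <- c(correct, groups[which.min(d)] == labels[i])
    }
    structure(mean(correct), n = length(correct))
}
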