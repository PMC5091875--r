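#' Association between subgroup labels and a categorical covariate
#'
#' Builds the subgroup-by-level contingency table and tests it with
#' Fisher's exact test (default; exact enumeration, falling back to a
#' simulated p-value for tables too large to enumerate) or the
#' chi-square test. Samples with a missing label or level are dropped
#' from the table.
#'
#' @param labels sample subgroup labels (vector or named vector).
#' @param covariate categorical covariate, aligned with \code{labels};
#'   alternatively pass a pre-built contingency matrix as \code{labels}
#'   and omit \code{covariate}.
#' @param test \code{"fisher"} or \code{"chi_square"}.
#' @return list of class \code{"AssociationResult"} with the
#'   contingency table, the test used and the p-value.
#' @export
associationTest <- function(labels, covariate = NULL,
                            test = c("fisher", "chi_square")) {
    test <- match.arg(test)
    if (is.matrix(labels) || is.table(labels)) {
        tab <- as.table(as.matrix(labels))
    } else {
        keep <- !is.na(labels) & !is.na(covariate)
        tab <- table(group = labels[keep], level = covariate[keep])
    }
    if (nrow(tab) < 2L)
        stop("need at least 2 subgroups with observed samples")
    if (ncol(tab) < 2L)
        stop("covariate has a single observed level")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("contingency table has an empty margin")
    p <- if (test == "fisher") {
        tryCatch(fisher.test(tab)$p.value,
                 error = function(e)
                     fisher.test(tab, simulate.p.value = TRUE,
                                 B = 1e5)$p.value)
    } else {
        suppressWarnings(chisq.test(tab)$p.value)
    }
    structure(list(contingency = tab, test = test, p_value = p),
              class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
    cat(sprintf("%s test: p = %.4g\n",
                if (x$test == "fisher") "Fisher exact" else "Chi-square",
                x$p_value))
    print(x$contingency)
    invisible(x)
}

#' Proportion of a covariate level within a set of subgroups
#'
#' Computes 100 * (samples at \code{focusLevel} within
#' \code{focusGroups}) / (samples with an observed level within
#' \code{focusGroups}); the rounded integer percent is what subgroup
#' reports display, the unrounded value is retained.
#'
#' @param labels sample subgroup labels.
#' @param covariate categorical covariate aligned with \code{labels}.
#' @param focusGroups subgroup labels forming the focus set.
#' @param focusLevel the covariate level counted.
#' @return list of class \code{"SubgroupProportion"} with \code{count},
#'   \code{total}, \code{proportion} (unrounded percent) and
#'   \code{percent} (rounded to the nearest integer).
#' @export
subgroupProportions <- function(labels, covariate, focusGroups,
                                focusLevel) {
    stopifnot(length(labels) == length(covariate), length(focusGroups) >= 1)
    keep <- !is.na(labels) & !is.na(covariate) & labels %in% focusGroups
    total <- sum(keep)
    if (total == 0L)
        stop("no sample with an observed level in the focus subgroups")
    count <- sum(covariate[keep] == focusLevel)
    pct <- 100 * count / total
    structure(list(count = count, total = total, proportion = pct,
                   percent = round(pct)),
              class = "SubgroupProportion")
}

#' @export
print.SubgroupProportion <- function(x, ...) {
    cat(sprintf("%d/%d = %.1f%% (reported as %d%%)\n",
                x$count, x$total, x$proportion, x$percent))
    invisible(x)
}

#' One-vs-rest ROC AUC of a feature for a subgroup
#'
#' Area under the ROC curve of the feature value as a score separating
#' the subgroup (positives) from all other samples, computed through
#' the Mann-Whitney identity AUC = U / (n1 * n0) with tied pairs
#' contributing 1/2. Orientation is fixed (higher value scores toward
#' the subgroup); \code{auc_direction_free} = max(AUC, 1 - AUC) covers
#' markers that distinguish a subgroup by low values.
#'
#' @param values numeric feature values per sample.
#' @param labels subgroup labels aligned with \code{values}.
#' @param subgroup the focus subgroup.
#' @return list of class \code{"AUCRecord"} with \code{auc},
#'   \code{auc_direction_free}, \code{n_pos}, \code{n_neg}.
#' @export
featureAUCOneVsRest <- function(values, labels, subgroup) {
    keep <- !is.na(values) & !is.na(labels)
    values <- values[keep]; labels <- labels[keep]
    pos <- labels == subgroup
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L)
        stop("subgroup must be nonempty and not contain all samples")
    r <- rank(values)
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    structure(list(auc = auc, auc_direction_free = max(auc, 1 - auc),
                   n_pos = n1, n_neg = n0),
              class = "AUCRecord")
}

#' Per-subgroup molecular signature table
#'
#' For every platform and subgroup, screens each feature with a
#' two-sample rank-sum test (subgroup vs rest), adjusts p-values by
#' Benjamini-Hochberg within each platform-subgroup screen, and
#' reports the features passing \code{alpha} (at most \code{topN} per
#' screen, strongest first) together with the effect direction and the
#' one-vs-rest AUC.
#'
#' @param platforms named list of \linkS4class{PlatformMatrix} objects.
#' @param labels named subgroup assignment covering the samples.
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param topN maximum reported features per platform and subgroup.
#' @return data.frame with columns \code{platform}, \code{subgroup},
#'   \code{feature_id}, \code{p_value}, \code{p_adj},
#'   \code{direction}, \code{auc}; zero rows when nothing passes.
#' @export
subgroupSignatureTable <- function(platforms, labels, alpha = 0.05,
                                   topN = 5L) {
    out <- list()
    for (nm in names(platforms)) {
        m <- assayValues(platforms[[nm]])
        ids <- intersect(colnames(m), names(labels))
        m <- m[, ids, drop = FALSE]
        lab <- labels[ids]
        for (gz in sort(unique(lab))) {
            pos <- lab == gz
            if (sum(pos) < 2L || sum(!pos) < 2L) next
            pv <- apply(m, 1L, function(v)
                suppressWarnings(wilcox.test(v[pos], v[!pos])$p.value))
            padj <- p.adjust(pv, "BH")
            hit <- which(padj < alpha)
            if (length(hit) == 0L) next
            hit <- hit[order(pv[hit])][seq_len(min(topN, length(hit)))]
            auc <- vapply(hit, function(i)
                featureAUCOneVsRest(m[i, ], lab, gz)$auc, numeric(1))
            out[[length(out) + 1L]] <- data.frame(
                platform = nm, subgroup = gz,
                feature_id = rownames(m)[hit],
                p_value = pv[hit], p_adj = padj[hit],
                direction = ifelse(auc >= 0.5, "up", "down"),
                auc = auc, stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(platform = character(0), subgroup = character(0),
                          feature_id = character(0), p_value = numeric(0),
                          p_adj = numeric(0), direction = character(0),
                          auc = numeric(0), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
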