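#' NA-tolerant distance between samples on a binary indicator matrix
#'
#' Distance between two samples is the fraction of mismatching indicator
#' rows among the rows where both samples are observed (NA-tolerant
#' Hamming distance); \code{"jaccard"} instead uses one minus the
#' Jaccard similarity of the 1-entries over mutually observed rows.
#' Sample pairs with no mutually observed row get distance 0.5 (the
#' uninformative midpoint) with a warning.
#'
#' @param x a \linkS4class{COCMatrix} or a 0/1/NA matrix with indicator
#'   rows and sample columns.
#' @param method \code{"hamming"} (default) or \code{"jaccard"}.
#' @return symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
binaryIndicatorDist <- function(x, method = c("hamming", "jaccard")) {
    method <- match.arg(method)
    X <- if (is(x, "COCMatrix")) indicatorMatrix(x) else x
    M <- !is.na(X)
    A <- X; A[!M] <- 0          # 1 where observed one
    B <- M - A                  # 1 where observed zero
    obs <- crossprod(M)
    if (method == "hamming") {
        mism <- crossprod(A, B)
        mism <- mism + t(mism)
        d <- mism / obs
    } else {
        both1 <- crossprod(A)
        either <- obs - crossprod(B)
        d <- 1 - both1 / either
        d[either == 0 & obs > 0] <- 0    # neither carries a 1: identical
    }
    never <- obs == 0
    if (any(never[upper.tri(never)])) {
        warning("sample pair(s) share no observed indicator row; distance set to 0.5")
        d[never] <- 0.5
    }
    diag(d) <- 0
    dimnames(d) <- list(colnames(X), colnames(X))
    d
}

# reassign the farthest member of the largest cluster into each empty one
.repairEmptyClusters <- function(cl, m, k) {
    for (empty in setdiff(seq_len(k), unique(cl))) {
        big <- as.integer(names(which.max(table(cl))))
        members <- which(cl == big)
        cen <- colMeans(m[members, , drop = FALSE])
        far <- members[which.max(rowSums((m[members, , drop = FALSE] -
                                          rep(cen, each = length(members)))^2))]
        cl[far] <- empty
    }
    cl
}

#' Divide platform features into k sub-clusters
#'
#' Groups the features of a preprocessed platform into \code{k}
#' sub-clusters. The default is hierarchical clustering with
#' correlation distance (1 - Pearson across samples) and average
#' linkage, cut at \code{k} — the standard approach for co-varying
#' feature blocks; \code{method = "kmeans"} clusters the feature
#' profiles directly (empty clusters repaired by moving the farthest
#' member of the largest cluster).
#'
#' @param x preprocessed \linkS4class{PlatformMatrix} (or numeric
#'   matrix, features x samples).
#' @param k number of sub-clusters (2 <= k <= number of features).
#' @param seed integer seed (used by the k-means option; the
#'   hierarchical default is deterministic).
#' @param method \code{"hclust"} (default) or \code{"kmeans"}.
#' @return list of class \code{"FeatureSubclusters"} with elements
#'   \code{platform}, \code{k} and \code{assignment} (named integer in
#'   1..k covering every feature).
#' @export
subclusterFeatures <- function(x, k, seed = 1L,
                               method = c("hclust", "kmeans")) {
    method <- match.arg(method)
    m <- if (is(x, "PlatformMatrix")) assayValues(x) else x
    kind <- if (is(x, "PlatformMatrix")) platformKind(x) else NA_character_
    k <- as.integer(k)
    if (k < 2L) stop("k must be at least 2")
    if (k > nrow(m))
        stop("k = ", k, " exceeds the number of features (", nrow(m), ")")
    if (method == "hclust") {
        cc <- suppressWarnings(cor(t(m)))
        cc[!is.finite(cc)] <- 0       # zero-variance features: uninformative
        cl <- cutree(hclust(as.dist(1 - cc), method = "average"), k = k)
    } else {
        cl <- withr::with_seed(seed,
            kmeans(m, centers = k, nstart = 10, iter.max = 50)$cluster)
        cl <- .repairEmptyClusters(cl, m, k)
    }
    names(cl) <- rownames(m)
    structure(list(platform = kind, k = k, assignment = cl),
              class = "FeatureSubclusters")
}

#' Binarise one feature sub-cluster into a sample indicator row
#'
#' Samples are split into two groups by hierarchical clustering (Ward
#' linkage on Euclidean distance) of the member-feature submatrix. If
#' either group contains fewer than \code{minGroupSize} samples the row
#' carries NA for every sample (the split is considered unreliable);
#' otherwise the group with the higher mean member-feature value is
#' labelled 1 and the other 0.
#'
#' @param x \linkS4class{PlatformMatrix} (or matrix) the sub-cluster
#'   came from.
#' @param members character vector of member feature IDs.
#' @param minGroupSize smallest admissible group (default 10).
#' @param subcluster integer index recorded in the row metadata.
#' @return list of class \code{"IndicatorRow"} with elements
#'   \code{platform}, \code{subcluster} and \code{labels} (named 0/1/NA
#'   per sample).
#' @export
indicatorFromSubcluster <- function(x, members, minGroupSize = 10L,
                                    subcluster = NA_integer_) {
    m <- if (is(x, "PlatformMatrix")) assayValues(x) else x
    kind <- if (is(x, "PlatformMatrix")) platformKind(x) else NA_character_
    members <- intersect(members, rownames(m))
    if (length(members) == 0L)
        stop("no member feature is present in the matrix")
    if (ncol(m) < 2L) stop("need at least 2 samples to split")
    sub <- m[members, , drop = FALSE]
    cl <- cutree(hclust(dist(t(sub)), method = "ward.D2"), k = 2L)
    labels <- rep(NA_real_, ncol(m))
    names(labels) <- colnames(m)
    if (min(table(cl)) >= minGroupSize) {
        mu <- tapply(colMeans(sub), cl, mean)
        hi <- as.integer(names(mu)[which.max(mu)])
        labels[] <- as.numeric(cl == hi)
    }
    structure(list(platform = kind, subcluster = as.integer(subcluster),
                   labels = labels),
              class = "IndicatorRow")
}

#' Build every indicator row for one platform at a given sub-cluster count
#'
#' Convenience wrapper: sub-clusters the features into \code{k} groups
#' and binarises each group with \code{\link{indicatorFromSubcluster}}.
#'
#' @inheritParams subclusterFeatures
#' @param minGroupSize smallest admissible sample group per split.
#' @return list of \code{k} \code{"IndicatorRow"} objects, ordered by
#'   sub-cluster index.
#' @export
platformIndicators <- function(x, k, minGroupSize = 10L, seed = 1L,
                               method = c("hclust", "kmeans")) {
    sc <- subclusterFeatures(x, k, seed = seed, method = method)
    lapply(seq_len(sc$k), function(i)
        indicatorFromSubcluster(x, names(sc$assignment)[sc$assignment == i],
                                minGroupSize = minGroupSize,
                                subcluster = i))
}

.PLATFORM_ORDER <- c("CNV", "MRNA", "MIRNA", "METH", "MUT", "PROT")

#' Stack indicator rows into the cluster-of-clusters matrix
#'
#' Rows are ordered by platform (CNV, mRNA, miRNA, methylation) and
#' then by sub-cluster index. All-NA rows are retained: they carry no
#' information for clustering but preserve the accounting that the row
#' count equals the sum of per-platform sub-cluster counts.
#'
#' @param rows list of \code{"IndicatorRow"} objects sharing one sample
#'   universe.
#' @param sampleUniverse optional explicit sample-ID vector to check
#'   against.
#' @return a \linkS4class{COCMatrix}.
#' @export
assembleCOCMatrix <- function(rows, sampleUniverse = NULL) {
    if (length(rows) == 0L) stop("no indicator rows supplied")
    ids <- lapply(rows, function(r) names(r$labels))
    ref <- if (is.null(sampleUniverse)) ids[[1L]] else sampleUniverse
    for (i in seq_along(ids)) {
        if (!setequal(ids[[i]], ref)) {
            asym <- c(setdiff(ids[[i]], ref), setdiff(ref, ids[[i]]))
            stop("indicator row ", i, " has an inconsistent sample set; ",
                 "asymmetric samples: ", paste(asym, collapse = ", "))
        }
    }
    plat <- vapply(rows, function(r) r$platform, character(1))
    sub <- vapply(rows, function(r) r$subcluster, integer(1))
    ord <- order(match(plat, .PLATFORM_ORDER), sub)
    rows <- rows[ord]
    ind <- do.call(rbind, lapply(rows, function(r) r$labels[ref]))
    colnames(ind) <- ref
    info <- data.frame(platform = plat[ord], subcluster = sub[ord],
                       stringsAsFactors = FALSE)
    rownames(ind) <- make.unique(paste0(info$platform, info$subcluster))
    new("COCMatrix", indicators = ind, rowInfo = info)
}

#' Consensus clustering of samples by resampling
#'
#' For each of \code{reps} repetitions, a fraction of the samples is
#' drawn without replacement, clustered into \code{k} groups by
#' hierarchical clustering (average linkage) on the NA-tolerant binary
#' distance, and co-clustering counts are accumulated. The consensus
#' entry for a sample pair is its co-clustering count divided by its
#' co-sampling count. Final subgroup labels come from hierarchical
#' clustering (average linkage) of one minus the consensus matrix. The
#' area under the empirical CDF of the off-diagonal consensus entries
#' is stored for choosing the number of subgroups.
#'
#' @param x \linkS4class{COCMatrix} (or 0/1/NA matrix).
#' @param k subgroup count (2 <= k <= number of samples).
#' @param reps number of resampling repetitions (default 1000).
#' @param sampleFraction fraction of samples drawn per repetition
#'   (default 0.8; 1 disables resampling variance).
#' @param seed integer seed controlling the subsampling.
#' @param distance passed to \code{\link{binaryIndicatorDist}}.
#' @return a \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(x, k, reps = 1000L, sampleFraction = 0.8,
                             seed = 1L, distance = "hamming") {
    X <- if (is(x, "COCMatrix")) indicatorMatrix(x) else x
    n <- ncol(X)
    k <- as.integer(k)
    if (k < 2L) stop("k must be at least 2")
    if (n < 2L || k > n)
        stop("k = ", k, " exceeds the number of samples (", n, ")")
    stopifnot(reps >= 1L, sampleFraction > 0, sampleFraction <= 1)
    D <- binaryIndicatorDist(X, method = distance)
    m <- max(2L, as.integer(floor(sampleFraction * n)))
    co <- matrix(0, n, n)
    tog <- matrix(0, n, n)
    withr::with_seed(as.integer(seed), {
        for (r in seq_len(reps)) {
            idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
            cl <- cutree(hclust(as.dist(D[idx, idx]), method = "average"),
                         k = min(k, m))
            tog[idx, idx] <- tog[idx, idx] + 1
            com <- outer(cl, cl, "==")
            co[idx, idx] <- co[idx, idx] + com
        }
    })
    cons <- co / tog
    if (any(tog == 0)) {
        warning("sample pair(s) never co-sampled; consensus entry set to 0 ",
                "(increase reps)")
        cons[tog == 0] <- 0
    }
    diag(cons) <- 1
    cons <- (cons + t(cons)) / 2
    dimnames(cons) <- list(colnames(X), colnames(X))
    labels <- cutree(hclust(as.dist(1 - cons), method = "average"), k = k)
    entries <- sort(cons[upper.tri(cons)])
    new("ConsensusResult", k = k, consensus = cons,
        labels = setNames(as.integer(labels), colnames(X)),
        area = .cdfArea(entries), entries = entries)
}

# area under the empirical CDF of consensus entries over [0, 1]
.cdfArea <- function(entries) {
    if (length(entries) == 0L) return(0)
    F <- ecdf(entries)
    xs <- sort(unique(c(0, entries, 1)))
    sum(diff(xs) * F(xs[-length(xs)]))
}

#' Choose the subgroup count from the consensus CDF delta-area curve
#'
#' Given consensus results for consecutive subgroup counts starting at
#' 2, computes the relative delta-area of the consensus CDF — the area
#' gain from k-1 to k divided by the area at k = 2, a fixed reference
#' that treats all k comparably (for k = 2 the area itself) — and
#' returns the largest k whose relative delta-area exceeds
#' \code{threshold}: the elbow of the CDF-area curve. An elbow only
#' exists if the curve has flattened by the end of the candidate
#' range: if the last delta-area still exceeds the threshold (the
#' curve is still climbing, as for structureless data), or no k ever
#' exceeds it, the minimum k is returned with an instability warning.
#'
#' @param results list of \linkS4class{ConsensusResult} objects for
#'   consecutive k starting at 2.
#' @param threshold relative delta-area stability threshold (default
#'   0.05).
#' @return chosen k (integer) with attribute \code{"deltaArea"} holding
#'   the named delta-area vector.
#' @export
selectKDeltaArea <- function(results, threshold = 0.05) {
    ks <- vapply(results, function(r) r@k, integer(1))
    if (length(ks) == 1L) {
        warning("single subgroup count supplied; returning it")
        return(structure(ks, deltaArea = setNames(NA_real_, ks)))
    }
    if (!all(diff(ks) == 1L) || ks[1L] != 2L)
        stop("results must cover consecutive subgroup counts starting at 2")
    areas <- vapply(results, function(r) r@area, numeric(1))
    ref <- areas[1L]
    delta <- c(ref, if (ref > 0) diff(areas) / ref else rep(0, length(areas) - 1L))
    names(delta) <- ks
    ok <- delta > threshold
    if (!any(ok) || ok[length(ok)]) {
        # either no count ever clears the threshold, or the area curve is
        # still climbing at the end of the range: no elbow exists
        warning("consensus CDF area curve shows no stable elbow over the ",
                "candidate range; returning the minimum subgroup count")
        chosen <- ks[1L]
    } else {
        chosen <- max(ks[ok])
    }
    structure(chosen, deltaArea = delta)
}
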