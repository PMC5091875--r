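#' Preprocessing configuration
#'
#' Bundles the per-platform feature-construction thresholds: the CNV
#' clipping bound and SD filter, the methylation top-N, and the
#' expression/miRNA log2 floors and top-N counts. Defaults are the
#' values used throughout the pipeline: CNV scores clipped to [-2, 2]
#' and kept when across-sample SD > 0.2; the 10000 most variable CpG
#' sites; mRNA log2 values floored at -26 with the top 6000 genes;
#' miRNA log2-RPM floored at 0 with the top 80 miRNAs.
#'
#' @param cnv_clip positive magnitude bound for CNV scores.
#' @param cnv_sd_min CNV across-sample SD threshold (strictly greater
#'   retained).
#' @param meth_top_n number of most-variable CpG sites kept.
#' @param mrna_floor log2 expression floor.
#' @param mrna_top_n number of most-variable genes kept.
#' @param mirna_floor log2 RPM floor.
#' @param mirna_top_n number of most-variable miRNAs kept.
#' @param cnv_weighting \code{"length"} (default) averages segment means
#'   weighted by overlapped base pairs; \code{"unweighted"} averages the
#'   overlapping segment values directly.
#' @return a list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(cnv_clip = 2, cnv_sd_min = 0.2,
                             meth_top_n = 10000,
                             mrna_floor = -26, mrna_top_n = 6000,
                             mirna_floor = 0, mirna_top_n = 80,
                             cnv_weighting = c("length", "unweighted")) {
    cnv_weighting <- match.arg(cnv_weighting)
    stopifnot(cnv_clip > 0, meth_top_n >= 1, mrna_top_n >= 1,
              mirna_top_n >= 1)
    structure(list(cnv_clip = cnv_clip, cnv_sd_min = cnv_sd_min,
                   meth_top_n = as.integer(meth_top_n),
                   mrna_floor = mrna_floor,
                   mrna_top_n = as.integer(mrna_top_n),
                   mirna_floor = mirna_floor,
                   mirna_top_n = as.integer(mirna_top_n),
                   cnv_weighting = cnv_weighting),
              class = "PreprocessConfig")
}

# row SDs with the n-1 denominator, NA-propagating
.rowSds <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (n - 1L))
}

# descending-SD order, ties broken lexicographically by feature ID so
# repeated runs are bit-reproducible
.topBySd <- function(m, top_n) {
    sds <- .rowSds(m)
    ord <- order(-sds, rownames(m), method = "radix")
    m[ord[seq_len(min(top_n, nrow(m)))], , drop = FALSE]
}

#' Gene-level copy-number scores from segment records
#'
#' For each gene and sample, averages the log2 segment means of all
#' segments overlapping the gene interval, by default weighting each
#' segment by the number of bases it contributes to the gene (an
#' unweighted mean of segment values is available via
#' \code{cnv_weighting = "unweighted"}). Scores are clipped to
#' \code{[-cnv_clip, cnv_clip]} to blunt extreme values, genes with a
#' missing score in any sample (no overlapping segment there) are
#' removed, and only genes whose across-sample SD exceeds
#' \code{cnv_sd_min} are retained.
#'
#' @param segments data.frame as returned by \code{\link{readSegFile}}.
#' @param genes \link[GenomicRanges]{GRanges} gene model (names = gene
#'   IDs), as returned by \code{\link{readGeneBed}}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return preprocessed \linkS4class{PlatformMatrix} of kind
#'   \code{"CNV"}.
#' @export
geneLevelCNV <- function(segments, genes, config = preprocessConfig()) {
    if (nrow(segments) == 0L) stop("no segment records supplied")
    if (length(genes) == 0L) stop("empty gene model")
    if (is.null(names(genes)) || anyDuplicated(names(genes)))
        stop("gene model must carry unique gene IDs as names")
    samples <- unique(segments$sample)
    segGR <- GenomicRanges::GRanges(
        seqnames = sub("^chr", "", segments$chrom),
        ranges = IRanges::IRanges(start = segments$start,
                                  end = segments$end))
    GenomeInfoDb::seqlevels(genes) <- sub("^chr", "",
                                          GenomeInfoDb::seqlevels(genes))
    lev <- union(GenomeInfoDb::seqlevels(genes),
                 GenomeInfoDb::seqlevels(segGR))
    GenomeInfoDb::seqlevels(genes) <- lev
    GenomeInfoDb::seqlevels(segGR) <- lev
    hits <- GenomicRanges::findOverlaps(genes, segGR, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ow <- GenomicRanges::width(GenomicRanges::pintersect(
        genes[qi], segGR[si]))
    w <- if (config$cnv_weighting == "length") ow else rep(1, length(ow))
    gi <- factor(names(genes)[qi], levels = names(genes))
    sf <- factor(segments$sample[si], levels = samples)
    num <- tapply(w * segments$seg_mean[si], list(gi, sf), sum)
    den <- tapply(w, list(gi, sf), sum)
    scores <- num / den          # genes x samples; NA where no overlap
    scores <- matrix(as.numeric(scores), nrow = length(genes),
                     dimnames = list(names(genes), samples))
    noCov <- rowSums(is.na(scores)) > 0L
    if (all(noCov))
        stop("no gene is covered by segments in every sample")
    if (any(noCov))
        warning(sum(noCov),
                " gene(s) lacking segment coverage in some sample dropped")
    scores <- scores[!noCov, , drop = FALSE]
    scores[scores > config$cnv_clip] <- config$cnv_clip
    scores[scores < -config$cnv_clip] <- -config$cnv_clip
    # SD is undefined for a single sample; the variance filter is vacuous then
    keep <- if (ncol(scores) > 1L) .rowSds(scores) > config$cnv_sd_min
            else rep(TRUE, nrow(scores))
    scores <- scores[keep, , drop = FALSE]
    if (nrow(scores) == 0L)
        stop("no gene passed the CNV SD filter (SD > ", config$cnv_sd_min, ")")
    PlatformMatrix(scores, kind = "CNV", state = "preprocessed",
                   params = list(clip = config$cnv_clip,
                                 sd_min = config$cnv_sd_min))
}

#' Preprocess a methylation beta-value matrix
#'
#' CpG sites with a missing beta value in any sample are removed, then
#' the \code{meth_top_n} sites with the highest across-sample SD are
#' retained (descending SD, ties broken by probe ID).
#'
#' @param x raw \linkS4class{PlatformMatrix} of kind \code{"METH"}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return preprocessed \linkS4class{PlatformMatrix}.
#' @export
prepMethylation <- function(x, config = preprocessConfig()) {
    stopifnot(is(x, "PlatformMatrix"), platformKind(x) == "METH")
    m <- assayValues(x)
    m <- m[complete.cases(m), , drop = FALSE]
    if (nrow(m) == 0L)
        stop("every CpG site contains a missing beta value")
    m <- .topBySd(m, config$meth_top_n)
    PlatformMatrix(m, kind = "METH", state = "preprocessed",
                   params = list(top_n = config$meth_top_n))
}

# shared log2 + floor + complete-case + top-N pathway for expression-like
# platforms; zeros map straight to the floor (log of zero undefined)
.prepExpressionLike <- function(m, floor, top_n) {
    m <- m[complete.cases(m), , drop = FALSE]
    if (nrow(m) == 0L)
        stop("no feature is detected in all samples")
    if (any(m < 0)) stop("expression values must be nonnegative")
    lg <- suppressWarnings(log2(m))
    lg[!is.finite(lg) | lg < floor] <- floor
    .topBySd(lg, top_n)
}

#' Preprocess an mRNA expression matrix
#'
#' Genes detected (non-missing) in all samples are log2-transformed,
#' values below \code{mrna_floor} (default -26) are replaced by the
#' floor — zeros map directly to it — and the \code{mrna_top_n} genes
#' with the highest SD are retained.
#'
#' @param x raw \linkS4class{PlatformMatrix} of kind \code{"MRNA"}
#'   holding nonnegative scaled estimates.
#' @param config a \code{\link{preprocessConfig}}.
#' @return preprocessed \linkS4class{PlatformMatrix}.
#' @export
prepExpression <- function(x, config = preprocessConfig()) {
    stopifnot(is(x, "PlatformMatrix"), platformKind(x) == "MRNA")
    m <- .prepExpressionLike(assayValues(x), config$mrna_floor,
                             config$mrna_top_n)
    PlatformMatrix(m, kind = "MRNA", state = "preprocessed",
                   params = list(floor = config$mrna_floor,
                                 top_n = config$mrna_top_n))
}

#' Preprocess a miRNA RPM matrix
#'
#' As \code{\link{prepExpression}}, with the miRNA defaults: log2 of
#' reads-per-million, floor at 0, top 80 by SD.
#'
#' @param x raw \linkS4class{PlatformMatrix} of kind \code{"MIRNA"}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return preprocessed \linkS4class{PlatformMatrix}.
#' @export
prepMirna <- function(x, config = preprocessConfig()) {
    stopifnot(is(x, "PlatformMatrix"), platformKind(x) == "MIRNA")
    m <- .prepExpressionLike(assayValues(x), config$mirna_floor,
                             config$mirna_top_n)
    PlatformMatrix(m, kind = "MIRNA", state = "preprocessed",
                   params = list(floor = config$mirna_floor,
                                 top_n = config$mirna_top_n))
}

#' Build a binary gene-by-sample mutation matrix
#'
#' @param calls data.frame (or list coercible to one) with columns
#'   \code{gene} and \code{sample}; duplicate calls are idempotent.
#' @param samples the full sample universe (columns of the result).
#' @return \linkS4class{PlatformMatrix} of kind \code{"MUT"} with 1 =
#'   mutated, 0 = non-mutated; genes with zero mutations are excluded.
#' @export
buildMutationMatrix <- function(calls, samples) {
    calls <- as.data.frame(calls)
    if (nrow(calls) == 0L) {
        m <- matrix(numeric(0), 0, length(samples),
                    dimnames = list(character(0), samples))
        return(PlatformMatrix(m, kind = "MUT", state = "preprocessed"))
    }
    stopifnot(all(c("gene", "sample") %in% names(calls)))
    unknown <- setdiff(calls$sample, samples)
    if (length(unknown))
        stop("mutation call(s) reference unknown sample(s): ",
             paste(unique(unknown), collapse = ", "))
    genes <- sort(unique(as.character(calls$gene)))
    m <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(as.character(calls$gene), as.character(calls$sample))] <- 1
    PlatformMatrix(m, kind = "MUT", state = "preprocessed")
}
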