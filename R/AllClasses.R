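#' @import methods
#' @importFrom stats sd ecdf cutree hclust dist as.dist cor kmeans pchisq
#'   rexp rbinom rnorm runif quantile p.adjust wilcox.test fisher.test
#'   chisq.test complete.cases setNames
#' @importFrom utils head read.delim write.table count.fields modifyList
NULL

.PLATFORM_KINDS <- c("CNV", "METH", "MRNA", "MIRNA", "MUT", "PROT")
.MATRIX_STATES <- c("raw", "preprocessed")

#' PlatformMatrix: a feature-by-sample omics matrix with platform semantics
#'
#' Container for one molecular platform. Rows are features (genes, CpG
#' probes, miRNAs, proteins), columns are samples. The \code{kind} tag
#' records the platform and the \code{state} tag whether platform-specific
#' preprocessing (clipping, floors, variance filtering) has been applied.
#' Preprocessing parameters actually used are kept in \code{params} so the
#' validity method can enforce the matching range invariants
#' (e.g. clipped CNV scores, beta values in [0,1], binary mutation calls).
#'
#' @slot values numeric matrix, features x samples, with dimnames.
#' @slot kind one of \code{"CNV"}, \code{"METH"}, \code{"MRNA"},
#'   \code{"MIRNA"}, \code{"MUT"}, \code{"PROT"}.
#' @slot state \code{"raw"} or \code{"preprocessed"}.
#' @slot params list of the preprocessing parameters applied (clip bound,
#'   floors); empty for raw matrices.
#'
#' @aliases PlatformMatrix-class
#' @exportClass PlatformMatrix
setClass("PlatformMatrix",
    representation(values = "matrix", kind = "character",
                   state = "character", params = "list"),
    prototype(values = matrix(numeric(0), 0, 0), kind = "MRNA",
              state = "raw", params = list()))

setValidity("PlatformMatrix", function(object) {
    v <- object@values
    msg <- character(0)
    if (length(object@kind) != 1L || !object@kind %in% .PLATFORM_KINDS)
        msg <- c(msg, sprintf("'kind' must be one of %s",
                              paste(.PLATFORM_KINDS, collapse = ", ")))
    if (length(object@state) != 1L || !object@state %in% .MATRIX_STATES)
        msg <- c(msg, "'state' must be 'raw' or 'preprocessed'")
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be numeric")
    if (nrow(v) > 0L && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
        msg <- c(msg, "feature IDs (rownames) must be present and unique")
    if (ncol(v) > 0L && (is.null(colnames(v)) || anyDuplicated(colnames(v))))
        msg <- c(msg, "sample IDs (colnames) must be present and unique")
    if (length(msg) == 0L && length(object@kind) == 1L) {
        fin <- v[!is.na(v)]
        if (object@kind == "METH" && length(fin) &&
            (min(fin) < 0 || max(fin) > 1))
            msg <- c(msg, "METH beta values must lie in [0, 1]")
        if (object@kind == "METH" && object@state == "preprocessed" &&
            anyNA(v))
            msg <- c(msg, "preprocessed METH matrix must have no missing entries")
        if (object@kind == "MUT" && length(fin) && !all(fin %in% c(0, 1)))
            msg <- c(msg, "MUT values must be 0/1")
        if (object@state == "preprocessed" && length(fin)) {
            if (object@kind == "CNV") {
                clip <- if (!is.null(object@params$clip)) object@params$clip else 2
                if (max(abs(fin)) > clip + 1e-12)
                    msg <- c(msg, sprintf("preprocessed CNV values must lie in [-%g, %g]",
                                          clip, clip))
            }
            if (object@kind == "MRNA") {
                fl <- if (!is.null(object@params$floor)) object@params$floor else -26
                if (min(fin) < fl - 1e-12)
                    msg <- c(msg, sprintf("preprocessed MRNA values must be >= %g", fl))
            }
            if (object@kind == "MIRNA") {
                fl <- if (!is.null(object@params$floor)) object@params$floor else 0
                if (min(fin) < fl - 1e-12)
                    msg <- c(msg, sprintf("preprocessed MIRNA values must be >= %g", fl))
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PlatformMatrix
#'
#' @param values numeric matrix (features x samples) with dimnames.
#' @param kind platform kind, one of \code{"CNV"}, \code{"METH"},
#'   \code{"MRNA"}, \code{"MIRNA"}, \code{"MUT"}, \code{"PROT"}.
#' @param state \code{"raw"} (default) or \code{"preprocessed"}.
#' @param params list of preprocessing parameters applied.
#' @return a \linkS4class{PlatformMatrix}.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' PlatformMatrix(m, "MRNA")
#' @export
PlatformMatrix <- function(values, kind, state = "raw", params = list()) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("PlatformMatrix", values = values, kind = kind, state = state,
        params = params)
}

#' COCMatrix: stacked binary sub-cluster indicators over samples
#'
#' The working object of cluster-of-clusters integration: each row is one
#' feature sub-cluster's binary 2-group split of the samples (0/1), or
#' all-NA where the split produced a group smaller than the minimum group
#' size. Row metadata records the originating platform and sub-cluster
#' index.
#'
#' @slot indicators numeric matrix with entries 0, 1 or NA; rows are
#'   sub-cluster indicators, columns are samples.
#' @slot rowInfo data.frame with columns \code{platform} and
#'   \code{subcluster}, one row per indicator row.
#'
#' @aliases COCMatrix-class
#' @exportClass COCMatrix
setClass("COCMatrix",
    representation(indicators = "matrix", rowInfo = "data.frame"))

setValidity("COCMatrix", function(object) {
    x <- object@indicators
    msg <- character(0)
    vals <- x[!is.na(x)]
    if (length(vals) && !all(vals %in% c(0, 1)))
        msg <- c(msg, "indicator entries must be 0, 1 or NA")
    if (nrow(object@rowInfo) != nrow(x))
        msg <- c(msg, "rowInfo must have one row per indicator row")
    if (!all(c("platform", "subcluster") %in% names(object@rowInfo)))
        msg <- c(msg, "rowInfo needs 'platform' and 'subcluster' columns")
    if (ncol(x) > 0L && (is.null(colnames(x)) || anyDuplicated(colnames(x))))
        msg <- c(msg, "sample IDs (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' ConsensusResult: consensus clustering output for one subgroup count
#'
#' Holds the sample-by-sample co-clustering frequency matrix accumulated
#' over resampled clustering runs, the final subgroup labels, and the
#' CDF-area statistic used for choosing the number of subgroups.
#'
#' @slot k integer subgroup count.
#' @slot consensus symmetric sample x sample matrix of co-clustering
#'   frequencies, unit diagonal, entries in [0,1].
#' @slot labels named integer vector of subgroup assignments (1..k).
#' @slot area area under the empirical CDF of the off-diagonal consensus
#'   entries.
#' @slot entries sorted off-diagonal consensus entries (upper triangle),
#'   from which the empirical CDF can be reconstructed.
#'
#' @aliases ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
    representation(k = "integer", consensus = "matrix", labels = "integer",
                   area = "numeric", entries = "numeric"))

setValidity("ConsensusResult", function(object) {
    cm <- object@consensus
    msg <- character(0)
    if (nrow(cm) != ncol(cm))
        msg <- c(msg, "consensus matrix must be square")
    else {
        if (max(abs(cm - t(cm))) > 1e-8)
            msg <- c(msg, "consensus matrix must be symmetric")
        if (nrow(cm) && max(abs(diag(cm) - 1)) > 1e-12)
            msg <- c(msg, "consensus diagonal must be 1")
        if (nrow(cm) && (min(cm) < -1e-12 || max(cm) > 1 + 1e-12))
            msg <- c(msg, "consensus entries must lie in [0, 1]")
    }
    if (length(object@labels) != nrow(cm))
        msg <- c(msg, "labels must cover every sample")
    if (length(msg)) msg else TRUE
})

#' SyntheticMultiOmics: a simulated multi-platform study with known truth
#'
#' Bundles the four simulated platforms (CNV as raw segment records plus a
#' gene model so the genomic-overlap code path is exercised; methylation,
#' mRNA and miRNA as raw matrices), a binary mutation matrix, a clinical
#' table with survival, and the planted subgroup labels.
#'
#' @slot segments data.frame of copy-number segments (sample, chrom,
#'   start, end, seg_mean).
#' @slot genes \link[GenomicRanges]{GRanges} gene model for CNV averaging.
#' @slot meth,mrna,mirna raw \linkS4class{PlatformMatrix} objects.
#' @slot mutation binary \linkS4class{PlatformMatrix} (\code{kind = "MUT"}).
#' @slot clinical data.frame with survival time, event and categorical
#'   covariates.
#' @slot trueLabels named factor of planted subgroup memberships.
#' @slot config the generator configuration used.
#'
#' @aliases SyntheticMultiOmics-class
#' @exportClass SyntheticMultiOmics
setClass("SyntheticMultiOmics",
    representation(segments = "data.frame", genes = "ANY",
                   meth = "PlatformMatrix", mrna = "PlatformMatrix",
                   mirna = "PlatformMatrix", mutation = "PlatformMatrix",
                   clinical = "data.frame", trueLabels = "factor",
                   config = "list"))

setValidity("SyntheticMultiOmics", function(object) {
    ids <- names(object@trueLabels)
    msg <- character(0)
    if (is.null(ids))
        msg <- c(msg, "trueLabels must be named by sample ID")
    else {
        for (nm in c("meth", "mrna", "mirna", "mutation")) {
            sm <- colnames(slot(object, nm)@values)
            if (!setequal(sm, ids))
                msg <- c(msg, sprintf("platform '%s' does not share the sample universe", nm))
        }
        if (!setequal(object@clinical$sample_id, ids))
            msg <- c(msg, "clinical table does not share the sample universe")
        if (!setequal(unique(object@segments$sample), ids))
            msg <- c(msg, "segment table does not share the sample universe")
    }
    if (length(msg)) msg else TRUE
})
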