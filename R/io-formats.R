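#' Read a copy-number segmentation (SEG) file
#'
#' Parses the tab-delimited level-3 style segment format with header
#' columns \code{Sample}, \code{Chromosome}, \code{Start}, \code{End},
#' \code{Segment_Mean}. Coordinates are taken as 1-based inclusive (the
#' common SEG dialect). Chromosome names are normalised by stripping a
#' leading \code{"chr"} so segment tables and gene models from different
#' sources join. Rows with a non-numeric segment mean are skipped; the
#' skip count is reported via a message and attached as the
#' \code{"skipped"} attribute so no row is dropped silently.
#'
#' @param path path to the SEG file.
#' @return data.frame with columns \code{sample}, \code{chrom},
#'   \code{start}, \code{end}, \code{seg_mean}; attribute
#'   \code{"skipped"} holds the number of rejected rows.
#' @export
readSegFile <- function(path) {
    req <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     colClasses = "character", check.names = FALSE)
    missing <- setdiff(req, names(df))
    if (length(missing))
        stop("SEG file is missing required column(s): ",
             paste(missing, collapse = ", "))
    if (nrow(df) == 0L) {
        warning("SEG file '", path, "' contains no data rows")
        out <- data.frame(sample = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          seg_mean = numeric(0))
        attr(out, "skipped") <- 0L
        return(out)
    }
    seg_mean <- suppressWarnings(as.numeric(df$Segment_Mean))
    bad <- is.na(seg_mean) | !is.finite(seg_mean)
    if (any(bad))
        message(sum(bad), " segment row(s) with non-numeric segment mean skipped")
    out <- data.frame(
        sample = df$Sample[!bad],
        chrom = sub("^chr", "", df$Chromosome[!bad]),
        start = as.integer(df$Start[!bad]),
        end = as.integer(df$End[!bad]),
        seg_mean = seg_mean[!bad],
        stringsAsFactors = FALSE)
    if (any(out$start > out$end))
        stop("SEG file contains segments with start > end")
    attr(out, "skipped") <- sum(bad)
    out
}

#' Read a gene model from a BED file
#'
#' BED coordinates on disk are 0-based half-open; they are converted to
#' the 1-based inclusive convention used internally (via
#' \code{rtracklayer}), matching the SEG dialect so interval overlaps are
#' not shifted by one base. Chromosome names are normalised by stripping
#' a leading \code{"chr"}.
#'
#' @param path path to a BED file whose name column carries gene IDs.
#' @return a \link[GenomicRanges]{GRanges} with gene IDs as names.
#' @export
readGeneBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name) || anyNA(gr$name))
        stop("BED gene model must carry gene IDs in the name column")
    if (anyDuplicated(gr$name))
        stop("duplicate gene IDs in BED gene model: ",
             paste(unique(gr$name[duplicated(gr$name)]), collapse = ", "))
    names(gr) <- gr$name
    GenomeInfoDb::seqlevels(gr) <- sub("^chr", "", GenomeInfoDb::seqlevels(gr))
    gr
}

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature IDs, remaining columns samples; cells are
#' numeric or the literal \code{"NA"} (the level-3 missing marker).
#' Duplicate feature or sample IDs and ragged rows are format errors.
#'
#' @param path path to the TSV file.
#' @param kind platform kind tag for the resulting matrix.
#' @return a raw \linkS4class{PlatformMatrix}.
#' @export
readMatrixTSV <- function(path, kind = "MRNA") {
    nf <- count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) > 1L)
        stop("ragged rows in matrix file '", path, "'")
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE, na.strings = "NA")
    if (ncol(df) < 2L)
        stop("matrix file must have a feature-ID column plus sample columns")
    feat <- as.character(df[[1L]])
    if (anyDuplicated(feat))
        stop("duplicate feature IDs: ",
             paste(unique(feat[duplicated(feat)]), collapse = ", "))
    samp <- colnames(df)[-1L]
    if (anyDuplicated(samp))
        stop("duplicate sample columns: ",
             paste(unique(samp[duplicated(samp)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric cells in matrix file '", path, "'")
    dimnames(m) <- list(feat, samp)
    PlatformMatrix(m, kind = kind, state = "raw")
}

#' Write a PlatformMatrix (or plain matrix) to TSV
#'
#' Missing cells are written as \code{"NA"}; finite values round-trip
#' bit-identically through \code{\link{readMatrixTSV}}.
#'
#' @param x a \linkS4class{PlatformMatrix} or numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn header for the feature-ID column.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(x, path, idColumn = "feature_id") {
    m <- if (is(x, "PlatformMatrix")) assayValues(x) else x
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a clinical table with survival and categorical covariates
#'
#' Expects a TSV with columns \code{sample_id}, \code{time} (days),
#' \code{event} (0 = censored, 1 = death), and optionally \code{gender},
#' \code{alcohol}, \code{afp} (numeric serum level), \code{ajcc_t}
#' (primary tumour stage), \code{child_pugh}, \code{hcv},
#' \code{vascular_invasion}. Numeric AFP is dichotomised at 20 into
#' \code{"Low(<20)"} / \code{"High(>20)"} and the T stage into
#' \code{"1"} / \code{">1"}, the binary groupings used downstream for
#' subgroup association tests.
#'
#' @param path path to the clinical TSV.
#' @return data.frame keyed by unique \code{sample_id}, with derived
#'   columns \code{afp_class} and \code{stage_class} where the source
#'   columns are present.
#' @export
readClinicalTSV <- function(path) {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE, na.strings = c("NA", ""))
    req <- c("sample_id", "time", "event")
    missing <- setdiff(req, names(df))
    if (length(missing))
        stop("clinical table is missing required column(s): ",
             paste(missing, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in clinical table")
    bad <- !is.na(df$time) & df$time <= 0
    if (any(bad))
        stop("non-positive survival time for sample(s): ",
             paste(df$sample_id[bad], collapse = ", "))
    if (!all(df$event[!is.na(df$event)] %in% c(0, 1)))
        stop("'event' must be 0 (censored) or 1 (death)")
    df$afp_class <- classifyAFP(df$afp)
    df$stage_class <- classifyStage(df$ajcc_t)
    df
}

#' Dichotomise serum AFP at 20
#'
#' @param afp numeric alpha-fetoprotein level (ng/ml).
#' @return character vector with levels \code{"Low(<20)"} and
#'   \code{"High(>20)"}; NA preserved. NULL input gives NULL.
#' @export
classifyAFP <- function(afp) {
    if (is.null(afp)) return(NULL)
    ifelse(is.na(afp), NA_character_,
           ifelse(as.numeric(afp) > 20, "High(>20)", "Low(<20)"))
}

#' Dichotomise AJCC primary-tumour stage as 1 vs >1
#'
#' Accepts stage labels such as \code{"1"}, \code{"T1"}, \code{"3"},
#' \code{"T2a"}; anything whose leading stage number exceeds 1 maps to
#' \code{">1"}.
#'
#' @param stage character or numeric stage labels.
#' @return character vector with levels \code{"1"} and \code{">1"}; NA
#'   preserved. NULL input gives NULL.
#' @export
classifyStage <- function(stage) {
    if (is.null(stage)) return(NULL)
    num <- suppressWarnings(as.numeric(sub("^T", "", as.character(stage))))
    num[is.na(num)] <- suppressWarnings(
        as.numeric(gsub("[^0-9].*$", "", sub("^T", "", as.character(stage)))))[is.na(num)]
    ifelse(is.na(num), NA_character_, ifelse(num > 1, ">1", "1"))
}
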