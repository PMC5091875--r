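#' Accessors for SurvCOCA classes
#'
#' \code{assayValues} returns the numeric feature-by-sample matrix;
#' \code{platformKind} and \code{matrixState} the platform tag and
#' preprocessing state; \code{featureIDs} and \code{sampleIDs} the
#' dimension names; \code{indicatorMatrix} and \code{indicatorInfo} the
#' 0/1/NA matrix and its row metadata; \code{consensusMatrix},
#' \code{subgroupLabels} and \code{cdfArea} the components of a
#' \linkS4class{ConsensusResult}; \code{trueLabels} and
#' \code{clinicalTable} the ground truth and clinical data of a
#' \linkS4class{SyntheticMultiOmics}.
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
#' @aliases assayValues platformKind matrixState featureIDs sampleIDs
#'   indicatorMatrix indicatorInfo consensusMatrix subgroupLabels cdfArea
#'   trueLabels clinicalTable
NULL

#' @rdname accessors
#' @export
setGeneric("assayValues", function(x) standardGeneric("assayValues"))
#' @rdname accessors
#' @export
setGeneric("platformKind", function(x) standardGeneric("platformKind"))
#' @rdname accessors
#' @export
setGeneric("matrixState", function(x) standardGeneric("matrixState"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("indicatorMatrix", function(x) standardGeneric("indicatorMatrix"))
#' @rdname accessors
#' @export
setGeneric("indicatorInfo", function(x) standardGeneric("indicatorInfo"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("subgroupLabels", function(x) standardGeneric("subgroupLabels"))
#' @rdname accessors
#' @export
setGeneric("cdfArea", function(x) standardGeneric("cdfArea"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' @rdname accessors
setMethod("assayValues", "PlatformMatrix", function(x) x@values)
#' @rdname accessors
setMethod("platformKind", "PlatformMatrix", function(x) x@kind)
#' @rdname accessors
setMethod("matrixState", "PlatformMatrix", function(x) x@state)
#' @rdname accessors
setMethod("featureIDs", "PlatformMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIDs", "PlatformMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("sampleIDs", "COCMatrix", function(x) colnames(x@indicators))
#' @rdname accessors
setMethod("indicatorMatrix", "COCMatrix", function(x) x@indicators)
#' @rdname accessors
setMethod("indicatorInfo", "COCMatrix", function(x) x@rowInfo)
#' @rdname accessors
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensus)
#' @rdname accessors
setMethod("subgroupLabels", "ConsensusResult", function(x) x@labels)
#' @rdname accessors
setMethod("cdfArea", "ConsensusResult", function(x) x@area)
#' @rdname accessors
setMethod("trueLabels", "SyntheticMultiOmics", function(x) x@trueLabels)
#' @rdname accessors
setMethod("clinicalTable", "SyntheticMultiOmics", function(x) x@clinical)

#' Extract one platform from a synthetic study
#'
#' @param x a \linkS4class{SyntheticMultiOmics}.
#' @param kind one of \code{"METH"}, \code{"MRNA"}, \code{"MIRNA"},
#'   \code{"MUT"}.
#' @return the requested raw \linkS4class{PlatformMatrix}.
#' @export
setGeneric("platformMatrix", function(x, kind) standardGeneric("platformMatrix"))

#' @rdname platformMatrix
setMethod("platformMatrix", "SyntheticMultiOmics", function(x, kind) {
    kind <- match.arg(kind, c("METH", "MRNA", "MIRNA", "MUT"))
    switch(kind, METH = x@meth, MRNA = x@mrna, MIRNA = x@mirna,
           MUT = x@mutation)
})

#' @describeIn accessors dimensions of the underlying matrix
#' @export
setMethod("dim", "PlatformMatrix", function(x) dim(x@values))
#' @rdname accessors
#' @export
setMethod("dim", "COCMatrix", function(x) dim(x@indicators))

setMethod("show", "PlatformMatrix", function(object) {
    cat(sprintf("PlatformMatrix [%s, %s]: %d features x %d samples\n",
                object@kind, object@state, nrow(object@values),
                ncol(object@values)))
    if (length(object@params))
        cat("  params:", paste(names(object@params),
                               unlist(object@params, use.names = FALSE),
                               sep = "=", collapse = ", "), "\n")
})

setMethod("show", "COCMatrix", function(object) {
    ri <- object@rowInfo
    allna <- sum(apply(object@indicators, 1L, function(r) all(is.na(r))))
    cat(sprintf("COCMatrix: %d sub-cluster indicators x %d samples (%d all-NA)\n",
                nrow(object@indicators), ncol(object@indicators), allna))
    tb <- table(ri$platform)
    cat("  rows per platform:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf("ConsensusResult: k = %d over %d samples; CDF area = %.3f\n",
                object@k, nrow(object@consensus), object@area))
    print(table(subgroup = object@labels))
})

setMethod("show", "SyntheticMultiOmics", function(object) {
    cat(sprintf("SyntheticMultiOmics: %d samples, %d planted subgroups\n",
                length(object@trueLabels), nlevels(object@trueLabels)))
    cat(sprintf("  segments: %d; meth %d x %d; mrna %d x %d; mirna %d x %d; mutation %d x %d\n",
                nrow(object@segments),
                nrow(object@meth@values), ncol(object@meth@values),
                nrow(object@mrna@values), ncol(object@mrna@values),
                nrow(object@mirna@values), ncol(object@mirna@values),
                nrow(object@mutation@values), ncol(object@mutation@values)))
})
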