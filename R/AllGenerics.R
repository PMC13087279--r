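#' Accessors for mscorrect classes
#'
#' Small accessor layer so user code never reaches into slots.
#'
#' @param x an object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("readId", function(x) standardGeneric("readId"))
#' @rdname accessors
#' @export
setMethod("readId", "MRead", function(x) x@readId)
#' @rdname accessors
#' @export
setMethod("readId", "ConsensusResult", function(x) x@readId)

#' @rdname accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))
#' @rdname accessors
#' @export
setMethod("hits", "MRead", function(x) x@hits)

#' @rdname accessors
#' @export
setGeneric("sketchDensity", function(x) standardGeneric("sketchDensity"))
#' @rdname accessors
#' @export
setMethod("sketchDensity", "MRead", function(x) x@density)
#' @rdname accessors
#' @export
setMethod("sketchDensity", "MReadSet", function(x) x@density)

#' @rdname accessors
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))
#' @rdname accessors
#' @export
setMethod("readLength", "MRead", function(x) x@readLength)

#' @rdname accessors
#' @export
setGeneric("sketchParams", function(x) standardGeneric("sketchParams"))
#' @rdname accessors
#' @export
setMethod("sketchParams", "MReadSet", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("sketchParams", "MinimizerIndex", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("alignmentOps", function(x) standardGeneric("alignmentOps"))
#' @rdname accessors
#' @export
setMethod("alignmentOps", "MAlignment", function(x) x@ops)

#' @rdname accessors
#' @export
setGeneric("divergence", function(x) standardGeneric("divergence"))
#' @rdname accessors
#' @export
setMethod("divergence", "MAlignment", function(x) x@divergence)

#' @rdname accessors
#' @export
setGeneric("targetSpan", function(x) standardGeneric("targetSpan"))
#' @rdname accessors
#' @export
setMethod("targetSpan", "MAlignment", function(x) x@tSpan)

#' @rdname accessors
#' @export
setGeneric("querySpan", function(x) standardGeneric("querySpan"))
#' @rdname accessors
#' @export
setMethod("querySpan", "MAlignment", function(x) x@qSpan)

#' @rdname accessors
#' @export
setGeneric("overhangs", function(x) standardGeneric("overhangs"))
#' @rdname accessors
#' @export
setMethod("overhangs", "MAlignment", function(x)
    c(left = x@overhangLeft, right = x@overhangRight))

#' Recruitment score of a candidate or alignment
#'
#' Number of minimizer matches minus the number of differences, where the
#' differences are the mismatches, insertions and deletions of the
#' minimizer-space alignment.
#'
#' @param x a [Candidate] or [MAlignment].
#' @return integer score.
#' @export
setGeneric("candidateScore", function(x) standardGeneric("candidateScore"))
#' @rdname candidateScore
#' @export
setMethod("candidateScore", "MAlignment", function(x) {
    nd <- sum(x@ops$op != "match")
    as.integer(x@nMatch - nd)
})
#' @rdname candidateScore
#' @export
setMethod("candidateScore", "Candidate", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("correctedMRead", function(x) standardGeneric("correctedMRead"))
#' @rdname accessors
#' @export
setMethod("correctedMRead", "ConsensusResult", function(x) x@corrected)

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setMethod("graphNodes", "VariationGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setMethod("graphEdges", "VariationGraph", function(x) x@edges)
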