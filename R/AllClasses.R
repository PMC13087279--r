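#' @import methods
NULL

#' Sketching parameters
#'
#' Parameters controlling universal-minimizer selection. A k-mer is selected
#' as a minimizer wherever its canonical-strand hash falls below `d * H`,
#' where `d` is the density and `H` the upper bound of the hash range. Two
#' nested densities share one hash function, so every low-density minimizer
#' is also a high-density minimizer.
#'
#' @slot k minimizer length in bases (default 15).
#' @slot seed integer hash seed folded into the hash function.
#' @slot H hash-range upper bound; `2^53 - 1` so hash values are exact in
#'   doubles.
#' @slot dLow low density fraction (default 0.005), used for recruitment.
#' @slot dHigh high density fraction (default 0.025), used for re-alignment
#'   and correction.
#' @slot repetitiveFraction fraction of distinct minimizers blacklisted as
#'   repetitive (default 1e-4).
#' @slot hpc homopolymer-compress sequences before sketching (default FALSE).
#' @export
setClass("SketchParams", representation(
    k = "integer", seed = "integer", H = "numeric",
    dLow = "numeric", dHigh = "numeric",
    repetitiveFraction = "numeric", hpc = "logical"))

setValidity("SketchParams", function(object) {
    msg <- NULL
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (!(object@dLow > 0 && object@dLow < object@dHigh && object@dHigh <= 1))
        msg <- c(msg, "need 0 < dLow < dHigh <= 1 (nested densities)")
    if (object@repetitiveFraction < 0 || object@repetitiveFraction >= 1)
        msg <- c(msg, "repetitiveFraction must be in [0, 1)")
    if (object@H <= 0) msg <- c(msg, "H must be positive")
    if (is.null(msg)) TRUE else msg
})

#' @param k,seed,dLow,dHigh,repetitiveFraction,hpc see slot documentation.
#' @rdname SketchParams-class
#' @export
SketchParams <- function(k = 15L, seed = 1L, dLow = 0.005, dHigh = 0.025,
                         repetitiveFraction = 1e-4, hpc = FALSE) {
    new("SketchParams", k = as.integer(k), seed = as.integer(seed),
        H = 2^53 - 1, dLow = dLow, dHigh = dHigh,
        repetitiveFraction = repetitiveFraction, hpc = hpc)
}

#' Chaining parameters
#'
#' Scoring constants for banded colinear chaining of anchors. Each chained
#' anchor earns `matchBonus`; extending a chain between anchors costs
#' `min(gapCap, gapScale * |diagonal drift in bases|)`. The dynamic program
#' examines up to `bandH` preceding anchors per step.
#'
#' @slot matchBonus score per chained anchor.
#' @slot gapScale penalty per base of diagonal drift.
#' @slot gapCap maximum per-transition gap penalty.
#' @slot bandH number of predecessor anchors examined.
#' @export
setClass("ChainParams", representation(
    matchBonus = "numeric", gapScale = "numeric",
    gapCap = "numeric", bandH = "integer"))

setValidity("ChainParams", function(object) {
    if (object@matchBonus < 0 || object@gapScale < 0 || object@gapCap < 0)
        return("scoring constants must be non-negative")
    if (object@bandH < 1L) return("bandH must be >= 1")
    TRUE
})

#' @param matchBonus,gapScale,gapCap,bandH see slot documentation.
#' @rdname ChainParams-class
#' @export
ChainParams <- function(matchBonus = 50, gapScale = 0.05, gapCap = 50,
                        bandH = 50L) {
    new("ChainParams", matchBonus = matchBonus, gapScale = gapScale,
        gapCap = gapCap, bandH = as.integer(bandH))
}

#' Alignment filtering parameters
#'
#' Thresholds applied to high-density alignments before pileup: alignments
#' with divergence above `maxDivergence`, target span below `minSpanBases`
#' or an end overhang above `maxOverhangBases` are discarded.
#'
#' @slot maxDivergence maximum estimated divergence (default 0.04).
#' @slot minSpanBases minimum aligned target span in bases (default 1000).
#' @slot maxOverhangBases maximum unaligned flank in bases (default 2000).
#' @export
setClass("FilterParams", representation(
    maxDivergence = "numeric", minSpanBases = "numeric",
    maxOverhangBases = "numeric"))

setValidity("FilterParams", function(object) {
    if (object@maxDivergence <= 0 || object@minSpanBases <= 0 ||
        object@maxOverhangBases <= 0)
        return("all filter thresholds must be positive")
    TRUE
})

#' @param maxDivergence,minSpanBases,maxOverhangBases see slot documentation.
#' @rdname FilterParams-class
#' @export
FilterParams <- function(maxDivergence = 0.04, minSpanBases = 1000,
                         maxOverhangBases = 2000) {
    new("FilterParams", maxDivergence = maxDivergence,
        minSpanBases = minSpanBases, maxOverhangBases = maxOverhangBases)
}

#' Minimizer-space read (mRead)
#'
#' A read represented as the ordered list of its selected universal
#' minimizers. `hits` is a data.frame with one row per minimizer:
#' `offset` (0-based position of the k-mer's leftmost base on the read's
#' forward strand), `orientation` (`"+"` if the forward-strand k-mer is the
#' canonical representative, `"-"` otherwise), `hash` (integer hash value,
#' exact in a double), and `quality` (minimum Phred score over the k
#' constituent bases, or `NA` for FASTA input).
#'
#' @slot readId read identifier.
#' @slot readLength read length in bases.
#' @slot density `"low"` or `"high"`.
#' @slot hits data.frame of minimizer hits, ascending offset.
#' @export
setClass("MRead", representation(
    readId = "character", readLength = "integer",
    density = "character", hits = "data.frame"))

setValidity("MRead", function(object) {
    msg <- NULL
    h <- object@hits
    if (!all(c("offset", "orientation", "hash", "quality") %in% names(h)))
        msg <- c(msg, "hits must have offset, orientation, hash, quality")
    if (!object@density %in% c("low", "high"))
        msg <- c(msg, "density must be 'low' or 'high'")
    if (nrow(h) > 0) {
        if (any(diff(h$offset) <= 0))
            msg <- c(msg, "hit offsets must be strictly increasing")
        if (h$offset[1] < 0)
            msg <- c(msg, "offsets must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MRead", function(object) {
    cat(sprintf("MRead '%s': %d bp, %d minimizers (%s density)\n",
                object@readId, object@readLength, nrow(object@hits),
                object@density))
})

#' A set of mReads sketched with shared parameters
#'
#' @slot mreads named list of [MRead] objects (names are read ids).
#' @slot params the shared [SketchParams].
#' @slot density `"low"` or `"high"`.
#' @export
setClass("MReadSet", representation(
    mreads = "list", params = "SketchParams", density = "character"))

setValidity("MReadSet", function(object) {
    ids <- names(object@mreads)
    if (length(object@mreads) > 0 && (is.null(ids) || anyDuplicated(ids)))
        return("mreads must be uniquely named by read id")
    TRUE
})

setMethod("show", "MReadSet", function(object) {
    cat(sprintf("MReadSet: %d reads (%s density, k=%d)\n",
                length(object@mreads), object@density, object@params@k))
})

setMethod("length", "MReadSet", function(x) length(x@mreads))
setMethod("names", "MReadSet", function(x) names(x@mreads))
setMethod("[[", "MReadSet", function(x, i, ...) x@mreads[[i]])

#' Minimizer abundance table
#'
#' Occurrence counts of distinct minimizer hashes across a read set, used to
#' blacklist extremely abundant (repetitive) minimizers.
#'
#' @slot hash distinct hash values.
#' @slot count occurrence count per hash (>= 1).
#' @slot totalDistinct number of distinct hashes.
#' @export
setClass("AbundanceTable", representation(
    hash = "numeric", count = "integer", totalDistinct = "integer"))

setValidity("AbundanceTable", function(object) {
    msg <- NULL
    if (length(object@hash) != length(object@count))
        msg <- c(msg, "hash and count lengths differ")
    if (object@totalDistinct != length(object@hash))
        msg <- c(msg, "totalDistinct must equal the number of keys")
    if (length(object@count) && any(object@count < 1L))
        msg <- c(msg, "counts must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Inverted minimizer index
#'
#' Maps each non-blacklisted hash to its occurrences across all low-density
#' mReads; supports exact-hash lookup during recruitment.
#'
#' @slot postings data.frame with columns hash, readId, hitIndex (0-based),
#'   orientation; sorted by hash, then readId.
#' @slot params the [SketchParams] the indexed mReads were sketched with.
#' @slot readIds ids of all indexed reads.
#' @slot readLengths named integer vector of read lengths.
#' @export
setClass("MinimizerIndex", representation(
    postings = "data.frame", params = "SketchParams",
    readIds = "character", readLengths = "integer"))

setMethod("show", "MinimizerIndex", function(object) {
    cat(sprintf("MinimizerIndex: %d postings over %d reads\n",
                nrow(object@postings), length(object@readIds)))
})

#' Minimizer-space alignment
#'
#' A chained-and-expanded alignment between two mReads: an ordered list of
#' match / mismatch / insertion / deletion operations over minimizers, plus
#' base-coordinate spans, overhangs and the sketch-estimated divergence
#' `1 - (n/m)^(1/k)` where `n` is the number of matching seeds and `m` the
#' number of query seeds within the aligned span.
#'
#' @slot targetId,queryId read ids.
#' @slot strand `"+"` (same strand) or `"-"` (opposite).
#' @slot ops data.frame with columns op (match/mismatch/insertion/deletion),
#'   qIndex, tIndex (0-based hit indices; NA on the absent side of an indel),
#'   in target-forward order.
#' @slot nMatch number of matching seeds (match ops).
#' @slot mSeeds number of query seeds within the aligned span.
#' @slot k minimizer length used.
#' @slot qSpan,tSpan base interval `[start, end)` of the aligned span on the
#'   query / target forward strand.
#' @slot overhangLeft,overhangRight unaligned flank in bases beyond each
#'   alignment end, `min(query flank, target flank)` per end.
#' @slot divergence estimated per-base divergence in [0, 1].
#' @slot chainScore score of the underlying anchor chain.
#' @slot qLen,tLen read lengths in bases.
#' @export
setClass("MAlignment", representation(
    targetId = "character", queryId = "character", strand = "character",
    ops = "data.frame", nMatch = "integer", mSeeds = "integer",
    k = "integer", qSpan = "numeric", tSpan = "numeric",
    overhangLeft = "numeric", overhangRight = "numeric",
    divergence = "numeric", chainScore = "numeric",
    qLen = "numeric", tLen = "numeric"))

setValidity("MAlignment", function(object) {
    msg <- NULL
    if (object@nMatch > object@mSeeds)
        msg <- c(msg, "nMatch cannot exceed mSeeds")
    if (object@divergence < 0 || object@divergence > 1)
        msg <- c(msg, "divergence must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MAlignment", function(object) {
    cat(sprintf(
        "MAlignment %s vs %s (%s): n=%d m=%d div=%.4f t[%d,%d) score=%.1f\n",
        object@queryId, object@targetId, object@strand, object@nMatch,
        object@mSeeds, object@divergence, object@tSpan[1], object@tSpan[2],
        object@chainScore))
})

#' Recruitment candidate
#'
#' @slot readId candidate read id.
#' @slot score recruitment score: matching seeds minus differences
#'   (mismatches + insertions + deletions).
#' @slot alignment the low-density [MAlignment] to the target.
#' @export
setClass("Candidate", representation(
    readId = "character", score = "integer", alignment = "MAlignment"))

#' Minimizer-space variation graph
#'
#' A DAG seeded with the target mRead's minimizer path. A supporter mismatch
#' creates a node parallel to a target node; an insertion creates a path
#' between two target nodes; a deletion contributes a weight-bearing edge
#' skipping the deleted target node. Edge weights accumulate supporter
#' transitions (counts, or minimizer-quality sums for FASTQ input), so the
#' graph is independent of the order supporters are added in.
#'
#' @slot targetId the target read id.
#' @slot nodes data.frame in topological order: id, type (target, mismatch,
#'   insertion), tPos (anchoring target hit index), hash, offset, orientation,
#'   quality.
#' @slot edges data.frame: from, to (node ids), weight.
#' @slot support per-supporter transition records backing the edges
#'   (from, to, w, readId, strand, oFrom, oTo, alnSpan).
#' @slot targetPath node ids of the target's own path.
#' @export
setClass("VariationGraph", representation(
    targetId = "character", nodes = "data.frame", edges = "data.frame",
    support = "data.frame", targetPath = "character"))

setMethod("show", "VariationGraph", function(object) {
    cat(sprintf("VariationGraph for '%s': %d nodes (%d target), %d edges\n",
                object@targetId, nrow(object@nodes),
                length(object@targetPath), nrow(object@edges)))
})

#' Consensus extraction result
#'
#' @slot readId target read id.
#' @slot corrected the corrected [MRead] (high density).
#' @slot path node ids of the chosen consensus path.
#' @slot supportWeights edge weights along the path.
#' @slot sMax cumulative support score of the chosen endpoint.
#' @slot supportersRecruited,supportersRetained supporter counts before and
#'   after high-density filtering.
#' @slot uncorrected TRUE when no supporter survived and the read is
#'   returned as-is.
#' @slot graph the [VariationGraph] the consensus was extracted from.
#' @export
setClass("ConsensusResult", representation(
    readId = "character", corrected = "MRead", path = "character",
    supportWeights = "numeric", sMax = "numeric",
    supportersRecruited = "integer", supportersRetained = "integer",
    uncorrected = "logical", graph = "VariationGraph"))

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf(
        "ConsensusResult '%s': %d hits, S_max=%.1f, supporters %d/%d%s\n",
        object@readId, nrow(object@corrected@hits), object@sMax,
        object@supportersRetained, object@supportersRecruited,
        if (object@uncorrected) " [uncorrected]" else ""))
})

#' Read error model for the simulator
#'
#' Per-base i.i.d. error process applied to reads drawn from simulated
#' genomes.
#'
#' @slot substitutionRate,insertionRate,deletionRate per-base probabilities.
#' @slot qualityMean mean Phred quality of simulated bases.
#' @slot seed RNG seed for read simulation.
#' @export
setClass("ErrorModel", representation(
    substitutionRate = "numeric", insertionRate = "numeric",
    deletionRate = "numeric", qualityMean = "numeric", seed = "integer"))

setValidity("ErrorModel", function(object) {
    r <- c(object@substitutionRate, object@insertionRate, object@deletionRate)
    if (any(r < 0) || any(r >= 1) || sum(r) >= 1)
        return("error rates must be in [0,1) and sum to < 1")
    TRUE
})

#' @param substitutionRate,insertionRate,deletionRate,qualityMean,seed see
#'   slot documentation.
#' @rdname ErrorModel-class
#' @export
ErrorModel <- function(substitutionRate = 0.01, insertionRate = 0,
                       deletionRate = 0, qualityMean = 20, seed = 1L) {
    new("ErrorModel", substitutionRate = substitutionRate,
        insertionRate = insertionRate, deletionRate = deletionRate,
        qualityMean = qualityMean, seed = as.integer(seed))
}

#' Simulated dataset with ground truth
#'
#' @slot genomes named character vector of genome sequences.
#' @slot reads named character vector of (error-laden) read sequences.
#' @slot qualities named list of integer Phred vectors (empty when reads are
#'   simulated without qualities).
#' @slot readInfo data.frame: readId, genome, start, end (0-based half-open
#'   origin interval), strand.
#' @slot truthMReads named list of ground-truth [MRead]s sketched from the
#'   uncorrupted origin intervals.
#' @slot params the [SketchParams] used for the truth sketches.
#' @slot errorModel the [ErrorModel] applied.
#' @export
setClass("SimulatedDataset", representation(
    genomes = "character", reads = "character", qualities = "list",
    readInfo = "data.frame", truthMReads = "list",
    params = "SketchParams", errorModel = "ErrorModel"))

setMethod("show", "SimulatedDataset", function(object) {
    cat(sprintf("SimulatedDataset: %d genome(s), %d reads\n",
                length(object@genomes), length(object@reads)))
})
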