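#' Colinear anchor chain
#'
#' @slot anchors data.frame of chained anchors (qIndex, tIndex, qOffset,
#'   tOffset), colinear with strictly increasing indices.
#' @slot score chain score under the banded DP recurrence.
#' @export
setClass("Chain", representation(anchors = "data.frame", score = "numeric"))

setMethod("show", "Chain", function(object) {
    cat(sprintf("Chain: %d anchors, score %.1f\n", nrow(object@anchors),
                object@score))
})

#' Find exact minimizer anchors between two mReads
#'
#' Returns every pair of hits with equal, non-blacklisted hashes, in both
#' strand phases. The relative strand of an anchor is `"same"` when the two
#' hits have equal orientation and `"opposite"` otherwise.
#'
#' @param query,target [MRead]s sketched at the same density.
#' @param blacklist numeric vector of hashes to ignore.
#' @return data.frame ordered by (qIndex, tIndex) with columns qIndex,
#'   tIndex (0-based hit indices), qOffset, tOffset, strand, hash.
#' @export
findAnchors <- function(query, target, blacklist = numeric()) {
    if (query@density != target@density)
        stop("query and target sketched at different densities")
    qh <- query@hits; th <- target@hits
    if (nrow(qh) == 0 || nrow(th) == 0)
        return(emptyAnchors())
    qok <- seq_len(nrow(qh)); tok <- seq_len(nrow(th))
    if (length(blacklist)) {
        qok <- qok[!(qh$hash %in% blacklist)]
        tok <- tok[!(th$hash %in% blacklist)]
    }
    if (!anyDuplicated(qh$hash[qok]) && !anyDuplicated(th$hash[tok])) {
        # fast path: at most one occurrence per hash on each side
        m <- match(qh$hash[qok], th$hash[tok])
        sel <- which(!is.na(m))
        if (length(sel) == 0) return(emptyAnchors())
        qi <- qok[sel]; ti <- tok[m[sel]]
        return(data.frame(
            qIndex = qi - 1L, tIndex = ti - 1L,
            qOffset = qh$offset[qi], tOffset = th$offset[ti],
            strand = ifelse(qh$orientation[qi] == th$orientation[ti],
                            "same", "opposite"),
            hash = qh$hash[qi]))
    }
    qdt <- data.table(hash = qh$hash[qok], qIndex = qok - 1L,
                      qOffset = qh$offset[qok], qOrient = qh$orientation[qok])
    tdt <- data.table(hash = th$hash[tok], tIndex = tok - 1L,
                      tOffset = th$offset[tok], tOrient = th$orientation[tok])
    a <- merge(qdt, tdt, by = "hash", allow.cartesian = TRUE)
    if (nrow(a) == 0) return(emptyAnchors())
    a[, strand := ifelse(qOrient == tOrient, "same", "opposite")]
    setorder(a, qIndex, tIndex)
    as.data.frame(a[, .(qIndex, tIndex, qOffset, tOffset, strand, hash)])
}

emptyAnchors <- function() {
    data.frame(qIndex = integer(0), tIndex = integer(0),
               qOffset = integer(0), tOffset = integer(0),
               strand = character(0), hash = numeric(0))
}

#' Chain anchors by banded dynamic programming
#'
#' Finds the maximum-score colinear chain under the recurrence
#' `score(j) = max_i score(i) + matchBonus - min(gapCap, gapScale * drift)`
#' where `drift` is the difference of query and target offset deltas, and
#' `i` ranges over the `bandH` anchors preceding `j` (sorted by qIndex, then
#' tIndex) with strictly increasing indices. Ties are broken toward the
#' smaller predecessor index.
#'
#' @param anchors data.frame of anchors from one (query, target,
#'   strand-phase) group, with columns qIndex, tIndex, qOffset, tOffset
#'   already in a common increasing coordinate frame.
#' @param params a [ChainParams].
#' @return a [Chain]; an empty anchor set yields an empty chain of score 0.
#' @export
chainAnchors <- function(anchors, params = ChainParams()) {
    if (nrow(anchors) == 0)
        return(new("Chain", anchors = anchors, score = 0))
    ord <- order(anchors$qIndex, anchors$tIndex)
    a <- anchors[ord, , drop = FALSE]
    res <- cpp_chain(as.integer(a$qIndex), as.integer(a$tIndex),
                     as.integer(a$qOffset), as.integer(a$tOffset),
                     params@matchBonus, params@gapScale, params@gapCap,
                     params@bandH)
    chosen <- a[res$idx, , drop = FALSE]
    rownames(chosen) <- NULL
    new("Chain", anchors = chosen, score = res$score)
}

#' Estimate sequence divergence from shared seeds
#'
#' Inverts the expected fraction of shared sketch k-mers: with `n` matching
#' seeds out of `m` query seeds in the aligned span and minimizer length
#' `k`, the per-base divergence estimate is `1 - (n/m)^(1/k)`.
#'
#' @param n number of matching seeds, `0 <= n <= m`.
#' @param m number of query seeds within the aligned span, `>= 1`.
#' @param k minimizer length.
#' @return estimated divergence in [0, 1].
#' @export
estimateDivergence <- function(n, m, k) {
    stopifnot(m >= 1, n >= 0, n <= m, k >= 1)
    1 - (n / m)^(1 / k)
}

# Reverse a hit frame for opposite-strand chaining: indices and offsets are
# remapped so both lists increase along the target's forward strand.
reverseHitFrame <- function(mread, k) {
    h <- mread@hits
    n <- nrow(h)
    data.frame(index = rev(seq_len(n) - 1L),
               offset = mread@readLength - (rev(h$offset) + k),
               hash = rev(h$hash))
}

#' Expand a chain into a minimizer-space alignment
#'
#' Between consecutive anchors, the unmatched query and target hits are
#' paired positionally: `min(u, v)` pairs become mismatches (or matches when
#' their hashes agree, which happens when the banded chain skipped a true
#' anchor), a query surplus becomes insertions and a target surplus
#' deletions. Populates seed counts, base spans, overhangs and the
#' divergence estimate.
#'
#' @param chain a non-empty [Chain] for one strand phase, in the common
#'   increasing frame (for `strand = "-"` the query frame is reversed).
#' @param query,target the [MRead]s the chain was computed from.
#' @param strand `"+"` or `"-"` relative strand.
#' @param k minimizer length in bases.
#' @return an [MAlignment] with coordinates on each read's forward strand.
#' @export
expandAlignment <- function(chain, query, target, strand = "+", k = 15L) {
    stopifnot(nrow(chain@anchors) > 0)
    a <- chain@anchors
    nQ <- nrow(query@hits)
    qHashFrame <- if (strand == "-") rev(query@hits$hash) else query@hits$hash
    ops <- cpp_expand(as.integer(a$qIndex), as.integer(a$tIndex),
                      qHashFrame, target@hits$hash)
    opName <- c("match", "mismatch", "insertion", "deletion")[ops$op + 1L]
    qIdxFrame <- ops$qIndex
    qIdxOrig <- ifelse(qIdxFrame < 0L, NA_integer_,
                       if (strand == "-") nQ - 1L - qIdxFrame else qIdxFrame)
    tIdx <- ifelse(ops$tIndex < 0L, NA_integer_, ops$tIndex)
    opsDf <- data.frame(op = opName, qIndex = as.integer(qIdxOrig),
                        tIndex = as.integer(tIdx))

    nMatch <- sum(opName == "match")
    mSeeds <- a$qIndex[nrow(a)] - a$qIndex[1] + 1L

    # spans on each read's forward strand
    qOrigIdx <- if (strand == "-") nQ - 1L - a$qIndex else a$qIndex
    qOffs <- query@hits$offset[range(qOrigIdx) + 1L]
    qSpan <- c(qOffs[1], qOffs[2] + k)
    tOffFirst <- target@hits$offset[a$tIndex[1] + 1L]
    tOffLast <- target@hits$offset[a$tIndex[nrow(a)] + 1L]
    tSpan <- c(tOffFirst, tOffLast + k)

    # overhangs per end (in the target's orientation), min of the two flanks
    qOffFrame <- a$qOffset  # already in the common frame
    ohL <- min(qOffFrame[1], tOffFirst)
    ohR <- min(query@readLength - (qOffFrame[length(qOffFrame)] + k),
               target@readLength - (tOffLast + k))

    new("MAlignment", targetId = target@readId, queryId = query@readId,
        strand = strand, ops = opsDf, nMatch = as.integer(nMatch),
        mSeeds = as.integer(mSeeds), k = as.integer(k),
        qSpan = as.numeric(qSpan), tSpan = as.numeric(tSpan),
        overhangLeft = as.numeric(ohL), overhangRight = as.numeric(ohR),
        divergence = estimateDivergence(nMatch, mSeeds, k),
        chainScore = chain@score,
        qLen = as.numeric(query@readLength),
        tLen = as.numeric(target@readLength))
}

#' Align two mReads in minimizer space
#'
#' Full seed-and-chaining alignment of a query mRead against a target:
#' anchors are found in both strand phases, each phase is chained by the
#' banded DP, the best-scoring phase is kept and expanded into a
#' minimizer-space alignment. Coordinates are reported on each read's
#' forward strand.
#'
#' @param query,target [MRead]s at the same density.
#' @param blacklist numeric vector of hashes to ignore.
#' @param chainParams a [ChainParams].
#' @param k minimizer length in bases.
#' @return an [MAlignment], or `NULL` when the reads share no usable anchor.
#' @export
alignMReads <- function(query, target, blacklist = numeric(),
                        chainParams = ChainParams(), k = 15L) {
    anchors <- findAnchors(query, target, blacklist)
    if (nrow(anchors) == 0) return(NULL)
    nQ <- nrow(query@hits)
    best <- NULL; bestStrand <- NULL
    for (ph in c("same", "opposite")) {
        a <- anchors[anchors$strand == ph, , drop = FALSE]
        if (nrow(a) == 0) next
        if (ph == "opposite") {
            a <- data.frame(qIndex = nQ - 1L - a$qIndex,
                            tIndex = a$tIndex,
                            qOffset = query@readLength - (a$qOffset + k),
                            tOffset = a$tOffset)
        }
        ch <- chainAnchors(a, chainParams)
        if (is.null(best) || ch@score > best@score) {
            best <- ch
            bestStrand <- if (ph == "same") "+" else "-"
        }
    }
    if (is.null(best) || nrow(best@anchors) == 0) return(NULL)
    expandAlignment(best, query, target, strand = bestStrand, k = k)
}
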