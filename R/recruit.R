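#' Build an inverted minimizer index over low-density mReads
#'
#' Indexes every non-blacklisted hit of every low-density mRead so that
#' recruitment can locate, for a target read, all reads sharing minimizers
#' with it by exact-hash lookup.
#'
#' @param mreads an [MReadSet] at low density.
#' @param blacklist numeric vector of repetitive hashes to exclude.
#' @return a [MinimizerIndex].
#' @export
buildMinimizerIndex <- function(mreads, blacklist = numeric()) {
    stopifnot(is(mreads, "MReadSet"))
    if (mreads@density != "low")
        warning("index is normally built from the low-density sketch")
    ids <- names(mreads@mreads)
    if (anyDuplicated(ids)) stop("duplicate read ids in index input")
    parts <- lapply(mreads@mreads, function(m) {
        h <- m@hits
        if (nrow(h) == 0) return(NULL)
        data.table(hash = h$hash, readId = m@readId,
                   hitIndex = seq_len(nrow(h)) - 1L,
                   orientation = h$orientation)
    })
    post <- rbindlist(Filter(Negate(is.null), parts))
    if (is.null(post) || nrow(post) == 0) {
        post <- data.table(hash = numeric(0), readId = character(0),
                           hitIndex = integer(0), orientation = character(0))
    } else {
        if (length(blacklist)) post <- post[!hash %in% blacklist]
        setorder(post, hash, readId, hitIndex)
    }
    lens <- vapply(mreads@mreads, function(m) m@readLength, integer(1))
    new("MinimizerIndex", postings = as.data.frame(post),
        params = mreads@params, readIds = ids, readLengths = lens)
}

#' Recruit the most similar reads for a target
#'
#' All-vs-one low-density mapping: reads sharing at least
#' `minSharedMinimizers` non-blacklisted minimizers with the target are
#' chained and expanded; candidates are ranked by descending recruitment
#' score (minimizer matches minus differences; ties by ascending read id)
#' and accepted greedily while the cumulative aligned-target-span coverage
#' stays within `coverageCap` times the target length; the first candidate
#' that would exceed the cap stops recruitment, so accepted coverage never
#' exceeds the cap. The target never recruits itself.
#'
#' @param target a low-density [MRead] (already blacklisted).
#' @param index a [MinimizerIndex] over the read set.
#' @param mreads the low-density [MReadSet] backing the index.
#' @param chainParams a [ChainParams].
#' @param coverageCap coverage multiple of the target length (default 20).
#' @param minSharedMinimizers shortlist threshold on shared distinct
#'   minimizers (default 2).
#' @return list of [Candidate]s in acceptance order (possibly empty).
#' @export
recruitReads <- function(target, index, mreads,
                         chainParams = ChainParams(), coverageCap = 20,
                         minSharedMinimizers = 2L) {
    k <- index@params@k
    th <- target@hits
    if (nrow(th) == 0) return(list())
    post <- as.data.table(index@postings)
    m <- post[hash %in% th$hash & readId != target@readId]
    if (nrow(m) == 0) return(list())
    shared <- m[, .(nShared = length(unique(hash))), by = readId]
    cand <- shared[nShared >= minSharedMinimizers, readId]
    if (length(cand) == 0) return(list())

    alns <- list()
    for (id in sort(cand)) {
        aln <- alignMReads(mreads[[id]], target, chainParams = chainParams,
                           k = k)
        if (is.null(aln)) next
        alns[[id]] <- new("Candidate", readId = id,
                          score = candidateScore(aln), alignment = aln)
    }
    if (length(alns) == 0) return(list())
    scores <- vapply(alns, function(x) x@score, integer(1))
    ord <- order(-scores, names(alns))
    alns <- alns[ord]

    capBases <- coverageCap * target@readLength
    accepted <- list(); cum <- 0
    for (cd in alns) {
        span <- cd@alignment@tSpan[2] - cd@alignment@tSpan[1]
        if (cum + span > capBases) break
        accepted[[cd@readId]] <- cd
        cum <- cum + span
    }
    unname(accepted)
}

#' Recruitment table for a candidate list
#'
#' @param target the target [MRead].
#' @param candidates list of [Candidate]s from [recruitReads].
#' @return data.frame: targetId, candidateId, strand, score, nMatch,
#'   differences, tStart, tEnd.
#' @export
recruitmentTable <- function(target, candidates) {
    if (length(candidates) == 0)
        return(data.frame(targetId = character(0), candidateId = character(0),
                          strand = character(0), score = integer(0),
                          nMatch = integer(0), differences = integer(0),
                          tStart = numeric(0), tEnd = numeric(0)))
    do.call(rbind, lapply(candidates, function(cd) {
        a <- cd@alignment
        data.frame(targetId = a@targetId, candidateId = cd@readId,
                   strand = a@strand, score = cd@score, nMatch = a@nMatch,
                   differences = a@nMatch - cd@score,
                   tStart = a@tSpan[1], tEnd = a@tSpan[2])
    }))
}
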