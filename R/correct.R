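#' Filter high-density alignments before pileup
#'
#' Keeps alignments satisfying every threshold: divergence at most
#' `maxDivergence` (discarding reads likely from other species while
#' tolerating sequencing error), aligned target span at least
#' `minSpanBases`, and both end overhangs at most `maxOverhangBases`
#' (so reads are recruited correctly across genomic repeats).
#'
#' @param alignments list of [MAlignment]s re-aligned at high density.
#' @param filterParams a [FilterParams].
#' @return the retained subset, in input order.
#' @export
filterRecruited <- function(alignments, filterParams = FilterParams()) {
    keep <- vapply(alignments, function(a) {
        span <- a@tSpan[2] - a@tSpan[1]
        a@divergence <= filterParams@maxDivergence &&
            span >= filterParams@minSpanBases &&
            max(a@overhangLeft, a@overhangRight) <= filterParams@maxOverhangBases
    }, logical(1))
    alignments[keep]
}

fmtHash <- function(h) sprintf("%.0f", h)

# Path of one supporter through the variation graph, as a data.frame of
# visited nodes in target-forward order. Insertion nodes are keyed by their
# flanking target indices and position within the inserted run, so identical
# insertions from different supporters merge onto the same nodes.
# Fully vectorized: called once per (target, supporter) pair.
supporterPath <- function(aln, query, target, k) {
    ops <- aln@ops
    qh <- query@hits
    th <- target@hits
    qLen <- query@readLength
    keep <- ops$op != "deletion"           # deletions emit no node
    op <- ops$op[keep]
    qi <- ops$qIndex[keep]
    ti <- ops$tIndex[keep]
    n <- length(op)
    if (n == 0) return(NULL)
    isIns <- op == "insertion"
    # flanking target indices for insertion runs: last/next emitted t
    tiFilled <- ti
    anchorPos <- which(!isIns)
    if (any(isIns)) {
        insPos <- which(isIns)
        prevIdx <- findInterval(insPos, anchorPos)           # 0 if none before
        nextIdx <- prevIdx + 1L
        tLeftIns <- ifelse(prevIdx == 0L, -1L, ti[anchorPos[prevIdx]])
        tRightIns <- ifelse(nextIdx > length(anchorPos), -1L,
                            ti[anchorPos[nextIdx]])
        # position within each consecutive insertion run
        runId <- cumsum(!isIns)[insPos]
        j <- stats::ave(seq_along(insPos), runId, FUN = seq_along)
    }
    type <- ifelse(isIns, "insertion", ifelse(op == "match", "target",
                                              "mismatch"))
    hash <- numeric(n); offset <- rep(NA_integer_, n)
    orient <- character(n)
    isTgt <- type == "target"
    hash[isTgt] <- th$hash[ti[isTgt] + 1L]
    offset[isTgt] <- th$offset[ti[isTgt] + 1L]
    orient[isTgt] <- th$orientation[ti[isTgt] + 1L]
    isVar <- !isTgt
    if (any(isVar)) {
        hash[isVar] <- qh$hash[qi[isVar] + 1L]
        qor <- qh$orientation[qi[isVar] + 1L]
        if (aln@strand == "-") qor <- ifelse(qor == "+", "-", "+")
        orient[isVar] <- qor
        isMis <- type == "mismatch"
        offset[isMis] <- th$offset[ti[isMis] + 1L]
    }
    nodeId <- character(n)
    nodeId[isTgt] <- paste0("T", ti[isTgt])
    isMis <- type == "mismatch"
    nodeId[isMis] <- paste0("M", ti[isMis], ":", fmtHash(hash[isMis]))
    tPos <- ti; tRight <- rep(NA_integer_, n); jcol <- integer(n)
    if (any(isIns)) {
        nodeId[isIns] <- paste0("I", tLeftIns, ":", tRightIns, ":", j, ":",
                                fmtHash(hash[isIns]))
        tPos[isIns] <- tLeftIns
        tRight[isIns] <- tRightIns
        jcol[isIns] <- j
    }
    quality <- qh$quality[qi + 1L]
    off <- qh$offset[qi + 1L]
    oAligned <- if (aln@strand == "-") qLen - (off + k) else off
    data.frame(nodeId = nodeId, type = type, tPos = tPos, tRight = tRight,
               j = jcol, hash = hash, offset = offset,
               orientation = orient, quality = quality, qIndex = qi,
               oAligned = oAligned)
}

# The target read's own path, contributing weight as one supporter.
targetPathDf <- function(target) {
    th <- target@hits
    n <- nrow(th)
    if (n == 0) return(NULL)
    data.frame(nodeId = paste0("T", seq_len(n) - 1L), type = "target",
               tPos = seq_len(n) - 1L, tRight = NA_integer_, j = 0L,
               hash = th$hash, offset = th$offset,
               orientation = th$orientation, quality = th$quality,
               qIndex = seq_len(n) - 1L, oAligned = th$offset)
}

pathToSupport <- function(df, readId, strand, alnSpan, useQuality) {
    n <- nrow(df)
    if (is.null(df) || n < 2) return(NULL)
    qs <- df$quality[-n]; qd <- df$quality[-1]
    w <- if (useQuality)
        as.numeric(ifelse(is.na(qs) | is.na(qd), 1, qs + qd))
    else rep(1, n - 1L)
    data.frame(from = df$nodeId[-n], to = df$nodeId[-1], w = w,
               readId = readId, strand = strand,
               oFrom = df$oAligned[-n], oTo = df$oAligned[-1],
               alnSpan = alnSpan)
}

#' Pile up supporters into a minimizer-space variation graph
#'
#' Initiates the graph with the target mRead's minimizer path, then threads
#' each filtered alignment through it: a supporter mismatch creates (or
#' merges into) a node parallel to the corresponding target node, an
#' insertion a path between two target nodes, and a deletion a
#' weight-bearing edge skipping the deleted node. Each supporter transition
#' increments its edge's weight by 1, or — with `useQuality` — by the sum of
#' the qualities of the source and destination minimizers. The target's own
#' path contributes as one supporter. Nodes, edges and weights are
#' independent of the order supporters are added in.
#'
#' @param target the high-density [MRead] being corrected.
#' @param alignments list of filtered high-density [MAlignment]s against
#'   `target`.
#' @param queries the high-density [MReadSet] holding the supporters.
#' @param useQuality weight edges by minimizer qualities (FASTQ input).
#' @return a [VariationGraph] with nodes in topological order.
#' @export
buildVariationGraph <- function(target, alignments, queries,
                                useQuality = FALSE) {
    k <- if (is(queries, "MReadSet")) queries@params@k else 15L
    paths <- list()
    supports <- list()
    tp <- targetPathDf(target)
    if (!is.null(tp)) {
        paths[[length(paths) + 1L]] <- cbind(tp, readId = target@readId)
        supports[[length(supports) + 1L]] <-
            pathToSupport(tp, target@readId, "+",
                          target@readLength, useQuality)
    }
    for (aln in alignments) {
        if (aln@targetId != target@readId)
            stop(sprintf("alignment targets '%s', not '%s'", aln@targetId,
                         target@readId))
        q <- queries[[aln@queryId]]
        df <- supporterPath(aln, q, target, k)
        if (is.null(df) || nrow(df) == 0) next
        paths[[length(paths) + 1L]] <- cbind(df, readId = aln@queryId)
        supports[[length(supports) + 1L]] <-
            pathToSupport(df, aln@queryId, aln@strand,
                          aln@tSpan[2] - aln@tSpan[1], useQuality)
    }
    if (length(paths) == 0) {
        empty <- data.frame()
        return(new("VariationGraph", targetId = target@readId,
                   nodes = data.frame(nodeId = character(0)),
                   edges = data.frame(from = character(0),
                                      to = character(0), weight = numeric(0)),
                   support = empty, targetPath = character(0)))
    }
    allNodes <- as.data.table(rbindlist(paths))
    # one attribute row per node, chosen deterministically (first observer
    # by read id) so the graph is permutation-invariant
    setorder(allNodes, nodeId, readId)
    nodes <- allNodes[!duplicated(nodeId)]
    # topological order: target position, then variant rank, then insertion
    # key; structural acyclicity follows from node identity by position
    typeRank <- c(target = 0L, mismatch = 1L, insertion = 2L)
    nodes[, rank := typeRank[type]]
    nodes[, tR := ifelse(is.na(tRight), -1L, tRight)]
    setorder(nodes, tPos, rank, tR, j, hash)
    nodesDf <- as.data.frame(nodes[, .(nodeId, type, tPos, tRight, j, hash,
                                       offset, orientation, quality)])
    supDt <- as.data.table(rbindlist(Filter(Negate(is.null), supports)))
    edges <- supDt[, .(weight = sum(w)), by = .(from, to)]
    topo <- seq_len(nrow(nodesDf)); names(topo) <- nodesDf$nodeId
    edges[, `:=`(fi = topo[from], ti = topo[to])]
    setorder(edges, fi, ti)
    edgesDf <- as.data.frame(edges[, .(from, to, weight)])
    setorder(supDt, from, to, readId)
    new("VariationGraph", targetId = target@readId, nodes = nodesDf,
        edges = edgesDf, support = as.data.frame(supDt),
        targetPath = if (is.null(tp)) character(0) else tp$nodeId)
}

#' Extract the most supported path as the consensus
#'
#' Dynamic program over the variation graph in topological order: support
#' scores start at zero, each node's parent is the incoming edge maximizing
#' the cumulative support `S[u] + w_e` (ties broken toward the earliest
#' topological index), and the consensus is obtained by backtracking from
#' the node with the highest score until a parentless node is reached. The
#' resulting path is returned as a corrected high-density [MRead];
#' insertion-node offsets are interpolated between their flanking target
#' offsets so offsets stay strictly increasing.
#'
#' @param graph a [VariationGraph].
#' @param k minimizer length in bases (sets the corrected read length).
#' @return a [ConsensusResult] (supporter counts left at zero; filled by
#'   [correctRead]).
#' @export
extractConsensus <- function(graph, k = 15L) {
    nodes <- graph@nodes
    n <- nrow(nodes)
    if (n == 0) stop("cannot extract a consensus from an empty graph")
    topo <- seq_len(n); names(topo) <- nodes$nodeId
    e <- graph@edges
    fi <- topo[e$from]; ti <- topo[e$to]
    if (any(fi >= ti)) stop("variation graph is not acyclic")
    S <- numeric(n); parent <- rep(NA_integer_, n)
    inc <- split(seq_len(nrow(e)), ti)
    for (v in seq_len(n)) {
        rows <- inc[[as.character(v)]]
        if (is.null(rows)) next
        cand <- S[fi[rows]] + e$weight[rows]
        best <- max(cand)
        hit <- rows[cand == best]
        parent[v] <- min(fi[hit])  # earliest topological index wins ties
        S[v] <- best
    }
    vmax <- which.max(S)  # first maximum = earliest topological index
    path <- integer(0); v <- vmax
    while (!is.na(v)) { path <- c(v, path); v <- parent[v] }
    pn <- nodes[path, , drop = FALSE]

    off <- pn$offset
    for (i in seq_along(off)) {
        if (is.na(off[i])) off[i] <- if (i > 1) off[i - 1] + 1L else 0L
        else if (i > 1 && off[i] <= off[i - 1]) off[i] <- off[i - 1] + 1L
    }
    hitsDf <- data.frame(offset = as.integer(off),
                         orientation = pn$orientation, hash = pn$hash,
                         quality = as.integer(pn$quality))
    lenGuess <- max(as.integer(off[length(off)]) + k, 0L)
    corrected <- new("MRead", readId = graph@targetId,
                     readLength = as.integer(lenGuess), density = "high",
                     hits = hitsDf)
    wts <- if (length(path) > 1) {
        key <- paste(nodes$nodeId[path[-length(path)]],
                     nodes$nodeId[path[-1]])
        ew <- e$weight; names(ew) <- paste(e$from, e$to)
        unname(ew[key])
    } else numeric(0)
    new("ConsensusResult", readId = graph@targetId, corrected = corrected,
        path = nodes$nodeId[path], supportWeights = wts, sMax = S[vmax],
        supportersRecruited = 0L, supportersRetained = 0L,
        uncorrected = FALSE, graph = graph)
}

#' Prepare the shared state for read correction
#'
#' Sketches the read set at both densities, builds the repetitive-minimizer
#' blacklist from the high-density abundance table (the low-density sketch
#' is nested inside it), applies it at both densities, and indexes the
#' low-density mReads.
#'
#' @param sequences named character vector (or `DNAStringSet`) of reads.
#' @param qualities optional named list of integer Phred vectors.
#' @param params a [SketchParams].
#' @return list with components `low`, `high` ([MReadSet]s, blacklisted),
#'   `index` ([MinimizerIndex]), `blacklist`, `params`, `sequences`,
#'   `qualities`, `useQuality`.
#' @export
prepareCorrection <- function(sequences, qualities = NULL,
                              params = SketchParams()) {
    ids <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- ids
    low <- sketchReads(sequences, params, "low", qualities)
    high <- sketchReads(sequences, params, "high", qualities)
    ab <- minimizerAbundance(high)
    bl <- repetitiveBlacklist(ab, params@repetitiveFraction)
    low <- applyBlacklist(low, bl)
    high <- applyBlacklist(high, bl)
    idx <- buildMinimizerIndex(low, blacklist = numeric())
    list(low = low, high = high, index = idx, blacklist = bl,
         params = params, sequences = sequences, qualities = qualities,
         useQuality = !is.null(qualities))
}

#' Correct one read in minimizer space
#'
#' Orchestrates the full per-read pipeline: low-density recruitment of the
#' most similar reads, high-density re-alignment and filtering, variation
#' graph pileup, and consensus extraction. A target with no surviving
#' supporter is returned uncorrected (its own mRead) and flagged.
#'
#' @param targetId id of the read to correct.
#' @param state shared state from [prepareCorrection].
#' @param chainParams a [ChainParams].
#' @param filterParams a [FilterParams].
#' @param coverageCap recruitment coverage cap (default 20).
#' @return a [ConsensusResult].
#' @export
correctRead <- function(targetId, state, chainParams = ChainParams(),
                        filterParams = FilterParams(), coverageCap = 20) {
    if (!targetId %in% names(state$high@mreads))
        stop(sprintf("unknown read id '%s'", targetId))
    tLow <- state$low[[targetId]]
    tHigh <- state$high[[targetId]]
    k <- state$params@k
    cands <- recruitReads(tLow, state$index, state$low,
                          chainParams = chainParams,
                          coverageCap = coverageCap)
    alns <- list()
    for (cd in cands) {
        a <- alignMReads(state$high[[cd@readId]], tHigh,
                         chainParams = chainParams, k = k)
        if (!is.null(a)) alns[[length(alns) + 1L]] <- a
    }
    kept <- filterRecruited(alns, filterParams)
    if (length(kept) == 0 || nrow(tHigh@hits) == 0) {
        g <- buildVariationGraph(tHigh, list(), state$high,
                                 useQuality = state$useQuality)
        res <- new("ConsensusResult", readId = targetId, corrected = tHigh,
                   path = g@targetPath, supportWeights = numeric(0),
                   sMax = 0, supportersRecruited = length(cands),
                   supportersRetained = 0L, uncorrected = TRUE, graph = g)
        return(res)
    }
    g <- buildVariationGraph(tHigh, kept, state$high,
                             useQuality = state$useQuality)
    res <- extractConsensus(g, k = k)
    res@supportersRecruited <- length(cands)
    res@supportersRetained <- length(kept)
    res
}

#' Correct every read of a set
#'
#' Runs [correctRead] independently for each read. Output order equals
#' input order. Per-read correction is independent and fully deterministic,
#' so results are identical for any `threads` value (execution is serial).
#'
#' @param sequences named character vector (or `DNAStringSet`) of reads.
#' @param qualities optional named list of integer Phred vectors; when
#'   present, graph edges are quality-weighted.
#' @param params a [SketchParams].
#' @param chainParams a [ChainParams].
#' @param filterParams a [FilterParams].
#' @param coverageCap recruitment coverage cap (default 20).
#' @param threads accepted for interface compatibility; must be >= 1.
#' @return list with `results` (named list of [ConsensusResult]s, input
#'   order), `report` (data.frame: readId, supportersRecruited,
#'   supportersRetained, sMax, correctedFlag) and `state` (the
#'   [prepareCorrection] state, for base-space reconstruction).
#' @export
correctReads <- function(sequences, qualities = NULL,
                         params = SketchParams(),
                         chainParams = ChainParams(),
                         filterParams = FilterParams(),
                         coverageCap = 20, threads = 1L) {
    stopifnot(threads >= 1L)
    state <- prepareCorrection(sequences, qualities, params)
    ids <- names(state$high@mreads)
    results <- vector("list", length(ids)); names(results) <- ids
    for (id in ids)
        results[[id]] <- correctRead(id, state, chainParams, filterParams,
                                     coverageCap)
    report <- data.frame(
        readId = ids,
        supportersRecruited = vapply(results, function(r)
            r@supportersRecruited, integer(1)),
        supportersRetained = vapply(results, function(r)
            r@supportersRetained, integer(1)),
        sMax = vapply(results, function(r) r@sMax, numeric(1)),
        correctedFlag = vapply(results, function(r) !r@uncorrected,
                               logical(1)),
        row.names = NULL)
    list(results = results, report = report, state = state)
}
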