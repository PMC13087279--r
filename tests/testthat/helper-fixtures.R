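# Shared fixtures and independent oracles for the test suite.

randomSeq <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Construct an MRead directly from hit vectors (synthetic cases).
makeMRead <- function(id, offsets, hashes, len = max(offsets) + 15L,
                      orientation = rep("+", length(offsets)),
                      quality = rep(NA_integer_, length(offsets)),
                      density = "high") {
    new("MRead", readId = id, readLength = as.integer(len),
        density = density,
        hits = data.frame(offset = as.integer(offsets),
                          orientation = orientation,
                          hash = as.numeric(hashes),
                          quality = as.integer(quality)))
}

# Construct a synthetic MAlignment with prescribed divergence, span and
# overhangs (ops left empty; used to exercise the filter in isolation).
makeAlignment <- function(targetId = "t", queryId = "q", divergence = 0,
                          tStart = 0, tEnd = 5000, overhangLeft = 0,
                          overhangRight = 0, tLen = 10000, qLen = 10000) {
    new("MAlignment", targetId = targetId, queryId = queryId, strand = "+",
        ops = data.frame(op = character(0), qIndex = integer(0),
                         tIndex = integer(0)),
        nMatch = 0L, mSeeds = 1L, k = 15L,
        qSpan = c(0, tEnd - tStart), tSpan = c(tStart, tEnd),
        overhangLeft = overhangLeft, overhangRight = overhangRight,
        divergence = divergence, chainScore = 0,
        qLen = qLen, tLen = tLen)
}

# Exhaustive chaining oracle: enumerates every colinear subset of anchors
# (each visited once, in its unique sorted order) and scores it with the
# same additive model as the DP. Independent of the banded implementation.
bruteChainScore <- function(anchors, params) {
    n <- nrow(anchors)
    if (n == 0) return(0)
    qi <- anchors$qIndex; ti <- anchors$tIndex
    qo <- anchors$qOffset; to <- anchors$tOffset
    best <- 0
    rec <- function(last, score) {
        if (score > best) best <<- score
        for (j in seq_len(n)) {
            if (last == 0L ||
                (qi[j] > qi[last] && ti[j] > ti[last])) {
                gap <- if (last == 0L) 0 else
                    min(params@gapCap,
                        params@gapScale * abs((qo[j] - qo[last]) -
                                              (to[j] - to[last])))
                rec(j, score + params@matchBonus - gap)
            }
        }
    }
    rec(0L, 0)
    best
}

randomAnchorSet <- function(n, seed) {
    set.seed(seed)
    repeat {
        qi <- sample.int(n + 4L, n, replace = TRUE) - 1L
        ti <- sample.int(n + 4L, n, replace = TRUE) - 1L
        if (!anyDuplicated(cbind(qi, ti))) break
    }
    ord <- order(qi, ti)
    data.frame(qIndex = qi[ord], tIndex = ti[ord],
               qOffset = qi[ord] * 40L + sample.int(30L, n, replace = TRUE),
               tOffset = ti[ord] * 40L + sample.int(30L, n, replace = TRUE))
}

# Exhaustive path oracle for DAGs: maximum cumulative edge weight over all
# paths (any start, any end), by depth-first enumeration.
brutePathMax <- function(nodeIds, edges) {
    out <- split(seq_len(nrow(edges)), factor(edges$from, levels = nodeIds))
    best <- 0
    rec <- function(v, score) {
        if (score > best) best <<- score
        for (r in out[[v]]) rec(edges$to[r], score + edges$weight[r])
    }
    for (v in nodeIds) rec(v, 0)
    best
}

# Random DAG in the VariationGraph container: nodes in topological order,
# edges only forward, random positive weights.
randomDAG <- function(nNodes, seed) {
    set.seed(seed)
    ids <- sprintf("T%d", seq_len(nNodes) - 1L)
    nodes <- data.frame(nodeId = ids, type = "target",
                        tPos = seq_len(nNodes) - 1L, tRight = NA_integer_,
                        j = 0L, hash = as.numeric(seq_len(nNodes)),
                        offset = (seq_len(nNodes) - 1L) * 40L,
                        orientation = "+", quality = NA_integer_)
    from <- integer(0); to <- integer(0)
    for (i in seq_len(nNodes - 1L)) {
        for (jj in (i + 1L):nNodes) {
            if (runif(1) < 0.35) { from <- c(from, i); to <- c(to, jj) }
        }
    }
    if (length(from) == 0) { from <- 1L; to <- 2L }
    edges <- data.frame(from = ids[from], to = ids[to],
                        weight = sample.int(9L, length(from), replace = TRUE))
    new("VariationGraph", targetId = "dag", nodes = nodes, edges = edges,
        support = data.frame(), targetPath = ids)
}

# Small clean read set: error-free reads tiling a random genome.
cleanReadSet <- function(genomeLen = 20000, readLen = 4000, step = 1000,
                         seed = 5) {
    g <- randomSeq(genomeLen, seed)
    starts <- seq(0, genomeLen - readLen, by = step)
    reads <- vapply(starts, function(s) substr(g, s + 1, s + readLen),
                    character(1))
    names(reads) <- sprintf("clean%03d", seq_along(starts))
    list(genome = g, reads = reads, starts = starts)
}
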