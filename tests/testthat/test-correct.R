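test_that("the high-density filter enforces every printed threshold", {
    fp <- FilterParams()
    keep <- function(a) length(filterRecruited(list(a), fp)) == 1
    expect_false(keep(makeAlignment(divergence = 0.05)))       # > 4% diverged
    expect_false(keep(makeAlignment(tStart = 0, tEnd = 900)))  # < 1000 bp span
    expect_false(keep(makeAlignment(overhangRight = 2500)))    # > 2000 bp hang
    expect_true(keep(makeAlignment(divergence = 0.03, tStart = 0,
                                   tEnd = 5000)))
    # boundary values are retained (thresholds are inclusive)
    expect_true(keep(makeAlignment(divergence = 0.04, tStart = 0,
                                   tEnd = 1000, overhangLeft = 2000)))
})

test_that("a lone target yields a linear graph whose consensus is itself", {
    sp <- SketchParams(seed = 5L)
    m <- buildMRead("t", randomSeq(8000, seed = 41), NULL, sp, "high")
    qs <- new("MReadSet", mreads = list(t = m), params = sp,
              density = "high")
    g <- buildVariationGraph(m, list(), qs)
    expect_equal(nrow(graphNodes(g)), nrow(hits(m)))
    expect_equal(nrow(graphEdges(g)), nrow(hits(m)) - 1)
    cons <- extractConsensus(g, k = sp@k)
    expect_identical(hits(cons@corrected)$hash, hits(m)$hash)
    expect_identical(hits(cons@corrected)$offset, hits(m)$offset)
    expect_equal(cons@sMax, sum(graphEdges(g)$weight))
})

test_that("a supporter mismatch creates one parallel variant node", {
    t <- makeMRead("t", c(0, 40, 80, 120), c(1, 5, 6, 2))
    q <- makeMRead("q", c(0, 40, 80, 120), c(1, 99, 6, 2))
    qs <- new("MReadSet", mreads = list(t = t, q = q),
              params = SketchParams(), density = "high")
    ch <- chainAnchors(findAnchors(q, t)[, 1:4], ChainParams())
    aln <- expandAlignment(ch, q, t, "+", 15L)
    g <- buildVariationGraph(t, list(aln), qs)
    nodes <- graphNodes(g)
    mis <- nodes[nodes$type == "mismatch", ]
    expect_equal(nrow(mis), 1)
    expect_equal(mis$hash, 99)
    expect_equal(mis$tPos, 1)
    e <- graphEdges(g)
    expect_equal(sum(e$to == mis$nodeId), 1)    # one incoming
    expect_equal(sum(e$from == mis$nodeId), 1)  # one outgoing
    # identical mismatches from further supporters pile on the same node
    g2 <- buildVariationGraph(t, list(aln, aln), qs)
    expect_identical(graphNodes(g2)$nodeId, nodes$nodeId)
    win <- graphEdges(g2)[graphEdges(g2)$to == mis$nodeId, "weight"]
    expect_equal(win, 2)
})

test_that("a supporter insertion bridges two target nodes", {
    t <- makeMRead("t", c(0, 40, 120), c(1, 5, 2))
    q <- makeMRead("q", c(0, 40, 80, 120), c(1, 5, 77, 2))
    qs <- new("MReadSet", mreads = list(t = t, q = q),
              params = SketchParams(), density = "high")
    ch <- chainAnchors(findAnchors(q, t)[, 1:4], ChainParams())
    aln <- expandAlignment(ch, q, t, "+", 15L)
    g <- buildVariationGraph(t, list(aln), qs)
    ins <- graphNodes(g)[graphNodes(g)$type == "insertion", ]
    expect_equal(nrow(ins), 1)
    expect_equal(ins$hash, 77)
    e <- graphEdges(g)
    expect_true(any(e$from == "T1" & e$to == ins$nodeId))
    expect_true(any(e$from == ins$nodeId & e$to == "T2"))
})

test_that("a supporter deletion contributes a weighted skip edge", {
    t <- makeMRead("t", c(0, 40, 80, 120), c(1, 5, 6, 2))
    q <- makeMRead("q", c(0, 40, 120), c(1, 5, 2))
    qs <- new("MReadSet", mreads = list(t = t, q = q),
              params = SketchParams(), density = "high")
    ch <- chainAnchors(findAnchors(q, t)[, 1:4], ChainParams())
    aln <- expandAlignment(ch, q, t, "+", 15L)
    g <- buildVariationGraph(t, list(aln), qs)
    e <- graphEdges(g)
    skip <- e[e$from == "T1" & e$to == "T3", ]
    expect_equal(nrow(skip), 1)
    expect_equal(skip$weight, 1)
})

test_that("the variation graph ignores supporter order", {
    sp <- SketchParams(seed = 5L)
    set.seed(42)
    for (inst in 1:10) {
        g0 <- randomSeq(15000)
        t <- buildMRead("t", substr(g0, 2001, 12000), NULL, sp, "high")
        sup <- list()
        ids <- sprintf("s%d", 1:5)
        qs <- list(t = t)
        for (id in ids) {
            s0 <- sample(1000:3000, 1)
            raw <- substr(g0, s0, s0 + 9999)
            # sprinkle a few substitutions
            ch <- strsplit(raw, "")[[1]]
            pos <- sample(seq_along(ch), 25)
            ch[pos] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
            qs[[id]] <- buildMRead(id, paste(ch, collapse = ""), NULL, sp,
                                   "high")
            aln <- alignMReads(qs[[id]], t)
            if (!is.null(aln)) sup[[length(sup) + 1]] <- aln
        }
        qset <- new("MReadSet", mreads = qs, params = sp, density = "high")
        ref <- buildVariationGraph(t, sup, qset)
        for (p in 1:4) {
            perm <- buildVariationGraph(t, sample(sup), qset)
            expect_identical(perm@nodes, ref@nodes)
            expect_identical(perm@edges, ref@edges)
        }
    }
})

test_that("consensus DP equals exhaustive path enumeration on DAGs", {
    for (trial in 1:20) {
        g <- randomDAG(nNodes = sample(4:12, 1), seed = 700 + trial)
        cons <- extractConsensus(g)
        expect_equal(cons@sMax, brutePathMax(g@nodes$nodeId, g@edges),
                     label = sprintf("trial %d", trial))
        expect_equal(sum(cons@supportWeights), cons@sMax)
    }
    # single bubble: branch weights 3 vs 1 -> heavy branch chosen
    nodes <- data.frame(nodeId = c("T0", "M1:9", "T1", "T2"),
                        type = c("target", "mismatch", "target", "target"),
                        tPos = c(0L, 1L, 1L, 2L), tRight = NA_integer_,
                        j = 0L, hash = c(1, 9, 5, 2),
                        offset = c(0L, 40L, 40L, 80L), orientation = "+",
                        quality = NA_integer_)
    edges <- data.frame(from = c("T0", "T0", "M1:9", "T1"),
                        to = c("M1:9", "T1", "T2", "T2"),
                        weight = c(3, 1, 3, 1))
    bubble <- new("VariationGraph", targetId = "t", nodes = nodes,
                  edges = edges, support = data.frame(),
                  targetPath = c("T0", "T1", "T2"))
    cons <- extractConsensus(bubble)
    expect_identical(cons@path, c("T0", "M1:9", "T2"))
    expect_equal(cons@sMax, 6)
    # variant offsets stay strictly increasing in the corrected mRead
    expect_true(all(diff(hits(cons@corrected)$offset) > 0))
})

test_that("quality weighting sums source and destination qualities", {
    t <- makeMRead("t", c(0, 40, 80), c(1, 5, 2),
                   quality = c(10L, 20L, 30L))
    qs <- new("MReadSet", mreads = list(t = t), params = SketchParams(),
              density = "high")
    g <- buildVariationGraph(t, list(), qs, useQuality = TRUE)
    expect_identical(graphEdges(g)$weight, c(10 + 20, 20 + 30))
})

test_that("correction is majority-driven and flags isolated reads", {
    sp <- SketchParams(seed = 5L)
    base <- randomSeq(12000, seed = 43)
    # corrupt the target with a clump of substitutions; 9 clean supporters
    ch <- strsplit(base, "")[[1]]
    pos <- 6000:6014
    ch[pos] <- c("T", "G", "A", "C", "T", "G", "A", "C", "T", "G", "A",
                 "C", "T", "G", "A")
    target <- paste(ch, collapse = "")
    reads <- c(tgt = target,
               stats::setNames(rep(base, 9), sprintf("sup%d", 1:9)))
    cr <- correctReads(reads, params = sp)
    res <- cr$results[["tgt"]]
    expect_false(res@uncorrected)
    truth <- buildMRead("tgt", base, NULL, sp, "high")
    got <- hits(res@corrected)$hash
    # corrupted minimizers are gone; the clean majority sketch is recovered
    expect_identical(got, hits(truth)$hash)

    lone <- c(alone = randomSeq(9000, seed = 44))
    crl <- correctReads(lone, params = sp)
    expect_true(crl$results[["alone"]]@uncorrected)
    expect_identical(hits(crl$results[["alone"]]@corrected)$hash,
                     hits(buildMRead("alone", lone[["alone"]], NULL, sp,
                                     "high"))$hash)
    expect_error(correctRead("nope", prepareCorrection(lone, params = sp)),
                 "unknown read id")
})

test_that("correcting clean reads leaves the sketches unchanged", {
    sp <- SketchParams(seed = 5L)
    cs <- cleanReadSet(genomeLen = 20000, readLen = 4000, step = 800,
                       seed = 45)
    cr <- correctReads(cs$reads, params = sp)
    truth <- sketchReads(cs$reads, sp, "high")
    unchanged <- vapply(names(cs$reads), function(id)
        identical(hits(cr$results[[id]]@corrected)$hash,
                  hits(truth[[id]])$hash), logical(1))
    expect_gte(mean(unchanged), 0.99)
})

test_that("correct_all is order-preserving and thread-invariant", {
    empty <- correctReads(stats::setNames(character(0), character(0)))
    expect_length(empty$results, 0)
    expect_equal(nrow(empty$report), 0)

    sp <- SketchParams(seed = 5L)
    cs <- cleanReadSet(genomeLen = 12000, readLen = 4000, step = 2000,
                       seed = 46)
    r1 <- correctReads(cs$reads, params = sp, threads = 1L)
    r4 <- correctReads(cs$reads, params = sp, threads = 4L)
    expect_identical(r1$report, r4$report)
    expect_identical(lapply(r1$results, function(x) hits(x@corrected)),
                     lapply(r4$results, function(x) hits(x@corrected)))
    expect_identical(names(r1$results), names(cs$reads))
})
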