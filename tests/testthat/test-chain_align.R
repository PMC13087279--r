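test_that("anchors are all equal-hash pairs, in deterministic order", {
    sp <- SketchParams(seed = 2L)
    s <- randomSeq(8000, seed = 21)
    m <- buildMRead("a", s, NULL, sp, "high")

    # a read against itself anchors the full diagonal
    a <- findAnchors(m, m)
    expect_gte(nrow(a), nrow(hits(m)))
    diag <- a[a$qIndex == a$tIndex, ]
    expect_equal(nrow(diag), nrow(hits(m)))
    expect_true(all(diag$strand == "same"))
    expect_false(is.unsorted(a$qIndex))

    # disjoint hash sets yield nothing
    m2 <- buildMRead("b", randomSeq(8000, seed = 22), NULL, sp, "high")
    shared <- intersect(hits(m)$hash, hits(m2)$hash)
    aa <- findAnchors(m, m2, blacklist = shared)
    expect_equal(nrow(aa), 0)

    # one shared hash that is blacklisted: empty
    x <- makeMRead("x", c(0, 100), c(7, 9))
    y <- makeMRead("y", c(0, 100), c(7, 13))
    expect_equal(nrow(findAnchors(x, y)), 1)
    expect_equal(nrow(findAnchors(x, y, blacklist = 7)), 0)

    lo <- buildMRead("a", s, NULL, sp, "low")
    expect_error(findAnchors(lo, m), "densities")
})

test_that("anchor join handles repeated hashes (all pairs)", {
    x <- makeMRead("x", c(0, 50, 100), c(7, 7, 9))
    y <- makeMRead("y", c(0, 80), c(7, 7))
    a <- findAnchors(x, y)
    # naive pairing oracle: every equal-hash (q, t) combination
    expect_equal(nrow(a), 4)
    expect_identical(a[, c("qIndex", "tIndex")],
                     data.frame(qIndex = c(0L, 0L, 1L, 1L),
                                tIndex = c(0L, 1L, 0L, 1L)))
})

test_that("banded chaining matches trivial closed forms", {
    cp <- ChainParams()
    one <- data.frame(qIndex = 0L, tIndex = 0L, qOffset = 0L, tOffset = 0L)
    ch <- chainAnchors(one, cp)
    expect_equal(ch@score, cp@matchBonus)
    expect_equal(nrow(ch@anchors), 1)

    # perfectly colinear on one diagonal: all chained, no gap cost
    n <- 12
    diag <- data.frame(qIndex = 0:(n - 1), tIndex = 0:(n - 1),
                       qOffset = (0:(n - 1)) * 40L,
                       tOffset = (0:(n - 1)) * 40L + 100L)
    ch <- chainAnchors(diag, cp)
    expect_equal(ch@score, n * cp@matchBonus)
    expect_equal(nrow(ch@anchors), n)

    empty <- chainAnchors(emptyAnchors <- data.frame(
        qIndex = integer(0), tIndex = integer(0),
        qOffset = integer(0), tOffset = integer(0)), cp)
    expect_equal(empty@score, 0)
})

test_that("banded DP equals the exhaustive chaining oracle", {
    cp <- ChainParams(bandH = 20L)
    for (trial in 1:60) {
        a <- randomAnchorSet(n = sample(2:10, 1), seed = 300 + trial)
        ch <- chainAnchors(a, cp)
        expect_equal(ch@score, bruteChainScore(a, cp),
                     tolerance = 1e-9,
                     label = sprintf("trial %d DP score", trial))
    }
})

test_that("adding an on-diagonal colinear anchor never lowers the score", {
    cp <- ChainParams(bandH = 50L)
    for (trial in 1:25) {
        a <- randomAnchorSet(n = 8, seed = 500 + trial)
        base <- chainAnchors(a, cp)@score
        extra <- data.frame(qIndex = max(a$qIndex) + 1L,
                            tIndex = max(a$tIndex) + 1L,
                            qOffset = max(a$qOffset) + 40L,
                            tOffset = max(a$tOffset) + 40L)
        grown <- chainAnchors(rbind(a, extra), cp)@score
        expect_gte(grown, base)
    }
})

test_that("expansion resolves inter-anchor hits by positional pairing", {
    # identical mReads: all matches
    sp <- SketchParams(seed = 2L)
    m <- buildMRead("a", randomSeq(6000, seed = 23), NULL, sp, "high")
    aln <- alignMReads(m, m)
    expect_true(all(alignmentOps(aln)$op == "match"))
    expect_equal(aln@nMatch, nrow(hits(m)))
    expect_equal(divergence(aln), 0)

    # one extra query hit between two anchors -> one insertion
    q <- makeMRead("q", c(0, 50, 100), c(1, 99, 2))
    t <- makeMRead("t", c(0, 100), c(1, 2))
    ch <- chainAnchors(findAnchors(q, t)[, 1:4], ChainParams())
    aln <- expandAlignment(ch, q, t, "+", 15L)
    expect_identical(alignmentOps(aln)$op, c("match", "insertion", "match"))

    # u = v = 2 between anchors -> two mismatches, paired in order
    q2 <- makeMRead("q", c(0, 40, 80, 120), c(1, 70, 71, 2))
    t2 <- makeMRead("t", c(0, 40, 80, 120), c(1, 80, 81, 2))
    ch2 <- chainAnchors(findAnchors(q2, t2)[, 1:4], ChainParams())
    aln2 <- expandAlignment(ch2, q2, t2, "+", 15L)
    ops2 <- alignmentOps(aln2)
    expect_identical(ops2$op, c("match", "mismatch", "mismatch", "match"))
    expect_identical(ops2$qIndex[2:3], 1:2)
    expect_identical(ops2$tIndex[2:3], 1:2)

    # target surplus -> deletions
    q3 <- makeMRead("q", c(0, 120), c(1, 2))
    t3 <- makeMRead("t", c(0, 40, 80, 120), c(1, 80, 81, 2))
    ch3 <- chainAnchors(findAnchors(q3, t3)[, 1:4], ChainParams())
    ops3 <- alignmentOps(expandAlignment(ch3, q3, t3, "+", 15L))
    expect_equal(sum(ops3$op == "deletion"), 2)
})

test_that("match counts are symmetric between query and target", {
    sp <- SketchParams(seed = 2L)
    g <- randomSeq(30000, seed = 24)
    r1 <- substr(g, 1, 20000)
    r2 <- substr(g, 8001, 28000)
    m1 <- buildMRead("r1", r1, NULL, sp, "high")
    m2 <- buildMRead("r2", r2, NULL, sp, "high")
    a12 <- alignMReads(m1, m2)
    a21 <- alignMReads(m2, m1)
    expect_equal(a12@nMatch, a21@nMatch)
})

test_that("opposite-strand alignments report target-forward coordinates", {
    sp <- SketchParams(seed = 2L)
    g <- randomSeq(30000, seed = 25)
    t <- substr(g, 1, 20000)
    q <- revcomp(substr(g, 5001, 25000))
    mt <- buildMRead("t", t, NULL, sp, "high")
    mq <- buildMRead("q", q, NULL, sp, "high")
    aln <- alignMReads(mq, mt)
    expect_equal(aln@strand, "-")
    expect_true(all(alignmentOps(aln)$op == "match"))
    # overlap covers target bases ~[5000, 20000)
    expect_lt(abs(aln@tSpan[1] - 5000), 200)
    expect_gt(aln@tSpan[2], 19000)
    # dovetail overlap: both overhangs essentially zero
    expect_lt(max(overhangs(aln)), 100)
})

test_that("divergence estimation inverts the shared-seed fraction", {
    expect_equal(estimateDivergence(10, 10, 15), 0)
    expect_equal(estimateDivergence(0, 10, 15), 1)
    expect_equal(estimateDivergence(round(0.98^15 * 1e6), 1e6, 15), 0.02,
                 tolerance = 1e-4)
    expect_error(estimateDivergence(5, 0, 15))
})
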