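test_that("minimizer selection respects the density threshold", {
    sp <- SketchParams(seed = 42L)
    s <- randomSeq(100000, seed = 1)

    lo <- selectMinimizers(s, sp, "low")
    frac <- nrow(lo) / (nchar(s) - sp@k + 1)
    expect_gt(frac, 0.004)
    expect_lt(frac, 0.006)

    # a sequence shorter than k has no k-mer
    expect_equal(nrow(selectMinimizers(substr(s, 1, sp@k - 1), sp, "low")), 0)

    # density 1 admits every N-free k-mer
    spAll <- SketchParams(dLow = 0.5, dHigh = 1.0)
    withN <- paste0(substr(s, 1, 50), "N", substr(s, 52, 100))
    hitsAll <- selectMinimizers(withN, spAll, "high")
    nFree <- sum(vapply(seq_len(nchar(withN) - spAll@k + 1), function(i)
        !grepl("N", substr(withN, i, i + spAll@k - 1)), logical(1)))
    expect_equal(nrow(hitsAll), nFree)
})

test_that("low-density hits are a subsequence of high-density hits", {
    sp <- SketchParams(seed = 3L)
    for (i in 1:1000) {
        s <- randomSeq(300)
        lo <- selectMinimizers(s, sp, "low")
        hi <- selectMinimizers(s, sp, "high")
        if (nrow(lo) == 0) next
        expect_true(all(lo$offset %in% hi$offset))
        expect_identical(lo$hash,
                         hi$hash[match(lo$offset, hi$offset)])
    }
})

test_that("mRead construction is deterministic and strand-symmetric", {
    sp <- SketchParams(seed = 9L)
    s <- randomSeq(20000, seed = 2)

    m1 <- buildMRead("r", s, NULL, sp, "high")
    m2 <- buildMRead("r", s, NULL, sp, "high")
    expect_identical(m1, m2)

    mrc <- buildMRead("rc", revcomp(s), NULL, sp, "high")
    expect_identical(sort(hits(m1)$hash), sort(hits(mrc)$hash))
    expect_identical(hits(m1)$hash, rev(hits(mrc)$hash))
    expect_true(all(hits(m1)$orientation != rev(hits(mrc)$orientation)))
    # mirrored offsets: a k-mer at offset o maps to length - o - k
    expect_identical(hits(m1)$offset,
                     rev(nchar(s) - hits(mrc)$offset - sp@k))

    expect_equal(nrow(hits(buildMRead("e", "", NULL, sp, "high"))), 0)
})

test_that("hit qualities are the minimum over the k constituent bases", {
    sp <- SketchParams(seed = 9L)
    s <- randomSeq(5000, seed = 4)
    q <- sample(2:40, nchar(s), replace = TRUE)
    m <- buildMRead("r", s, q, sp, "high")
    expected <- vapply(hits(m)$offset, function(o)
        min(q[(o + 1):(o + sp@k)]), integer(1))
    expect_identical(hits(m)$quality, expected)

    expect_warning(bad <- buildMRead("r", s, q[-1], sp, "high"),
                   "rejected")
    expect_null(bad)
})

test_that("homopolymer compression reports original coordinates", {
    # random sequence with homopolymer runs stretched in
    set.seed(9)
    units <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
    runs <- sample(1:4, 4000, replace = TRUE)
    s <- paste(rep(units, times = runs), collapse = "")
    sp <- SketchParams(seed = 9L, hpc = TRUE)
    m <- buildMRead("r", s, NULL, sp, "high")
    expect_gt(nrow(hits(m)), 0)
    expect_true(all(hits(m)$offset >= 0))
    expect_true(all(hits(m)$offset <= nchar(s) - sp@k))
    expect_true(all(diff(hits(m)$offset) > 0))
    # selection must equal plain selection on the collapsed string, and a
    # run-length-stretched copy must sketch to the same hash list
    comp <- gsub("(.)\\1+", "\\1", s)
    spPlain <- SketchParams(seed = 9L)
    expect_identical(hits(m)$hash,
                     selectMinimizers(comp, spPlain, "high")$hash)
    stretched <- paste(rep(strsplit(comp, "")[[1]],
                           times = sample(1:3, nchar(comp), replace = TRUE)),
                       collapse = "")
    m2 <- buildMRead("r2", stretched, NULL, sp, "high")
    expect_identical(hits(m2)$hash, hits(m)$hash)
})

test_that("repetitive blacklist takes the exact top fraction", {
    # 100,000 distinct hashes at fraction 1e-4 -> exactly 10
    set.seed(10)
    tab <- new("AbundanceTable", hash = as.numeric(sample.int(1e7, 100000)),
               count = sample.int(50L, 100000, replace = TRUE),
               totalDistinct = 100000L)
    bl <- repetitiveBlacklist(tab, 1e-4)
    expect_length(bl, 10)

    # brute-force sort oracle, incl. ties at the cutoff abundance
    tieTab <- new("AbundanceTable",
                  hash = as.numeric(c(11, 5, 8, 2, 14, 3, 9, 7, 1, 20)),
                  count = c(9L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 2L, 1L),
                  totalDistinct = 10L)
    got <- repetitiveBlacklist(tieTab, 0.45)   # floor(4.5) = 4 hashes
    ord <- order(-tieTab@count, tieTab@hash)
    expect_identical(got, tieTab@hash[ord][1:4])

    empty <- new("AbundanceTable", hash = numeric(0), count = integer(0),
                 totalDistinct = 0L)
    expect_length(repetitiveBlacklist(empty, 1e-4), 0)
})

test_that("abundance counts match a naive tabulation", {
    sp <- SketchParams(seed = 1L)
    reads <- vapply(1:5, function(i) randomSeq(3000), character(1))
    names(reads) <- paste0("r", 1:5)
    ms <- sketchReads(reads, sp, "high")
    ab <- minimizerAbundance(ms)
    naive <- table(unlist(lapply(names(reads), function(id)
        hits(ms[[id]])$hash)))
    expect_equal(ab@totalDistinct, length(naive))
    expect_identical(ab@count[match(as.numeric(names(naive)), ab@hash)],
                     as.integer(naive))
})

test_that("applying a blacklist equals a naive set-difference filter", {
    sp <- SketchParams(seed = 6L)
    m <- buildMRead("r", randomSeq(10000, seed = 7), NULL, sp, "high")
    expect_identical(applyBlacklist(m, numeric(0)), m)

    set.seed(8)
    bl <- sample(hits(m)$hash, 5)
    out <- applyBlacklist(m, bl)
    naive <- hits(m)[!(hits(m)$hash %in% bl), ]
    rownames(naive) <- NULL
    expect_identical(hits(out), naive)

    all <- applyBlacklist(m, hits(m)$hash)
    expect_equal(nrow(hits(all)), 0)
})
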