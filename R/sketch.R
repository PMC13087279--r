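#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   rbindlist setnames := .N .SD
NULL

# Homopolymer-compress a sequence. Returns the compressed string and the
# 0-based original offset of each compressed position's run start.
hpcCompress <- function(sequence) {
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    if (length(ch) == 0)
        return(list(seq = "", starts = integer(0), ends = integer(0)))
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    list(seq = paste(r$values, collapse = ""), starts = starts, ends = ends)
}

#' Select universal minimizers of a sequence
#'
#' Scans a DNA sequence and returns every k-mer whose canonical-strand hash
#' falls below `d * H`, where `d` is the requested density. Both strands of
#' a molecule therefore select the same minimizers; the orientation records
#' which strand carried the canonical representative. k-mers containing `N`
#' are never selected. Deterministic given the hash seed; on random sequence
#' the selected fraction approximates `d`.
#'
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @param params a [SketchParams] object.
#' @param density `"low"` or `"high"`, choosing `dLow` or `dHigh`.
#' @return data.frame of minimizer hits with columns `offset` (0-based),
#'   `orientation` (`"+"`/`"-"`), `hash`; ordered by offset. A sequence
#'   shorter than `k` yields zero rows.
#' @export
selectMinimizers <- function(sequence, params = SketchParams(),
                             density = c("low", "high")) {
    density <- match.arg(density)
    d <- if (density == "low") params@dLow else params@dHigh
    res <- cpp_sketch(sequence, params@k, params@seed, d * params@H)
    data.frame(offset = res$offset,
               orientation = c("+", "-")[res$strand + 1L],
               hash = res$hash)
}

#' Build the mRead of a single read
#'
#' Converts a read into its ordered list of universal minimizers. When a
#' quality string is supplied, each hit carries the minimum Phred score over
#' its k constituent bases. With `hpc = TRUE` in the parameters, selection
#' runs on the homopolymer-compressed sequence while offsets and qualities
#' are reported on the original coordinates.
#'
#' @param readId read identifier.
#' @param sequence DNA string.
#' @param qualities integer Phred vector of the same length as `sequence`,
#'   or `NULL`. A length mismatch rejects the read with a warning and
#'   returns `NULL`.
#' @param params a [SketchParams].
#' @param density `"low"` or `"high"`.
#' @return an [MRead], or `NULL` for a rejected read.
#' @export
buildMRead <- function(readId, sequence, qualities = NULL,
                       params = SketchParams(), density = c("low", "high")) {
    density <- match.arg(density)
    len <- nchar(sequence)
    if (!is.null(qualities) && length(qualities) != len) {
        warning(sprintf("read '%s': quality length %d != sequence length %d; read rejected",
                        readId, length(qualities), len))
        return(NULL)
    }
    d <- if (density == "low") params@dLow else params@dHigh
    if (params@hpc) {
        comp <- hpcCompress(sequence)
        res <- cpp_sketch(comp$seq, params@k, params@seed, d * params@H)
        # map compressed window back to original coordinates
        off <- comp$starts[res$offset + 1L]
        winEnd <- comp$ends[res$offset + params@k]  # 1 past last original base
        qual <- if (is.null(qualities)) rep(NA_integer_, length(off)) else
            vapply(seq_along(off), function(i)
                min(qualities[(off[i] + 1L):winEnd[i]]), integer(1))
    } else {
        res <- cpp_sketch(sequence, params@k, params@seed, d * params@H)
        off <- res$offset
        qual <- if (is.null(qualities)) rep(NA_integer_, length(off)) else
            cpp_window_min(as.integer(qualities), as.integer(off), params@k)
    }
    hitsDf <- data.frame(offset = as.integer(off),
                         orientation = c("+", "-")[res$strand + 1L],
                         hash = res$hash,
                         quality = as.integer(qual))
    new("MRead", readId = readId, readLength = as.integer(len),
        density = density, hits = hitsDf)
}

#' Sketch a set of reads at one density
#'
#' @param sequences named character vector (or `DNAStringSet`) of reads.
#' @param params a [SketchParams].
#' @param density `"low"` or `"high"`.
#' @param qualities optional named list of integer Phred vectors.
#' @return an [MReadSet]; reads rejected by [buildMRead] are dropped.
#' @export
sketchReads <- function(sequences, params = SketchParams(),
                        density = c("low", "high"), qualities = NULL) {
    density <- match.arg(density)
    ids <- names(sequences)
    sequences <- as.character(sequences)  # drops names; restore below
    names(sequences) <- ids
    if (is.null(ids)) stop("sequences must be named by read id")
    if (anyDuplicated(ids)) stop("duplicate read ids")
    mreads <- vector("list", length(ids))
    names(mreads) <- ids
    for (i in seq_along(ids)) {
        q <- if (is.null(qualities)) NULL else qualities[[ids[i]]]
        mreads[[i]] <- buildMRead(ids[i], sequences[[i]], q, params, density)
    }
    mreads <- Filter(Negate(is.null), mreads)
    new("MReadSet", mreads = mreads, params = params, density = density)
}

#' Minimizer abundance across a read set
#'
#' Counts how often each distinct minimizer hash occurs across all hits of
#' the set. Intended for the high-density sketch; since the low-density
#' sketch is nested inside it, one table serves both.
#'
#' @param mreads an [MReadSet] or a list of [MRead]s.
#' @return an [AbundanceTable].
#' @export
minimizerAbundance <- function(mreads) {
    if (is(mreads, "MReadSet")) mreads <- mreads@mreads
    hashes <- unlist(lapply(mreads, function(m) m@hits$hash), use.names = FALSE)
    if (length(hashes) == 0)
        return(new("AbundanceTable", hash = numeric(0), count = integer(0),
                   totalDistinct = 0L))
    dt <- data.table(hash = hashes)[, .(count = .N), by = hash]
    setorder(dt, hash)
    new("AbundanceTable", hash = dt$hash, count = as.integer(dt$count),
        totalDistinct = nrow(dt))
}

#' Blacklist the most repetitive minimizers
#'
#' Returns the `floor(fraction * totalDistinct)` most abundant distinct
#' hashes; ties at the cutoff abundance are broken by ascending hash value,
#' so the result is deterministic.
#'
#' @param table an [AbundanceTable].
#' @param fraction fraction of distinct minimizers to blacklist, in [0, 1).
#' @return numeric vector of blacklisted hash values (possibly empty).
#' @export
repetitiveBlacklist <- function(table, fraction = 1e-4) {
    stopifnot(fraction >= 0, fraction < 1)
    nSel <- floor(fraction * table@totalDistinct)
    if (nSel < 1 || table@totalDistinct == 0) return(numeric(0))
    ord <- order(-table@count, table@hash)
    table@hash[ord[seq_len(nSel)]]
}

#' Remove blacklisted minimizers from an mRead or set
#'
#' Hits whose hash is blacklisted are dropped; order is preserved and the
#' input is unmodified.
#'
#' @param x an [MRead] or [MReadSet].
#' @param blacklist numeric vector of blacklisted hashes.
#' @return object of the same class with blacklisted hits removed.
#' @export
applyBlacklist <- function(x, blacklist) {
    if (is(x, "MReadSet")) {
        x@mreads <- lapply(x@mreads, applyBlacklist, blacklist = blacklist)
        return(x)
    }
    stopifnot(is(x, "MRead"))
    if (length(blacklist) == 0 || nrow(x@hits) == 0) return(x)
    keep <- !(x@hits$hash %in% blacklist)
    x@hits <- x@hits[keep, , drop = FALSE]
    rownames(x@hits) <- NULL
    x
}
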