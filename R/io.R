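#' @importFrom jsonlite write_json read_json toJSON fromJSON
#' @importFrom utils read.delim write.table
NULL

# 53-bit hash values <-> lowercase hex strings (exact; doubles hold them).
hashToHex <- function(h) {
    a <- h %/% 2^48; r <- h - a * 2^48
    b <- r %/% 2^32; r <- r - b * 2^32
    cc <- r %/% 2^16; d <- r - cc * 2^16
    sprintf("%x%04x%04x%04x", as.integer(a), as.integer(b), as.integer(cc),
            as.integer(d))
}

hexToHash <- function(s) {
    vapply(s, function(x) {
        digs <- strtoi(strsplit(tolower(x), "", fixed = TRUE)[[1]], 16L)
        Reduce(function(a, d) a * 16 + d, digs, 0)
    }, numeric(1), USE.NAMES = FALSE)
}

#' Read sequences from FASTA or FASTQ (optionally gzipped)
#'
#' FASTQ qualities are parsed as Phred+33. Read ids are the first
#' whitespace-delimited token of each header; record order is preserved.
#'
#' @param path input file; format detected from the extension unless given.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return list with `sequences` (named character vector) and `qualities`
#'   (named list of integer vectors, or `NULL` for FASTA).
#' @export
readSeqFile <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (format == "auto") {
        base <- sub("\\.gz$", "", path)
        format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
            "fastq" else "fasta"
    }
    if (format == "fastq") {
        # coercions below warn about dropped (empty) metadata columns
        withCallingHandlers({
            x <- Biostrings::readQualityScaledDNAStringSet(path)
            seqs <- as.character(x)
            quals <- lapply(as(Biostrings::quality(x), "IntegerList"),
                            as.integer)
        }, warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
        ids <- sub("\\s.*$", "", names(x))
        names(seqs) <- ids
        names(quals) <- ids
        list(sequences = seqs, qualities = quals)
    } else {
        x <- Biostrings::readDNAStringSet(path)
        seqs <- as.character(x)
        names(seqs) <- sub("\\s.*$", "", names(x))
        list(sequences = seqs, qualities = NULL)
    }
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
writeFastaFile <- function(sequences, path) {
    x <- Biostrings::DNAStringSet(sequences)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Write sequences with qualities as FASTQ (Phred+33)
#'
#' @param sequences named character vector.
#' @param qualities named list of integer Phred vectors.
#' @param path output file.
#' @export
writeFastqFile <- function(sequences, qualities, path) {
    qstr <- vapply(names(sequences), function(id)
        rawToChar(as.raw(pmin(pmax(qualities[[id]], 0L), 93L) + 33L)),
        character(1))
    # Biostrings warns about dropped (empty) metadata columns here; harmless
    withCallingHandlers({
        x <- Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(sequences),
            Biostrings::PhredQuality(qstr))
        Biostrings::writeXStringSet(x, path, format = "fastq", qualities =
            Biostrings::quality(x))
    }, warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
            invokeRestart("muffleWarning")
    })
    invisible(path)
}

#' Write mReads to the TSV dump format
#'
#' One hit per line (readId, offset, orientation, hash in hex, quality,
#' readLength), preceded by a comment header recording k, seed and density.
#' Reads without hits are kept as a single placeholder line so the dump
#' round-trips exactly.
#'
#' @param x an [MReadSet] or named list of [MRead]s.
#' @param path output file.
#' @param params a [SketchParams] (taken from `x` when it is an
#'   [MReadSet]).
#' @param density sketch density label (taken from `x` when possible).
#' @export
writeMReads <- function(x, path, params = NULL, density = NULL) {
    if (is(x, "MReadSet")) {
        params <- x@params; density <- x@density; mreads <- x@mreads
    } else mreads <- x
    if (is.null(params)) params <- SketchParams()
    if (is.null(density)) density <- "high"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# mscorrect mreads k=%d seed=%d density=%s",
                       params@k, params@seed, density), con)
    writeLines(paste("readId", "offset", "orientation", "hash", "quality",
                     "readLength", sep = "\t"), con)
    for (m in mreads) {
        h <- m@hits
        if (nrow(h) == 0) {
            writeLines(paste(m@readId, ".", ".", ".", ".", m@readLength,
                             sep = "\t"), con)
        } else {
            q <- ifelse(is.na(h$quality), ".", as.character(h$quality))
            writeLines(paste(m@readId, h$offset, h$orientation,
                             hashToHex(h$hash), q, m@readLength, sep = "\t"),
                       con)
        }
    }
    invisible(path)
}

#' Read mReads back from the TSV dump format
#'
#' @param path file written by [writeMReads].
#' @param params optional [SketchParams]; k and seed are overridden by the
#'   file header.
#' @return an [MReadSet].
#' @export
readMReads <- function(path, params = NULL) {
    header <- readLines(path, n = 1L)
    mt <- regmatches(header,
        regexec("k=(\\d+) seed=(-?\\d+) density=(\\w+)", header))[[1]]
    if (length(mt) != 4) stop("malformed mReads dump header")
    if (is.null(params)) params <- SketchParams()
    params@k <- as.integer(mt[2]); params@seed <- as.integer(mt[3])
    density <- mt[4]
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "character",
                                    "character", "character", "integer"))
    mreads <- lapply(split(df, factor(df$readId, levels = unique(df$readId))),
                     function(sub) {
        if (nrow(sub) == 1 && sub$offset[1] == ".") {
            hitsDf <- data.frame(offset = integer(0),
                                 orientation = character(0),
                                 hash = numeric(0), quality = integer(0))
        } else {
            hitsDf <- data.frame(
                offset = as.integer(sub$offset),
                orientation = sub$orientation,
                hash = hexToHash(sub$hash),
                quality = suppressWarnings(as.integer(
                    ifelse(sub$quality == ".", NA, sub$quality))))
        }
        new("MRead", readId = sub$readId[1],
            readLength = sub$readLength[1], density = density,
            hits = hitsDf)
    })
    new("MReadSet", mreads = mreads, params = params, density = density)
}

#' Alignment dump (PAF-like TSV)
#'
#' @param alignments list of [MAlignment]s.
#' @param path output file.
#' @return the written data.frame, invisibly.
#' @export
writeAlignments <- function(alignments, path) {
    df <- do.call(rbind, lapply(alignments, function(a) data.frame(
        queryId = a@queryId, qLen = a@qLen, qStart = a@qSpan[1],
        qEnd = a@qSpan[2], strand = a@strand, targetId = a@targetId,
        tLen = a@tLen, tStart = a@tSpan[1], tEnd = a@tSpan[2],
        n = a@nMatch, m = a@mSeeds, divergence = a@divergence,
        score = a@chainScore)))
    if (is.null(df)) df <- data.frame()
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline; defaults are the method's
#' published operating point (k 15, densities 0.5% / 2.5%, repetitive
#' fraction 1e-4, coverage cap 20, divergence 4%, span 1000 bp, overhang
#' 2000 bp). Serializes to and from a single JSON file.
#'
#' @slot k,seed,dLow,dHigh,repetitiveFraction,hpc sketching (see
#'   [SketchParams]).
#' @slot matchBonus,gapScale,gapCap,bandH chaining (see [ChainParams]).
#' @slot maxDivergence,minSpanBases,maxOverhangBases filtering (see
#'   [FilterParams]).
#' @slot coverageCap recruitment coverage cap.
#' @slot threads worker count (execution is serial; results are identical
#'   for any value).
#' @slot input,output file paths.
#' @slot outputMode `"mreads"`, `"fasta"` or `"both"`.
#' @export
setClass("RunConfig", representation(
    k = "integer", seed = "integer", dLow = "numeric", dHigh = "numeric",
    repetitiveFraction = "numeric", hpc = "logical",
    matchBonus = "numeric", gapScale = "numeric", gapCap = "numeric",
    bandH = "integer", maxDivergence = "numeric", minSpanBases = "numeric",
    maxOverhangBases = "numeric", coverageCap = "numeric",
    threads = "integer", input = "character", output = "character",
    outputMode = "character"))

#' @param ... named fields overriding the defaults (see slots).
#' @rdname RunConfig-class
#' @export
RunConfig <- function(...) {
    defaults <- list(k = 15L, seed = 1L, dLow = 0.005, dHigh = 0.025,
                     repetitiveFraction = 1e-4, hpc = FALSE,
                     matchBonus = 50, gapScale = 0.05, gapCap = 50,
                     bandH = 50L, maxDivergence = 0.04,
                     minSpanBases = 1000, maxOverhangBases = 2000,
                     coverageCap = 20, threads = 1L,
                     input = "", output = "", outputMode = "both")
    args <- list(...)
    bad <- setdiff(names(args), names(defaults))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    defaults[names(args)] <- args
    for (f in c("k", "seed", "bandH", "threads"))
        defaults[[f]] <- as.integer(defaults[[f]])
    for (f in c("dLow", "dHigh", "repetitiveFraction", "matchBonus",
                "gapScale", "gapCap", "maxDivergence", "minSpanBases",
                "maxOverhangBases", "coverageCap"))
        defaults[[f]] <- as.numeric(defaults[[f]])
    defaults$hpc <- as.logical(defaults$hpc)
    do.call(new, c(list("RunConfig"), defaults))
}

#' @param config a [RunConfig].
#' @rdname RunConfig-class
#' @export
sketchParamsFromConfig <- function(config) {
    SketchParams(k = config@k, seed = config@seed, dLow = config@dLow,
                 dHigh = config@dHigh,
                 repetitiveFraction = config@repetitiveFraction,
                 hpc = config@hpc)
}

#' @rdname RunConfig-class
#' @export
chainParamsFromConfig <- function(config) {
    ChainParams(matchBonus = config@matchBonus, gapScale = config@gapScale,
                gapCap = config@gapCap, bandH = config@bandH)
}

#' @rdname RunConfig-class
#' @export
filterParamsFromConfig <- function(config) {
    FilterParams(maxDivergence = config@maxDivergence,
                 minSpanBases = config@minSpanBases,
                 maxOverhangBases = config@maxOverhangBases)
}

#' @param path JSON file path.
#' @rdname RunConfig-class
#' @export
writeRunConfig <- function(config, path) {
    fields <- slotNames("RunConfig")
    lst <- lapply(fields, function(f) slot(config, f))
    names(lst) <- fields
    write_json(lst, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname RunConfig-class
#' @export
readRunConfig <- function(path) {
    lst <- read_json(path, simplifyVector = TRUE)
    do.call(RunConfig, lst)
}

#' Write the per-read correction report
#'
#' @param report data.frame from [correctReads].
#' @param path output TSV path.
#' @export
writeReport <- function(report, path) {
    write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
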