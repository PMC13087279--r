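#' @importFrom stats rnorm runif
NULL

BASES <- c("A", "C", "G", "T")

randomOtherBase <- function(bases) {
    # one of the three bases differing from each input, uniformly
    alt <- vapply(bases, function(b) sample(setdiff(BASES, b), 1L),
                  character(1), USE.NAMES = FALSE)
    alt
}

#' Simulate one or more related genomes
#'
#' Draws a uniform-random genome at the requested GC content, then derives
#' `nSpecies - 1` copies by i.i.d. substitution at the stated pairwise
#' divergence — emulating the metagenomic situation where reads from
#' related species risk being recruited together.
#'
#' @param length genome length in bases (>= 10000 recommended).
#' @param gc GC fraction (default 0.5).
#' @param seed RNG seed.
#' @param nSpecies number of genomes (default 1).
#' @param divergenceBetweenSpecies substitution fraction between the base
#'   genome and each copy, in [0, 0.3].
#' @return named character vector of genome sequences.
#' @export
simulateGenome <- function(length, gc = 0.5, seed = 1L, nSpecies = 1L,
                           divergenceBetweenSpecies = 0) {
    stopifnot(divergenceBetweenSpecies >= 0, divergenceBetweenSpecies <= 0.3)
    set.seed(seed)
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    base <- sample(BASES, length, replace = TRUE, prob = p)
    genomes <- list(paste(base, collapse = ""))
    if (nSpecies > 1) {
        for (sp in 2:nSpecies) {
            mut <- base
            idx <- which(runif(length) < divergenceBetweenSpecies)
            if (length(idx)) mut[idx] <- randomOtherBase(mut[idx])
            genomes[[sp]] <- paste(mut, collapse = "")
        }
    }
    names(genomes) <- paste0("species", seq_len(nSpecies))
    unlist(genomes)
}

# Apply the i.i.d. error process to one template; returns the corrupted
# sequence. Events per base are mutually exclusive: substitution, deletion,
# or insertion of one random base after the current one.
corruptSequence <- function(template, model) {
    ch <- strsplit(template, "", fixed = TRUE)[[1]]
    n <- length(ch)
    u <- runif(n)
    ps <- model@substitutionRate; pd <- model@deletionRate
    pi <- model@insertionRate
    out <- ch
    sub <- u < ps
    if (any(sub)) out[sub] <- randomOtherBase(ch[sub])
    del <- u >= ps & u < ps + pd
    ins <- u >= ps + pd & u < ps + pd + pi
    if (any(ins))
        out[ins] <- paste0(out[ins], sample(BASES, sum(ins), replace = TRUE))
    out[del] <- ""
    paste(out, collapse = "")
}

#' Simulate error-laden long reads with ground truth
#'
#' Reads are drawn uniformly over the genomes (weighted by length) with
#' random strand; lengths are normal around `readLengthMean` (sd 10%),
#' truncated at genome ends (no wrap). The error model is applied i.i.d.
#' per base; qualities are normal around the model's `qualityMean`. The
#' ground-truth mRead of each read is the high-density sketch of its
#' uncorrupted origin interval, oriented as the read.
#'
#' @param genomes named character vector from [simulateGenome].
#' @param coverage mean per-genome coverage.
#' @param readLengthMean mean read length in bases.
#' @param errorModel an [ErrorModel] (carries the RNG seed).
#' @param params a [SketchParams] for the truth sketches.
#' @param withQualities simulate Phred qualities (default TRUE).
#' @return a [SimulatedDataset].
#' @export
simulateReads <- function(genomes, coverage, readLengthMean,
                          errorModel = ErrorModel(),
                          params = SketchParams(), withQualities = TRUE) {
    stopifnot(coverage > 0)
    set.seed(errorModel@seed)
    glens <- nchar(genomes)
    nReads <- max(1L, round(coverage * sum(glens) / readLengthMean))
    ids <- sprintf("read%04d", seq_len(nReads))
    reads <- character(nReads); quals <- vector("list", nReads)
    info <- vector("list", nReads); truth <- vector("list", nReads)
    for (i in seq_len(nReads)) {
        gi <- sample(seq_along(genomes), 1L, prob = glens)
        L <- glens[gi]
        len <- round(rnorm(1, readLengthMean, 0.1 * readLengthMean))
        len <- max(params@k + 10L, len)
        if (len > L) len <- L  # no wrap: truncate to the genome
        start <- sample.int(L - len + 1L, 1L) - 1L  # 0-based
        strand <- sample(c("+", "-"), 1L)
        template <- substr(genomes[[gi]], start + 1L, start + len)
        if (strand == "-") template <- revcompString(template)
        seq <- corruptSequence(template, errorModel)
        reads[i] <- seq
        if (withQualities) {
            q <- round(rnorm(nchar(seq), errorModel@qualityMean, 3))
            quals[[i]] <- as.integer(pmin(pmax(q, 2L), 41L))
        }
        info[[i]] <- data.frame(readId = ids[i],
                                genome = names(genomes)[gi],
                                start = start, end = start + len,
                                strand = strand)
        truth[[i]] <- buildMRead(ids[i], template, NULL, params, "high")
    }
    names(reads) <- ids; names(quals) <- ids; names(truth) <- ids
    new("SimulatedDataset", genomes = genomes, reads = reads,
        qualities = if (withQualities) quals else list(),
        readInfo = do.call(rbind, info), truthMReads = truth,
        params = params, errorModel = errorModel)
}

#' Write a simulated dataset to disk
#'
#' Writes genomes (FASTA), reads (FASTQ when qualities were simulated, else
#' FASTA), ground-truth mReads (TSV dump) and a manifest (JSON) into a
#' directory.
#'
#' @param ds a [SimulatedDataset].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
writeSimulatedDataset <- function(ds, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genomes = file.path(dir, "genomes.fasta"),
               reads = file.path(dir,
                   if (length(ds@qualities)) "reads.fastq" else "reads.fasta"),
               truth = file.path(dir, "truth_mreads.tsv"),
               manifest = file.path(dir, "manifest.json"))
    writeFastaFile(ds@genomes, paths[["genomes"]])
    if (length(ds@qualities))
        writeFastqFile(ds@reads, ds@qualities, paths[["reads"]])
    else writeFastaFile(ds@reads, paths[["reads"]])
    writeMReads(ds@truthMReads, paths[["truth"]], params = ds@params,
                density = "high")
    manifest <- list(nGenomes = length(ds@genomes),
                     nReads = length(ds@reads),
                     k = ds@params@k, seed = ds@errorModel@seed,
                     substitutionRate = ds@errorModel@substitutionRate,
                     insertionRate = ds@errorModel@insertionRate,
                     deletionRate = ds@errorModel@deletionRate,
                     files = as.list(basename(paths)))
    write_json(manifest, paths[["manifest"]], auto_unbox = TRUE)
    invisible(paths)
}

#' Correction-quality metrics against ground truth
#'
#' Aligns each corrected hash list to its ground-truth hash list (longest
#' common subsequence over hashes) and reports minimizer precision
#' (corrected hits present in truth / corrected hits), recall (truth hits
#' recovered / truth hits) and the error rate `1 - F1`, per read and
#' aggregated.
#'
#' @param corrected named list of [MRead]s (or an [MReadSet], or a list of
#'   [ConsensusResult]s).
#' @param truth named list of ground-truth [MRead]s covering the same ids.
#' @return list with `perRead` (data.frame) and aggregate `precision`,
#'   `recall`, `f1`, `errorRate`.
#' @export
evalCorrection <- function(corrected, truth) {
    if (is(corrected, "MReadSet")) corrected <- corrected@mreads
    corrected <- lapply(corrected, function(x)
        if (is(x, "ConsensusResult")) x@corrected else x)
    if (is(truth, "MReadSet")) truth <- truth@mreads
    ids <- names(corrected)
    if (!all(ids %in% names(truth)))
        stop("corrected read ids missing from truth set")
    rows <- lapply(ids, function(id) {
        ch <- corrected[[id]]@hits$hash
        th <- truth[[id]]@hits$hash
        L <- cpp_lcs(ch, th)
        data.frame(readId = id, nCorrected = length(ch),
                   nTruth = length(th), nMatched = L,
                   precision = if (length(ch)) L / length(ch) else 1,
                   recall = if (length(th)) L / length(th) else 1)
    })
    perRead <- do.call(rbind, rows)
    P <- sum(perRead$nMatched) / max(sum(perRead$nCorrected), 1)
    R <- sum(perRead$nMatched) / max(sum(perRead$nTruth), 1)
    f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
    list(perRead = perRead, precision = P, recall = R, f1 = f1,
         errorRate = 1 - f1)
}
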