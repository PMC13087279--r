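revcompString <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Reconstruct the base-space sequence of a corrected read
#'
#' For each consecutive pair of consensus minimizers, the base-space gap is
#' filled with the spanning subsequence of the supporting raw read whose
#' transition carried the highest weight (ties: longest alignment, then
#' ascending read id); the k bases of the final minimizer are appended from
#' the last gap's supporter. A gap no supporter spans is filled from the
#' target's own raw sequence and counted in the `unspanned` attribute.
#'
#' @param consensus a [ConsensusResult] carrying its variation graph.
#' @param rawSeqs named character vector of the raw read sequences.
#' @param k minimizer length in bases.
#' @return the reconstructed DNA string, with integer attribute `unspanned`
#'   giving the number of gaps filled from the target itself.
#' @export
reconstructBases <- function(consensus, rawSeqs, k = 15L) {
    path <- consensus@path
    g <- consensus@graph
    targetId <- consensus@readId
    corrected <- consensus@corrected
    if (length(path) == 0) {
        out <- ""
        attr(out, "unspanned") <- 0L
        return(out)
    }
    sup <- g@support
    rcCache <- new.env(parent = emptyenv())
    orientedSeq <- function(id, strand) {
        if (strand == "+") return(rawSeqs[[id]])
        key <- id
        if (!exists(key, envir = rcCache))
            assign(key, revcompString(rawSeqs[[id]]), envir = rcCache)
        get(key, envir = rcCache)
    }
    pieces <- character(0)
    unspanned <- 0L
    lastRow <- NULL
    if (length(path) > 1) {
        for (i in seq_len(length(path) - 1L)) {
            rows <- sup[sup$from == path[i] & sup$to == path[i + 1L], ,
                        drop = FALSE]
            rows <- rows[!is.na(rows$oFrom) & !is.na(rows$oTo), , drop = FALSE]
            if (nrow(rows) == 0) {
                # fall back to the target's own bases between the nodes
                unspanned <- unspanned + 1L
                a <- corrected@hits$offset[i]
                b <- corrected@hits$offset[i + 1L]
                pieces[i] <- substr(rawSeqs[[targetId]], a + 1L, b)
                lastRow <- list(readId = targetId, strand = "+", oTo = b)
                next
            }
            ord <- order(-rows$w, -rows$alnSpan, rows$readId)
            r <- rows[ord[1], ]
            s <- orientedSeq(r$readId, r$strand)
            pieces[i] <- substr(s, r$oFrom + 1L, r$oTo)
            lastRow <- r
        }
    }
    if (is.null(lastRow)) {
        # single-minimizer path: its k bases from the target itself
        a <- corrected@hits$offset[1]
        tail <- substr(rawSeqs[[targetId]], a + 1L, a + k)
    } else {
        s <- orientedSeq(lastRow$readId, lastRow$strand)
        tail <- substr(s, lastRow$oTo + 1L, lastRow$oTo + k)
    }
    out <- paste(c(pieces, tail), collapse = "")
    attr(out, "unspanned") <- unspanned
    out
}

#' Reconstruct all corrected reads of a correction run
#'
#' @param correction result list of [correctReads].
#' @param k minimizer length in bases.
#' @return named character vector of reconstructed sequences (input order).
#' @export
reconstructAll <- function(correction, k = 15L) {
    rawSeqs <- correction$state$sequences
    out <- vapply(correction$results, function(res)
        as.character(reconstructBases(res, rawSeqs, k = k)), character(1))
    out
}
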