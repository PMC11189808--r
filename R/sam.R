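# Minimal SAM-subset writer/reader so the pileup layer can also consume
# externally aligned data. Dialect: @HD and @SQ header lines; the 11
# mandatory columns with MAPQ=255, RNEXT=*, PNEXT=0, TLEN=0. Extra header
# lines and per-record tag fields are tolerated and ignored on input.

#' Write aligned reads as SAM
#'
#' @param aln an [AlignedReads-class].
#' @param path output file.
#' @param refSeq optional reference sequence; only used to fill the `@SQ`
#'   length when `aln@refLen` is `NA`.
#' @return the path, invisibly.
#' @export
writeSam <- function(aln, path, refSeq = NULL) {
    stopifnot(is(aln, "AlignedReads"))
    refLen <- aln@refLen
    if (is.na(refLen) && !is.null(refSeq)) refLen <- nchar(refSeq)
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", aln@refName, refLen))
    rec <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
                   aln@readId, aln@flag,
                   ifelse(aln@flag == 4L, "*", aln@refName),
                   aln@refStart, aln@cigar, aln@seq,
                   strrep("I", nchar(aln@seq)))
    writeLines(c(header, rec), path)
    invisible(path)
}

#' Read a minimal SAM file
#'
#' Parses the subset written by [writeSam()]: header lines are used for the
#' reference name/length, records for the mandatory columns. Unsorted
#' records are accepted (the pileup layer does its own indexing); malformed
#' CIGAR strings or coordinates raise an error naming the offending line.
#'
#' @param path SAM file path.
#' @return an [AlignedReads-class].
#' @export
readSam <- function(path) {
    lines <- readLines(path)
    isHeader <- startsWith(lines, "@")
    refName <- "ref"; refLen <- NA_integer_
    sq <- lines[isHeader & startsWith(lines, "@SQ")]
    if (length(sq)) {
        f <- strsplit(sq[1L], "\t", fixed = TRUE)[[1L]]
        sn <- sub("^SN:", "", f[startsWith(f, "SN:")])
        ln <- sub("^LN:", "", f[startsWith(f, "LN:")])
        if (length(sn)) refName <- sn[1L]
        if (length(ln)) refLen <- as.integer(ln[1L])
    }
    recLines <- which(!isHeader & nzchar(lines))
    n <- length(recLines)
    readId <- character(n); flag <- integer(n); refStart <- integer(n)
    cg <- character(n); seqs <- character(n)
    for (k in seq_len(n)) {
        ln <- recLines[k]
        f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 11L)
            stop("SAM line ", ln, ": expected 11 mandatory columns, got ",
                 length(f))
        pos <- suppressWarnings(as.integer(f[4L]))
        if (is.na(pos) || pos < 0L)
            stop("SAM line ", ln, ": invalid POS '", f[4L], "'")
        if (f[6L] != "*" && grepl("[^0-9MDIS]", f[6L]))
            stop("SAM line ", ln, ": unsupported CIGAR '", f[6L], "'")
        fl <- suppressWarnings(as.integer(f[2L]))
        if (is.na(fl)) stop("SAM line ", ln, ": invalid FLAG '", f[2L], "'")
        if (fl != 4L) {
            expLen <- cigarReadLength(f[6L])
            if (expLen != nchar(f[10L]))
                stop("SAM line ", ln, ": CIGAR covers ", expLen,
                     " read bases but SEQ has ", nchar(f[10L]))
        }
        readId[k] <- f[1L]; flag[k] <- fl; refStart[k] <- pos
        cg[k] <- f[6L]; seqs[k] <- f[10L]
    }
    AlignedReads(readId, refStart, cg, seqs, flag = flag,
                 refName = refName, refLen = refLen)
}
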