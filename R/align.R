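# R surface over the compiled Needleman-Wunsch aligner.

.defaultScoring <- function() list(match = 1L, mismatch = -1L, gap = -2L)

.checkSeq <- function(x, what) {
    if (!is.character(x) || any(!nzchar(x)) || anyNA(x))
        stop(what, " must be non-empty character sequence(s)")
    if (any(grepl("[^ACGTN]", x)))
        stop(what, " may only contain A, C, G, T, N")
    x
}

#' Construct an AlignedReads collection
#'
#' @param readId,refStart,cigar,seq per-read vectors (recycled to a common
#'   length where sensible).
#' @param flag SAM flags (default 0 = mapped).
#' @param refName,refLen reference name and length.
#' @return an [AlignedReads-class] object.
#' @export
AlignedReads <- function(readId, refStart, cigar, seq,
                         flag = 0L, refName = "amplicon",
                         refLen = NA_integer_) {
    n <- length(readId)
    new("AlignedReads", readId = as.character(readId),
        flag = rep_len(as.integer(flag), n),
        refStart = as.integer(refStart), cigar = as.character(cigar),
        seq = as.character(seq), refName = refName,
        refLen = as.integer(refLen))
}

#' @rdname AlignedReads
#' @param x,object an `AlignedReads`.
#' @export
setMethod("length", "AlignedReads", function(x) length(x@readId))

#' @rdname AlignedReads
#' @param i index vector.
#' @export
setMethod("[", "AlignedReads", function(x, i) {
    initialize(x, readId = x@readId[i], flag = x@flag[i],
               refStart = x@refStart[i], cigar = x@cigar[i], seq = x@seq[i])
})

#' @rdname AlignedReads
#' @export
setMethod("show", "AlignedReads", function(object) {
    cat(sprintf("AlignedReads: %d read(s) on %s (len %s)\n", length(object),
                object@refName, object@refLen))
    n <- min(5L, length(object))
    for (i in seq_len(n))
        cat(sprintf("  %s  pos %d  %s\n", object@readId[i],
                    object@refStart[i], object@cigar[i]))
    if (length(object) > n) cat("  ...\n")
})

#' @rdname AlignedReads
#' @export
readId <- function(x) x@readId

#' @rdname AlignedReads
#' @export
refStart <- function(x) x@refStart

#' @rdname AlignedReads
#' @export
cigar <- function(x) x@cigar

#' @rdname AlignedReads
#' @export
readSeq <- function(x) x@seq

# split "10M1D9M" into lengths + ops; returns list(len, op)
.parseCigar <- function(cg) {
    if (is.na(cg) || cg == "" || cg == "*") return(list(len = integer(), op = character()))
    if (grepl("[^0-9MDIS]", cg)) stop("unsupported CIGAR: ", cg)
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[MDIS]", cg))[[1L]]
    if (length(len) != length(op)) stop("malformed CIGAR: ", cg)
    list(len = len, op = op)
}

#' CIGAR arithmetic
#'
#' `cigarReadLength()` sums the ops that consume read bases (M, I, S);
#' `cigarRefSpan()` sums the ops that consume reference bases (M, D).
#' Vectorized over CIGAR strings.
#'
#' @param cg character vector of CIGAR strings.
#' @return integer vector.
#' @examples
#' cigarRefSpan("10M1D10M")     # 21
#' cigarReadLength("10M1D10M")  # 20
#' @export
cigarReadLength <- function(cg) {
    vapply(cg, function(x) {
        p <- .parseCigar(x)
        sum(p$len[p$op %in% c("M", "I", "S")])
    }, integer(1L), USE.NAMES = FALSE)
}

#' @rdname cigarReadLength
#' @export
cigarRefSpan <- function(cg) {
    vapply(cg, function(x) {
        p <- .parseCigar(x)
        sum(p$len[p$op %in% c("M", "D")])
    }, integer(1L), USE.NAMES = FALSE)
}

#' Global pairwise alignment with CIGAR output
#'
#' Needleman-Wunsch alignment under linear gap scoring (defaults: match +1,
#' mismatch -1, gap -2). Among co-optimal traces, ties are broken M over D
#' over I, which places deletions at the smallest reference coordinate
#' (left-aligned, the convention of standard variant normalization) so that
#' an RT jump is attributed to a deterministic position.
#'
#' @param read,ref sequences over A, C, G, T, N (single strings).
#' @param scoring list with integer `match`, `mismatch`, `gap`.
#' @param readId read name for the returned record.
#' @return a length-1 [AlignedReads-class] with the score in
#'   `attr(, "score")`.
#' @examples
#' aln <- globalAlign("ACGTT", "ACGTT")
#' cigar(aln)            # "5M"
#' attr(aln, "score")    # 5
#' @export
globalAlign <- function(read, ref, scoring = .defaultScoring(),
                        readId = "read") {
    .checkSeq(read, "read"); .checkSeq(ref, "ref")
    res <- .nw_align_many(read, ref, scoring$match, scoring$mismatch,
                          scoring$gap, FALSE)
    out <- AlignedReads(readId, res$ref_start, res$cigar, read,
                        refLen = nchar(ref))
    attr(out, "score") <- res$score
    out
}

#' Align amplicon reads against the reference
#'
#' The production alignment mode for the pipeline. Full-length amplicon
#' reads span the whole reference, but arrest-truncated reads cover only a
#' reference suffix; `mode = "overlap"` therefore uses end-gap-free
#' (semi-global) alignment in which leading/trailing *reference* bases are
#' skipped at no cost, so a truncation is represented by the mapping
#' position rather than penalized as a giant deletion. `mode = "global"`
#' forces strict global alignment.
#'
#' @param reads character vector of read sequences, or the list returned by
#'   [simulateSample()].
#' @param amplicon an [Amplicon-class], or a plain reference string.
#' @param mode `"overlap"` (default) or `"global"`.
#' @param scoring list with `match`, `mismatch`, `gap`.
#' @param readIds read names (defaults to `read1 ... readN` or the
#'   simulator's ids).
#' @return an [AlignedReads-class]; alignment scores in `attr(, "score")`.
#' @export
alignReads <- function(reads, amplicon, mode = c("overlap", "global"),
                       scoring = .defaultScoring(), readIds = NULL) {
    mode <- match.arg(mode)
    if (is.list(reads) && !is.null(reads$reads)) {
        if (is.null(readIds)) readIds <- reads$readIds
        reads <- reads$reads
    }
    ref <- if (is(amplicon, "Amplicon")) ampliconSeq(amplicon) else amplicon
    .checkSeq(reads, "reads"); .checkSeq(ref, "ref")
    if (is.null(readIds)) readIds <- paste0("read", seq_along(reads))
    res <- .nw_align_many(reads, ref, scoring$match, scoring$mismatch,
                          scoring$gap, mode == "overlap")
    out <- AlignedReads(readIds, res$ref_start, res$cigar, reads,
                        refLen = nchar(ref))
    attr(out, "score") <- res$score
    out
}
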