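# Per-site pileup counts and the signature statistics derived from them.

# what does this read contribute at reference position pos?
# returns list(kind = "base"/"del"/"term"/"none", qpos = read offset)
.classifyAt <- function(cg, start, pos) {
    if (start > pos) return(list(kind = "term", qpos = NA_integer_))
    p <- .parseCigar(cg)
    r <- start; q <- 0L
    for (k in seq_along(p$op)) {
        len <- p$len[k]
        switch(p$op[k],
            S = { q <- q + len },
            I = { q <- q + len },
            M = {
                if (pos < r + len)
                    return(list(kind = "base", qpos = q + (pos - r) + 1L))
                r <- r + len; q <- q + len
            },
            D = {
                if (pos < r + len)
                    return(list(kind = "del", qpos = NA_integer_))
                r <- r + len
            })
    }
    list(kind = "none", qpos = NA_integer_)  # alignment ends 5' of pos
}

#' Pile up one reference position
#'
#' Counts what every aligned read contributes at `pos`: a base call (an M op
#' covering the position), a deletion (a D op covering it), a termination
#' (alignment wholly 3' of the position -- RT stopped before reaching it),
#' or nothing. Each read contributes at most once; N base calls and
#' soft-clipped bases are never counted. Unmapped reads (flag 4) are
#' skipped.
#'
#' @param aln an [AlignedReads-class].
#' @param pos 1-based reference (amplicon-local) position.
#' @param ref the reference: an [Amplicon-class] or a plain string.
#' @return a [SitePileup-class].
#' @export
pileupSite <- function(aln, pos, ref) {
    stopifnot(is(aln, "AlignedReads"))
    refSeq <- if (is(ref, "Amplicon")) ampliconSeq(ref) else as.character(ref)
    pos <- as.integer(pos)
    if (is.na(pos) || pos < 1L || pos > nchar(refSeq))
        stop("position ", pos, " outside reference [1, ", nchar(refSeq), "]")
    refBase <- substr(refSeq, pos, pos)

    mapped <- which(aln@flag != 4L)
    baseCounts <- setNames(integer(4L), BASES)
    delCount <- 0L; termCount <- 0L
    if (length(mapped)) {
        # reads sharing (refStart, cigar) classify identically; amplicon
        # read sets collapse to a handful of groups
        key <- paste0(aln@refStart[mapped], "/", aln@cigar[mapped])
        groups <- split(mapped, key)
        for (idx in groups) {
            cls <- .classifyAt(aln@cigar[idx[1L]], aln@refStart[idx[1L]], pos)
            if (cls$kind == "del") {
                delCount <- delCount + length(idx)
            } else if (cls$kind == "term") {
                termCount <- termCount + length(idx)
            } else if (cls$kind == "base") {
                b <- substr(aln@seq[idx], cls$qpos, cls$qpos)
                tb <- table(factor(b, levels = BASES))  # drops N
                baseCounts <- baseCounts + as.integer(tb)
            }
        }
    }
    new("SitePileup", pos = pos, refBase = refBase, baseCounts = baseCounts,
        delCount = delCount, termCount = termCount)
}

#' @rdname SitePileup-class
#' @param x,object a `SitePileup`.
#' @export
spanCount <- function(x) sum(x@baseCounts) + x@delCount

#' @rdname SitePileup-class
#' @export
setMethod("show", "SitePileup", function(object) {
    cat(sprintf("SitePileup at %d (ref %s): A=%d C=%d G=%d T=%d del=%d term=%d (span %d)\n",
                object@pos, object@refBase, object@baseCounts[["A"]],
                object@baseCounts[["C"]], object@baseCounts[["G"]],
                object@baseCounts[["T"]], object@delCount, object@termCount,
                spanCount(object)))
})

#' Signature statistics from a site pileup
#'
#' The per-sample readout: `mismatchRate` is the fraction of base calls
#' differing from the reference base, decomposed by observed base in
#' `mismatchByBase`; `jumpRate` is the fraction of spanning reads (base
#' calls plus deletions) whose alignment deletes the position. The two
#' denominators differ by construction: a deleted site yields no base call.
#'
#' @param p a [SitePileup-class].
#' @param minDepth minimum spanning-read count (default 100); below it a
#'   condition of class `"lowCoverageError"` carrying the observed `depth`
#'   is raised, since binomial noise swamps sub-percent signatures.
#' @return a [SiteSignature-class].
#' @export
signatureFromPileup <- function(p, minDepth = 100L) {
    stopifnot(is(p, "SitePileup"))
    span <- spanCount(p)
    if (span < minDepth)
        stop(errorCondition(
            sprintf("coverage %d below minimum depth %d at position %d",
                    span, minDepth, p@pos),
            depth = span, class = "lowCoverageError"))
    nb <- sum(p@baseCounts)
    alt <- setdiff(c("T", "G", "C", "A"), p@refBase)
    byBase <- if (nb > 0L) p@baseCounts[alt] / nb
              else setNames(numeric(length(alt)), alt)  # no base calls at all
    new("SiteSignature", mismatchRate = sum(byBase),
        mismatchByBase = setNames(as.numeric(byBase), alt),
        jumpRate = p@delCount / span, depth = as.integer(span))
}

#' @rdname SiteSignature-class
#' @param object a `SiteSignature`.
#' @export
setMethod("show", "SiteSignature", function(object) {
    bb <- paste(sprintf("%s=%.4f", names(object@mismatchByBase),
                        object@mismatchByBase), collapse = " ")
    cat(sprintf("SiteSignature: mismatch %.4f (%s), jump %.4f, depth %d\n",
                object@mismatchRate, bb, object@jumpRate, object@depth))
})

#' @rdname SiteSignature-class
#' @param x a `SiteSignature`.
#' @export
mismatchRate <- function(x) x@mismatchRate

#' @rdname SiteSignature-class
#' @export
mismatchByBase <- function(x) x@mismatchByBase

#' @rdname SiteSignature-class
#' @export
jumpRate <- function(x) x@jumpRate

#' @rdname SiteSignature-class
#' @export
signatureDepth <- function(x) x@depth

#' Genotype a sample at the methylation-blocking SNP
#'
#' Calls the sample's G13708A status from the pileup at the SNP position.
#' The call is fraction-based rather than binary because mtDNA is
#' heteroplasmic: `carrier` when the alternative-allele fraction among base
#' calls is at least `vafThreshold`, `non_carrier` when it is at most
#' `1 - vafThreshold`, `indeterminate` otherwise or when coverage is below
#' `minDepth` (with a warning); indeterminate samples are excluded from
#' cohort comparisons.
#'
#' @param aln an [AlignedReads-class].
#' @param amplicon an [Amplicon-class] carrying the SNP position/alleles.
#' @param vafThreshold variant-allele-fraction cutoff (default 0.8).
#' @param minDepth minimum spanning coverage at the SNP site (default 100).
#' @return list with `status` (`"carrier"`, `"non_carrier"` or
#'   `"indeterminate"`), `vaf`, and `depth`.
#' @export
detectSnpCarrier <- function(aln, amplicon, vafThreshold = 0.8,
                             minDepth = 100L) {
    p <- pileupSite(aln, snpPos(amplicon), amplicon)
    nb <- sum(p@baseCounts)
    if (spanCount(p) < minDepth || nb == 0L) {
        warning("SNP site coverage ", spanCount(p), " below minimum depth ",
                minDepth, "; genotype indeterminate")
        return(list(status = "indeterminate", vaf = NA_real_,
                    depth = spanCount(p)))
    }
    vaf <- p@baseCounts[[amplicon@snpAlt]] / nb
    status <- if (vaf >= vafThreshold) "carrier"
              else if (vaf <= 1 - vafThreshold) "non_carrier"
              else "indeterminate"
    if (status == "indeterminate")
        warning(sprintf(
            "ambiguous alt-allele fraction %.3f at SNP site; genotype indeterminate",
            vaf))
    list(status = status, vaf = vaf, depth = spanCount(p))
}
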