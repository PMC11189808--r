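# Coordinate arithmetic, codon context, and RT complement logic.

#' Construct a GeneAnnotation
#'
#' @param geneName gene symbol.
#' @param genomeStart,genomeEnd 1-based inclusive genome coordinates.
#' @param strand `"+"` if the mRNA sense strand equals the genome forward
#'   strand (all packaged defaults), `"-"` otherwise.
#' @param cdsOffset transcript position of the first CDS base.
#' @return a [GeneAnnotation-class] object.
#' @examples
#' nd5 <- GeneAnnotation("MT-ND5", 12337, 14148)
#' mapTranscriptToGenome(1374, nd5)  # 13710
#' @export
GeneAnnotation <- function(geneName, genomeStart, genomeEnd, strand = "+",
                           cdsOffset = 1L) {
    new("GeneAnnotation", geneName = as.character(geneName),
        genomeStart = as.integer(genomeStart),
        genomeEnd = as.integer(genomeEnd), strand = strand,
        cdsOffset = as.integer(cdsOffset))
}

#' @describeIn GeneAnnotation Packaged default annotation for MT-ND5. The
#'   gene start 12337 is implied by the identity "transcript 1374 = mtDNA
#'   13710" under 1-based inclusive coordinates; the end is the rCRS ND5
#'   end (14148). Both are overridable.
#' @export
nd5Annotation <- function() GeneAnnotation("MT-ND5", 12337L, 14148L, "+", 1L)

#' @rdname GeneAnnotation
#' @param object,x a `GeneAnnotation`.
#' @export
setMethod("show", "GeneAnnotation", function(object) {
    cat(sprintf("GeneAnnotation %s: %d-%d (%s), CDS offset %d, length %d\n",
                object@geneName, object@genomeStart, object@genomeEnd,
                object@strand, object@cdsOffset, geneLength(object)))
})

#' @rdname GeneAnnotation
#' @export
geneLength <- function(x) x@genomeEnd - x@genomeStart + 1L

#' Construct a TargetSite
#'
#' @param transcriptPos,genomePos 1-based transcript and genome positions.
#' @param refBaseSense sense-strand reference base.
#' @param codonIndex,codonPos,codonSense codon context (see
#'   [TargetSite-class]).
#' @return a [TargetSite-class] object.
#' @export
TargetSite <- function(transcriptPos, genomePos, refBaseSense = "A",
                       codonIndex, codonPos, codonSense) {
    new("TargetSite", transcriptPos = as.integer(transcriptPos),
        genomePos = as.integer(genomePos), refBaseSense = refBaseSense,
        codonIndex = as.integer(codonIndex), codonPos = as.integer(codonPos),
        codonSense = codonSense)
}

#' @describeIn TargetSite The packaged default: the ND5 m1A at transcript
#'   position 1374 (mtDNA 13710), wobble position of codon 458 (`GCA`).
#' @export
nd5TargetSite <- function()
    TargetSite(1374L, 13710L, "A", 458L, 3L, "GCA")

#' @rdname TargetSite
#' @param object a `TargetSite`.
#' @export
setMethod("show", "TargetSite", function(object) {
    cat(sprintf(
        "TargetSite: transcript %d / genome %d, ref %s, codon %d pos %d (%s)\n",
        object@transcriptPos, object@genomePos, object@refBaseSense,
        object@codonIndex, object@codonPos, object@codonSense))
})

#' Construct a SnpRule
#'
#' @param genomePos 1-based genome position of the variant.
#' @param refAllele,altAllele sense-strand alleles.
#' @return a [SnpRule-class] object.
#' @export
SnpRule <- function(genomePos, refAllele, altAllele) {
    new("SnpRule", genomePos = as.integer(genomePos), refAllele = refAllele,
        altAllele = altAllele)
}

#' @describeIn SnpRule The packaged default: G13708A, which abolishes
#'   methylation of the m1A two bases downstream (mtDNA 13710).
#' @export
g13708aRule <- function() SnpRule(13708L, "G", "A")

#' @rdname SnpRule
#' @param object a `SnpRule`.
#' @export
setMethod("show", "SnpRule", function(object) {
    cat(sprintf("SnpRule: %s%d%s (%s)\n", object@refAllele, object@genomePos,
                object@altAllele, object@effect))
})

#' Map transcript positions to genome positions (and back)
#'
#' For a forward-sense gene, transcript position t maps to
#' `genomeStart + t - 1`; for a reverse-sense gene to `genomeEnd - t + 1`.
#' For the packaged ND5 annotation this reproduces the identity that
#' transcript position 1374 equates mtDNA position 13710. The two functions
#' are exact inverses on the gene span.
#'
#' @param t,g 1-based transcript / genome position(s); vectorized.
#' @param ann a [GeneAnnotation-class].
#' @return integer vector of mapped positions.
#' @examples
#' mapTranscriptToGenome(c(1, 1372, 1374), nd5Annotation())
#' mapGenomeToTranscript(13710, nd5Annotation())
#' @export
mapTranscriptToGenome <- function(t, ann) {
    t <- as.integer(t)
    len <- geneLength(ann)
    if (anyNA(t) || any(t < 1L) || any(t > len))
        stop("transcript position out of gene bounds [1, ", len, "]")
    if (ann@strand == "+") ann@genomeStart + t - 1L else ann@genomeEnd - t + 1L
}

#' @rdname mapTranscriptToGenome
#' @export
mapGenomeToTranscript <- function(g, ann) {
    g <- as.integer(g)
    if (anyNA(g) || any(g < ann@genomeStart) || any(g > ann@genomeEnd))
        stop("genome position outside gene [", ann@genomeStart, ", ",
             ann@genomeEnd, "]")
    if (ann@strand == "+") g - ann@genomeStart + 1L else ann@genomeEnd - g + 1L
}

#' Codon context of a transcript position
#'
#' Locates the codon containing transcript position `t` in the reading frame
#' given by the annotation's `cdsOffset`, and extracts the sense codon from a
#' supplied sense-strand sequence. `codonPos == 3` identifies the wobble
#' position.
#'
#' @param t 1-based transcript position.
#' @param ann a [GeneAnnotation-class].
#' @param senseSeq sense-strand sequence covering the codon (character or
#'   `DNAString`).
#' @param seqOffset transcript position of `senseSeq[1]` (default 1, i.e.
#'   `senseSeq` starts at the transcript start).
#' @return list with `codonIndex`, `codonPos`, `codonSense`.
#' @examples
#' seq <- paste(rep("ACT", 500), collapse = "")
#' codonOf(5, GeneAnnotation("toy", 1, 1500), seq)
#' @export
codonOf <- function(t, ann, senseSeq, seqOffset = 1L) {
    t <- as.integer(t)
    senseSeq <- as.character(senseSeq)
    if (t < ann@cdsOffset)
        stop("position ", t, " lies before the CDS (cdsOffset = ",
             ann@cdsOffset, ")")
    rel <- t - ann@cdsOffset
    codonIndex <- rel %/% 3L + 1L
    codonPos <- rel %% 3L + 1L
    codonStartTx <- ann@cdsOffset + (codonIndex - 1L) * 3L
    i <- codonStartTx - as.integer(seqOffset) + 1L
    if (i < 1L || i + 2L > nchar(senseSeq))
        stop("senseSeq does not cover the codon at transcript ",
             codonStartTx, "-", codonStartTx + 2L)
    list(codonIndex = codonIndex, codonPos = codonPos,
         codonSense = substr(senseSeq, i, i + 2L))
}

#' Map an incorporated cDNA base to the observed sense-strand base
#'
#' During reverse transcription the cDNA is the complement of the mRNA, so a
#' base incorporated opposite the (methylated) adenosine reads back on the
#' sense strand as its Watson-Crick complement: incorporation of A manifests
#' as a sense-strand T mismatch, C as G, G as C -- and correct incorporation
#' of T reads back as the reference A. The function is an involution.
#'
#' @param incorporatedBase character vector over A, C, G, T.
#' @return the sense-strand base(s) observed in sequencing.
#' @examples
#' incorporationToSenseMismatch(c("A", "C"))  # "T" "G"
#' @export
incorporationToSenseMismatch <- function(incorporatedBase) {
    if (!all(incorporatedBase %in% BASES))
        stop("incorporatedBase must be one of A, C, G, T")
    chartr("ACGT", "TGCA", incorporatedBase)
}

#' Read a gene annotation from a config file or BED line
#'
#' Accepts a YAML or JSON block with fields `name`, `start`, `end`, `strand`
#' (optional, default `"+"`) and `cds_offset` (optional, default 1), with
#' `start`/`end` 1-based inclusive; or a 6-column BED file (0-based
#' half-open), which is converted to the package's 1-based inclusive
#' convention.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`,
#'   `.json`, `.bed`).
#' @return a [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(path) {
    ext <- tolower(sub(".*\\.", "", path))
    if (ext %in% c("yaml", "yml", "json")) {
        cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
               else yaml::read_yaml(path)
        for (f in c("name", "start", "end"))
            if (is.null(cfg[[f]])) stop("annotation config lacks field '", f, "'")
        GeneAnnotation(cfg$name, cfg$start, cfg$end,
                       if (is.null(cfg$strand)) "+" else cfg$strand,
                       if (is.null(cfg$cds_offset)) 1L else cfg$cds_offset)
    } else if (ext == "bed") {
        bed <- read.delim(path, header = FALSE, nrows = 1L,
                          stringsAsFactors = FALSE)
        if (ncol(bed) < 3L) stop("BED line must have >= 3 columns")
        strand <- if (ncol(bed) >= 6L) bed[[6L]][1L] else "+"
        # BED is 0-based half-open: [start, end) -> 1-based inclusive
        GeneAnnotation(if (ncol(bed) >= 4L) bed[[4L]][1L] else "gene",
                       bed[[2L]][1L] + 1L, bed[[3L]][1L], strand)
    } else stop("unsupported annotation format: .", ext)
}
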