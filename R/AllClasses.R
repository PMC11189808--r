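# S4 class definitions. Constructors and accessors live with their modules.

#' GeneAnnotation: a single-exon gene on the mitochondrial genome
#'
#' Coordinate frame tying transcript positions to genome positions.
#' Coordinates are 1-based and inclusive at both ends, matching the usual
#' mtDNA (rCRS) convention. `strand == "+"` means the mRNA sense strand
#' equals the genome forward strand; `"-"` means it is the reverse
#' complement. `cdsOffset` is the transcript position of the first CDS base.
#'
#' @slot geneName single character, e.g. `"MT-ND5"`.
#' @slot genomeStart,genomeEnd 1-based inclusive genome span.
#' @slot strand `"+"` or `"-"`.
#' @slot cdsOffset transcript position (>= 1) of the first CDS base.
#' @export
setClass("GeneAnnotation",
    representation(geneName = "character", genomeStart = "integer",
                   genomeEnd = "integer", strand = "character",
                   cdsOffset = "integer"),
    prototype(geneName = NA_character_, genomeStart = 1L, genomeEnd = 1L,
              strand = "+", cdsOffset = 1L))

setValidity("GeneAnnotation", function(object) {
    msg <- character()
    if (length(object@geneName) != 1L) msg <- c(msg, "geneName must be length 1")
    if (length(object@genomeStart) != 1L || length(object@genomeEnd) != 1L ||
        is.na(object@genomeStart) || is.na(object@genomeEnd))
        msg <- c(msg, "genomeStart/genomeEnd must be single non-NA integers")
    else if (object@genomeStart > object@genomeEnd)
        msg <- c(msg, "genomeStart must be <= genomeEnd")
    if (!identical(length(object@strand), 1L) || !object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be \"+\" or \"-\"")
    if (length(object@cdsOffset) != 1L || is.na(object@cdsOffset) ||
        object@cdsOffset < 1L)
        msg <- c(msg, "cdsOffset must be >= 1")
    if (length(msg)) msg else TRUE
})

#' TargetSite: the modified adenosine under study
#'
#' A single transcript position with its genome coordinate and codon
#' context. For the packaged default (ND5 m1A) the site is transcript
#' position 1374 = mtDNA 13710, the third (wobble) position of codon 458,
#' sense codon `GCA`.
#'
#' @slot transcriptPos,genomePos 1-based positions.
#' @slot refBaseSense reference base on the mRNA sense strand (`"A"` for m1A).
#' @slot codonIndex 1-based codon number within the CDS.
#' @slot codonPos position within the codon, 1-3 (3 = wobble).
#' @slot codonSense the sense-strand codon 3-mer.
#' @export
setClass("TargetSite",
    representation(transcriptPos = "integer", genomePos = "integer",
                   refBaseSense = "character", codonIndex = "integer",
                   codonPos = "integer", codonSense = "character"))

setValidity("TargetSite", function(object) {
    msg <- character()
    if (!object@refBaseSense %in% BASES)
        msg <- c(msg, "refBaseSense must be one of A, C, G, T")
    if (!object@codonPos %in% 1:3)
        msg <- c(msg, "codonPos must be 1, 2 or 3")
    if (nchar(object@codonSense) != 3L)
        msg <- c(msg, "codonSense must be a 3-mer")
    else if (substr(object@codonSense, object@codonPos, object@codonPos) !=
             object@refBaseSense)
        msg <- c(msg, "codonSense does not carry refBaseSense at codonPos")
    if (length(msg)) msg else TRUE
})

#' SnpRule: a variant that abolishes methylation at the target site
#'
#' The packaged default is G13708A (Eurasian J haplogroup), two bases
#' upstream of the m1A genome position; carrier samples show no m1A
#' signature and are excluded from cohort comparisons.
#'
#' @slot genomePos 1-based genome position of the variant.
#' @slot refAllele,altAllele sense-strand alleles, must differ.
#' @slot effect currently only `"abolishes_methylation"`.
#' @export
setClass("SnpRule",
    representation(genomePos = "integer", refAllele = "character",
                   altAllele = "character", effect = "character"),
    prototype(effect = "abolishes_methylation"))

setValidity("SnpRule", function(object) {
    msg <- character()
    if (!object@refAllele %in% BASES || !object@altAllele %in% BASES)
        msg <- c(msg, "alleles must be single nucleotides")
    else if (object@refAllele == object@altAllele)
        msg <- c(msg, "refAllele and altAllele must differ")
    if (!identical(object@effect, "abolishes_methylation"))
        msg <- c(msg, "effect must be \"abolishes_methylation\"")
    if (length(msg)) msg else TRUE
})

#' SignatureParams: the RT outcome model at a modified adenosine
#'
#' Per-molecule event probabilities conditional on the template adenosine
#' being methylated, plus the uniform sequencing error rate. The four event
#' probabilities must sum to one: read-through (correct incorporation of T,
#' read back as the reference A), misincorporation of cDNA base `b` (read
#' back as the sense-strand complement of `b`), a single-base jump (deletion
#' in cDNA), or arrest (truncation at the site).
#'
#' @slot theta methylation stoichiometry in `[0, 1]` (fraction of molecules
#'   carrying m1A); per-sample specs usually override it.
#' @slot pReadthrough probability of correct incorporation given m1A.
#' @slot pMis named numeric over incorporated bases `A`, `C`, `G`
#'   (incorporating `T` is the correct outcome opposite A).
#' @slot pJump probability the RT skips the modified base.
#' @slot pArrest probability the RT terminates at the modified base.
#' @slot seqError per-base uniform substitution error rate in `[0, 0.1]`.
#' @export
setClass("SignatureParams",
    representation(theta = "numeric", pReadthrough = "numeric",
                   pMis = "numeric", pJump = "numeric", pArrest = "numeric",
                   seqError = "numeric"))

setValidity("SignatureParams", function(object) {
    msg <- character()
    p <- c(object@theta, object@pReadthrough, object@pMis, object@pJump,
           object@pArrest, object@seqError)
    if (anyNA(p) || any(p < 0) || any(p > 1))
        msg <- c(msg, "all probabilities must lie in [0, 1]")
    if (!all(names(object@pMis) %in% c("A", "C", "G")))
        msg <- c(msg, "pMis keys must be a subset of {A, C, G}")
    tot <- object@pReadthrough + sum(object@pMis) + object@pJump + object@pArrest
    if (is.na(tot) || abs(tot - 1) > 1e-12)
        msg <- c(msg, "pReadthrough + sum(pMis) + pJump + pArrest must equal 1")
    if (length(object@seqError) != 1L || is.na(object@seqError) ||
        object@seqError > 0.1)
        msg <- c(msg, "seqError must be a single value in [0, 0.1]")
    if (length(msg)) msg else TRUE
})

#' Amplicon: the sense-strand reference amplicon
#'
#' Holds the mRNA-sense reference sequence together with the local (amplicon)
#' coordinates of the modified site and of the SNP site, and the transcript
#' coordinate of the amplicon's first base so local positions can be mapped
#' back to transcript/genome coordinates.
#'
#' @slot seq reference sequence, uppercase ACGT.
#' @slot sitePos,snpPos 1-based local positions of the m1A and SNP sites.
#' @slot snpRef,snpAlt SNP alleles on the sense strand.
#' @slot txStart transcript position of amplicon base 1.
#' @slot annotation the [GeneAnnotation-class] the amplicon derives from.
#' @export
setClass("Amplicon",
    representation(seq = "character", sitePos = "integer", snpPos = "integer",
                   snpRef = "character", snpAlt = "character",
                   txStart = "integer", annotation = "GeneAnnotation"))

setValidity("Amplicon", function(object) {
    msg <- character()
    if (length(object@seq) != 1L || is.na(object@seq))
        msg <- c(msg, "seq must be a single string")
    else {
        if (grepl("[^ACGT]", object@seq))
            msg <- c(msg, "seq must contain only A, C, G, T")
        L <- nchar(object@seq)
        if (object@sitePos < 1L || object@sitePos > L ||
            object@snpPos < 1L || object@snpPos > L)
            msg <- c(msg, "sitePos and snpPos must lie inside the amplicon")
    }
    if (length(msg)) msg else TRUE
})

#' AlignedReads: a column-oriented collection of aligned amplicon reads
#'
#' One element per read; CIGARs use ops M (aligned, match or mismatch),
#' D (deletion from the reference), I (insertion) and S (soft clip). The
#' class is the carrier between the aligner / SAM layer and the pileup
#' layer.
#'
#' @slot readId,cigar,seq per-read character vectors.
#' @slot flag per-read SAM flags (0 mapped, 4 unmapped).
#' @slot refStart 1-based reference position of the first aligned base.
#' @slot refName,refLen reference name and length (length may be NA when a
#'   SAM file lacks an `@SQ` line).
#' @export
setClass("AlignedReads",
    representation(readId = "character", flag = "integer",
                   refStart = "integer", cigar = "character",
                   seq = "character", refName = "character",
                   refLen = "integer"),
    prototype(refName = "amplicon", refLen = NA_integer_))

setValidity("AlignedReads", function(object) {
    n <- length(object@readId)
    if (length(object@flag) != n || length(object@refStart) != n ||
        length(object@cigar) != n || length(object@seq) != n)
        return("per-read slots must have equal length")
    ok <- cigarReadLength(object@cigar) == nchar(object@seq)
    if (!all(ok | object@flag == 4L))
        return(sprintf("CIGAR/read length mismatch for read(s): %s",
                       paste(object@readId[!ok], collapse = ", ")))
    TRUE
})

#' SitePileup: per-site base, deletion and termination counts
#'
#' Counts at one reference position. Each spanning read contributes exactly
#' once: a base call (M op over the position), a deletion (D op over it), or
#' nothing. `termCount` tallies reads aligned wholly 3' of the position,
#' i.e. molecules whose reverse transcription (3'->5' along the mRNA)
#' terminated before reaching it; they do not span the site and are kept
#' out of every rate denominator. Base calls of N are dropped.
#'
#' @slot pos 1-based reference (amplicon-local) position.
#' @slot refBase reference base at `pos`.
#' @slot baseCounts named integer vector over A, C, G, T.
#' @slot delCount reads whose alignment deletes this position.
#' @slot termCount reads terminated 3' of this position.
#' @export
setClass("SitePileup",
    representation(pos = "integer", refBase = "character",
                   baseCounts = "integer", delCount = "integer",
                   termCount = "integer"))

setValidity("SitePileup", function(object) {
    msg <- character()
    if (!identical(sort(names(object@baseCounts)), sort(BASES)))
        msg <- c(msg, "baseCounts must be named over A, C, G, T")
    if (anyNA(c(object@baseCounts, object@delCount, object@termCount)) ||
        any(c(object@baseCounts, object@delCount, object@termCount) < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (!object@refBase %in% BASES)
        msg <- c(msg, "refBase must be one of A, C, G, T")
    if (length(msg)) msg else TRUE
})

#' SiteSignature: the per-sample readout at the modified site
#'
#' Misincorporation rate (overall and split by observed sense-strand base),
#' jump rate, and the depth they were estimated from. Mismatch rates are
#' fractions of base calls; the jump rate is a fraction of spanning reads
#' (base calls plus deletions), so the two denominators differ.
#'
#' @slot mismatchRate overall misincorporation rate.
#' @slot mismatchByBase named fractions for each non-reference base.
#' @slot jumpRate deletion fraction among spanning reads.
#' @slot depth spanning-read count the signature is based on.
#' @export
setClass("SiteSignature",
    representation(mismatchRate = "numeric", mismatchByBase = "numeric",
                   jumpRate = "numeric", depth = "integer"))

setValidity("SiteSignature", function(object) {
    msg <- character()
    rates <- c(object@mismatchRate, object@mismatchByBase, object@jumpRate)
    if (anyNA(rates) || any(rates < 0) || any(rates > 1))
        msg <- c(msg, "rates must lie in [0, 1]")
    if (abs(object@mismatchRate - sum(object@mismatchByBase)) > 1e-12)
        msg <- c(msg, "mismatchRate must equal sum(mismatchByBase)")
    if (length(msg)) msg else TRUE
})

#' ComparisonResult: a two-group comparison of one signature metric
#'
#' Output of [compareGroups()]: group sizes after exclusions, means with
#' SEM, the unpaired t-test, and a full account of which samples were
#' excluded at which stage (SNP carriers, indeterminate genotypes, missing
#' Braak stage under stratification, Grubbs outliers).
#'
#' @slot metric the compared column of the cohort table.
#' @slot stratification `"all"` or a Braak-stratification label.
#' @slot nControl,nCase group sizes entering the t-test.
#' @slot meanControl,semControl,meanCase,semCase group summaries.
#' @slot tStatistic,df,pValue unpaired t-test results.
#' @slot variant `"student"` (pooled variance) or `"welch"`.
#' @slot excludedSnp,excludedIndeterminate,excludedOutliers,droppedMissingBraak
#'   sample ids removed at each stage.
#' @export
setClass("ComparisonResult",
    representation(metric = "character", stratification = "character",
                   nControl = "integer", nCase = "integer",
                   meanControl = "numeric", semControl = "numeric",
                   meanCase = "numeric", semCase = "numeric",
                   tStatistic = "numeric", df = "numeric", pValue = "numeric",
                   variant = "character", excludedSnp = "character",
                   excludedIndeterminate = "character",
                   excludedOutliers = "character",
                   droppedMissingBraak = "character"))

setValidity("ComparisonResult", function(object) {
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
        return("pValue must lie in [0, 1]")
    TRUE
})
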