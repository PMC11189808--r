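# End-to-end glue: align each sample's reads, pile up the m1A and SNP
# sites, and assemble the cohort table consumed by compareGroups().

#' Signature and genotype for one sample
#'
#' Aligns a sample's reads (unless given an [AlignedReads-class] already),
#' piles up the modified site and the SNP site, and returns the per-sample
#' row of the cohort table.
#'
#' @param reads character vector of reads, a [simulateSample()] result, or
#'   an [AlignedReads-class].
#' @param amplicon an [Amplicon-class].
#' @param sampleId sample identifier for the output row.
#' @param minDepth minimum spanning depth for both sites (default 100).
#' @param vafThreshold SNP variant-allele-fraction cutoff (default 0.8).
#' @return one-row `data.frame` with columns `sample_id`, `depth`,
#'   `mismatch_rate`, `mm_T`, `mm_G`, `mm_C`, `jump_rate`, `snp_status`.
#' @export
analyzeSample <- function(reads, amplicon, sampleId = "sample",
                          minDepth = 100L, vafThreshold = 0.8) {
    aln <- if (is(reads, "AlignedReads")) reads
           else alignReads(reads, amplicon)
    sig <- signatureFromPileup(pileupSite(aln, sitePos(amplicon), amplicon),
                               minDepth = minDepth)
    snp <- detectSnpCarrier(aln, amplicon, vafThreshold = vafThreshold,
                            minDepth = minDepth)
    mb <- mismatchByBase(sig)
    data.frame(sample_id = sampleId, depth = signatureDepth(sig),
               mismatch_rate = mismatchRate(sig),
               mm_T = if ("T" %in% names(mb)) mb[["T"]] else NA_real_,
               mm_G = if ("G" %in% names(mb)) mb[["G"]] else NA_real_,
               mm_C = if ("C" %in% names(mb)) mb[["C"]] else NA_real_,
               jump_rate = jumpRate(sig), snp_status = snp$status,
               stringsAsFactors = FALSE)
}

# rebuild an Amplicon + sample list from a simulateCohort() output directory
.readCohortDir <- function(dir) {
    design <- yaml::read_yaml(file.path(dir, "design.yaml"))
    fa <- Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))
    g <- design$gene
    amplicon <- new("Amplicon", seq = as.character(fa[[1L]]),
                    sitePos = as.integer(design$site_pos),
                    snpPos = as.integer(design$snp_pos),
                    snpRef = design$snp_ref, snpAlt = design$snp_alt,
                    txStart = as.integer(design$tx_start),
                    annotation = GeneAnnotation(g$name, g$start, g$end,
                                                g$strand, g$cds_offset))
    metadata <- read.delim(file.path(dir, "metadata.tsv"),
                           stringsAsFactors = FALSE)
    reads <- lapply(metadata$sample_id, function(id) {
        fq <- .readFastq(file.path(dir, paste0(id, ".fastq")))
        list(reads = fq$seq, readIds = fq$id)
    })
    names(reads) <- metadata$sample_id
    list(samples = reads, metadata = metadata, amplicon = amplicon)
}

#' Analyze a cohort of amplicon samples
#'
#' Runs align -> pileup -> signature -> SNP genotyping for every sample and
#' joins the results with the cohort metadata. Accepts either the in-memory
#' result of [simulateCohort()] or a directory it wrote (FASTQ +
#' `metadata.tsv` + `reference.fasta` + `design.yaml`), so externally
#' produced files with the same layout can be analyzed too.
#'
#' @param cohort a [simulateCohort()] result or a directory path.
#' @param minDepth,vafThreshold passed to [analyzeSample()].
#' @return the cohort table: metadata columns (`sample_id`, `group`,
#'   `braak`) joined with the per-sample signature columns; the input of
#'   [compareGroups()].
#' @export
analyzeCohort <- function(cohort, minDepth = 100L, vafThreshold = 0.8) {
    if (is.character(cohort) && length(cohort) == 1L)
        cohort <- .readCohortDir(cohort)
    md <- cohort$metadata
    rows <- lapply(md$sample_id, function(id)
        analyzeSample(cohort$samples[[id]], cohort$amplicon, sampleId = id,
                      minDepth = minDepth, vafThreshold = vafThreshold))
    sig <- do.call(rbind, rows)
    out <- merge(md[c("sample_id", "group", "braak")], sig,
                 by = "sample_id", sort = TRUE)
    rownames(out) <- NULL
    out
}

#' Write / read the per-sample signature table
#'
#' TSV with columns `sample_id`, `group`, `braak`, `depth`,
#' `mismatch_rate`, `mm_T`, `mm_G`, `mm_C`, `jump_rate`, `snp_status`.
#'
#' @param tbl cohort table from [analyzeCohort()].
#' @param path output file.
#' @return the path (write) or the table (read).
#' @export
writeSignatureTable <- function(tbl, path) {
    write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSignatureTable
#' @export
readSignatureTable <- function(path)
    read.delim(path, stringsAsFactors = FALSE)

#' Simulate, align, quantify and compare in one call
#'
#' Convenience wrapper for the full synthetic experiment: simulate a cohort
#' under a master seed, align every read, compute per-sample signatures,
#' and run the stratified and unstratified group comparisons for the
#' mismatch and jump metrics.
#'
#' @param config cohort configuration (see [simulateCohort()]).
#' @param params a [SignatureParams-class].
#' @param seed master seed.
#' @param dir optional directory for FASTQ/TSV output.
#' @param stratify logical; also passed to [compareGroups()].
#' @param metrics which signature metrics to compare between groups.
#' @param minDepth,vafThreshold analysis thresholds.
#' @return list with `cohort` (simulation object), `table` (cohort table)
#'   and `comparisons` (named list of [ComparisonResult-class]).
#' @export
runPipeline <- function(config = list(), params = SignatureParams(),
                        seed = 1L, dir = NULL, stratify = FALSE,
                        metrics = c("mismatch_rate", "jump_rate"),
                        minDepth = 100L, vafThreshold = 0.8) {
    coh <- simulateCohort(config, params = params, dir = dir, seed = seed)
    tbl <- analyzeCohort(coh, minDepth = minDepth,
                         vafThreshold = vafThreshold)
    cmp <- lapply(metrics, function(m)
        compareGroups(tbl, m, stratify = stratify))
    names(cmp) <- metrics
    list(cohort = coh, table = tbl, comparisons = cmp)
}
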