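# Synthetic amplicon experiment: per-molecule RT outcomes at the modified
# site, uniform sequencing error, SNP-carrier samples, cohort metadata.

#' Construct SignatureParams
#'
#' Defaults are the package's synthetic study conditions: read-through 0.80,
#' misincorporation of A/C/G at 0.10/0.06/0.01 (so the sense-strand mismatch
#' composition is T > G > C), jump 0.02, arrest 0.01, sequencing error
#' 0.001. These event probabilities are free model parameters of the
#' simulator, not measured values. Missing `pMis` keys are filled with 0.
#'
#' @param theta methylation stoichiometry; usually overridden per sample.
#' @param pReadthrough,pMis,pJump,pArrest conditional RT event
#'   probabilities given a methylated template; must sum to 1.
#' @param seqError per-base uniform substitution error rate.
#' @return a [SignatureParams-class] object.
#' @export
SignatureParams <- function(theta = 0,
                            pReadthrough = 0.80,
                            pMis = c(A = 0.10, C = 0.06, G = 0.01),
                            pJump = 0.02, pArrest = 0.01,
                            seqError = 0.001) {
    full <- c(A = 0, C = 0, G = 0)
    if (length(pMis)) {
        if (is.null(names(pMis)) || !all(names(pMis) %in% names(full)))
            stop("pMis must be named over a subset of {A, C, G}")
        full[names(pMis)] <- pMis
    }
    new("SignatureParams", theta = theta, pReadthrough = pReadthrough,
        pMis = full, pJump = pJump, pArrest = pArrest, seqError = seqError)
}

#' @rdname SignatureParams
#' @param object a `SignatureParams`.
#' @export
setMethod("show", "SignatureParams", function(object) {
    cat(sprintf(
        paste0("SignatureParams: theta=%.3g | readthrough=%.3g ",
               "mis(A,C,G)=%.3g,%.3g,%.3g jump=%.3g arrest=%.3g | ",
               "seqError=%.3g\n"),
        object@theta, object@pReadthrough, object@pMis["A"], object@pMis["C"],
        object@pMis["G"], object@pJump, object@pArrest, object@seqError))
})

#' Build a sense-strand reference amplicon around the modified site
#'
#' Generates a random amplicon with the m1A site embedded in its GCA codon
#' context (positions `sitePos-2 .. sitePos` are `G`, `C`, `A`) and the SNP
#' reference allele at the SNP position (for the default G13708A rule this
#' coincides with the codon's G, two bases upstream of the site on the sense
#' strand). Flanks are generated without homopolymers of length >= 3
#' anywhere, so a single-base deletion at the site is always attributed to
#' an unambiguous coordinate by the left-aligning aligner.
#'
#' @param length amplicon length in nt (>= 60; default 200).
#' @param sitePos local 1-based position of the modified adenosine; default
#'   `floor(length / 2)`. Both the site and the SNP position need >= 20 nt
#'   flanks.
#' @param site a [TargetSite-class] (default [nd5TargetSite()]).
#' @param snp a [SnpRule-class] (default [g13708aRule()]).
#' @param annotation a [GeneAnnotation-class] (default [nd5Annotation()]).
#' @param seed optional integer; same seed, same sequence.
#' @return an [Amplicon-class] object.
#' @examples
#' amp <- makeReference(seed = 7)
#' substr(ampliconSeq(amp), sitePos(amp) - 2, sitePos(amp))  # "GCA"
#' @export
makeReference <- function(length = 200L, sitePos = NULL,
                          site = nd5TargetSite(), snp = g13708aRule(),
                          annotation = nd5Annotation(), seed = NULL) {
    length <- as.integer(length)
    if (length < 60L) stop("amplicon length must be >= 60")
    if (is.null(sitePos)) sitePos <- length %/% 2L
    sitePos <- as.integer(sitePos)
    txSnp <- mapGenomeToTranscript(snp@genomePos, annotation)
    snpPos <- sitePos - (site@transcriptPos - txSnp)
    for (p in c(sitePos, snpPos))
        if (p < 21L || p > length - 20L)
            stop("site and SNP positions must have >= 20 nt flanks")

    fixed <- character(length)
    fixed[(sitePos - 2L):sitePos] <- c("G", "C", "A")
    if (!nzchar(fixed[snpPos])) {
        fixed[snpPos] <- snp@refAllele
    } else if (fixed[snpPos] != snp@refAllele)
        stop("SNP reference allele conflicts with the codon context")

    seq <- withSeed(seed, {
        s <- character(length)
        for (i in seq_len(length)) {
            if (nzchar(fixed[i])) { s[i] <- fixed[i]; next }
            bad <- character()
            # no base may extend a run of 2 into a run of 3, looking both
            # backwards and across upcoming fixed positions
            if (i >= 3L && s[i - 1L] == s[i - 2L]) bad <- s[i - 1L]
            f1 <- if (i < length) fixed[i + 1L] else ""
            f2 <- if (i + 1L < length) fixed[i + 2L] else ""
            if (i >= 2L && nzchar(f1) && f1 == s[i - 1L]) bad <- c(bad, f1)
            if (nzchar(f1) && nzchar(f2) && f1 == f2) bad <- c(bad, f1)
            s[i] <- sample(setdiff(BASES, bad), 1L)
        }
        paste(s, collapse = "")
    })
    new("Amplicon", seq = seq, sitePos = sitePos, snpPos = snpPos,
        snpRef = snp@refAllele, snpAlt = snp@altAllele,
        txStart = site@transcriptPos - sitePos + 1L, annotation = annotation)
}

#' @rdname Amplicon-class
#' @param x,object an `Amplicon`.
#' @export
ampliconSeq <- function(x) x@seq

#' @rdname Amplicon-class
#' @export
sitePos <- function(x) x@sitePos

#' @rdname Amplicon-class
#' @export
snpPos <- function(x) x@snpPos

#' @rdname Amplicon-class
#' @param localPos 1-based position within the amplicon.
#' @export
localToGenome <- function(x, localPos)
    mapTranscriptToGenome(x@txStart + as.integer(localPos) - 1L, x@annotation)

#' @rdname Amplicon-class
#' @export
setMethod("show", "Amplicon", function(object) {
    cat(sprintf(
        "Amplicon: %d nt of %s sense strand, m1A site at %d (tx %d / genome %d), SNP %s>%s at %d\n",
        nchar(object@seq), object@annotation@geneName, object@sitePos,
        object@txStart + object@sitePos - 1L,
        localToGenome(object, object@sitePos),
        object@snpRef, object@snpAlt, object@snpPos))
})

# sense-strand base observed when cDNA base b is misincorporated
.MIS_SENSE <- c(mis_A = "T", mis_C = "G", mis_G = "C")
.EVENTS <- c("unmodified", "readthrough", "mis_A", "mis_C", "mis_G",
             "jump", "arrest")

# apply one RT event to the template; returns seq + refStart
.applyEvent <- function(ref, site, event) {
    L <- nchar(ref)
    switch(event,
        unmodified = ,
        readthrough = list(seq = ref, refStart = 1L),
        mis_A = ,
        mis_C = ,
        mis_G = {
            s <- ref
            substr(s, site, site) <- .MIS_SENSE[[event]]
            list(seq = s, refStart = 1L)
        },
        jump = list(seq = paste0(substr(ref, 1L, site - 1L),
                                 substr(ref, site + 1L, L)),
                    refStart = 1L),
        # RT runs 3'->5' along the mRNA: an arrested cDNA covers only the
        # region 3' of the site, so the emitted sense-frame read starts at
        # site + 1 and never calls a base at the site
        arrest = list(seq = substr(ref, site + 1L, L),
                      refStart = site + 1L),
        stop("unknown event: ", event))
}

# i.i.d. uniform substitution errors at rate e (no indel errors)
.applySeqError <- function(seqs, e) {
    if (e <= 0) return(seqs)
    L <- nchar(seqs)
    nerr <- rbinom(length(seqs), L, e)
    for (i in which(nerr > 0L)) {
        pos <- sample.int(L[i], nerr[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
        seqs[i] <- paste(ch, collapse = "")
    }
    seqs
}

# vectorized molecule simulation under the current RNG state
.simMolecules <- function(n, amplicon, theta, params, snpCarrier = FALSE) {
    ref <- amplicon@seq
    if (snpCarrier) {
        substr(ref, amplicon@snpPos, amplicon@snpPos) <- amplicon@snpAlt
        theta <- 0  # the variant abolishes methylation at the site
    }
    site <- amplicon@sitePos
    event <- rep("unmodified", n)
    modified <- runif(n) < theta
    k <- sum(modified)
    if (k > 0L) {
        pr <- c(params@pReadthrough, params@pMis[c("A", "C", "G")],
                params@pJump, params@pArrest)
        event[modified] <- sample(.EVENTS[-1L], k, replace = TRUE, prob = pr)
    }
    seqs <- character(n)
    refStart <- rep(1L, n)
    for (ev in unique(event)) {
        res <- .applyEvent(ref, site, ev)
        idx <- event == ev
        seqs[idx] <- res$seq
        refStart[idx] <- res$refStart
    }
    seqs <- .applySeqError(seqs, params@seqError)
    list(seq = seqs, event = event, refStart = refStart)
}

#' Simulate a single cDNA-derived read
#'
#' Draws (or takes as given) one RT outcome at the modified site and applies
#' uniform sequencing error. Misincorporation of cDNA base `b` substitutes
#' the sense-strand complement of `b` at the site; a jump deletes the site
#' base; arrest truncates the read so that it covers only the region 3' of
#' the site (reverse transcription proceeds 3'->5' along the mRNA).
#'
#' @param amplicon an [Amplicon-class].
#' @param params a [SignatureParams-class].
#' @param isModified logical; unmodified templates always read through.
#' @param event optional forced event, one of `"readthrough"`, `"mis_A"`,
#'   `"mis_C"`, `"mis_G"`, `"jump"`, `"arrest"` (ignored when
#'   `isModified = FALSE`).
#' @param seed optional integer seed.
#' @return list with `seq` (sense-frame read), `event`, and `refStart`
#'   (1-based amplicon position of the first read base).
#' @examples
#' amp <- makeReference(seed = 1)
#' p0 <- SignatureParams(seqError = 0)
#' simulateMolecule(amp, p0, TRUE, event = "jump")$event
#' @export
simulateMolecule <- function(amplicon, params, isModified,
                             event = NULL, seed = NULL) {
    withSeed(seed, {
        if (!isModified) {
            event <- "unmodified"
        } else if (is.null(event)) {
            pr <- c(params@pReadthrough, params@pMis[c("A", "C", "G")],
                    params@pJump, params@pArrest)
            event <- sample(.EVENTS[-1L], 1L, prob = pr)
        } else if (!event %in% .EVENTS[-1L])
            stop("unknown event: ", event)
        res <- .applyEvent(amplicon@seq, amplicon@sitePos, event)
        res$seq <- .applySeqError(res$seq, params@seqError)
        list(seq = res$seq, event = event, refStart = res$refStart)
    })
}

# FASTQ I/O (Phred+33, constant quality 'I' = Q40)
.writeFastq <- function(seqs, ids, path) {
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
    invisible(path)
}

.readFastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    list(seq = as.character(unname(x)), id = sub(" .*", "", names(x)))
}

#' Simulate one sample's amplicon reads
#'
#' Each molecule is methylated with probability `theta`; SNP-carrier samples
#' have an effective stoichiometry of zero and carry the alternative allele
#' at the SNP position in every molecule. Reads are emitted in the sense
#' frame; a truth record keeps the programmed parameters and realized event
#' counts for parameter-recovery tests.
#'
#' @param sampleId sample identifier (used in read names).
#' @param amplicon an [Amplicon-class].
#' @param params a [SignatureParams-class].
#' @param theta methylation stoichiometry (default `params@theta`).
#' @param nMolecules number of molecules/reads (>= 1).
#' @param group `"control"` or `"case"`; carried into the truth record.
#' @param braak Braak stage 0-6 or `NA`.
#' @param snpCarrier logical; forces `theta = 0` and the alt allele.
#' @param seed optional integer seed.
#' @param fastqPath optional path; when given the reads are also written as
#'   FASTQ (Phred+33, constant quality `I`).
#' @return list with `sampleId`, `reads` (character), `readIds`, `events`,
#'   and a one-row data.frame `truth`.
#' @export
simulateSample <- function(sampleId, amplicon, params, theta = params@theta,
                           nMolecules = 10000L, group = "case",
                           braak = NA_integer_, snpCarrier = FALSE,
                           seed = NULL, fastqPath = NULL) {
    nMolecules <- as.integer(nMolecules)
    if (nMolecules < 1L) stop("nMolecules must be >= 1")
    mol <- withSeed(seed,
        .simMolecules(nMolecules, amplicon, theta, params, snpCarrier))
    readIds <- sprintf("%s:%06d", sampleId, seq_len(nMolecules))
    counts <- table(factor(mol$event, levels = .EVENTS))
    truth <- data.frame(sample_id = sampleId, group = group,
                        braak = as.integer(braak), snp_carrier = snpCarrier,
                        theta = if (snpCarrier) 0 else theta,
                        n_molecules = nMolecules,
                        stringsAsFactors = FALSE)
    truth[paste0("n_", .EVENTS)] <- as.integer(counts)
    if (!is.null(fastqPath)) .writeFastq(mol$seq, readIds, fastqPath)
    list(sampleId = sampleId, reads = mol$seq, readIds = readIds,
         events = mol$event, truth = truth)
}

.defaultCohortConfig <- function() {
    list(n_control = 12L, n_case = 13L,
         theta_control = 0.05, theta_case = 0.15,
         n_molecules = 10000L, n_snp_carriers_case = 2L)
}

# Braak-stage sampling weights: controls centred near 2.5, cases near 4.8,
# mirroring the demographic structure the cohort emulates
.BRAAK_CONTROL_PROB <- c(`0` = 0.2, `1` = 0.3, `2` = 0.3, `3` = 0.2)
.BRAAK_CASE_PROB <- c(`4` = 0.35, `5` = 0.5, `6` = 0.15)

#' Simulate a full cohort of amplicon samples
#'
#' Generates per-sample FASTQ reads plus metadata and truth tables for a
#' two-group cohort. The default configuration mirrors the study structure
#' the package emulates: 12 controls vs 13 cases, two SNP-carrier samples in
#' the case group, depth 10,000 molecules per sample, stoichiometry 0.05 in
#' controls vs 0.15 in cases. All per-sample seeds are derived
#' deterministically from the master seed, so the same `(config, seed)` pair
#' reproduces byte-identical outputs.
#'
#' @param config a named list (or YAML/JSON file path) overriding any of
#'   `n_control`, `n_case`, `theta_control`, `theta_case`, `n_molecules`,
#'   `n_snp_carriers_case`; or a complete `samples` data.frame with columns
#'   `sample_id`, `group`, `braak`, `snp_carrier`, `theta`, `n_molecules`.
#' @param amplicon an [Amplicon-class]; generated from the master seed when
#'   `NULL`.
#' @param params a [SignatureParams-class].
#' @param dir optional output directory: per-sample `<id>.fastq`,
#'   `metadata.tsv`, `truth.tsv`, `reference.fasta` and `design.yaml` are
#'   written there.
#' @param seed master seed (integer).
#' @return list with `samples` (named list of [simulateSample()] results),
#'   `metadata`, `truth`, `amplicon`, `params` and `dir`.
#' @examples
#' coh <- simulateCohort(list(n_control = 2, n_case = 2, n_molecules = 200),
#'                       seed = 1)
#' coh$metadata
#' @export
simulateCohort <- function(config = list(), amplicon = NULL,
                           params = SignatureParams(), dir = NULL,
                           seed = 1L) {
    if (is.character(config) && length(config) == 1L) {
        ext <- tolower(sub(".*\\.", "", config))
        config <- if (ext == "json")
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    cfg <- utils::modifyList(.defaultCohortConfig(), config)

    drawn <- withSeed(seed, {
        refSeed <- sample.int(2147483646L, 1L)
        if (is.null(cfg$samples)) {
            if (cfg$n_control < 1L || cfg$n_case < 1L)
                stop("need at least one sample per group")
            ids <- c(sprintf("ctl%02d", seq_len(cfg$n_control)),
                     sprintf("ad%02d", seq_len(cfg$n_case)))
            braak <- c(sample(0:3, cfg$n_control, replace = TRUE,
                              prob = .BRAAK_CONTROL_PROB),
                       sample(4:6, cfg$n_case, replace = TRUE,
                              prob = .BRAAK_CASE_PROB))
            carrier <- logical(length(ids))
            if (cfg$n_snp_carriers_case > 0L)
                carrier[cfg$n_control +
                        sample(cfg$n_case, cfg$n_snp_carriers_case)] <- TRUE
            samples <- data.frame(
                sample_id = ids,
                group = rep(c("control", "case"),
                            c(cfg$n_control, cfg$n_case)),
                braak = braak, snp_carrier = carrier,
                theta = rep(c(cfg$theta_control, cfg$theta_case),
                            c(cfg$n_control, cfg$n_case)),
                n_molecules = cfg$n_molecules, stringsAsFactors = FALSE)
        } else samples <- as.data.frame(cfg$samples)
        list(refSeed = refSeed, samples = samples,
             sampleSeeds = sample.int(2147483646L, nrow(samples)))
    })
    samples <- drawn$samples
    if (anyDuplicated(samples$sample_id))
        stop("duplicate sample_id in cohort config")
    if (is.null(amplicon)) amplicon <- makeReference(seed = drawn$refSeed)

    if (!is.null(dir) && !dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    res <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
        s <- samples[i, ]
        res[[i]] <- simulateSample(
            s$sample_id, amplicon, params, theta = s$theta,
            nMolecules = s$n_molecules, group = s$group, braak = s$braak,
            snpCarrier = s$snp_carrier, seed = drawn$sampleSeeds[i],
            fastqPath = if (is.null(dir)) NULL
                        else file.path(dir, paste0(s$sample_id, ".fastq")))
    }
    names(res) <- samples$sample_id
    metadata <- samples[c("sample_id", "group", "braak", "snp_carrier")]
    truth <- do.call(rbind, lapply(res, `[[`, "truth"))
    rownames(truth) <- NULL

    if (!is.null(dir)) {
        tsv <- function(d, f) write.table(
            d, file.path(dir, f), sep = "\t", quote = FALSE,
            row.names = FALSE)
        tsv(metadata, "metadata.tsv")
        tsv(truth, "truth.tsv")
        fa <- Biostrings::DNAStringSet(ampliconSeq(amplicon))
        names(fa) <- "amplicon"
        Biostrings::writeXStringSet(fa, file.path(dir, "reference.fasta"))
        ann <- amplicon@annotation
        yaml::write_yaml(list(
            site_pos = amplicon@sitePos, snp_pos = amplicon@snpPos,
            snp_ref = amplicon@snpRef, snp_alt = amplicon@snpAlt,
            tx_start = amplicon@txStart,
            gene = list(name = ann@geneName, start = ann@genomeStart,
                        end = ann@genomeEnd, strand = ann@strand,
                        cds_offset = ann@cdsOffset)),
            file.path(dir, "design.yaml"))
    }
    list(samples = res, metadata = metadata, truth = truth,
         amplicon = amplicon, params = params, dir = dir)
}

#' Exact site-column outcome distribution of the simulator model
#'
#' Enumerates what a single molecule contributes at the modified site:
#' a base call (A, C, G or T on the sense strand, after sequencing error),
#' a deletion (jump), or a termination (arrest; no site coverage). Used for
#' closed-form expectations and for the site-level cohort simulator.
#'
#' @param theta methylation stoichiometry.
#' @param params a [SignatureParams-class].
#' @return named probability vector over `A`, `C`, `G`, `T`, `del`, `term`
#'   summing to 1.
#' @export
siteOutcomeProbs <- function(theta, params) {
    e <- params@seqError
    emit <- c(A = (1 - theta) + theta * params@pReadthrough,
              C = theta * params@pMis[["G"]],   # incorporated G -> sense C
              G = theta * params@pMis[["C"]],   # incorporated C -> sense G
              T = theta * params@pMis[["A"]])   # incorporated A -> sense T
    obs <- setNames(numeric(4L), BASES)
    for (b in BASES)
        obs[b] <- sum(emit * ifelse(BASES == b, 1 - e, e / 3))
    c(obs, del = theta * params@pJump, term = theta * params@pArrest)
}

#' Closed-form expected signature under the simulator model
#'
#' First-order expectations of the pileup estimators: the mismatch rate is
#' a fraction of base calls, the jump rate a fraction of spanning reads
#' (base calls + deletions).
#'
#' @inheritParams siteOutcomeProbs
#' @return list with `mismatchRate`, `mismatchByBase` (named over T, G, C)
#'   and `jumpRate`.
#' @examples
#' expectedSignature(0.5, SignatureParams(seqError = 0))$mismatchRate
#' @export
expectedSignature <- function(theta, params) {
    p <- siteOutcomeProbs(theta, params)
    bc <- sum(p[BASES])
    list(mismatchRate = unname((bc - p[["A"]]) / bc),
         mismatchByBase = p[c("T", "G", "C")] / bc,
         jumpRate = unname(p[["del"]] / (p[["del"]] + bc)))
}

#' Simulate a cohort at the site-count level
#'
#' Draws each sample's site column directly from the exact multinomial
#' outcome distribution of the RT event model ([siteOutcomeProbs()]) instead
#' of synthesizing and aligning reads. Because the site counts are
#' sufficient for every signature statistic, the resulting cohort table has
#' the same sampling distribution as the full read-level pipeline at a tiny
#' fraction of the cost -- this is the workhorse for statistical
#' calibration experiments (type-I error, power) that need hundreds of
#' cohorts. Genotyping is idealized: programmed carriers are labelled
#' `carrier` directly.
#'
#' @param nControl,nCase group sizes.
#' @param thetaControl,thetaCase group stoichiometries.
#' @param depth molecules per sample.
#' @param params a [SignatureParams-class].
#' @param nSnpCarriersCase number of case samples simulated as G13708A
#'   carriers (theta forced to 0).
#' @param seed optional integer seed.
#' @return a cohort table `data.frame` with columns `sample_id`, `group`,
#'   `braak`, `snp_status`, `depth`, `mismatch_rate`, `mm_T`, `mm_G`,
#'   `mm_C`, `jump_rate` -- the input format of [compareGroups()].
#' @export
simulateSignatureCohort <- function(nControl = 12L, nCase = 13L,
                                    thetaControl = 0.05, thetaCase = 0.15,
                                    depth = 10000L,
                                    params = SignatureParams(),
                                    nSnpCarriersCase = 0L, seed = NULL) {
    withSeed(seed, {
        n <- nControl + nCase
        ids <- c(sprintf("ctl%02d", seq_len(nControl)),
                 sprintf("ad%02d", seq_len(nCase)))
        group <- rep(c("control", "case"), c(nControl, nCase))
        braak <- c(sample(0:3, nControl, replace = TRUE,
                          prob = .BRAAK_CONTROL_PROB),
                   sample(4:6, nCase, replace = TRUE,
                          prob = .BRAAK_CASE_PROB))
        carrier <- logical(n)
        if (nSnpCarriersCase > 0L)
            carrier[nControl + sample(nCase, nSnpCarriersCase)] <- TRUE
        theta <- ifelse(carrier, 0,
                        ifelse(group == "control", thetaControl, thetaCase))
        rows <- lapply(seq_len(n), function(i) {
            cnt <- drop(rmultinom(1L, depth, siteOutcomeProbs(theta[i], params)))
            bc <- sum(cnt[BASES])
            span <- bc + cnt[["del"]]
            data.frame(sample_id = ids[i], group = group[i],
                       braak = braak[i],
                       snp_status = if (carrier[i]) "carrier" else "non_carrier",
                       depth = span,
                       mismatch_rate = if (bc > 0) (bc - cnt[["A"]]) / bc else 0,
                       mm_T = if (bc > 0) cnt[["T"]] / bc else 0,
                       mm_G = if (bc > 0) cnt[["G"]] / bc else 0,
                       mm_C = if (bc > 0) cnt[["C"]] / bc else 0,
                       jump_rate = cnt[["del"]] / span,
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
    })
}
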