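# hand-built fixture: 21-nt reference with the site at position 10
.fixtureRef <- "ACGTACGTAAGCATACGTACG"  # pos 10 is 'A'
.fixtureAln <- function() {
    ref <- .fixtureRef
    sub10 <- function(b) { s <- ref; substr(s, 10L, 10L) <- b; s }
    reads <- c(rep(ref, 6L),                       # 6 call the reference A
               rep(sub10("T"), 2L),                # 2 call T
               sub10("G"),                         # 1 calls G
               paste0(substr(ref, 1L, 9L), substr(ref, 11L, 21L)))  # 1 del
    cig <- c(rep("21M", 9L), "9M1D11M")
    AlignedReads(sprintf("r%02d", 1:10), rep(1L, 10L), cig, reads,
                 refLen = 21L)
}

test_that("pileup counts bases, deletions and terminations once per read", {
    p <- pileupSite(.fixtureAln(), 10L, .fixtureRef)
    expect_identical(p@baseCounts, c(A = 6L, C = 0L, G = 1L, T = 2L))
    expect_identical(p@delCount, 1L)
    expect_identical(spanCount(p), 10L)
    expect_identical(p@termCount, 0L)
    expect_identical(p@refBase, "A")

    # no read spans a position beyond every alignment
    aln1 <- AlignedReads("a", 1L, "5M", "ACGTA", refLen = 21L)
    p2 <- pileupSite(aln1, 10L, .fixtureRef)
    expect_identical(spanCount(p2), 0L)
    expect_identical(p2@termCount, 0L)

    # arrest-truncated read (starts 3' of the site) counts as termination
    term <- AlignedReads("t", 11L, "11M", substr(.fixtureRef, 11L, 21L),
                         refLen = 21L)
    p3 <- pileupSite(term, 10L, .fixtureRef)
    expect_identical(p3@termCount, 1L)
    expect_identical(spanCount(p3), 0L)

    expect_error(pileupSite(.fixtureAln(), 22L, .fixtureRef),
                 "outside reference")
})

test_that("N calls and unmapped or soft-clipped bases never count", {
    ref <- .fixtureRef
    withN <- ref
    substr(withN, 10L, 10L) <- "N"
    aln <- AlignedReads(c("n1", "u1", "s1"),
                        c(1L, 1L, 8L),
                        c("21M", "21M", "7S14M"),
                        c(withN, ref, ref),
                        flag = c(0L, 4L, 0L), refLen = 21L)
    p <- pileupSite(aln, 10L, ref)
    # N dropped entirely; unmapped skipped; soft-clip consumes read bases
    # before the first aligned one (s1 contributes its base 10)
    expect_identical(sum(p@baseCounts), 1L)
    expect_identical(p@baseCounts[["A"]], 1L)
})

test_that("signature statistics follow the two-denominator definitions", {
    sig <- signatureFromPileup(pileupSite(.fixtureAln(), 10L, .fixtureRef),
                               minDepth = 1L)
    expect_equal(mismatchRate(sig), 3 / 9)
    expect_equal(mismatchByBase(sig)[["T"]], 2 / 9)
    expect_equal(mismatchByBase(sig)[["G"]], 1 / 9)
    expect_equal(mismatchByBase(sig)[["C"]], 0)
    expect_equal(jumpRate(sig), 1 / 10)
    expect_identical(signatureDepth(sig), 10L)
    expect_equal(mismatchRate(sig), sum(mismatchByBase(sig)))

    allRef <- AlignedReads(paste0("r", 1:5), rep(1L, 5L), rep("21M", 5L),
                           rep(.fixtureRef, 5L), refLen = 21L)
    sigRef <- signatureFromPileup(pileupSite(allRef, 10L, .fixtureRef),
                                  minDepth = 1L)
    expect_identical(mismatchRate(sigRef), 0)
    expect_identical(jumpRate(sigRef), 0)

    err <- tryCatch(
        signatureFromPileup(pileupSite(.fixtureAln(), 10L, .fixtureRef),
                            minDepth = 100L),
        lowCoverageError = identity)
    expect_s3_class(err, "lowCoverageError")
    expect_identical(err$depth, 10L)
})

test_that("estimated rates track theta and the programmed composition", {
    amp <- testAmplicon()
    p0 <- errorFreeParams()
    thetas <- c(0, 0.25, 0.5, 0.75, 1)
    mm <- jp <- numeric(length(thetas))
    for (i in seq_along(thetas)) {
        s <- simulateSample("m", amp, p0, theta = thetas[i],
                            nMolecules = 4000L, seed = 400L + i)
        aln <- alignReads(s$reads, amp)
        sig <- signatureFromPileup(pileupSite(aln, sitePos(amp), amp))
        mm[i] <- mismatchRate(sig)
        jp[i] <- jumpRate(sig)
        if (thetas[i] >= 0.5) {
            bb <- mismatchByBase(sig)
            expect_true(bb[["T"]] > bb[["G"]] && bb[["G"]] > bb[["C"]],
                        label = paste("composition at theta", thetas[i]))
        }
    }
    # monotone in theta (rank correlation 1)
    expect_identical(order(mm), seq_along(thetas))
    expect_identical(order(jp), seq_along(thetas))
})

test_that("SNP genotyping classifies carriers by allele fraction", {
    amp <- testAmplicon()
    p <- SignatureParams()  # seqError 0.001
    car <- simulateSample("car", amp, p, theta = 0.5, nMolecules = 600L,
                          snpCarrier = TRUE, seed = 21L)
    non <- simulateSample("non", amp, p, theta = 0.5, nMolecules = 600L,
                          seed = 22L)
    gCar <- detectSnpCarrier(alignReads(car$reads, amp), amp)
    gNon <- detectSnpCarrier(alignReads(non$reads, amp), amp)
    expect_identical(gCar$status, "carrier")
    expect_gt(gCar$vaf, 0.99)
    expect_identical(gNon$status, "non_carrier")
    expect_lt(gNon$vaf, 0.01)

    # constructed 50/50 heteroplasmy is indeterminate
    ref <- ampliconSeq(amp)
    alt <- ref
    substr(alt, snpPos(amp), snpPos(amp)) <- "A"
    mixed <- AlignedReads(paste0("m", 1:200),
                          rep(1L, 200L), rep("200M", 200L),
                          c(rep(ref, 100L), rep(alt, 100L)),
                          refLen = 200L)
    expect_warning(gMix <- detectSnpCarrier(mixed, amp), "indeterminate")
    expect_identical(gMix$status, "indeterminate")

    # low coverage is indeterminate with a warning
    few <- AlignedReads("f1", 1L, "200M", ref, refLen = 200L)
    expect_warning(gLow <- detectSnpCarrier(few, amp), "below minimum depth")
    expect_identical(gLow$status, "indeterminate")
})
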