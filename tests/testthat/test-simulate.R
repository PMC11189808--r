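test_that("makeReference embeds the codon and SNP context deterministically", {
    amp <- makeReference(length = 200L, seed = 9L)
    s <- ampliconSeq(amp)
    expect_identical(nchar(s), 200L)
    expect_identical(substr(s, sitePos(amp) - 2L, sitePos(amp)), "GCA")
    # SNP two bases upstream of the site, carrying the reference G
    expect_identical(sitePos(amp) - snpPos(amp), 2L)
    expect_identical(localToGenome(amp, sitePos(amp)) -
                     localToGenome(amp, snpPos(amp)), 2L)
    expect_identical(substr(s, snpPos(amp), snpPos(amp)), "G")
    # no homopolymer of length >= 3 anywhere (keeps 1D placement unambiguous)
    expect_false(grepl("AAA|CCC|GGG|TTT", s))
    expect_identical(s, ampliconSeq(makeReference(length = 200L, seed = 9L)))
    expect_false(identical(s, ampliconSeq(makeReference(length = 200L, seed = 10L))))
    expect_error(makeReference(length = 50L), ">= 60")
    expect_error(makeReference(length = 100L, sitePos = 10L), "flanks")
})

test_that("forced RT events produce the defined read shapes", {
    amp <- testAmplicon()
    p0 <- errorFreeParams()
    ref <- ampliconSeq(amp)
    st <- sitePos(amp)

    expect_identical(simulateMolecule(amp, p0, FALSE)$seq, ref)

    mis <- simulateMolecule(amp, p0, TRUE, event = "mis_C")
    expect_identical(substr(mis$seq, st, st), "G")  # incorporated C -> sense G
    allBut <- function(x) paste0(substr(x, 1L, st - 1L),
                                 substr(x, st + 1L, nchar(x)))
    expect_identical(allBut(mis$seq), allBut(ref))  # all else reference
    expect_identical(nchar(mis$seq), nchar(ref))

    jmp <- simulateMolecule(amp, p0, TRUE, event = "jump")
    expect_identical(jmp$seq, paste0(substr(ref, 1L, st - 1L),
                                     substr(ref, st + 1L, nchar(ref))))

    arr <- simulateMolecule(amp, p0, TRUE, event = "arrest")
    expect_identical(arr$seq, substr(ref, st + 1L, nchar(ref)))
    expect_identical(arr$refStart, st + 1L)

    expect_error(simulateMolecule(amp, p0, TRUE, event = "hop"), "unknown event")
})

test_that("sample-level simulation honours theta and the SNP-carrier rule", {
    amp <- testAmplicon()
    p0 <- errorFreeParams()

    s0 <- simulateSample("t0", amp, p0, theta = 0, nMolecules = 50L, seed = 1L)
    expect_true(all(s0$reads == ampliconSeq(amp)))

    sc <- simulateSample("carrier", amp, p0, theta = 0.5, nMolecules = 80L,
                         snpCarrier = TRUE, seed = 2L)
    expect_true(all(s0$truth$n_unmodified == 50L))
    expect_identical(sc$truth$theta, 0)            # methylation abolished
    expect_true(all(substr(sc$reads, snpPos(amp), snpPos(amp)) == "A"))
    expect_true(all(substr(sc$reads, sitePos(amp), sitePos(amp)) == "A"))

    pj <- SignatureParams(pReadthrough = 0, pMis = c(A = 0, C = 0, G = 0),
                          pJump = 1, pArrest = 0, seqError = 0)
    sj <- simulateSample("j", amp, pj, theta = 1, nMolecules = 40L, seed = 3L)
    expect_true(all(nchar(sj$reads) == nchar(ampliconSeq(amp)) - 1L))
    expect_identical(sj$truth$n_jump, 40L)
})

test_that("realized event fractions concentrate around the programmed model", {
    amp <- testAmplicon()
    p0 <- errorFreeParams()
    n <- 10000L
    s <- simulateSample("conv", amp, p0, theta = 1, nMolecules = n, seed = 5L)
    prog <- c(readthrough = p0@pReadthrough, mis_A = p0@pMis[["A"]],
              mis_C = p0@pMis[["C"]], mis_G = p0@pMis[["G"]],
              jump = p0@pJump, arrest = p0@pArrest)
    for (ev in names(prog)) {
        frac <- s$truth[[paste0("n_", ev)]] / n
        tol <- 4 * sqrt(prog[[ev]] * (1 - prog[[ev]]) / n)
        expect_lt(abs(frac - prog[[ev]]), max(tol, 1e-12))
    }
    expect_identical(sum(unlist(s$truth[paste0("n_", c("unmodified",
        "readthrough", "mis_A", "mis_C", "mis_G", "jump", "arrest"))])), n)
})

test_that("site outcome distribution matches a direct enumeration", {
    p <- SignatureParams()  # seqError 0.001
    theta <- 0.4
    e <- p@seqError
    # enumerate by hand: emission before error, then uniform error channel
    emitted <- c(A = (1 - theta) + theta * p@pReadthrough,
                 T = theta * p@pMis[["A"]],
                 G = theta * p@pMis[["C"]],
                 C = theta * p@pMis[["G"]])
    exp <- sapply(c("A", "C", "G", "T"), function(b)
        emitted[[b]] * (1 - e) + (sum(emitted) - emitted[[b]]) * e / 3)
    probs <- siteOutcomeProbs(theta, p)
    expect_equal(probs[c("A", "C", "G", "T")], exp, tolerance = 1e-12)
    expect_equal(unname(probs[["del"]]), theta * p@pJump)
    expect_equal(unname(probs[["term"]]), theta * p@pArrest)
    expect_equal(sum(probs), 1, tolerance = 1e-12)
})

test_that("cohort simulation reproduces the configured structure byte-for-byte", {
    cfg <- list(n_control = 12L, n_case = 13L, n_molecules = 40L,
                n_snp_carriers_case = 2L)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    c1 <- simulateCohort(cfg, dir = d1, seed = 77L)
    c2 <- simulateCohort(cfg, dir = d2, seed = 77L)

    expect_identical(nrow(c1$metadata), 25L)
    expect_identical(sum(endsWith(list.files(d1), ".fastq")), 25L)
    expect_identical(sum(c1$truth$snp_carrier &
                         c1$truth$group == "case"), 2L)
    expect_identical(sum(c1$truth$snp_carrier), 2L)

    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    }
    c3 <- simulateCohort(cfg, seed = 78L)
    expect_false(identical(c1$samples$ctl01$reads, c3$samples$ctl01$reads))

    dup <- data.frame(sample_id = c("a", "a"), group = c("control", "case"),
                      braak = c(1L, 5L), snp_carrier = FALSE, theta = 0.1,
                      n_molecules = 10L)
    expect_error(simulateCohort(list(samples = dup)), "duplicate sample_id")
})
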