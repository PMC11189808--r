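Package: rtsig
Title: Site-Specific m1A Quantification from Reverse-Transcription
    Signatures in Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies N1-methyladenosine (m1A) at a single configured
    transcript site from the signature that reverse transcriptase leaves in
    amplicon sequencing reads: base misincorporation split by observed base,
    single-nucleotide jumps (deletions), and premature termination. Centred
    on the m1A at position 1374 of the mitochondrial ND5 mRNA (mtDNA
    position 13710), the package provides transcript/genome coordinate
    arithmetic, a synthetic amplicon read simulator with a per-molecule RT
    outcome model, a global/overlap pairwise aligner emitting CIGAR strings,
    per-site pileup statistics, SNP-carrier detection (G13708A) for sample
    exclusion, and cohort statistics (Grubbs outlier removal, unpaired
    t-tests, Braak-stage stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
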