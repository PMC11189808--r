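# Shared fixtures and independent oracles for the test suite.

# independent quadratic-space Needleman-Wunsch score (no traceback),
# written directly from the recurrence
nwScoreOracle <- function(read, ref, match = 1, mismatch = -1, gap = -2) {
    A <- strsplit(ref, "")[[1L]]
    B <- strsplit(read, "")[[1L]]
    n <- length(A); m <- length(B)
    F <- matrix(0L, n + 1L, m + 1L)
    F[1L, ] <- (0:m) * gap
    F[, 1L] <- (0:n) * gap
    for (i in seq_len(n)) for (j in seq_len(m))
        F[i + 1L, j + 1L] <- max(
            F[i, j] + if (A[i] == B[j]) match else mismatch,
            F[i, j + 1L] + gap,
            F[i + 1L, j] + gap)
    as.integer(F[n + 1L, m + 1L])
}

# reference coordinate of the single D op in a CIGAR made of M and D ops;
# fails (NA) if the CIGAR does not have exactly one 1D and no I/S
delPosFromCigar <- function(cg) {
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[A-Z]", cg))[[1L]]
    if (sum(op == "D") != 1L || any(!op %in% c("M", "D")) ||
        len[op == "D"] != 1L)
        return(NA_integer_)
    r <- 1L
    for (k in seq_along(op)) {
        if (op[k] == "D") return(r)
        r <- r + len[k]
    }
    NA_integer_
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

deleteAt <- function(s, i)
    paste0(substr(s, 1L, i - 1L), substr(s, i + 1L, nchar(s)))

# one shared default amplicon for tests that don't care about its seed
testAmplicon <- function() makeReference(seed = 42L)

errorFreeParams <- function(...) SignatureParams(seqError = 0, ...)
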