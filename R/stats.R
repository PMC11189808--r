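# Cohort statistics: Grubbs outlier exclusion, unpaired t-tests, and
# Braak-stage stratified group comparison.

#' Grubbs statistic for the most extreme point
#'
#' `G = max |x_i - mean(x)| / sd(x)` with the sample (n-1) standard
#' deviation; ties go to the first extreme point.
#'
#' @param x numeric vector, `n >= 3`, non-zero variance.
#' @return list with `G` and `index` of the extreme point.
#' @examples
#' grubbsStatistic(c(1, 1, 1, 5))  # G = 1.5, index 4
#' @export
grubbsStatistic <- function(x) {
    if (length(x) < 3L) stop("Grubbs test needs n >= 3")
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("Grubbs test needs non-zero variance")
    dev <- abs(x - mean(x))
    idx <- which.max(dev)
    list(G = dev[idx] / s, index = idx)
}

#' Two-sided Grubbs critical value
#'
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha/(2n)` quantile of Student's t with `n - 2` degrees of
#' freedom.
#'
#' @param n sample size (>= 3).
#' @param alpha two-sided significance level (default 0.05).
#' @return the critical value; observed `G` above it flags an outlier.
#' @export
grubbsCritical <- function(n, alpha = 0.05) {
    if (n < 3L) stop("Grubbs critical value needs n >= 3")
    t <- qt(1 - alpha / (2 * n), df = n - 2)
    ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iteratively remove extreme statistical outliers
#'
#' Repeats the Grubbs test, removing the extreme point while `G` exceeds the
#' critical value, at most `maxRemovals` times (default 1: only the single
#' most extreme point can ever be dropped, a conservative reading of
#' "extreme statistical outliers"). Deterministic; returns the input
#' unchanged when nothing exceeds the critical value.
#'
#' @param x numeric vector.
#' @param alpha significance level per step.
#' @param maxRemovals cap on removed points.
#' @return list with `values` (kept) and `removed` (indices into the
#'   original `x`, possibly empty).
#' @export
removeOutliers <- function(x, alpha = 0.05, maxRemovals = 1L) {
    keep <- seq_along(x)
    removed <- integer()
    while (length(removed) < maxRemovals && length(keep) >= 3L &&
           is.finite(sd(x[keep])) && sd(x[keep]) > 0) {
        g <- grubbsStatistic(x[keep])
        if (g$G <= grubbsCritical(length(keep), alpha)) break
        removed <- c(removed, keep[g$index])
        keep <- keep[-g$index]
    }
    list(values = x[keep], removed = removed)
}

#' Unpaired two-sample t-test
#'
#' Two-sided test of equal means, either with pooled variance (Student,
#' the default and the classical reading of "unpaired t-test") or with
#' Satterthwaite degrees of freedom (Welch).
#'
#' @param x,y numeric vectors, each `n >= 2`.
#' @param variant `"student"` or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
unpairedT <- function(x, y, variant = c("student", "welch")) {
    variant <- match.arg(variant)
    if (length(x) < 2L || length(y) < 2L)
        stop("each group needs n >= 2")
    if (sd(c(x - mean(x), y - mean(y))) == 0)
        stop("degenerate groups: zero within-group variance")
    ht <- t.test(x, y, var.equal = variant == "student")
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Stratify a cohort table by Braak stage
#'
#' Keeps controls at Braak stage `<= controlMax` and cases at a stage in
#' `caseStages` (defaults: stage 0-3 controls versus stage 5-6 cases).
#' Records with a missing Braak stage are dropped with a warning; an empty
#' stratum is an error naming the stratum.
#'
#' @param records cohort table with columns `sample_id`, `group`, `braak`.
#' @param controlMax highest control Braak stage kept (default 3).
#' @param caseStages case Braak stages kept (default `5:6`).
#' @return the filtered table, with dropped ids in
#'   `attr(, "droppedMissingBraak")`.
#' @export
stratifyBraak <- function(records, controlMax = 3L, caseStages = 5:6) {
    miss <- is.na(records$braak)
    dropped <- records$sample_id[miss]
    if (length(dropped))
        warning("dropping sample(s) with missing Braak stage: ",
                paste(dropped, collapse = ", "))
    records <- records[!miss, , drop = FALSE]
    keep <- (records$group == "control" & records$braak <= controlMax) |
            (records$group == "case" & records$braak %in% caseStages)
    out <- records[keep, , drop = FALSE]
    if (!any(out$group == "control"))
        stop("empty control stratum (Braak 0-", controlMax, ")")
    if (!any(out$group == "case"))
        stop("empty case stratum (Braak ",
             paste(range(caseStages), collapse = "-"), ")")
    attr(out, "droppedMissingBraak") <- as.character(dropped)
    out
}

#' Compare a signature metric between cohort groups
#'
#' The full group-comparison pipeline in a fixed, logged order:
#' (1) drop SNP carriers (and indeterminate genotypes), (2) optionally
#' stratify by Braak stage, (3) Grubbs outlier removal within each group,
#' (4) unpaired t-test. The result records every exclusion. Records are
#' ordered by `sample_id` internally, so the output does not depend on the
#' input row order.
#'
#' @param records cohort table as produced by [analyzeCohort()] or
#'   [simulateSignatureCohort()]: columns `sample_id`, `group`
#'   (`control`/`case`), `braak`, `snp_status`, and the metric columns.
#' @param metric one of `"mismatch_rate"`, `"jump_rate"`, `"mm_T"`,
#'   `"mm_G"`, `"mm_C"`.
#' @param stratify logical; apply [stratifyBraak()] with its defaults.
#' @param alpha significance level used for the Grubbs exclusion step.
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @param maxRemovals Grubbs removal cap per group (default 1).
#' @return a [ComparisonResult-class].
#' @export
compareGroups <- function(records,
                          metric = c("mismatch_rate", "jump_rate",
                                     "mm_T", "mm_G", "mm_C"),
                          stratify = FALSE, alpha = 0.05,
                          variant = c("student", "welch"),
                          maxRemovals = 1L) {
    metric <- match.arg(metric)
    variant <- match.arg(variant)
    if (!metric %in% names(records))
        stop("records lack metric column '", metric, "'")
    records <- records[order(records$sample_id), , drop = FALSE]
    if (is.null(records$snp_status)) records$snp_status <- "non_carrier"

    exclSnp <- records$sample_id[records$snp_status == "carrier"]
    exclInd <- records$sample_id[records$snp_status == "indeterminate"]
    records <- records[records$snp_status == "non_carrier", , drop = FALSE]

    droppedBraak <- character()
    stratLabel <- "all"
    if (stratify) {
        records <- stratifyBraak(records)
        droppedBraak <- attr(records, "droppedMissingBraak")
        stratLabel <- "case Braak 5-6 vs control Braak 0-3"
    }

    exclOut <- character()
    for (g in c("control", "case")) {
        idx <- which(records$group == g)
        if (length(idx) >= 3L && sd(records[[metric]][idx]) > 0) {
            ro <- removeOutliers(records[[metric]][idx], alpha, maxRemovals)
            if (length(ro$removed)) {
                exclOut <- c(exclOut, records$sample_id[idx[ro$removed]])
                records <- records[-idx[ro$removed], , drop = FALSE]
            }
        }
    }

    xc <- records[[metric]][records$group == "control"]
    xa <- records[[metric]][records$group == "case"]
    if (length(xc) < 2L || length(xa) < 2L)
        stop("fewer than 2 usable samples in a group after exclusions")
    ht <- unpairedT(xc, xa, variant)

    new("ComparisonResult", metric = metric, stratification = stratLabel,
        nControl = length(xc), nCase = length(xa),
        meanControl = mean(xc), semControl = sd(xc) / sqrt(length(xc)),
        meanCase = mean(xa), semCase = sd(xa) / sqrt(length(xa)),
        tStatistic = ht$t, df = ht$df, pValue = ht$p, variant = variant,
        excludedSnp = as.character(exclSnp),
        excludedIndeterminate = as.character(exclInd),
        excludedOutliers = as.character(exclOut),
        droppedMissingBraak = as.character(droppedBraak))
}

#' @rdname ComparisonResult-class
#' @param object a `ComparisonResult`.
#' @export
setMethod("show", "ComparisonResult", function(object) {
    cat(sprintf("ComparisonResult [%s, %s]\n", object@metric,
                object@stratification))
    cat(sprintf("  control: mean %.5f +/- %.5f SEM (n = %d)\n",
                object@meanControl, object@semControl, object@nControl))
    cat(sprintf("  case:    mean %.5f +/- %.5f SEM (n = %d)\n",
                object@meanCase, object@semCase, object@nCase))
    cat(sprintf("  unpaired t-test (%s): t = %.4f, df = %.2f, p = %.4g\n",
                object@variant, object@tStatistic, object@df, object@pValue))
    excl <- c(object@excludedSnp, object@excludedIndeterminate,
              object@excludedOutliers, object@droppedMissingBraak)
    if (length(excl))
        cat("  excluded:", paste(excl, collapse = ", "), "\n")
})

#' @rdname ComparisonResult-class
#' @param x a `ComparisonResult`.
#' @export
pValue <- function(x) x@pValue

#' Serialize a ComparisonResult
#'
#' `comparisonAsList()` returns a plain list (JSON-ready);
#' `writeComparison()` writes JSON plus a one-row human-readable TSV.
#'
#' @param x a [ComparisonResult-class].
#' @return a named list.
#' @export
comparisonAsList <- function(x) {
    list(metric = x@metric, stratification = x@stratification,
         n_control = x@nControl, n_case = x@nCase,
         mean_control = x@meanControl, sem_control = x@semControl,
         mean_case = x@meanCase, sem_case = x@semCase,
         t = x@tStatistic, df = x@df, p_value = x@pValue,
         variant = x@variant, excluded_snp = x@excludedSnp,
         excluded_indeterminate = x@excludedIndeterminate,
         excluded_outliers = x@excludedOutliers,
         dropped_missing_braak = x@droppedMissingBraak)
}

#' @rdname comparisonAsList
#' @param jsonPath,tsvPath output paths (either may be `NULL`).
#' @export
writeComparison <- function(x, jsonPath = NULL, tsvPath = NULL) {
    if (!is.null(jsonPath))
        jsonlite::write_json(comparisonAsList(x), jsonPath,
                             auto_unbox = TRUE, digits = NA)
    if (!is.null(tsvPath)) {
        l <- comparisonAsList(x)
        flat <- lapply(l, function(v)
            if (length(v) == 0L) "" else paste(v, collapse = ","))
        write.table(as.data.frame(flat, stringsAsFactors = FALSE), tsvPath,
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(x)
}
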