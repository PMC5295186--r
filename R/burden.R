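# Distribution statistics over pathogenic-variant frequency profiles:
# rank-sum comparisons, fraction-below-threshold tables, outlier reports and
# the publication-support summary.

#' Wilcoxon rank-sum comparison of two frequency samples
#'
#' Two-sided rank-sum test with the tie-corrected normal approximation;
#' exact enumeration is used when both samples have at most eight
#' observations and there are no ties.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `method`, `statistic` (the rank-sum W), `p_value`,
#'   `n_a`, `n_b`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("rank_sum_test() requires two non-empty samples")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) <= 8L && length(b) <= 8L && !ties)
  ht <- stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                           correct = !exact)
  list(method = if (exact) "wilcoxon_exact" else "wilcoxon_normal_approx",
       statistic = unname(ht$statistic),
       p_value = min(1, unname(ht$p.value)),
       n_a = length(a), n_b = length(b))
}

#' Fraction of frequencies strictly below a threshold
#'
#' @param mafs Numeric vector of allele-frequency fractions (absent variants
#'   enter as 0 and therefore count as below every positive threshold).
#' @param threshold Positive frequency threshold (fraction).
#' @return `|{m : m < threshold}| / n`.
#' @export
fraction_below <- function(mafs, threshold) {
  stopifnot(threshold > 0)
  if (length(mafs) == 0L) stop("fraction_below() is undefined on empty input")
  mean(mafs < threshold)
}

#' Default candidate thresholds for frequency profiles
#' @return Numeric fractions for 0.0025%, 0.005%, 0.01%, 0.05%, 0.1%.
#' @export
default_maf_thresholds <- function() {
  c(`0.0025%` = 2.5e-5, `0.005%` = 5e-5, `0.01%` = 1e-4,
    `0.05%` = 5e-4, `0.1%` = 1e-3)
}

#' Frequency profile of a pathogenic variant set
#'
#' Summarizes how a set of (presumed pathogenic) variants is distributed in
#' the cohort: how many are absent, how many are singletons, what fraction
#' falls below each candidate threshold, and which variants exceed the
#' recurrence rule (allele count above `max_ac`) and therefore demand
#' literature review as founder candidates.
#'
#' @param variants Data frame with `ac_adj` and `an_adj` (identifier columns
#'   are carried into the outlier table).
#' @param thresholds Named numeric vector of threshold fractions.
#' @param max_ac Recurrence threshold for [flag_recurrent()].
#' @return An object of class `frequency_profile`: list with `n_total`,
#'   `n_absent`, `n_singleton`, `fraction_below` (named vector),
#'   `outliers` (data frame with a `maf` column), and the input `variants`
#'   with their computed `maf`.
#' @export
frequency_profile <- function(variants,
                              thresholds = default_maf_thresholds(),
                              max_ac = 3L) {
  n <- nrow(variants)
  if (n == 0L) {
    variants$maf <- numeric(0)
    return(structure(list(n_total = 0L, n_absent = 0L, n_singleton = 0L,
                          fraction_below = stats::setNames(rep(NA_real_,
                                                        length(thresholds)),
                                                    names(thresholds)),
                          outliers = variants, variants = variants),
                     class = "frequency_profile"))
  }
  v <- variants
  v$maf <- compute_maf(v)
  fb <- vapply(thresholds, function(t) fraction_below(v$maf, t), numeric(1))
  out <- flag_recurrent(v, max_ac)
  structure(list(n_total = n,
                 n_absent = sum(v$ac_adj == 0L),
                 n_singleton = sum(v$ac_adj == 1L),
                 fraction_below = fb,
                 outliers = out,
                 variants = v),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat(sprintf("<frequency_profile> %d variants: %d absent (%.1f%%), %d singletons (%.1f%%)\n",
              x$n_total, x$n_absent, 100 * x$n_absent / max(1, x$n_total),
              x$n_singleton, 100 * x$n_singleton / max(1, x$n_total)))
  if (length(x$fraction_below) && !all(is.na(x$fraction_below))) {
    cat("  fraction below threshold:\n")
    for (nm in names(x$fraction_below))
      cat(sprintf("    %-8s %.1f%%\n", nm, 100 * x$fraction_below[[nm]]))
  }
  cat(sprintf("  recurrent outliers (founder candidates): %d\n",
              nrow(x$outliers)))
  invisible(x)
}

#' Threshold report with mandatory-review outlier lists
#'
#' For each candidate threshold, reports the share of the pathogenic set
#' captured below it and lists every pathogenic variant sitting above it
#' with its allele count and frequency, flagged as requiring literature
#' review (the expected explanation being founder effects or mutational hot
#' spots).
#'
#' @param profile A `frequency_profile`.
#' @param candidate_thresholds Named numeric vector of threshold fractions.
#' @return List with `summary` (data frame: threshold, `n_below`, `n_above`,
#'   `pct_captured`) and `outliers` (one data frame per threshold, each row
#'   flagged `requires_literature_review = TRUE`).
#' @export
threshold_report <- function(profile,
                             candidate_thresholds = default_maf_thresholds()) {
  stopifnot(inherits(profile, "frequency_profile"))
  v <- profile$variants
  rows <- lapply(seq_along(candidate_thresholds), function(i) {
    t <- candidate_thresholds[[i]]
    data.frame(threshold = t,
               threshold_label = names(candidate_thresholds)[i] %||%
                 format_maf_pct(t),
               n_below = sum(v$maf < t),
               n_above = sum(v$maf >= t),
               pct_captured = 100 * mean(v$maf < t),
               stringsAsFactors = FALSE)
  })
  outliers <- lapply(candidate_thresholds, function(t) {
    above <- v[v$maf >= t, , drop = FALSE]
    above <- above[order(-above$maf), , drop = FALSE]
    if (nrow(above) > 0L) above$requires_literature_review <- TRUE
    rownames(above) <- NULL
    above
  })
  list(summary = do.call(rbind, rows), outliers = outliers)
}

#' Publication-support summary for outlier-frequency variants
#'
#' Compares publication counts between consensus pathogenic and consensus
#' benign variants above a frequency threshold: per-class five-number
#' summaries (linear-interpolation quartiles, whiskers at min/max),
#' zero-publication counts, the within-class correlation between frequency
#' and publication count, and a rank-sum comparison of the two classes.
#'
#' @param records Data frame with columns `class` (`"pathogenic"` /
#'   `"benign"`), `maf` (fraction) and `publication_count`.
#' @param method Correlation estimator, `"pearson"` (product-moment,
#'   default) or `"spearman"`.
#' @return List with `per_class` (data frame of n, five-number summary,
#'   `n_zero`, `r`, `r_p_value`; correlation is `NA` for classes with fewer
#'   than three records) and `class_comparison` (rank-sum result for
#'   pathogenic vs benign counts, `NULL` unless both classes present).
#' @export
publication_summary <- function(records, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(records$publication_count >= 0))
  classes <- unique(records$class)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    r <- records[records$class == cl, , drop = FALSE]
    q <- stats::quantile(r$publication_count, c(0, .25, .5, .75, 1),
                         type = 7, names = FALSE)
    if (nrow(r) >= 3L && stats::sd(r$maf) > 0 &&
        stats::sd(r$publication_count) > 0) {
      ct <- stats::cor.test(r$maf, r$publication_count, method = method,
                            exact = FALSE)
      rr <- unname(ct$estimate); rp <- ct$p.value
    } else {
      rr <- NA_real_; rp <- NA_real_
    }
    data.frame(class = cl, n = nrow(r),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               n_zero = sum(r$publication_count == 0),
               r = rr, r_p_value = rp, stringsAsFactors = FALSE)
  }))
  comparison <- NULL
  if (all(c("pathogenic", "benign") %in% classes)) {
    comparison <- rank_sum_test(
      records$publication_count[records$class == "pathogenic"],
      records$publication_count[records$class == "benign"])
  }
  list(per_class = per_class, class_comparison = comparison)
}
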