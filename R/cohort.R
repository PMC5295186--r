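# Cohort allele-frequency accounting: quality/depth filters, MAF
# computation, frequency binning and the recurrence (founder-candidate)
# rule. MAFs are plain fractions internally; display helpers render the
# percent style used in reports (two significant figures).

#' Default allele-frequency bins
#'
#' The five left-closed/right-open bins used throughout the burden reports:
#' `<0.005%`, `0.005-0.01%`, `0.01-0.05%`, `0.05-0.1%`, `>=0.1%`.
#'
#' @return Data frame with columns `label`, `lower`, `upper` (fractions;
#'   upper bound of the top bin is `Inf`).
#' @export
default_frequency_bins <- function() {
  data.frame(
    label = c("<0.005%", "0.005-0.01%", "0.01-0.05%", "0.05-0.1%", ">=0.1%"),
    lower = c(0, 5e-5, 1e-4, 5e-4, 1e-3),
    upper = c(5e-5, 1e-4, 5e-4, 1e-3, Inf),
    stringsAsFactors = FALSE
  )
}

#' Cohort depth and quality filter
#'
#' A variant record qualifies when its filter status is `PASS` and the locus
#' was genotyped in at least `min_total_alleles` alleles (adjusted allele
#' number), ensuring enough cohort depth for an accurate frequency estimate.
#' The depth floor is inclusive.
#'
#' @param variants Data frame with columns `filter_status` and `an_adj`.
#' @param min_total_alleles Minimum adjusted allele number (default 80000).
#' @return Logical vector, one element per record.
#' @export
passes_cohort_filters <- function(variants, min_total_alleles = 80000L) {
  variants$filter_status == "PASS" & variants$an_adj >= min_total_alleles
}

#' Minor allele frequency from adjusted counts
#'
#' @param variants Data frame with `ac_adj` and `an_adj` columns (or two
#'   numeric vectors via `ac_adj`/`an_adj` directly).
#' @return Numeric vector of `ac_adj / an_adj` in `[0, 1]`.
#' @export
compute_maf <- function(variants) {
  ac <- variants$ac_adj
  an <- variants$an_adj
  if (any(an == 0))
    stop("undefined allele frequency: an_adj is zero for ",
         sum(an == 0), " record(s)")
  if (any(ac > an)) stop("ac_adj exceeds an_adj")
  ac / an
}

#' Assign allele frequencies to bins
#'
#' Bins are left-closed, right-open, covering `[0, Inf)`, so every
#' non-negative frequency maps to exactly one label.
#'
#' @param maf Numeric vector of allele-frequency fractions.
#' @param bins Bin table as from [default_frequency_bins()].
#' @return Character vector of bin labels.
#' @export
bin_maf <- function(maf, bins = default_frequency_bins()) {
  stopifnot(all(maf >= 0))
  idx <- findInterval(maf, bins$lower)
  bins$label[idx]
}

#' Flag recurrent (founder-candidate) variants
#'
#' Variants observed in more than `max_ac` alleles are outliers of the
#' pathogenic frequency distribution and require mandatory literature review;
#' in practice they are dominated by published founder mutations.
#'
#' @param variants Data frame with `ac_adj`.
#' @param max_ac Recurrence threshold; records with `ac_adj > max_ac` are
#'   flagged (default 3, i.e. "observed in more than three individuals").
#' @return The flagged subset, sorted by `ac_adj` descending.
#' @export
flag_recurrent <- function(variants, max_ac = 3L) {
  out <- variants[variants$ac_adj > max_ac, , drop = FALSE]
  out <- out[order(-out$ac_adj), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene burden table of NMD-triggering variants
#'
#' Counts filter-passing, observed (`ac_adj >= 1`) NMD_positive variants per
#' gene per frequency bin; absent variants (allele count zero) are excluded
#' from the bins and reported in a separate column.
#'
#' @param variants Annotated variant data frame with columns `gene`,
#'   `ac_adj`, `an_adj`, `filter_status`, `nmd_status` (e.g. from
#'   [annotate_nmd()] joined with cohort records).
#' @param bins Bin table as from [default_frequency_bins()].
#' @param min_total_alleles Depth floor passed to [passes_cohort_filters()].
#' @return Data frame with one row per gene: `gene`, one count column per
#'   bin label, `n_absent`, and `n_observed` (the row total over the bins).
#' @export
gene_burden_table <- function(variants, bins = default_frequency_bins(),
                              min_total_alleles = 80000L) {
  keep <- passes_cohort_filters(variants, min_total_alleles) &
    variants$nmd_status == "NMD_positive"
  v <- variants[keep, , drop = FALSE]
  genes <- sort(unique(v$gene))
  obs <- v[v$ac_adj >= 1L, , drop = FALSE]
  lab <- bin_maf(compute_maf(obs), bins)
  counts <- table(factor(obs$gene, levels = genes),
                  factor(lab, levels = bins$label))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (b in bins$label) out[[b]] <- as.integer(counts[, b])
  out$n_absent <- as.integer(table(factor(v$gene[v$ac_adj == 0L],
                                          levels = genes)))
  out$n_observed <- as.integer(rowSums(counts))
  rownames(out) <- NULL
  out
}

#' Format a frequency fraction the way burden reports print it
#'
#' Two significant figures, as a percentage (`2.7e-4` -> `"0.027%"`).
#'
#' @param maf Numeric vector of fractions.
#' @return Character vector.
#' @export
format_maf_pct <- function(maf) {
  ifelse(maf == 0, "0", paste0(signif(maf * 100, 2), "%"))
}
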