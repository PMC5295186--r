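# Packaged reference tables.
#
# Machine-readable transcriptions of published frequency summaries for a
# large exome-aggregation cohort (~60,700 exomes, ~121,000 alleles per
# well-covered site): the fourteen recurrent/founder pathogenic BRCA1/2
# variants with their allele counts, the per-gene frequency-bin table for 79
# loss-of-function-mechanism genes across three clinical areas, and the
# 74-variant hypertrophic-cardiomyopathy "gold standard" missense set.
# Loaders verify an md5 checksum so any edit to a transcription fails
# loudly.

FIXTURE_MD5 <- c(
  brca_founder_variants.tsv = "2a2b95b7996bc7477cb1a3345f70a75d",
  nmd_burden_by_gene.tsv = "6b5da40440170d6ad0c1ad7b6e7dd415",
  hcm_gold_standard_missense.tsv = "b5b2bb6bb570e70b7c51014ed45719ff"
)

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "nmdburden")
  if (p == "") stop("fixture ", name, " not found")
  got <- unname(tools::md5sum(p))
  if (!identical(got, unname(FIXTURE_MD5[[name]])))
    stop("fixture ", name, " fails its checksum (", got,
         "); the transcription has been modified")
  p
}

#' Recurrent/founder pathogenic BRCA1/2 variants
#'
#' The fourteen pathogenic BRCA1/2 variants observed in more than three
#' cohort individuals, with printed allele counts and frequencies; all are
#' published founder or common recurrent variants. `an_adj` is
#' reconstructed as `round(allele_count / maf)`.
#'
#' @return Data frame with `gene`, `hgvs_c`, `effect`, `type`, `ac_adj`,
#'   `an_adj`, `maf_pct`.
#' @export
load_brca_founder_variants <- function() {
  x <- read_tsv_file(fixture_path("brca_founder_variants.tsv"))
  x$ac_adj <- as.integer(x$allele_count)
  x$an_adj <- as.integer(round(x$allele_count / (x$maf_pct / 100)))
  x
}

#' Reconstructed BRCA1/2 pathogenic variant set
#'
#' The full 1364-variant pathogenic set at the allele-count resolution the
#' published profile reports: 1163 variants absent from the cohort, 150
#' singletons, 37 at allele count 2-3, and the fourteen printed
#' founder/recurrent variants. Synthesized rows (everything but the
#' fourteen) carry the nominal cohort allele number of 121,000; only their
#' count class, not their identity, is published.
#'
#' @return Data frame with `gene`, `ac_adj`, `an_adj`, `filter_status` and
#'   an `is_founder_row` flag.
#' @export
load_brca_pathogenic_set <- function() {
  founders <- load_brca_founder_variants()
  an0 <- 121000L
  synth <- function(n, ac) if (n > 0L)
    data.frame(gene = "BRCA1/2", ac_adj = as.integer(ac), an_adj = an0,
               stringsAsFactors = FALSE) [rep(1L, n), , drop = FALSE]
    else NULL
  out <- rbind(
    data.frame(gene = founders$gene, ac_adj = founders$ac_adj,
               an_adj = founders$an_adj, stringsAsFactors = FALSE),
    synth(19L, 2L), synth(18L, 3L), synth(150L, 1L), synth(1163L, 0L))
  out$filter_status <- "PASS"
  out$is_founder_row <- c(rep(TRUE, nrow(founders)),
                          rep(FALSE, nrow(out) - nrow(founders)))
  rownames(out) <- NULL
  out
}

#' Per-gene frequency-bin reference table
#'
#' NMD-triggering variant counts per gene per allele-frequency bin for 79
#' genes with established loss-of-function disease mechanisms, grouped into
#' hereditary cancer (33 genes incl. BRCA1/2), primary ciliary dyskinesia
#' (25) and arrhythmia/cardiomyopathy (21).
#'
#' @return Data frame with `clinical_area`, `gene`, `inheritance` and one
#'   count column per bin.
#' @export
load_gene_burden_reference <- function() {
  read_tsv_file(fixture_path("nmd_burden_by_gene.tsv"))
}

BURDEN_BIN_COLS <- c("n_lt_0.005", "n_0.005_0.01", "n_0.01_0.05",
                     "n_0.05_0.1", "n_ge_0.1")

#' Summarize a gene-bin table against a frequency threshold
#'
#' @param tbl Rows of the table from [load_gene_burden_reference()].
#' @return Named list with `n_total` (all binned variants), `n_below_0.01`,
#'   `n_above_0.01` (bins at or above 0.01%), and `n_above_0.05`.
#' @export
burden_bin_summary <- function(tbl) {
  tot <- sum(as.matrix(tbl[, BURDEN_BIN_COLS]))
  above01 <- sum(as.matrix(tbl[, BURDEN_BIN_COLS[3:5]]))
  above05 <- sum(as.matrix(tbl[, BURDEN_BIN_COLS[4:5]]))
  list(n_total = tot, n_below_0.01 = tot - above01,
       n_above_0.01 = above01, n_above_0.05 = above05)
}

#' Hypertrophic-cardiomyopathy gold-standard missense set
#'
#' A previously curated list of 74 missense variants (41 pathogenic, 33
#' benign/likely benign) in six sarcomere genes, with cohort frequencies and
#' two flags: `low_an` (locus covered by fewer than 80,000 alleles) and
#' `non_pass` (failed the cohort's variant-calling quality filter).
#'
#' @return Data frame with `gene`, `hgvs_c`, `effect_p`, `classification`,
#'   `maf_pct`, `low_an`, `non_pass`.
#' @export
load_hcm_gold_standard <- function() {
  read_tsv_file(fixture_path("hcm_gold_standard_missense.tsv"))
}

#' Apply the depth and quality filters to the gold-standard set
#'
#' Drops variants at loci under the allele-number floor and variants failing
#' the quality filter, mirroring [passes_cohort_filters()] on a table that
#' carries flags instead of raw AN/FILTER values.
#'
#' @param x Table from [load_hcm_gold_standard()].
#' @return The filtered subset.
#' @export
gold_standard_filtered <- function(x) {
  x[x$low_an == 0 & x$non_pass == 0, , drop = FALSE]
}
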