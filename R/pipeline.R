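# End-to-end driver: annotate -> filter -> consensus -> burden -> stats.
# Inputs may be file paths (VCF / GFF3 / FASTA / TSV) or the in-memory
# objects the readers produce; every stage logs its input and surviving
# record counts so the final reports can be audited against the raw input.

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file not found: ", x)
    return(reader(x))
  }
  x
}

#' Run the full burden-analysis pipeline
#'
#' Annotates every cohort variant with its consequence and NMD fate on the
#' clinically relevant transcript, applies the depth/quality filters,
#' aggregates submitter assertions into consensus calls, assembles the
#' pathogenic set (consensus plus adjudicated plus NMD-triggering in
#' loss-of-function-mechanism genes), and computes the frequency profile,
#' per-gene burden table, threshold report and (when publication counts are
#' supplied) the publication-support summary.
#'
#' @param inputs List with elements `vcf`, `transcripts`, `genome`, and
#'   optionally `submissions`, `adjudications`, `publications`, `overrides`;
#'   each a path or an object of the matching type.
#' @param config A `pipeline_config` (see [default_pipeline_config()] /
#'   [read_config()]). When `lof_mechanism_genes` is empty, every annotated
#'   gene is treated as loss-of-function-mechanism.
#' @return List of class `burden_report` with `annotated`, `filtered`,
#'   `consensus`, `pathogenic_set`, `profile`, `burden_table`,
#'   `threshold_report`, `publication_summary`, and `log` (a data frame of
#'   per-stage record counts).
#' @export
run_pipeline <- function(inputs, config = default_pipeline_config()) {
  genome <- resolve_input(inputs$genome, read_genome_fasta)
  transcripts <- resolve_input(inputs$transcripts, read_transcripts_gff3)
  variants <- resolve_input(inputs$vcf, read_cohort_vcf)
  submissions <- resolve_input(inputs$submissions, read_tsv_file)
  adjudications <- resolve_input(inputs$adjudications, read_tsv_file)
  publications <- resolve_input(inputs$publications, read_tsv_file)
  overrides <- resolve_input(inputs$overrides, read_tsv_file)
  if (is.null(genome) || is.null(transcripts) || is.null(variants))
    stop("inputs must provide at least vcf, transcripts and genome")

  log <- data.frame(stage = character(), n_in = integer(), n_out = integer(),
                    stringsAsFactors = FALSE)
  note <- function(stage, n_in, n_out) {
    log <<- rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                                  stringsAsFactors = FALSE))
  }

  annotated <- annotate_nmd(variants, transcripts, genome, overrides,
                            escape_window = config$escape_window)
  note("annotate", nrow(variants), nrow(annotated))

  keep <- passes_cohort_filters(annotated, config$min_total_alleles)
  filtered <- annotated[keep, , drop = FALSE]
  note("depth_quality_filter", nrow(annotated), nrow(filtered))

  consensus <- NULL
  if (!is.null(submissions) && nrow(submissions) > 0L) {
    consensus <- consensus_classification(submissions,
                                          config$trusted_submitters)
    note("consensus", nrow(submissions), nrow(consensus))
  }

  lof_genes <- config$lof_mechanism_genes
  if (length(lof_genes) == 0L)
    lof_genes <- unique(filtered$gene)
  pathogenic <- assemble_pathogenic_set(consensus, adjudications, filtered,
                                        lof_genes)
  note("pathogenic_set", nrow(filtered), nrow(pathogenic))

  filtered$key <- variant_key(filtered$chrom, filtered$pos, filtered$ref,
                              filtered$alt)
  path_variants <- filtered[filtered$key %in% pathogenic$key, , drop = FALSE]
  profile <- frequency_profile(path_variants,
                               max_ac = config$recurrence_max_ac)
  thresholds <- unlist(config$thresholds)
  report <- threshold_report(profile, thresholds)
  burden <- gene_burden_table(filtered,
                              min_total_alleles = config$min_total_alleles)

  pub_summary <- NULL
  if (!is.null(publications) && nrow(publications) > 0L) {
    pub_summary <- publication_summary(publications,
                                       method = config$correlation_method)
  }

  structure(list(annotated = annotated, filtered = filtered,
                 consensus = consensus, pathogenic_set = pathogenic,
                 profile = profile, burden_table = burden,
                 threshold_report = report,
                 publication_summary = pub_summary, log = log),
            class = "burden_report")
}

#' Write a pipeline report bundle to disk
#'
#' Emits TSVs for the annotated variants, consensus calls, burden table and
#' stage log, plus a machine-readable JSON summary of the frequency profile
#' and threshold report.
#'
#' @param bundle A `burden_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "burden_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name) {
    if (is.null(x)) return()
    p <- file.path(dir, name)
    write_tsv_file(x, p)
    files <<- c(files, p)
  }
  emit(bundle$annotated, "annotated_variants.tsv")
  emit(bundle$consensus, "consensus_calls.tsv")
  emit(bundle$pathogenic_set, "pathogenic_set.tsv")
  emit(bundle$burden_table, "gene_burden_table.tsv")
  emit(bundle$threshold_report$summary, "threshold_summary.tsv")
  emit(bundle$log, "stage_log.tsv")
  summary <- list(
    n_total = bundle$profile$n_total,
    n_absent = bundle$profile$n_absent,
    n_singleton = bundle$profile$n_singleton,
    fraction_below = as.list(bundle$profile$fraction_below),
    n_outliers = nrow(bundle$profile$outliers)
  )
  if (!is.null(bundle$publication_summary))
    summary$publication_classes <- bundle$publication_summary$per_class
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA)
  files <- c(files, jp)
  invisible(files)
}
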