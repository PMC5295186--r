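# Format readers and writers.
#
# FASTA via Biostrings, GFF3/BED12 via rtracklayer, VCF via vcfR; the VCF
# and GFF3 writers emit the line formats directly. All readers return the
# package's plain containers (named character genome, transcript_model
# lists, data frames), and every reader/writer pair round-trips.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences (names truncated
#'   at the first whitespace).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(genome)), path,
                              width = 70L)
  invisible(path)
}

#' Write transcript models as GFF3
#'
#' Emits gene / mRNA / exon / CDS features with ID/Parent links; the mRNA
#' row carries a `clinically_relevant` attribute.
#'
#' @param transcripts Named list of `transcript_model` objects.
#' @param path Output file.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (tx in transcripts) {
    lo <- min(tx$exon_start); hi <- max(tx$exon_end)
    gid <- paste0("gene:", tx$gene); mid <- paste0("tx:", tx$transcript_id)
    lines <- c(lines,
      paste(tx$chrom, "nmdburden", "gene", lo, hi, ".", tx$strand, ".",
            paste0("ID=", gid, ";Name=", tx$gene), sep = "\t"),
      paste(tx$chrom, "nmdburden", "mRNA", lo, hi, ".", tx$strand, ".",
            paste0("ID=", mid, ";Parent=", gid, ";Name=", tx$transcript_id,
                   ";clinically_relevant=",
                   if (tx$clinically_relevant) "1" else "0"), sep = "\t"))
    for (j in seq_along(tx$exon_start)) {
      lines <- c(lines,
        paste(tx$chrom, "nmdburden", "exon", tx$exon_start[j], tx$exon_end[j],
              ".", tx$strand, ".",
              paste0("ID=", mid, ":exon", j, ";Parent=", mid), sep = "\t"))
      cs <- max(tx$exon_start[j], tx$cds_start)
      ce <- min(tx$exon_end[j], tx$cds_end)
      if (cs <= ce) {
        lines <- c(lines,
          paste(tx$chrom, "nmdburden", "CDS", cs, ce, ".", tx$strand, "0",
                paste0("ID=", mid, ":cds", j, ";Parent=", mid), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Expects mRNA features with exon and CDS children linked by Parent (the
#' dialect written by [write_transcripts_gff3()] and common annotation
#' exports). One transcript per mRNA feature.
#'
#' @param path GFF3 file.
#' @return Named list of `transcript_model` objects.
#' @export
read_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  md$Parent <- vapply(md$Parent, function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]]), character(1))
  mrna <- md[md$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna) == 0L) stop("format error: no mRNA features in ", path)
  genes <- md[md$type == "gene", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(mrna))) {
    mid <- mrna$ID[i]
    kids <- md[!is.na(md$Parent) & md$Parent == mid, , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L)
      stop("format error: mRNA ", mid, " has no exon features")
    if (nrow(cds) == 0L)
      stop("format error: mRNA ", mid, " has no CDS features")
    ord <- order(ex$start)
    gene <- if ("Name" %in% names(genes) && mrna$Parent[i] %in% genes$ID) {
      genes$Name[match(mrna$Parent[i], genes$ID)]
    } else sub("^gene:", "", mrna$Parent[i] %||% mid)
    rel <- if ("clinically_relevant" %in% names(mrna))
      !identical(mrna$clinically_relevant[i], "0") else TRUE
    name <- if ("Name" %in% names(mrna) && !is.na(mrna$Name[i]))
      mrna$Name[i] else sub("^tx:", "", mid)
    tx <- transcript_model(
      transcript_id = name, gene = gene,
      chrom = as.character(mrna$seqnames[i]),
      strand = as.character(mrna$strand[i]),
      exon_start = ex$start[ord], exon_end = ex$end[ord],
      cds_start = min(cds$start), cds_end = max(cds$end),
      clinically_relevant = rel)
    out[[tx$transcript_id]] <- tx
  }
  out
}

#' Read transcript models from BED12
#'
#' Blocks become exons, thickStart/thickEnd the CDS; BED's 0-based
#' half-open coordinates are converted to 1-based inclusive. The name field
#' doubles as transcript and gene identifier (BED12 carries no gene column).
#'
#' @param path BED12 file.
#' @return Named list of `transcript_model` objects.
#' @export
read_transcripts_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- list()
  for (i in seq_along(gr)) {
    bl <- gr$blocks[[i]]
    abs_start <- GenomicRanges::start(gr)[i] - 1L + IRanges::start(bl)
    abs_end <- GenomicRanges::start(gr)[i] - 1L + IRanges::end(bl)
    thick <- gr$thick[i]
    name <- if (!is.null(gr$name)) gr$name[i] else paste0("bed_tx_", i)
    tx <- transcript_model(
      transcript_id = name, gene = name,
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      exon_start = abs_start, exon_end = abs_end,
      cds_start = IRanges::start(thick), cds_end = IRanges::end(thick))
    out[[tx$transcript_id]] <- tx
  }
  out
}

#' Write a cohort variant table as VCF
#'
#' One record per alternate allele, with `AC_Adj`/`AN_Adj` INFO fields and
#' the filter status in FILTER.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `filter_status`, `ac_adj`, `an_adj`.
#' @param path Output file.
#' @export
write_cohort_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC_Adj,Number=A,Type=Integer,Description=\"Adjusted allele count\">",
    "##INFO=<ID=AN_Adj,Number=1,Type=Integer,Description=\"Adjusted total alleles\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants) == 0L) character(0) else
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt, ".",
          variants$filter_status,
          paste0("AC_Adj=", variants$ac_adj, ";AN_Adj=", variants$an_adj),
          sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort variant VCF
#'
#' Parses FILTER and the adjusted allele count/number INFO fields;
#' multi-allelic records are decomposed into one row per alternate allele
#' (AC is per allele, AN shared across the site).
#'
#' @param path VCF file.
#' @param info_ac,info_an INFO keys holding the allele count (A-typed) and
#'   total allele number; set to `"AC"`/`"AN"` for callsets without adjusted
#'   fields.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `filter_status`,
#'   `ac_adj`, `an_adj`.
#' @export
read_cohort_vcf <- function(path, info_ac = "AC_Adj", info_an = "AN_Adj") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)) && length(fix) > 0L)
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (is.null(dim(fix)) || nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), filter_status = character(),
                      ac_adj = integer(), an_adj = integer(),
                      stringsAsFactors = FALSE))
  }
  ac_raw <- vcfR::extract.info(vcf, element = info_ac)
  an_raw <- vcfR::extract.info(vcf, element = info_an)
  if (all(is.na(ac_raw)))
    stop("format error: INFO key ", info_ac, " missing from ", path)
  if (all(is.na(an_raw)))
    stop("format error: INFO key ", info_an, " missing from ", path)

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    acs <- as.integer(strsplit(ac_raw[i], ",", fixed = TRUE)[[1L]])
    if (length(acs) != length(alts))
      stop("format error at record ", i, ": ", info_ac,
           " has ", length(acs), " values for ", length(alts), " alt allele(s)")
    data.frame(chrom = unname(fix[i, "CHROM"]),
               pos = as.integer(fix[i, "POS"]),
               ref = unname(fix[i, "REF"]), alt = unname(alts),
               filter_status = unname(fix[i, "FILTER"]),
               ac_adj = acs, an_adj = as.integer(an_raw[i]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (any(out$ac_adj > out$an_adj))
    stop("format error: ac_adj exceeds an_adj in ", path)
  rownames(out) <- NULL
  out
}

#' Read a tab-separated table
#' @param path TSV file with a header row.
#' @return Data frame (no factor conversion, `#` is not a comment char).
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "", check.names = FALSE)
}

#' Write a tab-separated table
#' @param x Data frame.
#' @param path Output file.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All thresholds the analysis depends on, in one place: the 80,000-allele
#' depth floor, the allele-count recurrence rule (more than three alleles),
#' the five frequency bins, the 50-nt NMD escape window, the
#' trusted-submitter list and the loss-of-function-mechanism gene list.
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    min_total_alleles = 80000L,
    recurrence_max_ac = 3L,
    escape_window = 50L,
    bin_lowers = c(0, 5e-5, 1e-4, 5e-4, 1e-3),
    thresholds = as.list(default_maf_thresholds()),
    trusted_submitters = character(0),
    lof_mechanism_genes = character(0),
    correlation_method = "pearson",
    seed = 1L
  ), class = "pipeline_config")
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' Values found in the file override [default_pipeline_config()]; YAML and
#' JSON files with the same content yield the same configuration.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config error: unsupported config extension .", ext))
  cfg <- utils::modifyList(unclass(default_pipeline_config()), raw)
  if (cfg$min_total_alleles <= 0 || cfg$recurrence_max_ac <= 0 ||
      cfg$escape_window <= 0)
    stop("config error: thresholds must be positive")
  if (is.unsorted(unlist(cfg$bin_lowers), strictly = TRUE))
    stop("config error: bin edges must be strictly increasing")
  class(cfg) <- "pipeline_config"
  cfg
}
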