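# Consequence calling and NMD-fate classification.
#
# A truncating variant is predicted to trigger nonsense-mediated decay
# (NMD_positive) unless the premature termination codon (PTC) lands in the
# final exon, within 50 nt upstream of the final exon-exon junction, or the
# variant disrupts the consensus splice dinucleotides of the final intron;
# variants with published experimental evidence of escape are overridden to
# NMD_negative. Everything downstream (frequency profiles, burden tables)
# keys off this binary status.

CONSEQUENCE_CATEGORIES <- c("nonsense", "frameshift", "splice_donor",
                            "splice_acceptor", "missense", "synonymous",
                            "inframe_indel", "intronic_other", "other")

NMD_REASONS <- c("qualifying_ptc", "non_final_intron_splice", "last_exon",
                 "within_50bp_of_final_junction", "final_intron_splice",
                 "single_exon", "no_ptc_found", "experimental_escape_override",
                 "non_truncating")

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt Variant fields (vectorized).
#' @return Character key `chrom:pos:ref:alt`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Length of the common prefix of two allele strings (VCF anchor handling).
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1L]][seq_len(n)]
  bv <- strsplit(b, "")[[1L]][seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Genomic positions actually changed by the variant, after trimming the
# shared VCF anchor prefix. Pure insertions report the anchor and the next
# base so boundary-spanning insertions still hit the splice branch.
changed_positions <- function(pos, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  k <- common_prefix_len(ref, alt)
  if (lr == la) return(pos:(pos + lr - 1L))
  if (k >= lr) return(c(pos + lr - 1L, pos + lr))  # pure insertion
  (pos + k):(pos + lr - 1L)
}

# Transcript-space edit for a variant whose full REF footprint is exonic:
# mRNA start of the replaced block plus transcription-direction alleles.
transcript_edit <- function(pos, ref, alt, tx) {
  lr <- nchar(ref)
  fp <- pos:(pos + lr - 1L)
  m <- genomic_to_mrna(fp, tx)
  if (anyNA(m)) return(NULL)
  if (tx$strand == "+") {
    list(m_start = m[1L], ref_tx = ref, alt_tx = alt)
  } else {
    list(m_start = m[lr], ref_tx = revcomp(ref), alt_tx = revcomp(alt))
  }
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Call the molecular consequence of a variant on a transcript
#'
#' Classifies a single alternate allele against one transcript: coding SNVs
#' by mutant-codon translation (nonsense / missense / synonymous), coding
#' indels by frame (frameshift when the length change is not a multiple of
#' three, else in-frame), splice-dinucleotide hits as donor/acceptor (taking
#' precedence for indels spanning an exon-intron boundary), remaining
#' intronic positions as `intronic_other`, and anything else as `other`.
#'
#' @param variant List or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param tx A `transcript_model` (the clinically relevant transcript).
#' @param genome Genome as a named character vector.
#' @return A list of class `consequence_call` with fields `key`,
#'   `transcript_id`, `category`, `ptc_mrna_pos` (first base of the
#'   variant-created stop, `NA` unless nonsense; frameshifts are located
#'   lazily by [locate_ptc()]) and `intron_index` (`NA` unless splice).
#' @export
call_consequence <- function(variant, tx, genome) {
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  if (chrom != tx$chrom)
    stop("variant chromosome ", chrom, " does not match transcript ", tx$chrom)
  obs <- seq_at(genome, chrom, pos, pos + nchar(ref) - 1L)
  if (!identical(toupper(obs), ref))
    stop("REF mismatch at ", chrom, ":", pos, ": expected ", ref,
         " but genome has ", obs)

  res <- list(key = variant_key(chrom, pos, ref, alt),
              transcript_id = tx$transcript_id,
              chrom = chrom, pos = pos, ref = ref, alt = alt,
              category = "other",
              ptc_mrna_pos = NA_integer_, intron_index = NA_integer_)
  class(res) <- "consequence_call"

  ch <- changed_positions(pos, ref, alt)

  # Splice branch first: any changed base inside a consensus dinucleotide.
  it <- intron_table(tx)
  if (nrow(it) > 0L) {
    for (k in seq_len(nrow(it))) {
      if (any(ch %in% c(it$donor1[k], it$donor2[k]))) {
        res$category <- "splice_donor"; res$intron_index <- it$intron[k]
        return(res)
      }
      if (any(ch %in% c(it$acceptor1[k], it$acceptor2[k]))) {
        res$category <- "splice_acceptor"; res$intron_index <- it$intron[k]
        return(res)
      }
    }
  }

  m_ch <- genomic_to_mrna(ch, tx)
  span_lo <- min(tx$exon_start); span_hi <- max(tx$exon_end)
  if (all(is.na(m_ch))) {
    res$category <- if (all(ch >= span_lo & ch <= span_hi)) "intronic_other" else "other"
    return(res)
  }
  if (anyNA(m_ch)) return(res)  # straddles a boundary outside the dinucleotides

  cm <- cds_mrna_span(tx)
  if (any(m_ch < cm[1L] | m_ch > cm[2L])) return(res)  # exonic, outside CDS

  ed <- transcript_edit(pos, ref, alt, tx)
  if (is.null(ed)) return(res)  # footprint leaves the exon; unclassifiable

  lr <- nchar(ref); la <- nchar(alt)
  if (lr != la) {
    res$category <- if ((abs(la - lr) %% 3L) != 0L) "frameshift" else "inframe_indel"
    return(res)
  }

  # Substitution fully inside the CDS: translate the affected codons.
  cds <- spliced_cds(tx, genome)
  rel_start <- ed$m_start - cm[1L] + 1L
  rel_end <- rel_start + lr - 1L
  mut_cds <- paste0(substr(cds, 1L, rel_start - 1L), ed$alt_tx,
                    substr(cds, rel_end + 1L, nchar(cds)))
  first_codon <- (rel_start - 1L) %/% 3L + 1L
  last_codon <- (rel_end - 1L) %/% 3L + 1L
  cats <- character(0)
  for (ci in first_codon:last_codon) {
    from <- 3L * (ci - 1L) + 1L
    ref_aa <- translate_codon(substr(cds, from, from + 2L))
    mut_aa <- translate_codon(substr(mut_cds, from, from + 2L))
    if (is.na(ref_aa) || is.na(mut_aa)) next
    if (mut_aa == "*" && ref_aa != "*") {
      res$category <- "nonsense"
      res$ptc_mrna_pos <- cm[1L] + from - 1L
      return(res)
    }
    cats <- c(cats, if (mut_aa == ref_aa) "synonymous" else "missense")
  }
  res$category <- if (any(cats == "missense")) "missense" else "synonymous"
  res
}

#' Locate the premature termination codon of a truncating variant
#'
#' For nonsense variants, the mRNA position of the first base of the
#' variant-created stop codon. For frameshifts, reconstructs the mutant
#' spliced transcript, translates from the CDS start in the shifted frame
#' through the 3' UTR, and maps the first stop codon back to reference-frame
#' mRNA coordinates; returns `NA` when no stop occurs before the transcript
#' end.
#'
#' @param call A `consequence_call` with category nonsense or frameshift.
#' @param tx The matching `transcript_model`.
#' @param genome Genome as a named character vector.
#' @return Integer mRNA position of the PTC's first base, or `NA`.
#' @export
locate_ptc <- function(call, tx, genome) {
  if (!call$category %in% c("nonsense", "frameshift"))
    stop("locate_ptc() is only defined for nonsense and frameshift calls")
  if (call$category == "nonsense") {
    if (!is.na(call$ptc_mrna_pos)) return(call$ptc_mrna_pos)
  }
  ed <- transcript_edit(call$pos, call$ref, call$alt, tx)
  if (is.null(ed)) return(NA_integer_)
  mrna <- spliced_mrna(tx, genome)
  lr <- nchar(ed$ref_tx)
  mut <- paste0(substr(mrna, 1L, ed$m_start - 1L), ed$alt_tx,
                substr(mrna, ed$m_start + lr, nchar(mrna)))
  cm <- cds_mrna_span(tx)
  delta <- nchar(ed$alt_tx) - lr
  from <- cm[1L]
  while (from + 2L <= nchar(mut)) {
    aa <- translate_codon(substr(mut, from, from + 2L))
    if (!is.na(aa) && aa == "*") {
      # Map the mutant coordinate back to the reference mRNA frame; positions
      # downstream of the edit shift by the net length change, stops landing
      # inside an inserted block map to the edit start.
      ref_pos <- if (from < ed$m_start) from else max(ed$m_start, from - delta)
      if (call$category == "nonsense" && ref_pos >= cm[2L] - 2L)
        return(NA_integer_)  # the reference stop itself is not premature
      return(as.integer(ref_pos))
    }
    from <- from + 3L
  }
  NA_integer_
}

#' Classify the NMD fate of a consequence call
#'
#' Applies the decision cascade: experimental-escape override; splice
#' dinucleotide variants (final intron escapes, any earlier intron triggers);
#' non-truncating categories escape; single-exon transcripts escape; no PTC
#' found escapes; PTC in the final exon or within 50 nt (inclusive) of the
#' final exon-exon junction escapes; anything else triggers NMD.
#'
#' @param call A `consequence_call`, with `ptc_mrna_pos` filled in for
#'   nonsense/frameshift calls (see [locate_ptc()]).
#' @param tx The matching `transcript_model`.
#' @param overrides Optional escape-override table (data frame with `chrom`,
#'   `pos`, `ref`, `alt`) of variants with published experimental evidence of
#'   NMD escape.
#' @param escape_window Width of the junction-proximal escape window in
#'   nucleotides (default 50, inclusive).
#' @return List with `status` (`"NMD_positive"`/`"NMD_negative"`) and
#'   `reason` (one of the machine-readable reason codes).
#' @export
classify_nmd <- function(call, tx, overrides = NULL, escape_window = 50L) {
  out <- function(status, reason) list(status = status, reason = reason)

  if (!is.null(overrides) && nrow(overrides) > 0L) {
    keys <- variant_key(overrides$chrom, overrides$pos,
                        toupper(overrides$ref), toupper(overrides$alt))
    if (call$key %in% keys)
      return(out("NMD_negative", "experimental_escape_override"))
  }
  if (call$category %in% c("splice_donor", "splice_acceptor")) {
    if (call$intron_index == n_introns(tx))
      return(out("NMD_negative", "final_intron_splice"))
    return(out("NMD_positive", "non_final_intron_splice"))
  }
  if (!call$category %in% c("nonsense", "frameshift"))
    return(out("NMD_negative", "non_truncating"))
  if (length(tx$exon_start) == 1L)
    return(out("NMD_negative", "single_exon"))
  if (is.na(call$ptc_mrna_pos))
    return(out("NMD_negative", "no_ptc_found"))
  junction <- final_junction_mrna(tx)
  if (call$ptc_mrna_pos > junction)
    return(out("NMD_negative", "last_exon"))
  if (junction - call$ptc_mrna_pos <= escape_window)
    return(out("NMD_negative", "within_50bp_of_final_junction"))
  out("NMD_positive", "qualifying_ptc")
}

#' Annotate a variant table with consequence and NMD status
#'
#' Runs [call_consequence()], [locate_ptc()] and [classify_nmd()] for every
#' variant against the clinically relevant transcript of its gene. Variants
#' on chromosomes with no supplied transcript are dropped with a warning
#' (the analysis is restricted to designated transcripts).
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt` (additional
#'   columns are carried through).
#' @param transcripts Named list of `transcript_model` objects; matching is
#'   by chromosome, preferring transcripts flagged clinically relevant.
#' @param genome Genome as a named character vector.
#' @param overrides Optional escape-override table (see [classify_nmd()]).
#' @param escape_window Junction-proximal escape window, default 50 nt.
#' @return The input data frame plus columns `gene`, `transcript_id`,
#'   `category`, `ptc_mrna_pos`, `intron_index`, `nmd_status`, `nmd_reason`.
#' @export
annotate_nmd <- function(variants, transcripts, genome, overrides = NULL,
                         escape_window = 50L) {
  stopifnot(is.data.frame(variants))
  tx_chrom <- vapply(transcripts, function(t) t$chrom, character(1))
  tx_rel <- vapply(transcripts, function(t) isTRUE(t$clinically_relevant), logical(1))

  n <- nrow(variants)
  gene <- tx_id <- category <- reason <- status <- rep(NA_character_, n)
  ptc <- intron <- rep(NA_integer_, n)
  keep <- rep(TRUE, n)

  for (i in seq_len(n)) {
    cand <- which(tx_chrom == as.character(variants$chrom[i]))
    if (length(cand) > 1L) cand <- cand[order(!tx_rel[cand])]
    if (length(cand) == 0L) { keep[i] <- FALSE; next }
    tx <- transcripts[[cand[1L]]]
    cc <- call_consequence(variants[i, , drop = FALSE], tx, genome)
    if (cc$category %in% c("nonsense", "frameshift"))
      cc$ptc_mrna_pos <- locate_ptc(cc, tx, genome)
    st <- classify_nmd(cc, tx, overrides, escape_window)
    gene[i] <- tx$gene; tx_id[i] <- tx$transcript_id
    category[i] <- cc$category; ptc[i] <- cc$ptc_mrna_pos
    intron[i] <- cc$intron_index
    status[i] <- st$status; reason[i] <- st$reason
  }
  if (any(!keep))
    warning(sum(!keep), " variant(s) mapped to no clinically relevant ",
            "transcript and were dropped")
  res <- variants[keep, , drop = FALSE]
  res$gene <- gene[keep]
  res$transcript_id <- tx_id[keep]
  res$category <- category[keep]
  res$ptc_mrna_pos <- ptc[keep]
  res$intron_index <- intron[keep]
  res$nmd_status <- status[keep]
  res$nmd_reason <- reason[keep]
  rownames(res) <- NULL
  res
}
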