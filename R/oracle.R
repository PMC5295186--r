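# Brute-force NMD oracle.
#
# A deliberately independent re-derivation of the consequence + NMD cascade:
# coordinates come from an explicit per-base exon-walk enumeration (not the
# arithmetic mapper), complementation and translation come from seqinr (not
# Biostrings), and the mutant transcript is rebuilt base-by-base. The
# synthetic-data generator records this oracle's verdicts as ground truth, so
# agreement between classifier and oracle on generated data is a real test,
# not a tautology.

oracle_complement <- function(chars) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
}

# Genomic positions of the transcript's exonic bases, 5'->3' in
# transcription direction.
oracle_exonic_positions <- function(tx) {
  pos <- unlist(mapply(seq, tx$exon_start, tx$exon_end, SIMPLIFY = FALSE),
                use.names = FALSE)
  if (tx$strand == "-") rev(pos) else pos
}

# Per-intron genomic positions in transcription direction, as a list indexed
# by transcription intron number.
oracle_intron_positions <- function(tx) {
  n <- length(tx$exon_start)
  if (n < 2L) return(list())
  gaps <- lapply(seq_len(n - 1L), function(g) {
    seq(tx$exon_end[g] + 1L, tx$exon_start[g + 1L] - 1L)
  })
  if (tx$strand == "-") lapply(rev(gaps), rev) else gaps
}

oracle_translate <- function(chars) {
  n <- (length(chars) %/% 3L) * 3L
  if (n == 0L) return(character(0))
  seqinr::translate(tolower(chars[seq_len(n)]))
}

#' Brute-force NMD classification by full mutant-transcript reconstruction
#'
#' Re-derives the NMD status of a variant from first principles: enumerates
#' every exonic base, rebuilds the complete mutant spliced mRNA, translates
#' it codon-by-codon through the 3' UTR, and applies the escape rules
#' (final exon, 50-nt junction window, final-intron splice dinucleotide,
#' experimental overrides) literally. Used to record ground truth in the
#' synthetic-data generator and as the independent cross-check of
#' [classify_nmd()] in the test-suite.
#'
#' @inheritParams call_consequence
#' @param overrides Optional escape-override table.
#' @param escape_window Junction-proximal escape window (default 50 nt).
#' @return List with `status`, `reason`, `category` and `ptc_mrna_pos`
#'   (reference-frame, `NA` when no PTC exists).
#' @export
nmd_oracle <- function(variant, tx, genome, overrides = NULL,
                       escape_window = 50L) {
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  res <- list(status = NA_character_, reason = NA_character_,
              category = NA_character_, ptc_mrna_pos = NA_integer_)
  done <- function(status, reason, category, ptc = NA_integer_) {
    list(status = status, reason = reason, category = category,
         ptc_mrna_pos = as.integer(ptc))
  }

  # Override list wins over everything.
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    hit <- overrides$chrom == chrom & overrides$pos == pos &
      toupper(overrides$ref) == ref & toupper(overrides$alt) == alt
    if (any(hit))
      return(done("NMD_negative", "experimental_escape_override", "override"))
  }

  # Changed genomic positions after trimming the shared VCF anchor prefix
  # (own implementation, kept inline).
  rv <- strsplit(ref, "")[[1L]]; av <- strsplit(alt, "")[[1L]]
  k <- 0L
  while (k < min(length(rv), length(av)) && rv[k + 1L] == av[k + 1L]) k <- k + 1L
  changed <- if (length(rv) == length(av)) {
    pos:(pos + length(rv) - 1L)
  } else if (k >= length(rv)) {
    c(pos + length(rv) - 1L, pos + length(rv))
  } else {
    (pos + k):(pos + length(rv) - 1L)
  }

  # Splice dinucleotides from the literal intron enumeration.
  introns <- oracle_intron_positions(tx)
  for (i in seq_along(introns)) {
    din <- c(utils::head(introns[[i]], 2L), utils::tail(introns[[i]], 2L))
    if (any(changed %in% din)) {
      site <- if (any(changed %in% utils::head(introns[[i]], 2L)))
        "splice_donor" else "splice_acceptor"
      if (i == length(introns))
        return(done("NMD_negative", "final_intron_splice", site))
      return(done("NMD_positive", "non_final_intron_splice", site))
    }
  }

  expos <- oracle_exonic_positions(tx)
  mrna_chars <- substring(genome[[chrom]], expos, expos)
  if (tx$strand == "-") mrna_chars <- oracle_complement(mrna_chars)

  cds_idx <- sort(match(c(tx$cds_start, tx$cds_end), expos))
  footprint <- pos:(pos + length(rv) - 1L)
  idx <- match(footprint, expos)
  if (anyNA(match(changed, expos)) || anyNA(idx) ||
      any(match(changed, expos) < cds_idx[1L]) ||
      any(match(changed, expos) > cds_idx[2L])) {
    return(done("NMD_negative", "non_truncating",
                if (all(changed %in% unlist(introns))) "intronic_other" else "other"))
  }

  # Rebuild the complete mutant mRNA base-by-base.
  idx <- sort(idx)
  alt_chars <- av
  if (tx$strand == "-") alt_chars <- rev(oracle_complement(av))
  mut_chars <- c(mrna_chars[seq_len(idx[1L] - 1L)], alt_chars,
                 if (idx[length(idx)] < length(mrna_chars))
                   mrna_chars[(idx[length(idx)] + 1L):length(mrna_chars)]
                 else character(0))

  delta <- length(av) - length(rv)
  m_start <- idx[1L]

  if (delta == 0L) {
    # Substitution: compare full CDS translations.
    ref_prot <- oracle_translate(mrna_chars[cds_idx[1L]:cds_idx[2L]])
    mut_prot <- oracle_translate(mut_chars[cds_idx[1L]:cds_idx[2L]])
    diffs <- which(ref_prot != mut_prot)
    new_stop <- diffs[mut_prot[diffs] == "*" & ref_prot[diffs] != "*"]
    if (length(new_stop) == 0L) {
      cat_ <- if (length(diffs) == 0L) "synonymous" else "missense"
      return(done("NMD_negative", "non_truncating", cat_))
    }
    ptc <- cds_idx[1L] + 3L * (min(new_stop) - 1L)
    category <- "nonsense"
  } else if ((abs(delta) %% 3L) != 0L) {
    category <- "frameshift"
    # Translate the mutant transcript from the CDS start through the 3' UTR.
    prot <- oracle_translate(mut_chars[cds_idx[1L]:length(mut_chars)])
    stops <- which(prot == "*")
    if (length(stops) == 0L) {
      if (length(tx$exon_start) == 1L)
        return(done("NMD_negative", "single_exon", category))
      return(done("NMD_negative", "no_ptc_found", category))
    }
    ptc_mut <- cds_idx[1L] + 3L * (min(stops) - 1L)
    # Reference-frame coordinate of the stop codon's first base (positions
    # downstream of the edit shift back; stops inside inserted bases map to
    # the edit start).
    ptc <- if (ptc_mut < m_start) ptc_mut else max(m_start, ptc_mut - delta)
  } else {
    return(done("NMD_negative", "non_truncating", "inframe_indel"))
  }

  if (length(tx$exon_start) == 1L)
    return(done("NMD_negative", "single_exon", category, ptc))
  # Final junction: number of exonic bases in transcription exons 1..(n-1),
  # counted off the literal enumeration.
  last_exon_len <- if (tx$strand == "+") {
    tx$exon_end[length(tx$exon_end)] - tx$exon_start[length(tx$exon_start)] + 1L
  } else {
    tx$exon_end[1L] - tx$exon_start[1L] + 1L
  }
  junction <- length(expos) - last_exon_len
  if (ptc > junction)
    return(done("NMD_negative", "last_exon", category, ptc))
  if (junction - ptc <= escape_window)
    return(done("NMD_negative", "within_50bp_of_final_junction", category, ptc))
  done("NMD_positive", "qualifying_ptc", category, ptc)
}
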