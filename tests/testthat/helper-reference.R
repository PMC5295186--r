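# In-code fixtures: hand-laid transcripts with known exon geometry and a
# valid ORF, independent of the package's own study generator.

ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"), paste0),
                              c("A", "C", "G", "T"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, c("TAA", "TAG", "TGA"))

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a single-transcript reference with chosen exon widths (transcription
# order), strand and UTR lengths. Introns are 60 nt with canonical
# dinucleotides. Returns list(genome, tx, mrna, utr5, cds_len).
toy_reference <- function(widths = c(300L, 200L, 150L), strand = "+",
                          utr5 = 12L, intron = 60L, seed = 42L,
                          chrom = "chrT") {
  set.seed(seed)
  L <- sum(widths)
  cds_len <- 3L * ((L - utr5 - 30L) %/% 3L)
  utr3 <- L - utr5 - cds_len
  stopifnot(cds_len >= 9L, utr3 >= 3L)
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, cds_len / 3L - 2L, replace = TRUE),
                      collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1L))
  mrna <- paste0(random_bases(utr5), cds, random_bases(utr3))

  n <- length(widths)
  cum <- cumsum(c(0L, widths))
  chunks <- substring(mrna, cum[-length(cum)] + 1L, cum[-1L])  # transcription
  if (strand == "-") {
    genomic_chunks <- rev(vapply(chunks, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      character(1)))
    genomic_widths <- rev(widths)
    intron_seq <- paste0("CT", random_bases(intron - 4L), "AC")
  } else {
    genomic_chunks <- chunks
    genomic_widths <- widths
    intron_seq <- paste0("GT", random_bases(intron - 4L), "AG")
  }

  pad <- 50L
  pieces <- character(0)
  exon_start <- integer(n); exon_end <- integer(n)
  at <- pad
  for (j in seq_len(n)) {
    exon_start[j] <- at + 1L
    exon_end[j] <- at + genomic_widths[j]
    pieces <- c(pieces, genomic_chunks[j])
    at <- at + genomic_widths[j]
    if (j < n) {
      pieces <- c(pieces, intron_seq)
      at <- at + intron
    }
  }
  genome <- stats::setNames(
    paste0(random_bases(pad), paste(pieces, collapse = ""), random_bases(pad)),
    chrom)

  draft <- structure(list(strand = strand, exon_start = exon_start,
                          exon_end = exon_end), class = "transcript_model")
  cds_g <- mrna_to_genomic(c(utr5 + 1L, utr5 + cds_len), draft)
  tx <- transcript_model("TOY1", "TOYGENE", chrom, strand,
                         exon_start, exon_end, min(cds_g), max(cds_g))
  list(genome = genome, tx = tx, mrna = mrna, utr5 = utr5, cds_len = cds_len)
}

# Literal exon-walk enumeration: genomic positions of the spliced transcript
# in transcription order (the brute-force coordinate oracle).
exon_walk <- function(tx) {
  pos <- unlist(mapply(seq, tx$exon_start, tx$exon_end, SIMPLIFY = FALSE))
  if (tx$strand == "-") rev(pos) else pos
}

# A small pool of generator-made references for property tests.
reference_pool <- function(seeds = 1:4) {
  lapply(seeds, function(s)
    generate_reference(generator_params(seed = s, n_genes = 4L)))
}

# Exact two-sided rank-sum p by enumeration over all labelings (no ties).
ranksum_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  mu <- n * length(b) / 2
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
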