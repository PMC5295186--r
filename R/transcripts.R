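# Transcript models and genomic <-> mRNA coordinate arithmetic.
#
# All genomic coordinates are 1-based inclusive (VCF convention); mRNA
# coordinates are 1-based in transcription direction, so the 50-bp NMD rule
# is a plain subtraction. Minus-strand transcripts are handled by reverse
# complement at sequence-extraction time only; all structural logic works on
# the genomic exon list sorted by start.

#' Construct a transcript model
#'
#' A transcript model is the coordinate substrate for NMD prediction: an
#' ordered exon list on a strand plus the genomic CDS endpoints. Exons are
#' given in genomic order (sorted by start); for minus-strand transcripts the
#' transcription order is the reverse.
#'
#' @param transcript_id Transcript identifier.
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Integer vectors of 1-based inclusive exon
#'   boundaries, sorted by start, pairwise non-overlapping, separated by at
#'   least one intronic base.
#' @param cds_start,cds_end Genomic positions of the CDS span
#'   (`cds_start <= cds_end` regardless of strand); both must fall inside an
#'   exon.
#' @param clinically_relevant Logical flag marking the designated clinically
#'   relevant transcript for the gene.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, chrom, strand,
                             exon_start, exon_end,
                             cds_start, cds_end,
                             clinically_relevant = TRUE) {
  tx <- structure(list(
    transcript_id = as.character(transcript_id),
    gene = as.character(gene),
    chrom = as.character(chrom),
    strand = match.arg(strand, c("+", "-")),
    exon_start = as.integer(exon_start),
    exon_end = as.integer(exon_end),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    clinically_relevant = isTRUE(clinically_relevant)
  ), class = "transcript_model")
  validate_transcript(tx)
  tx
}

#' Validate transcript structural invariants
#'
#' Checks exon ordering, non-overlap, non-empty introns, and that both CDS
#' endpoints are exonic. Called by [transcript_model()]; exported so readers
#' can re-validate after file import.
#'
#' @param tx A `transcript_model`.
#' @return `tx`, invisibly. Throws a structural-validation error otherwise.
#' @export
validate_transcript <- function(tx) {
  n <- length(tx$exon_start)
  if (n < 1L) stop("transcript ", tx$transcript_id, ": at least one exon required")
  if (length(tx$exon_end) != n)
    stop("transcript ", tx$transcript_id, ": exon_start/exon_end length mismatch")
  if (any(tx$exon_end < tx$exon_start))
    stop("transcript ", tx$transcript_id, ": exon end before start")
  if (n > 1L) {
    if (is.unsorted(tx$exon_start, strictly = TRUE))
      stop("transcript ", tx$transcript_id, ": exons not sorted by genomic start")
    gap <- tx$exon_start[-1L] - tx$exon_end[-n]
    if (any(gap < 2L))
      stop("transcript ", tx$transcript_id, ": exons overlap or introns empty")
  }
  if (tx$cds_start > tx$cds_end)
    stop("transcript ", tx$transcript_id, ": cds_start > cds_end")
  for (p in c(tx$cds_start, tx$cds_end)) {
    if (!any(p >= tx$exon_start & p <= tx$exon_end))
      stop("transcript ", tx$transcript_id, ": CDS endpoint ", p, " is not exonic")
  }
  invisible(tx)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s\n",
              x$transcript_id, x$gene, x$chrom,
              paste0(min(x$exon_start), "-", max(x$exon_end)), x$strand))
  cat(sprintf("  %d exon(s), mRNA %d nt, CDS %d-%d%s\n",
              length(x$exon_start), mrna_length(x), x$cds_start, x$cds_end,
              if (x$clinically_relevant) ", clinically relevant" else ""))
  invisible(x)
}

exon_widths <- function(tx) tx$exon_end - tx$exon_start + 1L

#' Spliced transcript length
#'
#' @param tx A `transcript_model`.
#' @return Total mRNA length (sum of exon widths).
#' @export
mrna_length <- function(tx) sum(exon_widths(tx))

#' Map genomic positions to spliced-transcript coordinates
#'
#' Returns the 1-based position of each genomic position in the spliced
#' transcript, counted 5' to 3' in transcription direction (so minus-strand
#' transcripts count from the genomically last exonic base). Intronic
#' positions and positions outside the transcript span map to `NA`.
#'
#' @param pos Integer vector of genomic positions.
#' @param tx A `transcript_model`.
#' @return Integer vector of mRNA positions (`NA` where non-exonic).
#' @export
genomic_to_mrna <- function(pos, tx) {
  w <- exon_widths(tx)
  before <- cumsum(c(0L, w))[seq_along(w)]
  out <- rep(NA_integer_, length(pos))
  for (j in seq_along(w)) {
    hit <- !is.na(pos) & pos >= tx$exon_start[j] & pos <= tx$exon_end[j]
    out[hit] <- before[j] + (pos[hit] - tx$exon_start[j] + 1L)
  }
  if (tx$strand == "-") {
    L <- sum(w)
    out <- ifelse(is.na(out), NA_integer_, L - out + 1L)
  }
  as.integer(out)
}

#' Map spliced-transcript coordinates back to genomic positions
#'
#' Inverse of [genomic_to_mrna()] on the exonic domain.
#'
#' @param mpos Integer vector of 1-based mRNA positions.
#' @param tx A `transcript_model`.
#' @return Integer vector of genomic positions (`NA` outside `1..mRNA length`).
#' @export
mrna_to_genomic <- function(mpos, tx) {
  w <- exon_widths(tx)
  L <- sum(w)
  plus_idx <- if (tx$strand == "-") L - as.integer(mpos) + 1L else as.integer(mpos)
  before <- cumsum(c(0L, w))
  out <- rep(NA_integer_, length(mpos))
  ok <- !is.na(plus_idx) & plus_idx >= 1L & plus_idx <= L
  j <- findInterval(plus_idx[ok] - 1L, before[-length(before)])
  out[ok] <- tx$exon_start[j] + (plus_idx[ok] - before[j] - 1L)
  as.integer(out)
}

#' Reconstruct the spliced mRNA sequence
#'
#' Concatenates exonic genome sequence in genomic order and
#' reverse-complements the result for minus-strand transcripts.
#'
#' @param tx A `transcript_model`.
#' @param genome A genome as returned by [read_genome_fasta()] (named
#'   character vector of chromosome sequences).
#' @return The spliced transcript sequence (character scalar).
#' @export
spliced_mrna <- function(tx, genome) {
  chrom_seq <- get_chrom_seq(genome, tx$chrom)
  pieces <- substring(chrom_seq, tx$exon_start, tx$exon_end)
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

#' mRNA span of the coding sequence
#'
#' @param tx A `transcript_model`.
#' @return Integer vector `c(start, end)` of the CDS in mRNA coordinates
#'   (transcription direction, start <= end).
#' @export
cds_mrna_span <- function(tx) {
  m <- genomic_to_mrna(c(tx$cds_start, tx$cds_end), tx)
  if (anyNA(m)) stop("transcript ", tx$transcript_id, ": CDS endpoint is intronic")
  sort(m)
}

#' Extract the spliced coding sequence
#'
#' Exonic bases from the CDS start to the CDS end in transcription direction,
#' reverse-complemented for minus-strand transcripts.
#'
#' @inheritParams spliced_mrna
#' @return The coding sequence (character scalar).
#' @export
spliced_cds <- function(tx, genome) {
  span <- cds_mrna_span(tx)
  substr(spliced_mrna(tx, genome), span[1L], span[2L])
}

#' mRNA position of the final exon-exon junction
#'
#' The last base of the penultimate exon in transcription direction. This is
#' the reference point of the 50-bp NMD rule: premature stops landing
#' downstream of, or within 50 nt upstream of, this junction are predicted to
#' escape decay.
#'
#' @param tx A `transcript_model`.
#' @return Integer mRNA position, or `NA` for single-exon transcripts.
#' @export
final_junction_mrna <- function(tx) {
  w <- exon_widths(tx)
  n <- length(w)
  if (n < 2L) return(NA_integer_)
  last_w <- if (tx$strand == "+") w[n] else w[1L]
  as.integer(sum(w) - last_w)
}

# Transcription-direction intron table: one row per intron i in 1..(n-1),
# with the genomic positions of the donor (first two intronic bases) and
# acceptor (last two) dinucleotides and the genomic gap span.
intron_table <- function(tx) {
  n <- length(tx$exon_start)
  if (n < 2L) {
    return(data.frame(intron = integer(), gap = integer(),
                      donor1 = integer(), donor2 = integer(),
                      acceptor1 = integer(), acceptor2 = integer(),
                      gap_start = integer(), gap_end = integer()))
  }
  i <- seq_len(n - 1L)
  if (tx$strand == "+") {
    gap <- i
    donor1 <- tx$exon_end[i] + 1L
    donor2 <- tx$exon_end[i] + 2L
    acceptor1 <- tx$exon_start[i + 1L] - 2L
    acceptor2 <- tx$exon_start[i + 1L] - 1L
  } else {
    gap <- n - i
    donor1 <- tx$exon_start[gap + 1L] - 1L
    donor2 <- tx$exon_start[gap + 1L] - 2L
    acceptor1 <- tx$exon_end[gap] + 2L
    acceptor2 <- tx$exon_end[gap] + 1L
  }
  data.frame(intron = i, gap = gap,
             donor1 = donor1, donor2 = donor2,
             acceptor1 = acceptor1, acceptor2 = acceptor2,
             gap_start = tx$exon_end[gap] + 1L,
             gap_end = tx$exon_start[gap + 1L] - 1L)
}

#' Locate a position within consensus splice-site dinucleotides
#'
#' Tests whether a genomic position is one of the first two (donor) or last
#' two (acceptor) intronic bases of an intron, with introns numbered
#' `1..(n_exons - 1)` in transcription direction ("final intron" is the
#' biologically last one, not the genomically last).
#'
#' @param pos A single genomic position.
#' @param tx A `transcript_model`.
#' @return `NULL` when the position is not part of a splice dinucleotide,
#'   otherwise a list with elements `intron` (index in transcription order)
#'   and `site` (`"donor"` or `"acceptor"`).
#' @export
intron_index_of_splice_site <- function(pos, tx) {
  it <- intron_table(tx)
  for (k in seq_len(nrow(it))) {
    if (pos %in% c(it$donor1[k], it$donor2[k]))
      return(list(intron = it$intron[k], site = "donor"))
    if (pos %in% c(it$acceptor1[k], it$acceptor2[k]))
      return(list(intron = it$intron[k], site = "acceptor"))
  }
  NULL
}

#' Number of introns of a transcript
#' @param tx A `transcript_model`.
#' @return `n_exons - 1`.
#' @export
n_introns <- function(tx) length(tx$exon_start) - 1L

# -- genome helpers -----------------------------------------------------------

get_chrom_seq <- function(genome, chrom) {
  s <- genome[[chrom]]
  if (is.null(s) || is.na(s))
    stop("chromosome ", chrom, " not present in genome")
  s
}

# Single extraction point for genomic subsequences (plus strand).
seq_at <- function(genome, chrom, start, end = start) {
  substr(get_chrom_seq(genome, chrom), start, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
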