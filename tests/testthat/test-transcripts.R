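test_that("transcript validation rejects malformed structures", {
  expect_error(transcript_model("t", "g", "c", "+", integer(0), integer(0), 1, 2),
               "at least one exon")
  expect_error(transcript_model("t", "g", "c", "+", c(1, 50), c(60, 90), 5, 80),
               "overlap|sorted")
  expect_error(transcript_model("t", "g", "c", "+", c(1, 62), c(60, 90), 5, 95),
               "not exonic")
  expect_error(transcript_model("t", "g", "c", "+", c(1, 61), c(60, 61), 5, 61),
               "introns empty|overlap")
})

test_that("genomic/mRNA mapping matches the exon-walk enumeration", {
  for (ref in reference_pool()) {
    for (tx in ref$transcripts) {
      walk <- exon_walk(tx)
      # every exonic position maps to its index in the enumeration
      expect_identical(genomic_to_mrna(walk, tx), seq_along(walk))
      # round trip is the identity on both sides
      expect_identical(mrna_to_genomic(seq_along(walk), tx), walk)
      # intronic and flanking positions map to NA
      outside <- c(min(tx$exon_start) - 1L, max(tx$exon_end) + 1L)
      if (length(tx$exon_start) > 1L)
        outside <- c(outside, tx$exon_end[1L] + 1L)
      expect_true(all(is.na(genomic_to_mrna(outside, tx))))
    }
  }
})

test_that("first exonic base maps to 1 and mapping is a bijection", {
  toy <- toy_reference(seed = 7)
  tx <- toy$tx
  expect_identical(genomic_to_mrna(tx$exon_start[1L], tx), 1L)
  expect_true(is.na(genomic_to_mrna(tx$exon_end[1L] + 5L, tx)))
  m <- genomic_to_mrna(exon_walk(tx), tx)
  expect_identical(sort(m), seq_len(mrna_length(tx)))
})

test_that("spliced CDS extraction is exact and strand-symmetric", {
  # single-exon plus-strand transcript around "ATGAAATGA"
  genome <- c(chrS = "TTATGAAATGATT")
  tx <- transcript_model("S", "S", "chrS", "+", 3L, 11L, 3L, 11L)
  expect_identical(spliced_cds(tx, genome), "ATGAAATGA")
  # same exons on the minus strand: reverse complement of the plus extraction
  txm <- transcript_model("Sm", "S", "chrS", "-", 3L, 11L, 3L, 11L)
  expect_identical(
    spliced_cds(txm, genome),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGAAATGA"))))
})

test_that("spliced sequences equal per-base extraction on random transcripts", {
  for (ref in reference_pool(seeds = 2:3)) {
    for (tx in ref$transcripts) {
      chrom_seq <- ref$genome[[tx$chrom]]
      per_base <- vapply(exon_walk(tx), function(p)
        substring(chrom_seq, p, p), character(1))
      if (tx$strand == "-")
        per_base <- unname(c(A = "T", C = "G", G = "C", T = "A")[per_base])
      expect_identical(spliced_mrna(tx, ref$genome),
                       paste(per_base, collapse = ""))
      span <- cds_mrna_span(tx)
      cds <- spliced_cds(tx, ref$genome)
      expect_identical(nchar(cds), span[2L] - span[1L] + 1L)
    }
  }
})

test_that("final junction position is the cumulative-length arithmetic", {
  toy <- toy_reference(widths = c(300L, 200L, 150L))
  expect_identical(final_junction_mrna(toy$tx), 500L)
  single <- toy_reference(widths = 400L)
  expect_true(is.na(final_junction_mrna(single$tx)))
  for (ref in reference_pool(seeds = 4)) {
    for (tx in ref$transcripts) {
      j <- final_junction_mrna(tx)
      if (length(tx$exon_start) == 1L) {
        expect_true(is.na(j))
      } else {
        w <- tx$exon_end - tx$exon_start + 1L
        last_w <- if (tx$strand == "+") w[length(w)] else w[1L]
        expect_identical(j, mrna_length(tx) - last_w)
        expect_lt(j, mrna_length(tx))
      }
    }
  }
})

test_that("splice dinucleotide lookup follows transcription order on both strands", {
  plus <- toy_reference(widths = c(100L, 90L, 120L), strand = "+", seed = 11)
  tx <- plus$tx
  first_intronic <- tx$exon_end[1L] + 1L
  expect_equal(intron_index_of_splice_site(first_intronic, tx),
               list(intron = 1L, site = "donor"))
  expect_null(intron_index_of_splice_site(tx$exon_end[1L] + 3L, tx))
  expect_equal(intron_index_of_splice_site(tx$exon_start[2L] - 1L, tx),
               list(intron = 1L, site = "acceptor"))

  minus <- toy_reference(widths = c(100L, 90L, 120L), strand = "-", seed = 11)
  txm <- minus$tx
  # strand-flip oracle: walk each intron in transcription direction and
  # recompute donor/acceptor membership from the literal enumeration
  n <- length(txm$exon_start)
  for (g in seq_len(n - 1L)) {
    gap <- seq(txm$exon_end[g] + 1L, txm$exon_start[g + 1L] - 1L)
    gap_tx_order <- rev(gap)                # minus strand reads high -> low
    i_tx <- n - g                           # transcription intron index
    for (p in utils::head(gap_tx_order, 2L))
      expect_equal(intron_index_of_splice_site(p, txm),
                   list(intron = i_tx, site = "donor"))
    for (p in utils::tail(gap_tx_order, 2L))
      expect_equal(intron_index_of_splice_site(p, txm),
                   list(intron = i_tx, site = "acceptor"))
    for (p in gap_tx_order[3:(length(gap_tx_order) - 2L)])
      expect_null(intron_index_of_splice_site(p, txm))
  }
})

test_that("generated splice dinucleotides are canonical in transcription direction", {
  for (ref in reference_pool(seeds = 5)) {
    for (tx in ref$transcripts) {
      n <- length(tx$exon_start)
      if (n < 2L) next
      chrom_seq <- ref$genome[[tx$chrom]]
      for (g in seq_len(n - 1L)) {
        gap <- substring(chrom_seq, tx$exon_end[g] + 1L,
                         tx$exon_start[g + 1L] - 1L)
        if (tx$strand == "-")
          gap <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(gap)))
        expect_identical(substr(gap, 1L, 2L), "GT")
        expect_identical(substr(gap, nchar(gap) - 1L, nchar(gap)), "AG")
      }
    }
  }
})
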