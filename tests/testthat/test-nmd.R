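test_that("a codon-2 stop substitution is called nonsense at the right position", {
  # CDS "ATG CAA AAA TGA"; c.4C>T turns CAA into TAA
  genome <- c(chrN = "TTATGCAAAAATGATT")
  tx <- transcript_model("N", "N", "chrN", "+", 3L, 14L, 3L, 14L)
  cc <- call_consequence(list(chrom = "chrN", pos = 6L, ref = "C", alt = "T"),
                         tx, genome)
  expect_identical(cc$category, "nonsense")
  expect_identical(cc$ptc_mrna_pos, 4L)  # first base of codon 2
})

test_that("REF mismatches are rejected", {
  genome <- c(chrN = "TTATGCAAAAATGATT")
  tx <- transcript_model("N", "N", "chrN", "+", 3L, 14L, 3L, 14L)
  expect_error(call_consequence(list(chrom = "chrN", pos = 6L, ref = "G",
                                     alt = "T"), tx, genome),
               "REF mismatch")
})

test_that("coding indels split into frameshift and in-frame by length", {
  toy <- toy_reference(seed = 21)
  tx <- toy$tx
  cm <- cds_mrna_span(tx)
  g1 <- mrna_to_genomic(cm[1L] + 6L, tx)
  ref2 <- substring(toy$genome[[tx$chrom]], g1, g1 + 1L)
  cc <- call_consequence(list(chrom = tx$chrom, pos = g1, ref = ref2,
                              alt = substr(ref2, 1L, 1L)), tx, toy$genome)
  expect_identical(cc$category, "frameshift")  # 1 bp deletion, 1 %% 3 != 0
  ref4 <- substring(toy$genome[[tx$chrom]], g1, g1 + 3L)
  cc3 <- call_consequence(list(chrom = tx$chrom, pos = g1, ref = ref4,
                               alt = substr(ref4, 1L, 1L)), tx, toy$genome)
  expect_identical(cc3$category, "inframe_indel")  # 3 bp deletion
})

test_that("random coding SNVs agree with the whole-CDS translation oracle", {
  for (ref in reference_pool(seeds = 6:7)) {
    for (tx in ref$transcripts) {
      cm <- cds_mrna_span(tx)
      set.seed(tx$cds_start)
      for (m in sample((cm[1L] + 3L):(cm[2L] - 3L), 12L)) {
        g <- mrna_to_genomic(m, tx)
        b <- substring(ref$genome[[tx$chrom]], g, g)
        alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        v <- list(chrom = tx$chrom, pos = g, ref = b, alt = alt)
        cc <- call_consequence(v, tx, ref$genome)
        orc <- nmd_oracle(v, tx, ref$genome)
        expect_identical(cc$category, orc$category)
        if (cc$category == "nonsense")
          expect_identical(cc$ptc_mrna_pos, orc$ptc_mrna_pos)
      }
    }
  }
})

test_that("frameshift PTC localization matches hand translation", {
  # CDS = whole exon: ATG AAA ATA AGG TGA TTT TAA (21 nt);
  # deleting CDS base 4 shifts to ATG AAA TAA ..., a stop whose bases are
  # reference positions 8-10, so the reference-frame PTC first base is
  # mRNA position 8.
  genome <- c(chrF = paste0("TT", "ATGAAAATAAGGTGATTTTAA", "TT"))
  tx <- transcript_model("F", "F", "chrF", "+", 3L, 23L, 3L, 23L)
  v <- list(chrom = "chrF", pos = 5L, ref = "GA", alt = "G")
  cc <- call_consequence(v, tx, genome)
  expect_identical(cc$category, "frameshift")
  expect_identical(locate_ptc(cc, tx, genome), 8L)
  expect_identical(nmd_oracle(v, tx, genome)$ptc_mrna_pos, 8L)
})

test_that("a frameshift with no downstream stop yields no PTC", {
  # After deleting one base the shifted frame reads AAA.. to transcript end.
  genome <- c(chrZ = paste0("TT", "ATGAAAAAAAAAAAAAAAAAAAAA", "TT"))
  tx <- transcript_model("Z", "Z", "chrZ", "+", 3L, 26L, 3L, 23L)
  v <- list(chrom = "chrZ", pos = 5L, ref = "GA", alt = "G")
  cc <- call_consequence(v, tx, genome)
  expect_identical(cc$category, "frameshift")
  expect_true(is.na(locate_ptc(cc, tx, genome)))
  cc$ptc_mrna_pos <- locate_ptc(cc, tx, genome)
  expect_identical(classify_nmd(cc, tx)$reason, "single_exon")
})

test_that("nonsense SNVs at known codons place the PTC by definition", {
  toy <- toy_reference(seed = 33)
  tx <- toy$tx
  cds <- spliced_cds(tx, toy$genome)
  cm <- cds_mrna_span(tx)
  # find a codon one substitution away from a stop
  hits <- 0L
  for (k in 2:(nchar(cds) / 3 - 1)) {
    codon <- substr(cds, 3 * k - 2, 3 * k)
    for (st in c("TAA", "TAG", "TGA")) {
      d <- which(strsplit(codon, "")[[1]] != strsplit(st, "")[[1]])
      if (length(d) != 1L) next
      m <- cm[1L] + 3L * (k - 1L) + (d - 1L)
      g <- mrna_to_genomic(m, tx)
      b <- substring(toy$genome[[tx$chrom]], g, g)
      alt_tx <- substr(st, d, d)
      alt <- if (tx$strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt_tx)))
      else alt_tx
      cc <- call_consequence(list(chrom = tx$chrom, pos = g, ref = b,
                                  alt = alt), tx, toy$genome)
      expect_identical(cc$category, "nonsense")
      expect_identical(cc$ptc_mrna_pos, cm[1L] + 3L * (k - 1L))
      hits <- hits + 1L
      break
    }
    if (hits >= 5L) break
  }
  expect_gte(hits, 5L)
})

test_that("the escape cascade applies the 50-nt junction rule inclusively", {
  toy <- toy_reference(widths = c(300L, 200L, 150L))
  tx <- toy$tx  # junction at mRNA 500
  mk <- function(ptc) list(key = "k", category = "nonsense",
                           ptc_mrna_pos = ptc, intron_index = NA_integer_)
  expect_identical(classify_nmd(mk(430L), tx),
                   list(status = "NMD_positive", reason = "qualifying_ptc"))
  expect_identical(classify_nmd(mk(455L), tx),
                   list(status = "NMD_negative",
                        reason = "within_50bp_of_final_junction"))
  expect_identical(classify_nmd(mk(449L), tx)$status, "NMD_positive")  # 51 nt
  expect_identical(classify_nmd(mk(450L), tx)$status, "NMD_negative") # 50 nt
  expect_identical(classify_nmd(mk(501L), tx)$reason, "last_exon")
})

test_that("splice, single-exon, override and non-truncating branches resolve", {
  toy <- toy_reference(widths = c(120L, 90L, 100L), seed = 13)
  tx <- toy$tx
  spl <- list(key = "k", category = "splice_acceptor", intron_index = 2L,
              ptc_mrna_pos = NA_integer_)
  expect_identical(classify_nmd(spl, tx)$reason, "final_intron_splice")
  spl1 <- within(spl, intron_index <- 1L)
  expect_identical(classify_nmd(spl1, tx),
                   list(status = "NMD_positive",
                        reason = "non_final_intron_splice"))
  mis <- list(key = "k", category = "missense", intron_index = NA_integer_,
              ptc_mrna_pos = NA_integer_)
  expect_identical(classify_nmd(mis, tx)$reason, "non_truncating")

  single <- toy_reference(widths = 300L)
  non <- list(key = "k", category = "nonsense", ptc_mrna_pos = 30L,
              intron_index = NA_integer_)
  expect_identical(classify_nmd(non, single$tx)$reason, "single_exon")

  ov <- data.frame(chrom = "chrT", pos = 10L, ref = "A", alt = "T")
  call <- list(key = variant_key("chrT", 10L, "A", "T"), category = "nonsense",
               ptc_mrna_pos = 100L, intron_index = NA_integer_)
  expect_identical(classify_nmd(call, tx, overrides = ov)$reason,
                   "experimental_escape_override")
})

test_that("NMD calls for nonsense PTCs are monotone in transcript position", {
  for (ref in reference_pool(seeds = 8:9)) {
    for (tx in ref$transcripts) {
      if (length(tx$exon_start) < 2L) next
      cm <- cds_mrna_span(tx)
      ptcs <- seq(cm[1L], cm[2L] - 3L, by = 3L)
      status <- vapply(ptcs, function(p) {
        classify_nmd(list(key = "k", category = "nonsense", ptc_mrna_pos = p,
                          intron_index = NA_integer_), tx)$status
      }, character(1))
      pos_idx <- which(status == "NMD_positive")
      if (length(pos_idx) > 0L) {
        # every PTC upstream of a triggering PTC also triggers
        expect_true(all(status[seq_len(max(pos_idx))] == "NMD_positive"))
      }
    }
  }
})

test_that("every annotated variant gets exactly one status and one reason", {
  p <- generator_params(seed = 17, n_pathogenic = 40L, n_benign_lof = 15L,
                        n_background = 25L)
  ref <- generate_reference(p)
  co <- generate_cohort(ref, p)
  ann <- annotate_nmd(co$variants, ref$transcripts, ref$genome)
  expect_identical(nrow(ann), nrow(co$variants))
  expect_true(all(ann$nmd_status %in% c("NMD_positive", "NMD_negative")))
  expect_false(anyNA(ann$nmd_reason))
  # status <-> reason coupling
  pos <- ann$nmd_status == "NMD_positive"
  expect_true(all(ann$nmd_reason[pos] %in%
                    c("qualifying_ptc", "non_final_intron_splice")))
  expect_false(any(ann$nmd_reason[!pos] %in%
                     c("qualifying_ptc", "non_final_intron_splice")))
})

test_that("variants with no matching transcript are dropped with a warning", {
  toy <- toy_reference(seed = 3)
  v <- data.frame(chrom = c(toy$tx$chrom, "chrMissing"),
                  pos = c(toy$tx$exon_start[1L], 5L),
                  ref = c(substring(toy$genome[[toy$tx$chrom]],
                                    toy$tx$exon_start[1L],
                                    toy$tx$exon_start[1L]), "A"),
                  alt = c("NNN", "T"), stringsAsFactors = FALSE)
  v$alt[1] <- setdiff(c("A", "C", "G", "T"), v$ref[1])[1]
  expect_warning(ann <- annotate_nmd(v, list(toy$tx), toy$genome),
                 "no clinically relevant")
  expect_identical(nrow(ann), 1L)
})
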