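test_that("generator parameters are validated", {
  expect_error(generator_params(founder_count = 50L, n_pathogenic = 10L),
               "more founders")
  expect_error(generator_params(absent_fraction = 1.2), "\\[0, 1\\]")
  expect_error(generator_params(exon_length = c(300L, 90L)), "range")
  expect_error(generator_params(trusted_submitters = "nobody"), "subset")
})

test_that("generated references have valid ORFs and in-range exon counts", {
  p <- generator_params(seed = 41, n_genes = 10L, exons_per_gene = c(2L, 6L))
  ref <- generate_reference(p)
  expect_identical(length(ref$transcripts), 10L)
  n_ex <- vapply(ref$transcripts, function(t) length(t$exon_start), integer(1))
  expect_true(all(n_ex >= 2L & n_ex <= 6L))
  expect_setequal(unique(vapply(ref$transcripts, function(t) t$strand,
                                character(1))), c("+", "-"))
  for (tx in ref$transcripts) {
    cds <- spliced_cds(tx, ref$genome)
    expect_identical(nchar(cds) %% 3L, 0L)
    expect_identical(substr(cds, 1, 3), "ATG")
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds))), "")[[1]]
    expect_identical(sum(aa == "*"), 1L)          # exactly one stop...
    expect_identical(aa[length(aa)], "*")         # ...at the end
  }
})

test_that("regeneration under a fixed seed is byte-identical", {
  p <- generator_params(seed = 5, n_genes = 4L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_study(p, d1)
  s2 <- simulate_study(p, d2)
  f1 <- sort(unlist(s1$files)); f2 <- sort(unlist(s2$files))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the data
  s3 <- generate_reference(generator_params(seed = 6, n_genes = 4L))
  expect_false(identical(s1$reference$genome, s3$genome))
})

test_that("cohort structure matches the requested frequency architecture", {
  p <- generator_params(seed = 8, n_pathogenic = 400L, n_benign_lof = 40L,
                        n_background = 60L, founder_count = 7L)
  ref <- generate_reference(p)
  co <- generate_cohort(ref, p)
  m <- co$manifest

  # manifest covers every emitted variant exactly once
  vk <- variant_key(co$variants$chrom, co$variants$pos, co$variants$ref,
                    co$variants$alt)
  mk <- variant_key(m$chrom, m$pos, m$ref, m$alt)
  expect_identical(sort(vk), sort(mk))
  expect_identical(anyDuplicated(mk), 0L)

  expect_true(all(co$variants$ac_adj <= co$variants$an_adj))
  expect_identical(sum(m$planted_founder), 7L)
  expect_true(all(m$ac_adj[m$planted_founder] > 3L))
  expect_true(all(m$ac_adj[m$planted_founder] >= p$founder_ac[1L] &
                    m$ac_adj[m$planted_founder] <= p$founder_ac[2L]))
  # non-founder pathogenic variants never cross the recurrence rule
  path <- m$class == "pathogenic"
  expect_true(all(m$ac_adj[path & !m$planted_founder] <= 3L))

  # absent fraction within a binomial 99% interval of its target
  n_path <- sum(path)
  expect_identical(n_path, 400L)
  absent <- sum(m$ac_adj[path] == 0L)
  expected <- p$absent_fraction * n_path
  half <- qnorm(0.995) * sqrt(n_path * p$absent_fraction *
                                (1 - p$absent_fraction))
  expect_true(abs(absent - expected) <= half + 0.5)

  # a visible minority of low-depth and non-PASS records
  expect_gt(sum(co$variants$an_adj < 80000L), 0L)
  expect_gt(sum(co$variants$filter_status != "PASS"), 0L)
  expect_lt(mean(co$variants$filter_status != "PASS"), 0.2)
})

test_that("manifest truth comes from the oracle and matches planted intent", {
  p <- generator_params(seed = 12)
  ref <- generate_reference(p)
  co <- generate_cohort(ref, p)
  m <- co$manifest
  # planted NMD-triggering intents are indeed NMD_positive in truth
  expect_true(all(m$true_nmd_status[m$intent == "splice"] == "NMD_positive"))
  expect_true(all(m$true_nmd_status[m$intent == "nonsense"] == "NMD_positive"))
  expect_true(all(m$true_nmd_status[m$intent %in%
                                      c("escape_nonsense",
                                        "final_intron_splice",
                                        "background")] == "NMD_negative"))
  # spot-check a sample of rows against a fresh oracle call
  set.seed(1)
  for (i in sample(nrow(m), 25L)) {
    orc <- nmd_oracle(m[i, ], ref$transcripts[[m$transcript_id[i]]],
                      ref$genome)
    expect_identical(orc$status, m$true_nmd_status[i])
    expect_identical(orc$reason, m$true_nmd_reason[i])
  }
})

test_that("submission and publication tables follow their planted models", {
  p <- generator_params(seed = 19, n_pathogenic = 150L)
  s <- simulate_study(p)
  subs <- s$submissions
  expect_true(all(subs$classification %in% c("P", "LP", "VUS", "LB", "B")))
  expect_true(all(subs$submitter %in% p$submitters))
  # noise rate within loose binomial bounds
  noise <- mean(subs$classification == "VUS")
  expect_lt(abs(noise - p$assertion_noise), 0.05)

  pub <- s$publications
  expect_true(all(pub$publication_count >= 0))
  # only observed variants carry publication records
  obs_keys <- variant_key(s$manifest$chrom, s$manifest$pos, s$manifest$ref,
                          s$manifest$alt)[s$manifest$ac_adj >= 1L]
  expect_setequal(variant_key(pub$chrom, pub$pos, pub$ref, pub$alt), obs_keys)
  ben <- pub$publication_count[pub$class == "benign"]
  expect_lt(abs(mean(ben == 0) - p$benign_zero_pub_fraction), 0.2)
  # planted positive frequency dependence for pathogenic counts
  pth <- pub[pub$class == "pathogenic", ]
  if (nrow(pth) >= 10L)
    expect_gt(cor(pth$maf, pth$publication_count, method = "spearman"), 0)
})
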