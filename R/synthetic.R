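# Synthetic study generator.
#
# Emits a miniature reference (genome + transcript models with valid ORFs),
# a cohort variant table shaped like a large exome-aggregation callset
# (most pathogenic alleles absent or singleton, a handful of planted
# founders above the recurrence threshold, per-site allele numbers around
# 121,000 with a minority under the 80,000 depth floor, a minority of
# non-PASS records), per-submitter assertion tables and publication counts.
# Every emitted variant is recorded in a ground-truth manifest whose NMD
# status comes from the brute-force oracle, so the production classifier can
# be scored against generation-time truth.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Parameters for the synthetic study generator
#'
#' Defaults mirror the frequency structure of the well-characterized
#' hereditary-cancer profile that motivates the analysis: ~85% of pathogenic
#' variants absent from the cohort, ~75% of the observed ones singletons, a
#' small planted founder set at allele counts 4-40, allele numbers around
#' 121,000 with a 5% tail below the 80,000 depth floor and 5% non-PASS
#' records.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_genes Number of genes (one per chromosome, strands alternate).
#' @param exons_per_gene,exon_length,intron_length,utr5_length,utr3_length
#'   Integer ranges `c(lo, hi)` sampled per gene.
#' @param n_pathogenic,n_benign_lof,n_background Variants per class:
#'   pathogenic truncating; benign NMD-escaping truncating (last exon /
#'   junction-proximal / final intron); missense-synonymous background.
#' @param founder_count Exact number of planted founders (allele count above
#'   the recurrence threshold).
#' @param founder_ac Allele-count range for planted founders.
#' @param absent_fraction Probability a pathogenic variant has allele count 0.
#' @param singleton_fraction Probability an observed non-founder pathogenic
#'   variant is a singleton.
#' @param an_mean,an_sd Normal model for per-site total allele number.
#' @param low_an_fraction Fraction of sites with allele number drawn below
#'   the 80,000 depth floor.
#' @param non_pass_fraction Fraction of records with a non-PASS filter.
#' @param submitters,trusted_submitters Submitter pool and its trusted
#'   subset.
#' @param assertion_noise Probability an assertion is degraded to VUS
#'   (creates conflicts).
#' @param benign_zero_pub_fraction Zero-inflation of benign publication
#'   counts.
#' @param pub_size,pub_b0,pub_b1 Negative-binomial publication-count model
#'   for pathogenic variants: `mu = exp(pub_b0 + pub_b1 * (log10(maf) + 4))`,
#'   planting a positive frequency-publication correlation.
#' @return Validated list of class `generator_params`.
#' @export
generator_params <- function(seed = 1L,
                             n_genes = 8L,
                             exons_per_gene = c(1L, 12L),
                             exon_length = c(90L, 300L),
                             intron_length = c(60L, 400L),
                             utr5_length = c(12L, 60L),
                             utr3_length = c(60L, 240L),
                             n_pathogenic = 80L,
                             n_benign_lof = 25L,
                             n_background = 60L,
                             founder_count = 5L,
                             founder_ac = c(4L, 40L),
                             absent_fraction = 0.853,
                             singleton_fraction = 0.746,
                             an_mean = 121000,
                             an_sd = 4000,
                             low_an_fraction = 0.05,
                             non_pass_fraction = 0.05,
                             submitters = c("lab_alpha", "lab_beta",
                                            "lab_gamma", "lab_delta",
                                            "lab_epsilon", "lab_zeta"),
                             trusted_submitters = c("lab_alpha", "lab_beta",
                                                    "lab_gamma", "lab_delta"),
                             assertion_noise = 0.08,
                             benign_zero_pub_fraction = 0.47,
                             pub_size = 2,
                             pub_b0 = 2,
                             pub_b1 = 0.9) {
  p <- as.list(environment())
  for (nm in c("exons_per_gene", "exon_length", "intron_length",
               "utr5_length", "utr3_length", "founder_ac")) {
    r <- p[[nm]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L)
      stop("parameter error: ", nm, " must be a non-degenerate range")
  }
  for (nm in c("absent_fraction", "singleton_fraction", "low_an_fraction",
               "non_pass_fraction", "benign_zero_pub_fraction", "assertion_noise")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("parameter error: ", nm, " must lie in [0, 1]")
  }
  if (p$founder_count > p$n_pathogenic)
    stop("parameter error: more founders requested than pathogenic variants")
  if (!all(p$trusted_submitters %in% p$submitters))
    stop("parameter error: trusted_submitters must be a subset of submitters")
  class(p) <- "generator_params"
  p
}

#' Generator parameters at the published BRCA-profile scale
#'
#' The study conditions used for end-to-end recovery runs: 1364 pathogenic
#' variants with 14 planted founders (the published BRCA1/2 profile), a
#' deeper gene set so that many distinct truncating variants can be placed,
#' and the default frequency architecture of [generator_params()].
#'
#' @param seed Integer seed.
#' @return A `generator_params` object.
#' @export
study_scale_params <- function(seed = 1L) {
  generator_params(seed = seed, n_genes = 14L, exons_per_gene = c(3L, 12L),
                   exon_length = c(120L, 300L), n_pathogenic = 1364L,
                   n_benign_lof = 120L, n_background = 200L,
                   founder_count = 14L)
}

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sense_codons <- function() {
  all <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               paste0), c("A", "C", "G", "T"), paste0))
  setdiff(all, STOP_CODONS)
}

#' Generate a synthetic reference (genome + transcript models)
#'
#' One gene per chromosome; strands alternate so both orientations are
#' exercised. Every CDS is a valid ORF: it begins with ATG, contains no
#' internal stop in the reference frame, and ends with a stop codon.
#' Introns carry canonical GT..AG dinucleotides in transcription direction.
#'
#' @param params A `generator_params` object.
#' @return List with `genome` (named character vector) and `transcripts`
#'   (named list of `transcript_model`).
#' @export
generate_reference <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  genome <- character(0)
  transcripts <- list()
  sense <- sense_codons()

  for (g in seq_len(params$n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_ex <- sample(params$exons_per_gene[1L]:params$exons_per_gene[2L], 1L)
    ex_w <- sample(params$exon_length[1L]:params$exon_length[2L], n_ex,
                   replace = TRUE)
    in_w <- if (n_ex > 1L)
      sample(params$intron_length[1L]:params$intron_length[2L], n_ex - 1L,
             replace = TRUE) else integer(0)
    L <- sum(ex_w)
    utr5 <- min(sample(params$utr5_length[1L]:params$utr5_length[2L], 1L),
                L - 9L - 3L)
    utr3 <- min(sample(params$utr3_length[1L]:params$utr3_length[2L], 1L),
                L - utr5 - 9L)
    cds_len <- L - utr5 - utr3
    cds_len <- cds_len - (cds_len %% 3L)
    utr3 <- L - utr5 - cds_len
    if (cds_len < 9L) stop("parameter error: exons too short for a valid ORF")

    n_cod <- cds_len %/% 3L
    cds_seq <- paste0("ATG",
                      paste(sample(sense, n_cod - 2L, replace = TRUE),
                            collapse = ""),
                      sample(STOP_CODONS, 1L))
    mrna <- paste0(rand_dna(utr5), cds_seq, rand_dna(utr3))

    # Lay the transcript onto the plus strand of its own chromosome.
    chunk_at <- cumsum(c(0L, ex_w))
    chunks <- substring(mrna, chunk_at[-length(chunk_at)] + 1L,
                        chunk_at[-1L])  # transcription order
    genomic_chunks <- if (strand == "+") chunks else
      rev(vapply(chunks, revcomp, character(1)))
    gap_seq <- vapply(in_w, function(w) {
      if (strand == "+") paste0("GT", rand_dna(w - 4L), "AG")
      else paste0("CT", rand_dna(w - 4L), "AC")
    }, character(1))

    pad <- 100L
    pieces <- character(0)
    exon_start <- integer(n_ex); exon_end <- integer(n_ex)
    at <- pad
    for (j in seq_len(n_ex)) {
      exon_start[j] <- at + 1L
      wj <- if (strand == "+") ex_w[j] else rev(ex_w)[j]
      exon_end[j] <- at + wj
      pieces <- c(pieces, genomic_chunks[j])
      at <- at + wj
      if (j < n_ex) {
        wi <- if (strand == "+") in_w[j] else rev(in_w)[j]
        pieces <- c(pieces, gap_seq[if (strand == "+") j else n_ex - j])
        at <- at + wi
      }
    }
    chrom <- paste0("chr", g)
    genome[[chrom]] <- paste0(rand_dna(pad), paste(pieces, collapse = ""),
                              rand_dna(pad))

    draft <- structure(list(strand = strand, exon_start = exon_start,
                            exon_end = exon_end), class = "transcript_model")
    cds_g <- mrna_to_genomic(c(utr5 + 1L, utr5 + cds_len), draft)
    tx <- transcript_model(
      transcript_id = sprintf("TX%03d", g),
      gene = sprintf("GENE%03d", g),
      chrom = chrom, strand = strand,
      exon_start = exon_start, exon_end = exon_end,
      cds_start = min(cds_g), cds_end = max(cds_g),
      clinically_relevant = TRUE
    )
    transcripts[[tx$transcript_id]] <- tx
  }
  list(genome = genome, transcripts = transcripts)
}

# -- variant construction helpers --------------------------------------------

# Single-base edits that turn a sense codon into a stop codon. Returns a data
# frame of candidate nonsense SNVs in mRNA coordinates.
nonsense_edits <- function(tx, genome) {
  cds <- spliced_cds(tx, genome)
  cm <- cds_mrna_span(tx)
  n_cod <- nchar(cds) %/% 3L
  out <- list()
  for (ci in 2L:(n_cod - 1L)) {
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    if (codon %in% STOP_CODONS) next
    for (st in STOP_CODONS) {
      d <- which(strsplit(codon, "")[[1L]] != strsplit(st, "")[[1L]])
      if (length(d) == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          codon_idx = ci, offset = d - 1L,
          new_base = substr(st, d, d),
          ptc_mrna = cm[1L] + 3L * (ci - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Convert a transcript-space SNV (mRNA position, new transcript base) into a
# genomic VCF record.
snv_record <- function(tx, genome, m_pos, new_base_tx) {
  gpos <- mrna_to_genomic(m_pos, tx)
  ref <- seq_at(genome, tx$chrom, gpos)
  alt <- if (tx$strand == "-") revcomp(new_base_tx) else new_base_tx
  if (identical(alt, ref)) return(NULL)
  list(chrom = tx$chrom, pos = gpos, ref = ref, alt = alt)
}

make_nonsense_variant <- function(tx, genome, region = c("any", "trigger", "escape"),
                                  cache = NULL) {
  region <- match.arg(region)
  ed <- if (!is.null(cache)) {
    if (is.null(cache[[tx$transcript_id]]))
      cache[[tx$transcript_id]] <- nonsense_edits(tx, genome)
    cache[[tx$transcript_id]]
  } else nonsense_edits(tx, genome)
  if (is.null(ed)) return(NULL)
  junction <- final_junction_mrna(tx)
  if (!is.na(junction)) {
    if (region == "trigger") ed <- ed[junction - ed$ptc_mrna > 50L, , drop = FALSE]
    if (region == "escape") ed <- ed[junction - ed$ptc_mrna <= 50L, , drop = FALSE]
  }
  if (nrow(ed) == 0L) return(NULL)
  e <- ed[sample.int(nrow(ed), 1L), ]
  snv_record(tx, genome, e$ptc_mrna + e$offset, e$new_base)
}

make_frameshift_variant <- function(tx, genome) {
  cm <- cds_mrna_span(tx)
  gpos <- mrna_to_genomic((cm[1L] + 3L):(cm[2L] - 6L), tx)
  gpos <- sort(gpos)
  insertion <- runif(1) < 0.35
  if (insertion) {
    q <- sample(gpos, 1L)
    ref <- seq_at(genome, tx$chrom, q)
    list(chrom = tx$chrom, pos = q, ref = ref,
         alt = paste0(ref, sample(c("A", "C", "G", "T"), 1L)))
  } else {
    ok <- gpos[(gpos + 1L) %in% gpos]
    if (length(ok) == 0L) return(NULL)
    q <- if (length(ok) == 1L) ok else sample(ok, 1L)
    list(chrom = tx$chrom, pos = q,
         ref = seq_at(genome, tx$chrom, q, q + 1L),
         alt = seq_at(genome, tx$chrom, q))
  }
}

make_splice_variant <- function(tx, genome, final = FALSE) {
  it <- intron_table(tx)
  if (nrow(it) == 0L) return(NULL)
  k <- if (final) nrow(it) else if (nrow(it) == 1L) 1L else
    sample(seq_len(nrow(it) - 1L), 1L)
  gpos <- sample(c(it$donor1[k], it$donor2[k], it$acceptor1[k], it$acceptor2[k]), 1L)
  ref <- seq_at(genome, tx$chrom, gpos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(chrom = tx$chrom, pos = gpos, ref = ref, alt = alt)
}

make_background_variant <- function(tx, genome) {
  cm <- cds_mrna_span(tx)
  cds <- spliced_cds(tx, genome)
  for (attempt in 1:20) {
    m <- sample((cm[1L] + 3L):(cm[2L] - 3L), 1L)
    rel <- m - cm[1L] + 1L
    ci <- (rel - 1L) %/% 3L + 1L
    codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    off <- (rel - 1L) %% 3L + 1L
    old <- substr(codon, off, off)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    mut <- codon
    substr(mut, off, off) <- new
    if (mut %in% STOP_CODONS || codon %in% STOP_CODONS) next
    rec <- snv_record(tx, genome, m, new)
    if (!is.null(rec)) return(rec)
  }
  NULL
}

#' Generate a synthetic cohort with ground truth
#'
#' Plants pathogenic truncating variants (nonsense, frameshift, non-final
#' splice), benign NMD-escaping truncations, and a missense/synonymous
#' background; samples allele counts so that roughly `absent_fraction` of
#' pathogenic variants are unobserved and exactly `founder_count` exceed the
#' recurrence threshold; draws per-site allele numbers with a configurable
#' tail below the depth floor; marks a configurable fraction non-PASS. The
#' NMD truth in the manifest comes from [nmd_oracle()], not from the
#' production classifier.
#'
#' @param reference Output of [generate_reference()].
#' @param params A `generator_params` object.
#' @return List with `variants` (cohort table: `chrom`, `pos`, `ref`, `alt`,
#'   `filter_status`, `ac_adj`, `an_adj`) and `manifest` (ground truth per
#'   variant).
#' @export
generate_cohort <- function(reference, params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed + 1001L)
  txs <- reference$transcripts
  genome <- reference$genome
  multi <- Filter(function(t) length(t$exon_start) > 1L, txs)
  if (length(multi) == 0L) stop("parameter error: no multi-exon transcripts")

  seen <- character(0)
  recs <- list()
  edit_cache <- new.env(parent = emptyenv())
  plant <- function(maker, class, intent, n) {
    made <- 0L
    attempts <- 0L
    while (made < n && attempts < 50L * n) {
      attempts <- attempts + 1L
      tx <- multi[[sample.int(length(multi), 1L)]]
      v <- maker(tx)
      if (is.null(v)) next
      k <- variant_key(v$chrom, v$pos, v$ref, v$alt)
      if (k %in% seen) next
      seen <<- c(seen, k)
      v$gene <- tx$gene; v$transcript_id <- tx$transcript_id
      v$class <- class; v$intent <- intent
      recs[[length(recs) + 1L]] <<- v
      made <- made + 1L
    }
    if (made < n)
      stop("generator could not place ", n, " ", intent, " variants")
  }

  n_non <- round(params$n_pathogenic * 0.45)
  n_fs <- round(params$n_pathogenic * 0.35)
  n_spl <- params$n_pathogenic - n_non - n_fs
  plant(function(tx) make_nonsense_variant(tx, genome, "trigger", edit_cache),
        "pathogenic", "nonsense", n_non)
  plant(function(tx) make_frameshift_variant(tx, genome),
        "pathogenic", "frameshift", n_fs)
  plant(function(tx) if (n_introns(tx) >= 2L)
    make_splice_variant(tx, genome, final = FALSE) else NULL,
    "pathogenic", "splice", n_spl)

  n_esc_non <- round(params$n_benign_lof * 0.6)
  plant(function(tx) make_nonsense_variant(tx, genome, "escape", edit_cache),
        "benign", "escape_nonsense", n_esc_non)
  plant(function(tx) make_splice_variant(tx, genome, final = TRUE),
        "benign", "final_intron_splice", params$n_benign_lof - n_esc_non)
  plant(function(tx) make_background_variant(tx, genome),
        "benign", "background", params$n_background)

  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))

  # Allele counts. Pathogenic: absent / singleton / low-recurrence, with
  # exactly founder_count planted founders among the observed.
  n <- nrow(df)
  is_path <- df$class == "pathogenic"
  ac <- integer(n)
  path_idx <- which(is_path)
  observed <- path_idx[runif(length(path_idx)) >= params$absent_fraction]
  if (length(observed) < params$founder_count) {
    extra <- setdiff(path_idx, observed)
    observed <- c(observed, extra[seq_len(params$founder_count - length(observed))])
  }
  founders <- if (length(observed) == params$founder_count) sort(observed)
    else sort(observed[sample.int(length(observed), params$founder_count)])
  rest <- setdiff(observed, founders)
  ac[founders] <- sample(params$founder_ac[1L]:params$founder_ac[2L],
                         length(founders), replace = TRUE)
  sing <- runif(length(rest)) < params$singleton_fraction
  ac[rest] <- ifelse(sing, 1L, sample(2:3, length(rest), replace = TRUE))

  ben_idx <- which(!is_path)
  log_maf <- runif(length(ben_idx), -5, -1.5)
  an_tmp <- params$an_mean
  ac[ben_idx] <- pmax(0L, as.integer(round(10^log_maf * an_tmp)))

  low <- runif(n) < params$low_an_fraction
  an <- as.integer(round(stats::rnorm(n, params$an_mean, params$an_sd)))
  an[low] <- as.integer(sample(40000:79999, sum(low), replace = TRUE))
  an <- pmax(an, ac, 1L)
  filt <- ifelse(runif(n) < params$non_pass_fraction, "LowQual", "PASS")

  df$ac <- ac
  df$an <- an
  df$filter <- filt
  df$planted_founder <- seq_len(n) %in% founders

  # Ground truth from the brute-force oracle.
  truth <- lapply(seq_len(n), function(i) {
    nmd_oracle(df[i, ], txs[[df$transcript_id[i]]], genome)
  })
  df$true_category <- vapply(truth, function(t) t$category, character(1))
  df$true_nmd_status <- vapply(truth, function(t) t$status, character(1))
  df$true_nmd_reason <- vapply(truth, function(t) t$reason, character(1))
  df$true_ptc_mrna_pos <- vapply(truth, function(t) t$ptc_mrna_pos, integer(1))

  ord <- order(match(df$chrom, names(genome)), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  variants <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                         alt = df$alt, filter_status = df$filter,
                         ac_adj = df$ac, an_adj = df$an,
                         stringsAsFactors = FALSE)
  manifest <- df
  names(manifest)[names(manifest) == "ac"] <- "ac_adj"
  names(manifest)[names(manifest) == "an"] <- "an_adj"
  names(manifest)[names(manifest) == "filter"] <- "filter_status"
  list(variants = variants, manifest = manifest)
}

#' Generate per-submitter assertion records
#'
#' Pathogenic variants receive 0-4 assertions drawn from the submitter pool,
#' P/LP with probability `1 - assertion_noise` (VUS otherwise, creating
#' conflicts); benign variants receive LB/B assertions with the same noise.
#'
#' @param manifest Manifest from [generate_cohort()].
#' @param params A `generator_params` object.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `submitter`, `classification`.
#' @export
generate_submissions <- function(manifest, params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed + 2002L)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    n_sub <- sample(0:4, 1L, prob = c(0.15, 0.25, 0.30, 0.20, 0.10))
    if (n_sub == 0L) next
    subs <- sample(params$submitters, n_sub)
    for (s in subs) {
      noisy <- runif(1) < params$assertion_noise
      cls <- if (noisy) "VUS" else if (manifest$class[i] == "pathogenic")
        sample(c("P", "LP"), 1L) else sample(c("LB", "B"), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = manifest$chrom[i], pos = manifest$pos[i],
        ref = manifest$ref[i], alt = manifest$alt[i],
        gene = manifest$gene[i], submitter = s, classification = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), submitter = character(),
                      classification = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Generate publication counts with a planted frequency dependence
#'
#' Observed pathogenic variants draw counts from an overdispersed
#' negative-binomial model whose mean increases with allele frequency
#' (planting a positive correlation); benign counts are zero-inflated and
#' small.
#'
#' @param manifest Manifest from [generate_cohort()].
#' @param params A `generator_params` object.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `class`, `maf`,
#'   `publication_count`.
#' @export
generate_publications <- function(manifest, params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed + 3003L)
  obs <- manifest[manifest$ac_adj >= 1L, , drop = FALSE]
  maf <- obs$ac_adj / obs$an_adj
  cls <- ifelse(obs$class == "pathogenic", "pathogenic", "benign")
  mu <- exp(params$pub_b0 + params$pub_b1 * (log10(maf) + 4))
  count <- integer(nrow(obs))
  is_p <- cls == "pathogenic"
  count[is_p] <- stats::rnbinom(sum(is_p), size = params$pub_size,
                                mu = mu[is_p])
  nb <- sum(!is_p)
  zeros <- runif(nb) < params$benign_zero_pub_fraction
  count[!is_p] <- ifelse(zeros, 0L, stats::rpois(nb, 2.5))
  data.frame(chrom = obs$chrom, pos = obs$pos, ref = obs$ref, alt = obs$alt,
             class = cls, maf = maf, publication_count = count,
             stringsAsFactors = FALSE)
}

#' Run the full generator and (optionally) write study files
#'
#' Calls [generate_reference()], [generate_cohort()],
#' [generate_submissions()] and [generate_publications()] in order, each
#' seeded deterministically from `params$seed`, and optionally writes
#' `genome.fa`, `transcripts.gff3`, `cohort.vcf`, `submissions.tsv`,
#' `publications.tsv` and `manifest.tsv` into `dir`. Regeneration under the
#' same seed is byte-identical.
#'
#' @param params A `generator_params` object.
#' @param dir Optional output directory (created if missing).
#' @return List with `reference`, `variants`, `manifest`, `submissions`,
#'   `publications`, and `files` (paths, when `dir` was given).
#' @export
simulate_study <- function(params = generator_params(), dir = NULL) {
  reference <- generate_reference(params)
  cohort <- generate_cohort(reference, params)
  submissions <- generate_submissions(cohort$manifest, params)
  publications <- generate_publications(cohort$manifest, params)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      genome = file.path(dir, "genome.fa"),
      transcripts = file.path(dir, "transcripts.gff3"),
      vcf = file.path(dir, "cohort.vcf"),
      submissions = file.path(dir, "submissions.tsv"),
      publications = file.path(dir, "publications.tsv"),
      manifest = file.path(dir, "manifest.tsv")
    )
    write_genome_fasta(reference$genome, files$genome)
    write_transcripts_gff3(reference$transcripts, files$transcripts)
    write_cohort_vcf(cohort$variants, files$vcf)
    write_tsv_file(submissions, files$submissions)
    write_tsv_file(publications, files$publications)
    write_tsv_file(cohort$manifest, files$manifest)
  }
  list(reference = reference, variants = cohort$variants,
       manifest = cohort$manifest, submissions = submissions,
       publications = publications, files = files)
}
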