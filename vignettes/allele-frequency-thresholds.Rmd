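---
title: "Empirical allele-frequency thresholds from the population burden of pathogenic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical allele-frequency thresholds from the population burden of pathogenic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The rarity of a variant in the general population is a prerequisite for
pathogenicity in Mendelian disease (founder mutations excepted), and
"allele frequency greater than expected for disorder" is strong evidence
for a benign classification under the ACMG/AMP framework. But *how common
is too common*? Large exome-aggregation cohorts (tens of thousands of
individuals, on the order of 121,000 genotyped alleles per well-covered
site) make it possible to answer the question empirically: measure the
frequency distribution of variants that are confidently pathogenic, and
place the threshold just above the bulk of that distribution. Variants
above the threshold are not automatically benign — founder mutations sit
there — but they are rare enough, and well-published enough, that a
mandatory literature review is a workable safeguard.

`nmdburden` implements this analysis as a reusable, fully testable
pipeline. Because curated pathogenic catalogs exist for very few genes,
the pipeline leans on a structural surrogate: truncating variants
predicted to trigger nonsense-mediated decay (NMD) are expected to be
pathogenic in genes where loss of protein function is the established
disease mechanism, regardless of whether anyone has asserted them yet.

## The NMD model

A premature termination codon (PTC) usually commits a transcript to decay,
with well-known escape routes tied to transcript structure. The classifier
works entirely in spliced-transcript ("mRNA") coordinates on the single
clinically relevant transcript designated per gene:

1. **Consequence calling.** Coding SNVs are classified by translating the
   mutant codon (nonsense / missense / synonymous); coding indels by the
   length change modulo 3 (frameshift vs in-frame); variants touching the
   consensus splice dinucleotides (first/last two intronic bases) are
   splice donor/acceptor calls, and splice disruption takes precedence for
   indels spanning an exon–intron boundary.
2. **PTC localization.** For nonsense variants the PTC is the affected
   codon. For frameshifts the mutant spliced transcript is rebuilt and
   translated from the CDS start in the shifted frame, through the 3' UTR,
   until the first stop; that stop is mapped back to reference-frame mRNA
   coordinates (positions downstream of the edit shift by the net length
   change; a stop starting inside inserted bases maps to the edit start).
   A frameshift reaching the transcript end without a stop yields no PTC.
3. **Escape rules.** A truncating variant is `NMD_negative` when its
   variant key is on the experimental-escape override list; when it is a
   splice-dinucleotide variant of the *final* intron; when the transcript
   has a single exon; when no PTC exists; when the PTC's first base lies in
   the final exon (past the final exon–exon junction); or when the PTC
   lies within 50 nt upstream of that junction. Everything else —
   a junction-distal PTC, or a splice-dinucleotide hit in any non-final
   intron — is `NMD_positive`. Intron indices follow transcription order,
   so "final intron" is the biologically last one on either strand.

Design choices worth stating explicitly, since the underlying biology does
not force them:

* **The 50-nt window is inclusive**: a PTC exactly 50 nt upstream of the
  junction escapes. The canonical statement of the rule does not specify
  the boundary; ties at the boundary are rare and the choice is
  documented here and pinned by tests.
* **Non-final-intron splice variants are `NMD_positive` without PTC
  modelling.** No exon-skipping simulation is attempted; the only splice
  escape recognized is the final intron.
* **Frameshifts with no downstream stop are `NMD_negative`
  (`no_ptc_found`)**: without a PTC the trigger definition cannot be met.
* **Reference-frame mapping of frameshift PTCs** keeps every downstream
  rule a subtraction against the reference junction position. For stops
  that begin inside inserted bases the mapped coordinate is clamped to the
  edit start, which can differ from the physical mutant-transcript
  distance by at most the insertion length minus one — well inside the
  window's biological fuzziness, and applied identically by the classifier
  and the independent oracle so the dual-route check is exact.

Every classification carries a machine-readable reason code, and
`NMD_positive`/`NMD_negative` partition the input: any variant that does
not meet the trigger criteria is an escape.

## Cohort frequency accounting

Frequencies are `AC_adj / AN_adj` — adjusted allele count over adjusted
total alleles — computed only at sites that pass two filters: the cohort's
own quality filter (`PASS`) and a minimum depth of **80,000 genotyped
alleles**, read as an inclusive floor ("a minimum of" is an attainable
bound). Multi-allelic records are decomposed into one record per alternate
allele with the site's shared allele number. Subpopulation stratification
is deliberately out of scope: the analysis targets the global cohort
frequency.

Observed variants are binned into five left-closed, right-open bins
(`<0.005%`, `0.005–0.01%`, `0.01–0.05%`, `0.05–0.1%`, `≥0.1%`); absent
variants (allele count 0) are excluded from bins and reported separately,
but count as "below" every positive threshold in fraction-below-threshold
summaries. Variants observed in **more than three** alleles are flagged as
recurrence outliers — the founder-mutation candidates that any
threshold-based rule must route to literature review. Reported
frequencies are displayed as percentages at two significant figures;
internal arithmetic is full precision.

## Consensus pathogenicity and the pathogenic set

Per-submitter assertions on the five-level vocabulary (P/LP/VUS/LB/B) are
restricted to a trusted-submitter list, then collapsed per variant: two or
more trusted submitters all asserting P/LP give `consensus_pathogenic`;
unanimous LB/B gives `consensus_benign`; P/LP mixed with anything else is
`conflicting`; a lone trusted P/LP is `single_submitter_pathogenic` and
must be resolved by an external adjudication table (a full ACMG criteria
engine is out of scope — the adjudication file is an input). Assertions
outside the five terms are dropped with a warning.

The analysis's *pathogenic set* is the union of consensus-pathogenic
variants, adjudicated single-submitter/conflicting variants, and
`NMD_positive` variants in genes with an established loss-of-function
mechanism (expected pathogenic by variant type alone); members carry
provenance tags, and consensus beats any contradicting adjudication.

## Statistics

* **Rank-sum comparisons** (e.g. NMD-triggering vs NMD-escaping frequency
  distributions, pathogenic vs benign publication counts) use the
  two-sided Wilcoxon test with the tie-corrected normal approximation,
  switching to exact enumeration when both samples have at most eight
  observations and no ties. The test suite checks the exact branch against
  a brute-force enumeration over all labelings and the approximate branch
  against a type-I-error simulation at n = 200 per group (1,000 replicates
  of a zero-inflated frequency null).
* **Correlations** between frequency and publication count default to the
  product-moment estimator on raw values, with a rank-based (Spearman)
  switch in the configuration; the source analyses never name their
  estimator, so both are offered and neither is asserted as canonical.
* **Box summaries** use linear-interpolation quartiles (R's type 7) with
  whiskers at the minimum and maximum, so summary output is deterministic.

## What the synthetic generator emulates

`generator_params()` / `simulate_study()` produce a complete miniature
study: a genome with one gene per chromosome (1–12 exons, both strands,
canonical GT..AG introns, valid ORFs), a cohort VCF, submission and
publication tables, and a ground-truth manifest. The frequency
architecture mirrors the published BRCA1/2 pathogenic profile: ~85.3% of
pathogenic variants absent, ~74.6% of observed ones singletons (150 of
201 in the published profile), the remainder at allele counts 2–3, and an
exact number of planted founders at allele counts 4–40. Allele numbers
are drawn around 121,000 (SD 4,000) with 5% of sites below the 80,000
floor, and 5% of records are non-PASS. Publication counts for pathogenic
variants follow an overdispersed negative-binomial model whose mean rises
with frequency, planting a positive correlation; benign counts are
zero-inflated at 47%.

Ground-truth NMD status is computed at generation time by
`nmd_oracle()` — an independent implementation that enumerates exonic
positions base by base, rebuilds the full mutant transcript, translates it
with a different codon engine, and applies the escape rules literally — so
agreement between the production classifier and the manifest is a real
two-route check, not a tautology.

What the generator does **not** emulate: real human gene structure and
length distributions, mutation-rate or coalescent population models,
linkage, sequencing error, or the long tail of annotation pathologies in
real transcript databases (overlapping transcripts, non-canonical splice
sites, selenoproteins). Passing recovery tests therefore demonstrates the
*pipeline's* correctness on structurally valid inputs, not robustness to
every oddity of real annotation.

## Problem sizes and numerical choices

End-to-end recovery runs use `study_scale_params()`: 14 genes, 1,364
pathogenic variants, 14 planted founders — the published profile's scale,
at which absent-fraction sampling is checked against a binomial 99%
interval and founder recovery above the 0.01% threshold must be exact.
Classifier-vs-oracle agreement is measured on upwards of a thousand
random transcript × variant cases per run, with 100% agreement required.
The rank-sum null simulation uses 1,000 replicates at 200 observations
per arm. Degenerate inputs are defined, not improvised: zero allele
number is an error for frequency computation, empty variant sets yield
zero-count profiles with `NA` fractions, correlation is reported as `NA`
for classes with fewer than three records or zero variance, and binning
is total over `[0, ∞)`.

## Packaged reference tables

Three transcribed published summary tables ship under `inst/extdata/`
(each guarded by a checksum): the fourteen recurrent/founder BRCA1/2
pathogenic variants with allele counts, the per-gene five-bin frequency
table for 79 loss-of-function-mechanism genes, and the 74-variant
hypertrophic-cardiomyopathy gold-standard missense set with its depth and
quality flags. `load_brca_pathogenic_set()` reconstructs the full
1,364-variant profile from the printed composition (1,163 absent, 150
singletons, 37 at allele count 2–3, 14 founders); synthesized rows use
the nominal 121,000-allele depth since only their count class is
published. One transcription caveat: the published share of variants
below 0.005% (99.4%) implies eight variants at or above that threshold,
while the printed per-variant frequencies place only seven there — the
reconstruction therefore reports 99.5%, one variant shy of the printed
fraction, and the tables are kept faithful to the printed values rather
than adjusted.

## Known limitations

* One clinically relevant transcript per gene; variants mapping to no
  supplied transcript are dropped with a warning.
* No exon-definition or readthrough NMD models; no start-loss handling.
* The ACMG adjudication of non-consensus variants is an input, not a
  computation.
* Publication counts are an input table; no literature retrieval.
* Figures are not rendered; all summaries are numeric tables.
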