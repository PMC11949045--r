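---
title: "Quantifying APOBEC3 mutagenesis and EMT shifts in paired tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying APOBEC3 mutagenesis and EMT shifts in paired tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apobecemt)
```

## The scientific problem

APOBEC3 cytidine deaminases — principally APOBEC3A (A3A) and APOBEC3B
(A3B) — mutate cytosine in single-stranded DNA and leave a recognizable
imprint on tumor genomes: C>T and C>G substitutions concentrated at TpC
dinucleotides, catalogued as single-base-substitution signatures SBS2 and
SBS13. In high-grade serous ovarian carcinoma (HGSOC), the burden of this
mutational process varies widely between patients, tends to be higher in
metastatic than in matched primary lesions, and correlates with shorter
overall survival and with a shift of the tumor transcriptome away from the
epithelial program toward hybrid-EMT and mesenchymal states.

`apobecemt` implements the computational chain needed to study these
questions on somatic SNV calls and expression matrices:

1. **catalog** — 96-channel pyrimidine-normalized trinucleotide mutation
   catalogs from VCF/variant tables plus a reference sequence;
2. **signatures** — non-negative least-squares (NNLS) refitting against a
   fixed reference signature set, de novo extraction by Kullback–Leibler
   NMF, cosine matching, and the SBS2+SBS13 "APOBEC fraction";
3. **attribution** — A3A-like versus A3B-like calls from the
   tetranucleotide context (YTCA vs RTCA) of mutated cytosines;
4. **cohort** — APOBEC-high/low classification, paired primary/metastatic
   enrichment, survivor classes and survival summaries;
5. **emt_scoring** — relative fold changes, DEG threshold filtering, the
   epithelial/hEMT/mesenchymal trajectory score, and the IL6-correlated
   functional-category score;
6. **synthetic_data** — seeded generators for every input above, with
   planted, recorded ground truth.

Upstream read alignment and variant calling, differential-expression model
fitting and gene-set enrichment analysis are out of scope: the package
consumes their outputs.

## Mutation catalogs

Every SNV is assigned to one of 96 channels: six pyrimidine substitution
classes (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flanking-base pairs. A
mutation whose reference base is a purine is reverse-complemented first, so
`G>A` at `TGA` is counted as `C>T` at `TCA`. Channel order is the standard
layout: substitution class slowest, then 5' flank, then 3' flank, each in
A, C, G, T order.

Variants that contradict the reference (REF mismatch), sit too close to a
contig end for a full trinucleotide, or have an ambiguous base in the
window are skipped and itemized in a `skip_report`, never silently counted.
Coordinates are 1-based and fully closed, matching VCF.

```{r catalog-example}
ref <- make_reference(50000, gc_fraction = 0.41, n_contigs = 1, seed = 1)
sig <- reference_signatures()
v <- sample_variants(ref, sig[, "SBS2"], n = 1000, seed = 2)
catalog <- build_catalog(v, ref)
catalog
head(sort(catalog[, 1], decreasing = TRUE))
```

## Signature refitting and extraction

**Refitting.** `fit_exposures()` solves, per sample, the non-negative
least-squares problem `min ||m - S a||` over activities `a >= 0`, where `m`
is the 96-channel catalog column and `S` the reference signature matrix.
Relative contributions are `a / sum(a)`; the APOBEC fraction is the summed
relative contribution of SBS2 and SBS13. The squared-error/NNLS objective is
the classic fit-to-signatures behavior; the refit loss is a package choice,
as only the reference set itself is conventionally fixed. Per-sample
diagnostics (relative L2 residual, cosine to data) are always returned, and
`prune_reference_refit()` offers optional backward elimination (drop a
signature while no sample's cosine-to-data falls by more than 0.01),
because refitting against large reference sets is known to overfit.

**The bundled reference.** `reference_signatures()` ships five synthetic
signature shapes named after the processes they emulate (SBS2, SBS13, SBS1,
SBS5, SBS18). They reproduce the qualitative channel structure — TpC C>T
and C>G peaks for the APOBEC pair, CpG C>T for SBS1, a flat clock-like
background, a C>A process — with pairwise cosines below 0.4, but they are
**not** the COSMIC estimates, which are not redistributed here. For real
analyses, load a COSMIC-format TSV with `read_signature_tsv()`.

**De novo extraction.** `nmf_extract()` factorizes the catalog matrix under
the generalized Kullback–Leibler divergence with the standard multiplicative
updates, the objective tracked every iteration (the trace is non-increasing
by construction and asserted in tests), multiple seeded random restarts
(default 20), and the best restart kept. Columns are renormalized to sum 1
with the scale folded into exposures, so exposures stay in mutation units.
Rank selection is deliberately user-supplied; nothing auto-selects a rank.
Extracted signatures are identified by `match_signatures()`, which solves
the one-to-one assignment maximizing total cosine similarity (exhaustive for
small problems, greedy beyond ~200k candidate assignments) and flags pairs
below a 0.75 reporting floor.

```{r refit-example}
fit <- fit_exposures(catalog, sig)
round(fit$relative[, 1], 3)
apobec_fraction(fit)
```

## Enzyme attribution: YTCA vs RTCA

A3A preferentially deaminates cytosine in a YTCA tetranucleotide (Y = C or
T 5' of the TpC), A3B in RTCA (R = A or G). `count_tca_contexts()` counts,
over qualifying mutations (C>T or C>G at a TCA trinucleotide after
pyrimidine normalization — the substitution composition of SBS2/13), the
YTCA and RTCA classes of the 4-mer, plus the genomic availability of both
contexts from a double-stranded 4-mer scan of the reference.
`attribute_enzyme()` labels a sample A3A-like when the
background-normalized ratio `(ytca / bg_ytca) / (rtca / bg_rtca)` exceeds
`1 + margin` (default margin 0.10), A3B-like below the reciprocal, and
indeterminate otherwise or below `min_support` (default 20) informative
mutations. The normalized ratio is the simplest statistic consistent with
the Y/R dichotomy; no enrichment formula is standard, so both the raw and
normalized ratios are reported, and both per-sample and pooled modes exist
(`attribute_samples()`).

## Cohort classification and survival

`classify_apobec()` labels a sample APOBEC-high when its fraction strictly
exceeds the threshold — either a fixed cutoff (conventionally >4%, i.e.
0.04) or the cohort's upper quartile; with the strict inequality, ties at
the quartile fall to low. `paired_enrichment()` reports per-patient
metastatic/primary ratios (undefined for zero primary fractions) and the
pooled ratio of summed fractions, which is the robust quantity when primary
fractions are near zero. `survivor_class()` uses strict cuts at 3.5 and 5
years (365.25 days/year). `group_survival_summary()` gives arithmetic group
means with a Welch two-sided test — a difference of means, not a censoring
model, because only group averages are being compared.
`association_test()` is the uncorrected two-sided Fisher exact test with a
Haldane-corrected sample odds ratio when a cell is zero.

## Expression scores

Fold changes are linear relative fold changes,
`(x - mean_ref) / mean_ref` (`log2` optionally), computed per gene from
group means via `fold_change_table()`; genes with a zero reference mean are
dropped and reported. `filter_degs()` applies strict `adjusted_p < p_cut`
and `|fc| > fc_cut` thresholds.

The **EMT trajectory score** takes three curated gene sets. The epithelial
score is the mean fold change over epithelial genes; the hEMT and
mesenchymal scores are their category means minus the epithelial mean, so a
positive mesenchymal score means the mesenchymal program rose relative to
the epithelial one, and values below 0 indicate underrepresented gene
groups. Genes absent from the fold-change table are skipped and counted —
never imputed as zero, which would drag the subtracted scores toward the
epithelial mean.

The **IL6-correlated gene score** averages each member gene over replicates
and reports, per functional category (inflammation, metabolism, cell cycle
control/apoptosis, motility/adhesion, proliferation), the summed case means
minus summed control means. The sign convention — positive = elevated in
the case (A3A-exposed) group — matches the direction in which IL-6 and its
co-expressed program move; the opposite subtraction order is a one-line
change if needed. The expression scale is whatever normalized matrix the
user supplies; library-size-normalized counts are the intended input, and
replicate averaging precedes summation.

The gene sets shipped in `example_emt_gene_sets()`,
`example_il6_gene_sets()` and the `inst/extdata/*_synthetic.gmt` fixtures
are illustrative stand-ins built from widely used marker genes; curated
published lists should be substituted via `read_gmt()` for real data.

## What the simulators emulate — and what they do not

The generators produce data under the conditions the analyses are designed
for, with all truth recorded at generation time:

- `make_reference()` — i.i.d. bases at a target GC (default scenarios use
  100 kb at GC 0.41, matching the human genome-wide GC fraction; long
  enough that all 32 trinucleotide contexts have thousands of positions).
- `sample_variants()` — channel first (multinomial over the 96 channels),
  then a uniformly chosen genomic position matching the channel's context
  on either strand. This guarantees catalog/truth consistency by
  construction: rebuilding the catalog reproduces the drawn channels
  exactly. Channels without genomic support are renormalized away.
- `simulate_cohort()` — per patient, a primary sample at APOBEC weight
  `base_apobec` and a metastatic sample at `min(1, base_apobec * met_fold)`
  (clamps recorded), the weight split equally between SBS2 and SBS13 and
  the remainder spread over the background signatures; 5,000 mutations per
  sample by default, a size chosen for signature-recovery power since
  per-sample exome counts entering such analyses are rarely reported.
  Default planted parameters mirror the motivating comparisons: a 6-fold
  metastatic enrichment on a 1% primary weight, and survival means of
  816.7 / 1,655.3 days (sd 200) for APOBEC-high/low truth labels, floored
  at 1 day. Survival is normal because only group means are modeled —
  there is no censoring process to emulate.
- `simulate_expression()` — gamma-Poisson (negative binomial) counts with a
  common base mean and dispersion (`variance = mu + dispersion * mu^2`;
  dispersion 0 gives Poisson), case-group genes in effect sets scaled
  multiplicatively. NB is the standard bulk RNA-seq count model.

They deliberately do **not** emulate: non-uniform genomic composition,
replication-timing or strand biases, indels/CNVs/SVs, tumor purity or
subclonal structure, per-gene baseline variation, library-size differences,
or censored survival. Passing tests therefore demonstrate that the
estimators recover what was planted under clean sampling noise — they are
statements about the pipeline's correctness, not about robustness to every
artifact of real cohorts.

## Numerical choices

- NNLS via an active-set solver; relative contributions are `NA` (flagged),
  not 0/0, for an all-zero sample.
- KL-NMF: multiplicative updates with an epsilon guard of 1e-12 in
  divisions; convergence at relative objective change below `tol` (default
  1e-6), maximum 2,000 iterations, 20 restarts seeded `seed + restart - 1`;
  non-convergence returns the result with a warning, never an error.
- Strict inequalities wherever a published cutoff is phrased as ">": the
  4% classification cut, both survivor-class cuts, and both DEG filters.
- Assignment matching enumerates injective assignments up to 2e5
  candidates, then falls back to greedy.
- Simulation sizes in tests (100 kb references, 5,000 mutations/sample,
  20–50 replicates) are chosen so that Monte-Carlo envelopes are tight at
  desk scale while the full suite stays inside a coffee break.

## Known limitations

- The bundled signature shapes are stand-ins; absolute exposures refit
  against them are not comparable to COSMIC-based exposures on real data.
- The YTCA/RTCA statistic attributes bulk tendencies; it cannot deconvolve
  mixed A3A+A3B activity within one sample.
- No opportunity (exome-territory) renormalization of catalogs is applied
  by default; raw counts are used, with the channel-weighting hook left to
  the user.
- Survival handling has no censoring model; it reproduces mean-based
  comparisons only.
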