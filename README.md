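# apobecemt

Quantify APOBEC3-driven mutagenesis from somatic SNVs and relate it to
tumor progression — built for paired primary/metastatic cancer cohorts such
as high-grade serous ovarian carcinoma (HGSOC), where APOBEC3A activity is
enriched in metastases, correlates with shorter survival, and shifts tumors
toward hybrid-EMT/mesenchymal expression states.

The package is aimed at cancer-genomics analysts who have somatic variant
calls (VCF or a variant table), a reference sequence, and expression
matrices, and want a tested, seeded pipeline rather than a one-off script.

## What it computes

**Mutation catalogs.** SNVs are classified into the 96 standard channels
(six pyrimidine substitution classes × 16 trinucleotide flank pairs, purine
references reverse-complemented), giving a per-sample catalog matrix
*M* (96 × samples).

**Signature activities.** Refitting solves, per sample,

    min_{a >= 0} || m - S a ||_2

for a reference signature matrix *S* (96 × k, columns summing to 1);
relative contributions are *a / Σa*, and the **APOBEC fraction** is the
SBS2 + SBS13 relative contribution. De novo extraction factorizes
*M ≈ W H* by NMF under the generalized Kullback–Leibler divergence
(multiplicative updates, seeded restarts, monotone objective trace), with
cosine-similarity assignment of extracted columns to references.

**Enzyme attribution.** Qualifying mutations (C>T/C>G at TpCpA) are split
by the tetranucleotide base 5′ of the TpC — YTCA (APOBEC3A-like) versus
RTCA (APOBEC3B-like) — and compared against genomic context availability
via the background-normalized ratio `(ytca/bg_ytca) / (rtca/bg_rtca)`.

**Cohort analysis.** APOBEC-high/low labels (strict `> threshold`, fixed
4% or upper-quartile), per-patient and pooled metastatic/primary
enrichment ratios, short/long survivor classes (<3.5 y, >5 y), Welch mean
comparisons, and Fisher exact association tests.

**Expression scores.** Linear relative fold changes
`(x − ref_mean)/ref_mean`, strict DEG filters, the EMT trajectory score
(epithelial mean; hEMT and mesenchymal category means minus the epithelial
mean), and the IL6-correlated gene score (per functional category, summed
case − control means).

**Synthetic data.** Seeded generators for references, signature-mixture
variant sets, paired cohorts with planted enrichment/survival structure,
and negative-binomial expression with planted gene-set shifts — every
record carries its generating truth.

The bundled `reference_signatures()` are synthetic stand-in shapes (TpC
APOBEC peaks, CpG clock, flat background, C>A process), not COSMIC
estimates; load a COSMIC-format TSV with `read_signature_tsv()` for real
analyses.

## Worked example

Simulate six patients with a planted 6-fold metastatic APOBEC enrichment,
rebuild catalogs, refit exposures, and run the cohort analysis:

```r
library(apobecemt)

sim <- simulate_cohort(n_patients = 6, base_apobec = 0.02, met_fold = 6,
                       n_mutations = 3000, seed = 42)
catalog <- build_catalog(sim$variants[, 1:5], sim$reference)
fit <- fit_exposures(catalog, reference_signatures())
frac <- apobec_fraction(fit)
round(head(frac, 4), 4)
#>    P01_primary P01_metastatic    P02_primary P02_metastatic
#>         0.0181         0.1243         0.0185         0.1192

cohort <- data.frame(sample_id = sim$truth$sample_id,
                     patient_id = sim$truth$patient_id,
                     site = sim$truth$site,
                     apobec_fraction = unname(frac[sim$truth$sample_id]),
                     survival_days = sim$truth$survival_days)
paired_enrichment(cohort)$pooled_ratio
#> [1] 6.507067

ann <- annotate_cohort(cohort, mode = "fixed", threshold = 0.04)
table(ann$apobec_label[ann$site == "metastatic"])
#> high
#>    6
```

The refitted fractions recover the planted weights (primary 0.02,
metastatic 0.12), the pooled metastatic/primary ratio lands near the
planted 6-fold, and every patient is APOBEC-high because the planted
metastatic weight (12%) exceeds the 4% cutoff. Attribution on a planted
A3A-like process:

```r
va <- sample_apobec_variants(sim$reference, 100, enzyme = "A3A", seed = 7)
attribute_enzyme(count_tca_contexts(va, sim$reference))
#> enzyme attribution: A3A-like (normalized YTCA:RTCA ratio Inf, n = 100)
```

(All 100 mutations sit at YTCA, so the RTCA count is zero and the ratio is
infinite — the label is still called because support is ample.)

## Layout

- `R/` — modules: `channels`/`catalog` (96-channel machinery),
  `signatures` (NNLS, KL-NMF, matching), `attribution` (YTCA/RTCA),
  `cohort`, `emt_scoring`, `synthetic_data`, `io` (FASTA/VCF/TSV/GMT),
  `reference_signatures`.
- `inst/extdata/` — synthetic stand-in signature TSV and GMT gene sets.
- `vignettes/apobec-signatures-and-emt.Rmd` — the methods vignette: model
  assumptions, parameter meanings, simulator scope, numerical choices,
  limitations.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
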