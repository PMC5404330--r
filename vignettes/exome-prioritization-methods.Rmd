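---
title: "Prioritizing exome variants in SLI nuclear families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing exome variants in SLI nuclear families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sliexome)
```

## The problem and the model

Specific language impairment (SLI) is a developmental disorder of spoken
language in children with otherwise normal nonverbal ability and opportunity.
It is strongly heritable, but cohorts assembled for exome sequencing are
small — on the order of forty nuclear families — so exome-wide burden or
association testing is underpowered. The analysis this package implements is
instead a *prioritization cascade*: a sequence of increasingly specific
filters and screens, each grounded in an explicit prior about where
high-penetrance variation is most likely to hide, followed by within-family
segregation evidence and pathway-level aggregation. None of the steps is a
formal estimator of effect size; the outputs are candidate lists with
reproducible membership rules, which is exactly what the package tests.

The cascade, in order:

1. **Exclusion filter** (`qc_filter`): keep only protein-affecting calls
   (nonsynonymous, stop-gain/loss, splice, frameshift and non-frameshift
   indels); drop anything in a known segmental duplication (read-mapping
   artefacts concentrate there) and anything whose carrier read depth is
   below 10. Exclusions are attributed to the first failing rule in the
   fixed order class → segdup → depth, so the per-rule counts are
   deterministic.
2. **Frequency tiering** (`frequency_tier`): *novel* means absent from both
   reference panels; otherwise the maximum available panel frequency `f`
   sets the tier — *rare* `f < 0.01`, *low-frequency* `0.01 ≤ f ≤ 0.05`,
   *common* `f > 0.05`.
3. **Deleteriousness** (`is_deleterious`): `SIFT ≤ 0.05` or
   `PolyPhen-2 ≥ 0.85`; loss-of-function classes pass by class.
4. **Screens**: candidate-gene tallies and the rare/novel shortlist
   (`screen_candidates`), the truncating-variant screen
   (`stopgain_screen`), compound-heterozygote groups
   (`comphet_candidates`), and the multiple-hit report
   (`multihit_probands`).
5. **Segregation** (`transmission_check`, `phase_comphet`, `cosegregation`):
   parental origin, de novo flagging, trans/cis phase, and a co-segregation
   verdict over the genotyped, phenotyped children.
6. **Pathways** (`permutation_fdr`, `enrich`): a within-proband
   pathway-sharing permutation test and pooled hypergeometric
   over-representation with Benjamini–Hochberg adjustment.

## Parameters that matter

All thresholds live in one object, `filter_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `rare_threshold` | 0.01 | allele fraction | upper bound (strict) of the rare tier |
| `low_freq_threshold` | 0.05 | allele fraction | upper bound (inclusive) of the low-frequency tier |
| `sift_max` | 0.05 | SIFT score | deleterious at or below |
| `polyphen_min` | 0.85 | PolyPhen-2 score | deleterious at or above |
| `min_depth_required` | 10 | reads | exclusion filter depth rule |
| `comphet_proximity_bp` | 10 | bp | both members of a closer pair are removed |
| `stopgain_exempt_from_scores` | TRUE | — | truncating classes deleterious by class |
| `tier_panel` | "max" | — | which panel(s) set the tier |
| `depth_semantics` | "any_carrier" | — | reading of the depth rule |

Three of these defaults resolve genuine ambiguities in the methodology this
package operationalizes, and deserve a note:

* **Strict vs inclusive rare boundary.** The source descriptions mix "< 1%"
  and "≤ 1%". We adopt the strict `f < 0.01`; no record in the packaged
  worked-example tables sits at exactly 1%, so the choice is observationally
  neutral there, and `rare_threshold` is the one-line override.
* **Panel maximum.** Tiering uses the maximum over available panel
  frequencies — the conservative choice, since a variant common in either
  panel is not rare. `tier_panel = "kg"` or `"evs"` restores single-panel
  behaviour.
* **Score exemption for truncating variants.** SIFT routinely reports 1.00
  for stop-gains (the score is defined for substitutions), yet truncating
  alleles are the canonical deleterious class. With the exemption off, a
  stop-gain with SIFT 1.00 and no PolyPhen value would absurdly fail the
  deleteriousness predicate.
* **Depth semantics.** "Depth below 10 in all probands" can mean *exclude
  when every carrier is under-covered* or *require every carrier to be
  covered*. The stored `min_depth` is the minimum over carriers; the default
  `any_carrier` reading excludes a variant only when no carrier reaches 10×.

The affection threshold is fixed by the phenotype definition: CELF-R
expressive/receptive scores are standardized to mean 100, SD 15, and a child
is affected when either score is more than 1.5 SD below the mean, i.e.
strictly below 77.5. A score of exactly 77.5 is unaffected; children without
CELF scores (e.g. a sibling with only a dyslexia diagnosis) are `unknown`
and excluded from co-segregation counts. Parents are never classified from
scores — the language instruments are child-normed — so co-segregation is a
children-only comparison.

## Counting rules and edge cases

* Counting in every screen is by **distinct variant**, not
  (variant, carrier) pair: a shortlist variant carried by three probands is
  one call. The multi-hit report, conversely, pools per proband and asks for
  ≥ 2 *distinct variants* across categories, so a single compound-het pair
  suffices (one gene hit spanning two variants).
* Proximity exclusion removes **both** members of a pair within
  `comphet_proximity_bp` (the rule models local alignment artefacts; there
  is no reason to trust either member). Distance is `|pos₁ − pos₂|` on the
  same chromosome, 1-based inclusive coordinates throughout.
* Compound-het groups of more than two variants are phased pairwise; the
  candidate is *trans* if any pair resolves to opposite parents, *cis* if
  pairs resolve only to the same parent, otherwise *unknown*.
* A homozygous rare deleterious genotype also satisfies "two variant alleles
  in one gene" but is biologically distinct; `hom_alt_disruptive()` reports
  these separately instead of forcing them into the compound-het category.
* The permutation "FDR" is a per-pathway **empirical tail probability**
  (`perm_geq / n_perm`, ties counting), not a multiplicity-adjusted error
  rate; the name follows the field's usage and the output records `n_perm`
  and the seed. Its grid is `1/n_perm` and its floor is 0. Probands with
  empty qualifying gene lists stay in the cohort (they can never share a
  pathway, which is exactly what the statistic should reflect).
* The hypergeometric upper tail is accumulated in log space
  (`lchoose` + log-sum-exp); `P(X ≥ 0)` is exactly 1. The enrichment report
  follows the "size > 10 genes, P < 0.01, FDR < 0.01" table convention, with
  FDR from standard Benjamini–Hochberg over all tested sets. (Published
  tables of this analysis show FDR columns that are not monotone in P; their
  construction is undocumented, and we deliberately do not reverse-engineer
  it.)
* Frequency stratification for the exploratory enrichment uses the relaxed
  filter — nonsynonymous/stop-gain/stop-loss at ≤ 5% panel-A frequency,
  ignoring SIFT/PolyPhen — and assigns each variant to exactly one stratum
  by panel-A frequency (novel requires absence from both panels). A variant
  absent from panel A but present in panel B fits no stratum and is dropped,
  which mirrors the stratum definitions rather than inventing a fourth
  class.

## The synthetic cohort generator

The real cohort is access-restricted, so `simulate_cohort()` generates a
structurally faithful stand-in: 43 nuclear families (two parents, one
proband, 1–3 siblings), background variants on a synthetic gene map with a
four-tier frequency spectrum, Hardy–Weinberg parental genotypes, Mendelian
transmission to children, and ascertainment through at least one carrier
proband per variant. The default tier mixture (48.6 / 21.6 / 16.2 / 13.5 %
common / low / rare / novel) matches the validated candidate-call spectrum
of the study design it emulates. Tier frequencies are drawn log-uniformly
within tier bounds; novel variants carry no panel frequencies and transmit
at an effective allele frequency of 5×10⁻⁴.

Planted signals are placed explicitly: rare/novel deleterious candidate-gene
variants, rare stop-gains (below 0.25% in both panels), trans compound-het
pairs (one variant per parental haplotype, > 10 bp apart, both transmitted
to the proband), de novos (heterozygous proband, both parents genotyped
homozygous reference), and a pathway-sharing excess (one qualifying variant
in a designated gene set for 70% of probands). Background variants carry
benign scores (SIFT above 0.10, PolyPhen below 0.80, beta-distributed), so
planted and background variants are separable by construction and screen
recovery against the truth manifest is exact. Phenotype scores are drawn on
the side of the 77.5 cutoff implied by the assigned affection, so
`affection_status()` round-trips; sibling affection follows carrier status
with penetrance 0.9 and a 5% phenocopy rate.

What the simulator does **not** emulate — and therefore what passing
recovery tests do *not* show about real data: linkage disequilibrium and
haplotype structure (each variant transmits independently), population
stratification, genotyping error and missingness, score noise near the
deleteriousness cuts (real pathogenic variants are not guaranteed to pass
SIFT/PolyPhen), and the mapping-artefact excess in olfactory-receptor/mucin
gene families that makes some validated stop-gains suspect in practice.
Recovery of 1.0 sensitivity/specificity is a correctness check of the
screening logic under clean separation, not an estimate of field
performance.

## Numerical and testing choices

* Percent columns in the on-disk dialect are divided by 100 on read and
  re-formatted with 15 significant digits on write; values with up to four
  decimal digits of percent round-trip exactly, which the suite asserts.
* `"NA"` is the only missing-value token; an empty cell is an error. This
  guards against silent column drift in hand-edited TSVs.
* Permutation and simulation functions take explicit seeds, record them in
  their outputs, and restore the caller's RNG state on exit.
* The suite's problem sizes are chosen to keep the full run under a minute
  while still exercising every branch: the brute-force compound-het oracle
  sweeps 100 random cohorts of up to 20 probands × 200 variants; the
  hypergeometric tail is checked against exhaustive draw enumeration for
  every parameter combination up to universe size 12; the permutation-FDR
  null calibration uses 200 replicates at 200 permutations (the
  Kolmogorov–Smirnov check exploits the probability-integral-transform
  property of the empirical tail probability, with per-replicate random
  list sizes to smooth the discrete support); and the planted-signal
  recovery runs the full default 43-family cohort.
* The protein lengths behind the truncation percentages of the packaged
  stop-gain table are synthetic (the source prints only the percentages):
  they are the integer lengths consistent with the printed values under
  `100·(L − p + 1)/L`. For one record (OR52B2, stop at residue 243) no
  integer length reproduces the printed 25.0% under this formula — the
  closest, L = 323, gives 25.1% — suggesting the original computation used
  `(L − p)/L`; we keep the formula that matches the remaining six records
  exactly and document the 0.1-point discrepancy.

## Known limitations

* Gene symbols are matched exactly (case-insensitively); there is no alias
  resolution, so candidate lists must use the same symbol vocabulary as the
  annotation.
* Indels are represented VCF-style (anchored ref/alt) but indel-specific
  annotation is minimal; the splice/frameshift classes are carried through
  the class-based rules only.
* VCF import covers the minimal INFO-key subset defined in
  `import_vcf()` — not phased genotypes, breakends, or arbitrary
  annotations.
* The within-proband pathway test treats gene sets as flat membership lists;
  there is no ontology-graph conditioning or topology-aware statistic.
* Whether a phased-trans compound het should additionally be required to
  co-segregate before counting as a "case" is left to the report consumer:
  the package exposes `phase` and the co-segregation verdict as separate
  fields rather than hard-coding their conjunction.
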