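---
title: "Gene-based collapsing analysis: models, diagnostics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based collapsing analysis: models, diagnostics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecollapse)
```

## The statistic

A collapsing analysis tests genes, not variants. For a gene $g$, a
qualifying-variant model $M$ and a sample $i$, define the carrier indicator
$X_{ig} \in \{0, 1\}$: 1 if the sample carries at least one variant in $g$
passing $M$'s filters (under the recessive model, two qualifying alleles).
Cases and controls are compared on the 2×2 table of carriers versus
non-carriers with a two-tailed Fisher exact test, and the effect size is the
unadjusted cross-product odds ratio. The method deliberately discards dose
information within the carrier state — unlike burden tests, which sum
variant counts over a region — because with ultra-rare variants the carrier
indicator is where essentially all of the signal lives, and the exact test
is valid at any case count.

The method's validity rests on three assumptions the rest of the package
exists to enforce or check:

1. **Unrelated samples.** Cases recruited through multiplex families are
   relatives; `prune_one_case_per_family()` keeps exactly one case per
   family (the flagged proband; ties broken by lexicographic sample id, so
   the operation is deterministic and idempotent).
2. **Equal opportunity to call variants.** A group with lower sequencing
   depth at a site under-calls genotypes there, biasing carrier counts
   toward the better covered group. `prune_sites()` removes sites where the
   fraction of cases and the fraction of controls with ≥ 10× depth differ
   by 10 percentage points or more (keep iff $|f_{case} - f_{ctl}| < 0.10$,
   strict, with a $10^{-9}$ numeric guard so a difference of exactly the
   threshold is excluded). `synonymous_burden_qc()` then tallies rare
   synonymous variants — presumed neutral — per sample and compares groups
   with a two-sided Wilcoxon rank-sum test; a significant difference flags
   residual technical stratification. The rank-sum test was chosen for
   robustness to the skew of per-sample counts; a degenerate tally (all
   counts tied) reports $p = 1$.
3. **Comparable ancestry.** Carrier-frequency differences between
   populations masquerade as association. The permutation QQ/λ diagnostic
   measures exome-wide inflation, and the ancestry module reruns the scan
   within a genetically homogeneous cluster.

## Qualifying-variant models

`builtin_models()` returns the nine standard rule sets:

| model | inheritance | function class | missense gate | LOO AF ≤ | external AF ≤ |
|---|---|---|---|---|---|
| synonymous | dominant | synonymous | — | 0.0005 | 0 |
| ultra_rare | dominant | all functional | PolyPhen damaging | 0.0005 | 0 |
| rare_damaging_revel | dominant | all functional | REVEL > 0.5 | 0.0005 | 0.00005 |
| rare_damaging_polyphen | dominant | all functional | PolyPhen damaging | 0.0005 | 0.00005 |
| flexible_revel | dominant | all functional | REVEL > 0.5 | 0.001 | 0.001 |
| flexible_polyphen | dominant | all functional | PolyPhen damaging | 0.001 | 0.001 |
| flexible_no_score | dominant | all functional | — | 0.001 | 0.001 |
| ptv | dominant | PTV | — | 0.001 | 0.001 |
| recessive | compound het | all functional | — | 0.01 | 0.01 |

Conventions, several of which are genuinely open choices that needed fixing:

- **Leave-one-out allele frequency.** The internal frequency of a variant
  excluding the evaluated sample: $(AC - d)/(AN - 2)$, where $AC$/$AN$ are
  the allele count and number over the analyzed (combined case + control)
  cohort and $d$ is the sample's dose. Missing genotypes contribute nothing
  to $AN$ and count as dose 0. The denominator removes both of the
  evaluated sample's alleles; a cohort singleton therefore has LOO AF 0 in
  its carrier but $AC/ (AN-2) > 0$ in everyone else, which is what makes
  the filter self-consistent: carrier status in one sample never depends on
  that sample's own contribution to the cohort frequency.
- **External frequencies.** A variant must pass *both* reference ceilings;
  the code compares $\max(\text{gnomAD}, \text{ExAC})$ to the model
  ceiling. A ceiling of 0 means absent from both references.
- **Score gates are missense-only.** PTVs and inframe indels are presumed
  damaging by class; PolyPhen/REVEL gates never apply to them. A missense
  variant missing a required score fails the gate silently (it simply does
  not qualify) — an error would make whole cohorts unusable over one
  unannotated site.
- **REVEL is strict** (> 0.5, not ≥).
- **Compound heterozygotes without phase.** Two distinct het qualifying
  variants in one gene are assumed *in trans*; a homozygous qualifying
  variant counts as biallelic. This is the standard unphased approximation
  and overcounts when two hets are actually in *cis*.
- **Autosomes only** by default; the simulator emits autosomes and the
  models make no sex-aware dose adjustment. (Hemizygous genotypes can be
  read on the 0/2 dose scale via `read_vcf(allow_haploid = TRUE)`.)

Carrier status is anti-monotone in filter stringency: lowering a frequency
ceiling or adding a score gate can only remove qualifying variants, never
convert a non-carrier to a carrier. This invariant is property-tested.

## The exact test, odds ratios and multiplicity

`fisher_two_sided()` uses the minimum-likelihood two-sided definition: with
margins fixed, sum the hypergeometric probabilities of all tables whose
probability does not exceed the observed table's (relative tolerance
$1 + 10^{-7}$, matching the reference implementation in `stats`). The
alternative "doubling" definition does not reproduce conventionally
published collapsing p-values. The implementation enumerates the
hypergeometric support directly, which makes a permutation analysis of a
whole scan cheap; `stats::fisher.test` serves as an independent oracle in
the test suite, including exhaustive agreement over all tables with small
totals.

`odds_ratio()` is the raw cross-product with no continuity correction —
that is the convention behind published gene-level ORs (e.g. a 2/53 vs
3/8,983 carrier table gives $2 \cdot 8980 / (51 \cdot 3) = 117.39$). Zero
control carriers with case carriers give $\infty$; a table with no carriers
at all is undefined (`NaN`) and such genes are retained in the scan with
$p = 1$ rather than dropped, keeping the output schema stable. The
Haldane–Anscombe +0.5 correction exists only as an explicit display option.
Displayed ORs round half *up* at the second decimal (`round_half_up()`):
IEEE round-half-even would print a cross-product of exactly 44.855 as
44.85, whereas published tables use the half-up convention.
`recover_counts_from_or()` inverts the rounding: it enumerates integer
carrier pairs and returns every table whose rounded OR matches a printed
value, pinning published statistics to exact tables.

`bonferroni_threshold()` is $\alpha / (\text{genes} \times \text{models})$.
At the conventional exome scale of 18,666 protein-coding genes this gives
$2.67\times10^{-6}$ for a single model and $2.97\times10^{-7}$ across nine
models (printed figures truncate the quotient at the third significant
digit).

## Permutation QQ and λ

Under label permutation the per-gene margins (total carriers $K_g$) are
fixed, so each permuted p-value is determined by the hypergeometric draw of
case carriers. `permutation_expected()` exploits this: it shuffles
case/control labels (group sizes preserved), looks up each gene's exact p
from a cached table keyed by $(K_g, a)$, sorts each permutation's p-vector,
and averages order statistics — `expected_p[i]` is the permutation mean of
the $i$-th smallest p. This is exactly equivalent to recomputing the FET
per gene per permutation, at a small fraction of the cost. The inflation
factor is

$$\lambda = \frac{\mathrm{median}\, \chi^2_1(\text{observed } p)}{\mathrm{median}\, \chi^2_1(\text{expected } p)},$$

using the upper-tail $\chi^2_1$ quantile transform. Fisher p-values are
discrete with an atom at 1; when both medians sit on that atom both
quantiles are 0 and λ is reported as 1 (the two distributions agree at the
median, so no inflation is measurable there). An observed median strictly
more extreme than a degenerate expectation reports $\lambda = \infty$.
Default 1,000 permutations, seed required; given the seed the result is
bit-reproducible.

## What the simulator emulates — and what it does not

`generate_cohort()` produces cohorts with the structure the analysis
assumes. Defaults follow the multiplex-family study design the package
targets: 53 case families (two affected same-sex siblings each, one flagged
as proband) and 8,983 unrelated controls. The remaining defaults are one
package-level choice of "realistic" for a rare-variant exome study:

- **Site frequency spectrum**: a point mass of cohort singletons
  (`singleton_prop = 0.5`) plus a Beta(0.3, 400) low-frequency tail
  (mean ≈ 7.5×10⁻⁴), placing variant mass on both sides of the 0.0005 /
  0.001 / 0.01 model ceilings so that every filter boundary is exercised.
- **Effect classes**: synonymous 0.35, missense 0.52, inframe indel 0.03,
  PTV 0.10 — approximately exome-like proportions for rare variation; 35%
  of missense calls are PolyPhen "probably damaging"; REVEL scores are
  Beta(1.2, 3).
- **External references**: 60% of variants are absent from both gnomAD and
  ExAC (frequency 0); the rest draw log-uniform frequencies in
  $[10^{-6}, 10^{-2}]$.
- **Families**: each parent's two alleles are Bernoulli draws at the
  population frequency; each sibling inherits one allele per parent,
  independently per variant, so sibs share each parental haplotype with
  probability 1/2. No recombination model — only relatedness pruning is
  tested downstream, and for that purpose per-variant transmission
  suffices.
- **Population structure**: per-population frequencies follow a
  Balding–Nichols model, $p_k \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$
  with differentiation $F \in [0,1)$; $F = 0$ gives identical populations.
- **Coverage**: group fractions near 0.95–1.00; a configurable 2% of sites
  get a 0.2 depression of the control fraction, exceeding the 0.10
  harmonization threshold so pruning has work to do.
- **Missingness** defaults to 0 and is configurable per genotype.

`spike_risk_gene()` plants exact carrier enrichment: each chosen carrier
(drawn without replacement from the analyzed probands/controls, under the
config seed) receives a *private singleton* variant compatible with the
targeted model — LOO AF 0 by construction, absent from external references,
homozygous under the recessive model — and pre-existing carriers of
model-candidate variants in that gene are reset so the post-spike carrier
table is exactly as requested. This is what lets published OR/p pairs be
reproduced end to end through the genuine pipeline rather than from typed-in
tables.

The simulator does **not** emulate: linkage disequilibrium, recombination,
pedigrees beyond sib-pairs, sequencing/calling error, sex chromosomes,
batch effects correlated across sites, or annotation error. Passing tests
on these cohorts therefore demonstrate the statistical machinery —
calibration of the exact test, the permutation expectation, filter logic,
pruning — not robustness to real-data artifacts such as LD-correlated
carrier states or systematic miscalling.

## Ancestry clustering

The ancestry module infers genetic ancestry from common variation only
(combined-cohort AF ≥ 0.05): doses are mean-imputed, centered, scaled and
reduced to the top 10 principal axes (`genotype_features()`);
`embed_and_cluster()` takes the two leading axes as the embedding and
assigns clusters with a Gaussian-mixture model (mclust), the number of
components chosen by BIC over 1–10. This design was an open choice; the
mixture model was selected because it is fully deterministic given a seed,
assigns every sample a label (no noise class to re-assign), and recovers
synthetic populations at adjusted Rand index ≥ 0.9 for differentiation
$F \ge 0.1$ at the cohort sizes tested. Nonlinear embeddings would
separate fine-grained structure better on real data but add stochasticity
and tuning burden that nothing downstream needs. Self-reported ancestry
labels are carried for reporting only; clustering never uses them.

`filtered_analysis()` reruns the complete scan inside one cluster. The
leave-one-out allele frequencies are *recomputed within the restricted
cohort* rather than inherited — the matched comparison is a self-contained
case/control study, and frequencies inherited from the full cohort would
leak between-population variation back into the filter.

## Phenotype scoring

`feighner_diagnosis()` encodes the classic criteria: a diagnosis requires
at least one symptom in three of four problem categories (medical
consequences; attempts to control drinking; legal/social problems;
self-reported excessive drinking). Given each category's earliest symptom
age, the first-problem age is the minimum and the onset age is the third
order statistic of the endorsed ages — ties share a value, so four
categories endorsed at the same age give that age. `dsm5_severity()` maps a
DSM-V criteria count to no disorder (< 2), mild (2–3), moderate (4–5) or
severe (≥ 6); `severity_distribution()` reports counts, percentages (1
d.p., half-up) and the mean ± sd (n − 1 denominator) of the counts. The
criteria count is taken as given — mapping interview items to DSM-V
concepts is an instrument-specific step outside computational scope.

## Numerical and degenerate-input conventions

- Exact-test minimum-likelihood comparison at relative tolerance
  $1 + 10^{-7}$; degenerate margins (no carriers, or all carriers) give
  $p = 1$.
- LOO AF with $AN \le 2$ (single genotyped sample): 0 if the sample holds
  all copies, else 1 — the variant cannot be frequency-classified and is
  conservatively excluded for non-carriers.
- Site length for retained-base accounting: $\max(\mathrm{nchar(ref)}, 1)$
  bp, so indel records count their reference span.
- All stochastic operations (cohort generation, spiking, permutation,
  clustering) take explicit integer seeds and restore the caller's RNG
  state.
- Multi-allelic VCF records are decomposed into one biallelic record per
  alternate allele before any filtering, since frequency filters are
  per-allele.

## Problem sizes in the test suite

The suite validates calibration at reduced scale, chosen so the full run
completes comfortably on one CPU: 200 null cohorts of 500 genes with 50
analyzed cases vs 2,000 controls for type-I error and permutation λ (1,000
permutations each); 20 seeds × 3 spiked genes for top-10 recovery at
OR ≥ 50; 20 replicates of 3-population cohorts (n = 300) for ancestry
recovery; exhaustive exact-test agreement over all tables with total
n ≤ 18 plus randomized larger margins. Gene count scales the scan linearly
and does not change per-gene calibration, which is why a 500-gene null
cohort is an adequate stand-in for an 18,666-gene exome.

## Known limitations

- Unphased compound-het calling overcounts cis configurations.
- The exact test conditions on margins; it does not adjust for covariates
  (no regression layer is provided, matching the collapsing convention).
- Coverage harmonization uses per-site sample fractions; exon-level or
  per-base depth bookkeeping from alignments is out of scope (the coverage
  table is an input).
- The ancestry clustering targets discrete strata; admixed samples land in
  whichever component claims them, and no admixture proportions are
  estimated.
- Annotation (effect class, PolyPhen, REVEL, reference frequencies) is
  consumed, never computed.
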