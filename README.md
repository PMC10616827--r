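# rarecollapse

Gene-based rare-variant collapsing analysis for case-control exome cohorts.

Rare-variant association studies with small, deeply phenotyped case groups
(for example, probands drawn from multiplex families densely affected by a
disorder) cannot power per-variant tests. The collapsing strategy tests each
*gene* instead: every sample is reduced to an indicator

> Xᵢg = 1 if sample *i* carries at least one *qualifying variant* in gene
> *g*, else 0,

and the per-gene 2×2 table of carriers × case/control status is tested with
a two-tailed Fisher exact test (FET), reported with the cross-product odds
ratio OR = (a·d)/(b·c). A *qualifying variant* is one passing a model's
filters: an internal leave-one-out allele frequency ceiling
(AC − dose)/(AN − 2), external reference (gnomAD/ExAC) frequency ceilings,
a functional-class restriction (synonymous / missense + inframe indel + PTV
/ PTV only), and optional missense deleteriousness gates (PolyPhen
"probably damaging" or REVEL > 0.5). Nine standard models span ultra-rare
(leave-one-out AF ≤ 0.0005, absent from external references) through
flexible (≤ 0.001) to an autosomal recessive compound-het model, plus a
synonymous negative control.

The package implements the full workflow around that statistic:

- **Synthetic cohorts** (`sim_config()`, `generate_cohort()`,
  `spike_risk_gene()`, `write_cohort()`) — multiplex sibling-pair families,
  unrelated controls, Balding–Nichols population structure, an
  ultra-rare-dominated site frequency spectrum, annotation fields and
  coverage tables, plus exact carrier-count spiking for power studies.
- **Cohort IO and relatedness pruning** (`read_cohort()`, `read_vcf()`,
  `prune_one_case_per_family()`).
- **Coverage harmonization and neutral-variation QC** (`prune_sites()`,
  `cohort_coverage_check()`, `synonymous_burden_qc()`).
- **Qualifying-variant models** (`builtin_models()`, `variant_qualifies()`,
  `carrier_states()`).
- **The scan and its diagnostics** (`collapsing_scan()`,
  `bonferroni_threshold()`, `permutation_expected()` for the
  permutation-expected QQ distribution and inflation factor λ,
  `geneset_test()`, `recover_counts_from_or()`).
- **Ancestry stratification** (`genotype_features()`,
  `embed_and_cluster()`, `filtered_analysis()`).
- **Phenotype scoring** (`feighner_diagnosis()`, `dsm5_severity()`,
  `severity_distribution()`).

## Worked example

```r
library(rarecollapse)

cfg    <- sim_config(n_case_families = 53, n_control = 2000,
                     n_genes = 100, seed = 7)
cohort <- generate_cohort(cfg)
cohort <- spike_risk_gene(cohort,
                          spike_spec("G0042", 3, 2, model_targeted = "ultra_rare"))
cohort
#> rv_cohort: 2106 samples (106 cases, 2000 controls), 822 variants in 100 genes

scan <- collapsing_scan(cohort, models = "ultra_rare",
                        coverage_config = coverage_config())
print(scan, n = 3)
#> gene-based collapsing scan: 100 genes x 1 model(s), 53 cases vs 2000 controls
#> top 3 gene/model results:
#>   gene      model case_carriers control_carriers odds_ratio   p_value
#>  G0042 ultra_rare             3                2      59.94 0.0001568
#>  G0063 ultra_rare             1                1      38.44 0.0509776
#>  G0033 ultra_rare             1                2      19.21 0.0755013

permutation_expected(scan, n_permutations = 1000, seed = 7)
#> permutation QQ for model 'ultra_rare': 100 genes, 1000 permutations, lambda = 1.000
```

The 106 case samples are 53 sibling pairs; one case per family enters the
test, so the scan compares 53 cases with 2,000 controls. The spiked gene
G0042 tops the scan with 3 of 53 case carriers versus 2 of 2,000 control
carriers (OR = 3·1998/(50·2) = 59.94, exact p = 1.6×10⁻⁴); λ = 1 indicates
no exome-wide inflation among the remaining null genes. With 100 genes the
single-model Bonferroni threshold is 0.05/100 = 5×10⁻⁴
(`bonferroni_threshold(0.05, 100)`), so the spike is study-wide significant
while the best null gene (p = 0.051) is not.

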