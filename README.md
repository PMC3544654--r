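# mirage

Age-stratified evolutionary analysis of miRNA genes.

Human miRNA families were acquired continuously along the vertebrate lineage,
and most newly gained families decay again quickly. `mirage` is an R package
for the desk analysis of this process, for researchers in molecular evolution
who have (or simulate) phyletic profiles of miRNA families, a dated species
tree, precursor sequences, variant tables, a small-RNA expression atlas and
target/host annotations:

* **Parsimony dating** — each family's presence/absence profile across
  species is placed on the tree and its origin inferred by maximum parsimony
  (gains and losses at unit cost, `unknown` tips free). With the packaged
  11-taxon vertebrate tree the root-to-human path has 7 internal nodes, so
  origins fall into 8 age groups `t0` (human-specific) … `t7`
  (pre-vertebrate).
* **Birth–death turnover** — the extant age distribution is fitted by least
  squares with a constant birth rate `v` and Gamma survivorship
  `P(t) = 1 − GammaCDF(t; k, θ)`, giving the expected cumulative count
  `N(t) = v ∫₀ᵗ P(s) ds` and the long-term net gain `v · P(horizon)`.
* **Age-group statistics** — mature/seed sequence sharing (Table-1-style
  matrices with a Unique(%) column), SNP/indel density per region class,
  Kimura two-parameter substitution rates under a molecular clock
  (`d = −½ ln(1−2P−Q) − ¼ ln(1−2Q)`), NMFE (MFE/length) group means and
  variances, information-content tissue specificity
  (`log2 n + Σ pᵢ log2 pᵢ`), maximal expression abundance, hypergeometric
  malignancy enrichment, target-set overlap/multiplicity, and the genic
  miRNA × host-gene age cross-tabulation.
* **Synthetic data** — seeded generators (`sim_config()`,
  `simulate_study()`) produce every input the readers consume with the
  statistical structure the analysis assumes, so the full pipeline runs and
  is tested without any external downloads.

## Worked example

Simulate a study, date the families, and fit the turnover model:

```r
library(mirage)

tree <- default_species_tree()
cfg  <- sim_config(seed = 42)

# families with ages drawn from the published census proportions
fam  <- simulate_families(cfg, n_families = 300, ages_from = "census")
ages <- assign_ages(tree, fam$profiles, tie_break = "youngest")
head(ages, 3)
#> # A tibble: 3 × 5
#>   family   age_index age_label change_count ambiguous
#>   <chr>        <int> <chr>            <dbl> <lgl>
#> 1 fam00001         1 t1                   1 FALSE
#> 2 fam00002         1 t1                   1 FALSE
#> 3 fam00003         3 t3                   1 FALSE

mean(ages$age_index == fam$truth$age_index)   # homoplasy-free: exact recovery
#> [1] 1

# full birth-death process at the default conditions, then refit
proc <- simulate_families(cfg)
fit  <- bd_fit(observed_cumulative(proc$truth, tree))
fit
#> Birth-death fit (constant birth, Gamma survivorship)
#>   v = 42.584 /Myr, shape = 2.056, scale = 20.939 Myr
#>   SSE = 126.8 over 7 time points; converged: TRUE
#>   asymptotic extant count v*shape*scale = 1833.4

bd_derived_rates(fit$params, horizon = 100)
#> # A tibble: 1 × 4
#>   horizon_myr birth_rate survivorship net_gain
#>         <dbl>      <dbl>        <dbl>    <dbl>
#> 1         100       42.6       0.0525     2.23
```

The fitted birth rate (~40 new families/Myr), survivorship at 100 Myr (~5%)
and net gain (~2 lasting families/Myr) recover the generating conditions;
`tidy(fit)`, `glance(fit)` and `autoplot(fit)` expose the parameters, fit
summary and observed-vs-fitted curve. Downstream, `sharing_matrix()`,
`variant_density()`, `clock_rates_by_group()`, `tissue_specificity()`,
`malignancy_enrichment()`, `overlap_matrix()` and `host_age_crosstab()`
compute the per-age-group statistics; `vignettes/mirage-methods.Rmd`
documents the models, parameter choices and limitations.

A thin command-line wrapper with `simulate` / `ages` / `fit-bd` / `report`
subcommands is included at `inst/scripts/mirage.R`.

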