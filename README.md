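# microhi

Assessing the health of wild fish — and whole fish communities — from
microbiome profiles, without handling the animals twice. `microhi`
implements a complete analysis pipeline around the **microbiota health
index (microHI)**: the average abundance ratio of microbes *without*
three health-negative phenotypes (potentially pathogenic, contains
mobile elements, stress tolerant),

```
microHI = ((1 - Pm) + (1 - Po) + (1 - Pp)) / 3
```

where `Pm`, `Po`, `Pp` are the per-sample relative-abundance fractions of
taxa carrying mobile elements, oxidative-stress tolerance, and potential
pathogenicity. The index is computed for both gut samples and water
eDNA samples, which makes it possible to ask when the *water*
environmental microHI can stand in for invasive gut sampling.

The pipeline covers:

- **Scoring** (`microhi_scores`): phenotype ratios, microHI and Fulton's
  condition factor `K = m/L^3 x 100` per sample, from a taxon-by-sample
  abundance table (TSV or BIOM JSON) and a taxon-to-phenotype weight map.
- **Dysbiosis classification** (`classify_dysbiosis`): each gut sample is
  labeled healthy or unhealthy (disordered microbiota) from its position
  in a Bray-Curtis / average-linkage dendrogram, relative to the "normal
  branches" anchored by its own species or by species of the same
  ecotype; `classify_consensus` combines species/genus/family levels.
- **Effectiveness analysis** (`compare_health_groups`,
  `species_baselines`, `weighted_community_microhi`, `ecotype_microhi`,
  `env_gut_regression`): healthy-vs-unhealthy contrasts, species-specific
  gut microHI baselines, community-structure-weighted aggregation, and
  water-to-gut microHI regressions at community and ecotype level.
- **Key-taxon screening** (`key_taxa_cascade`): a four-stage funnel —
  phenotype-linked, water-gut correlated (r2 > 0.6), positive slope
  (> 0.1), and Kruskal-Wallis + LDA (score >= 3) differentially abundant
  in the unhealthy group of at least 3 ecotypes — isolating the water
  taxa that plausibly impact host health.
- **Synthetic cohorts with ground truth** (`simulate_dataset`,
  `study_preset`): paired gut/water datasets with species-specific
  baselines, a dysbiotic subpopulation, site-year environmental
  gradients, ecotype-specific water-gut coupling and spiked key taxa, so
  every stage of the pipeline can be validated end to end.

See `vignettes/microhi-methods.Rmd` for the models, the tunable
parameters and the design choices.

## Worked example

```r
library(microhi)

sim <- simulate_dataset(seed = 1)      # 200 gut + 30 water samples
scores <- microhi_scores(sim$gut, sim$map, sim$meta)
labels <- classify_dysbiosis(sim$gut, sim$meta)
labels
#> health_labels: 200 gut samples, 49 (24%) with disordered microbiota

compare_health_groups(scores, labels)
#>        unit n_healthy n_unhealthy mean_healthy mean_unhealthy     delta       test_p significance
#> 1 community       151          49    0.7074815      0.5718251 0.1356565 2.659603e-20           **
```

Healthy individuals average a gut microHI of 0.71 against 0.58 for
individuals with disordered microbiota — the index separates the groups
(rank-sum p < 0.01). Relating gut to water at the ecotype level:

```r
water_scores <- microhi_scores(sim$water, sim$map)
all_scores <- rbind(scores[names(water_scores)], water_scores)
pts <- regression_points(all_scores, labels, sim$meta, sim$community,
                         ecotype = "carnivorous")
env_gut_regression(pts$env, pts$gut, "carnivorous")
#>          unit n_points     slope intercept        r2           p flag
#> 1 carnivorous        6 0.4908491 0.4025309 0.9310127 0.001827426   ok
```

For carnivorous fish the community-weighted gut microHI tracks the water
environmental microHI (slope 0.49, r2 0.93 across six site-year units);
the other three ecotypes fail the slope > 0.1, r2 > 0.6 screen — their
longer guts buffer the environmental signal. Finally, the key-taxon
cascade:

```r
key_taxa_cascade(sim$gut, sim$water, sim$map, labels, sim$meta,
                 microhi_config(seed = 1))
#> key_taxa_report
#>   screen funnel: phenotype_linked=100 -> correlated=10 -> positive=9 -> differential=3 -> key=3
#>   key taxa: T001, T002, T003
```

Of 100 phenotype-carrying taxa, exactly the three taxa the generator
spiked into dysbiotic guts (in proportion to their water abundance)
survive all four screens — the funnel a real survey shows when isolating
taxa such as Alcaligenaceae or Enterobacteriaceae.

A shell interface with subcommands `simulate`, `score`, `classify`,
`analyze` and `key-taxa` ships at
`system.file("cli", "microhi.R", package = "microhi")`; every invocation
writes a deterministic run manifest (config, seed, input checksums).

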