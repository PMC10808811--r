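---
title: "The microbiota health index pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The microbiota health index pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microhi)
```

## The index

The microbiota health index (microHI) summarizes how much of a microbial
community carries one of three health-negative phenotypes: potential
pathogenicity, mobile element content, and oxidative stress tolerance.
With $P_p$, $P_m$, $P_o$ the relative-abundance fractions of taxa carrying
each phenotype,

$$\mathrm{microHI} = \frac{(1-P_m) + (1-P_o) + (1-P_p)}{3},$$

so a community free of flagged taxa scores 1 and a saturated one scores 0.
The phenotype fractions are abundance-weighted sums of a user-supplied
taxon-to-phenotype map with weights in $[0,1]$; binary maps are the common
case, fractional weights express phenotype calls made on part of a taxon's
strains. Taxa absent from the map are treated as unclassified and dropped,
and by default the fractions are renormalized over the covered abundance
(`renormalize = FALSE` keeps the full-abundance scale instead — the two
conventions coincide at full coverage, and `classified_fraction` is always
reported so the information loss stays visible; below 50% coverage a
warning is raised).

Host body condition uses Fulton's factor $K = m/L^3 \times 100$ with
weight in grams and length in centimeters, the unit convention under which
$K \approx 1$ for fusiform fish.

## Calling disordered microbiota from the dendrogram

Gut samples are clustered by Bray–Curtis dissimilarity
($BC(a,b) = 1 - \sum_t \min(a_t, b_t)$ on relative abundances) with
average linkage (UPGMA). The anchoring assumption is that most
individuals of a species have a normal gut microbiota, so the bulk
conspecific branches define normality and samples falling outside every
such branch are called disordered.

Operationally the tree is cut into flat branches, and a branch is a
*normal branch* for species $s$ when it holds at least `min_conspecifics`
(default 3) samples of $s$, or when it is anchored by at least
`min_conspecifics` samples of some species and is dominated (fraction
$\ge$ `purity_min`, default 0.6) by species sharing $s$'s ecotype. The
anchoring requirement matters: normal branches are recognized through a
definite species, and ecotype similarity only extends membership of such
established branches — without it, any ecotype-pure trio of co-clustering
disordered samples would bless itself as normal. Species with fewer than
`min_conspecifics` samples are judged by the ecotype clause alone (with a
warning).

The cut height is species-informed: the lower-quartile conspecific
distance plus `cut_frac` (default 0.5) of the gap up to the median
heterospecific distance. We use the lower quartile because at a
substantial dysbiosis prevalence up to half of the conspecific pairs
involve a disordered sample and would inflate a mean or median. A fixed
quantile of the merge heights was considered and rejected: merge-height
quantiles are dominated by the many small within-cluster merges, so in a
cohort with little dysbiosis any low quantile lands inside the
conspecific band and fragments tight species clusters, while a quantile
high enough to avoid that absorbs genuinely displaced samples when
dysbiosis is common. Anchoring the cut to the two distance scales that
the species labels themselves define behaves correctly in both regimes.
When the data contain a single species the heterospecific scale does not
exist and the classifier falls back to the 75th percentile of merge
heights, with a warning.

Classification can be repeated at species, genus and family level
(`classify_consensus()`), combined by majority vote; an exact tie over an
even number of levels resolves to disordered, so borderline samples are
flagged for inspection. All tie-breaking is deterministic and the module
uses no randomness.

## Effectiveness analysis

Healthy/unhealthy contrasts of gut microHI (or Fulton's K) are two-sided
Wilcoxon rank-sum tests — the two-sample special case of the
Kruskal–Wallis test — exact by enumeration (midranks under ties) when
both groups have at most 8 samples, normal approximation with tie
correction otherwise. Stars follow the usual convention (\* p<0.05,
\*\* p<0.01), with raw p-values by default and a Benjamini–Hochberg
option behind `adjust_p`.

A species' baseline gut microHI is the mean over its healthy
individuals. Community- and ecotype-level values are weighted averages of
per-species means, the weight being each species' share of individuals in
the surveyed fish community (renormalized within an ecotype). The
water-to-gut relationship is an ordinary least-squares fit of gut on
water environmental microHI over aggregation units — site-year by
default; the pairing of water with gut samples is a configuration choice
(`unit`), not something the data dictate. The gut value of a unit is the
community-weighted average of per-species means over individuals labeled
healthy, so that dysbiosis does not masquerade as an environmental
signal. Fits with fewer than 3 points are flagged underdetermined and
zero environmental variance flags them degenerate, rather than erroring,
so screening loops can proceed.

## The key-taxon cascade

Candidate health-impacting taxa of water origin pass four nested screens:

1. *phenotype-linked*: any positive phenotype weight and nonzero abundance;
2. *correlated*: per-taxon OLS of mean gut abundance on mean water
   abundance across units with $r^2 >$ `r2_min` (default 0.6);
3. *positive*: slope $>$ `slope_min` (default 0.1);
4. *differential*: within each ecotype, Kruskal–Wallis p $<$ `alpha` and
   an LDA effect size $\ge$ `lda_min` (default 3) with direction
   up-in-unhealthy, required in at least `ecotypes_required` (default 3)
   ecotypes.

The LDA effect size follows the LEfSe recipe: abundances rescaled to a
per-sample total of $10^6$; over `n_boot` (default 30) bootstrap rounds
of two-thirds subsamples per class, a linear discriminant is fitted to
the taxa passing the Kruskal–Wallis gate, and a taxon's effect is the
average of its raw between-class mean difference and its share of the
class separation along the discriminant axis; the score is the log10 of
the median effect across rounds, floored at 1 (score 0). The 3.0
threshold only has meaning on this log10, $10^6$-scaled axis. Where the
discriminant fit is singular the raw mean-difference term alone is used
for that round. The bootstrap is the pipeline's only stochastic stage and
is driven by the configured seed; identical configuration and seed
reproduce byte-identical reports. The subclass structure of the original
LEfSe design is not used: the factor is health status within one ecotype.

Per-stage survivor counts are reported and are non-increasing by
construction, reproducing the funnel shape typical of such screens (many
phenotype-linked taxa, few correlated and positive, very few key).

## What the synthetic cohort emulates

`simulate_dataset()` generates a paired gut/water cohort with known
ground truth. The default study conditions: 8 species, two per ecotype
(filter-feeding, scraper-feeding, omnivorous, carnivorous), 25 gut
samples each (200 total); 3 sites $\times$ 2 years (6 units) with 5
water samples per unit (30 total); 150 taxa of which 100 carry
health-negative phenotypes, including 3 designated key taxa; per-species
healthy baselines spread $0.71 \pm 0.07$; dysbiosis prevalence 0.30 with
a mean microHI depression of 0.13 (healthy 0.71 vs unhealthy 0.58 at the
community level); environmental microHI spanning 0.60–0.90 across units;
water-to-gut compositional coupling $\beta = 0.5$ for carnivorous
species and 0 elsewhere. `study_preset()` provides cohort shapes echoing
the field campaigns this emulates: 14 species with per-species counts
between 2 and 41 (214 gut samples, 30 water samples), and a two-year
variant whose second campaign has environmental microHI 0.83 (n=13)
against 0.71 (n=30).

Mechanisms, and why they are shaped this way:

- **Compositions** are Dirichlet draws around base compositions;
  concentration 50 for guts (moderate overdispersion between
  individuals) and 2000 for water (replicate filters from a well-mixed
  river transect vary far less than gut communities do). Base
  compositions are solved by mixing a phenotype-free and a
  phenotype-carrying taxon pool so their phenotype-weighted microHI hits
  the target exactly.
- **Coupling acts on composition**: a gut sample of a species with
  coupling $\beta$ mixes its core composition with the local water
  composition at rate $\beta$, so the microHI relationship (slope
  $\approx \beta$) emerges from community mixing instead of being
  injected into the index directly. Core microHI targets are solved so
  the expected healthy mean equals the configured baseline after mixing
  and carryover.
- **Key taxa reach guts from water** through two channels: a passive
  carryover in every gut sample, proportional to the keys' local water
  abundance (`carryover`, default 0.3), and the dysbiotic spike, whose
  key share scales with the local key water abundance and mirrors the
  water key profile taxon by taxon. The keys' share of the water
  composition tiles a high/low ABBA pattern across units, deliberately
  orthogonal to the environmental-microHI gradient, so the key-taxon
  water signal is a spatial pattern of its own rather than a mirror
  image of water quality — without this, the carryover channel would
  leak a small spurious water-quality slope into every ecotype.
- **Dysbiosis** is both a microHI depression and a compositional
  displacement, because the classifier and the score are distinct
  readouts. A dysbiotic sample receives the key-taxon spike plus an
  idiosyncratic displacement (`personal_weight`, default 0.62): a sparse
  composition on a random support that avoids the species' own core
  taxa, solved to the sample's expected microHI so it is
  microHI-neutral. Random supports make each displaced sample head in
  its own direction — disordered communities are each disordered in
  their own way — which is what keeps them from founding spurious
  "normal branches" of their own. The spike's non-key share goes to
  high-load resident taxa absent from the water support, so bystander
  opportunists carry no spurious water signal.
- **Morphometrics**: lengths are log-normal per species; Fulton's K is
  drawn around 1.02 for healthy and 6% lower for dysbiotic fish, keeping
  the group difference under 9%.

What the generator does **not** emulate: read-level noise and
compositional zeros from sequencing depth, taxonomically structured
phenotype correlations, seasonal dynamics within a unit, or genuinely
unknown phenotype maps. Passing the recovery tests therefore shows the
pipeline's statistical machinery is correct and calibrated under the
stated structure, not that the biological conclusions transfer to any
real dataset.

## Validation experiments and problem sizes

The test suite validates, at fixed seeds: exact agreement of the index
and condition formulas with direct evaluation (1,000 random inputs,
1e-12); Bray–Curtis and UPGMA against brute-force oracles (100 random
tables up to 10 taxa × 8 samples, exact); rank-sum p-values against full
enumeration (fixtures up to n=12) and null uniformity of the
large-sample path (KS test over 1,000 replicates at n=30 per group);
classifier recovery on the default cohort (sensitivity and specificity
≥ 0.9, recovered disordered fraction within ±7 points of 30%); group-mean
recovery (0.71/0.58 within ±0.02 at n=200, ground-truth labels);
ecotype-specific coupling (50 replicates at 60 gut samples per species —
the pooled two-campaign scale — requiring the carnivorous flag and no
other, ≥90%); exact key-taxon recovery with zero false positives (50
replicates at defaults, ≥90%); and byte-identical reruns of every CLI
subcommand under a fixed seed. The ecotype experiment uses the larger
cohort because with only six aggregation units the $r^2 > 0.6$ screen
has an intrinsic, noise-scale-independent null pass rate of a few percent
per ecotype; at the pooled-cohort size the slope threshold becomes the
binding constraint and the experiment measures the coupling pattern
rather than small-sample correlation noise.

## Numerical and degenerate-input conventions

Column normalization rejects all-zero samples by name; duplicate taxon
or sample identifiers are format errors. A sample with zero map-covered
abundance is an error naming the sample. Dirichlet draws that underflow
to all-zero (possible at very small shape parameters) fall back to a
point mass on the largest shape. Exact rank-sum enumeration doubles the
smaller tail and caps at 1. Regression fits report NA estimates with a
flag, never an error, for underdetermined or degenerate inputs. All
writers format numbers at 15 significant digits so identical analyses
are byte-identical on disk; manifests contain no timestamps.

## Known limitations

The disorder call depends on the cohort's species composition: a species
represented by very few individuals is judged against ecotype branches
only, and a cohort of one species falls back to a merge-height quantile
cut. The LDA effect size, as in the published recipe, is permissive for
high-abundance taxa (a 0.1% absolute shift on the $10^6$ scale already
scores 3), so the correlation screens carry most of the specificity of
the cascade. The aggregation-unit choice for pairing water with gut
samples is a declared convention; with few units the regression
diagnostics, not the point estimates, should guide interpretation.
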