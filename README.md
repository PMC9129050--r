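# micrand

Randomization-based causal inference for matched microbiome cohorts.

## What problem this solves, and for whom

Epidemiological cohorts increasingly carry 16S amplicon gut-microbiome
profiles alongside environmental exposures (air pollution, smoking, ...).
Because exposures are not randomized, naive group comparisons confound
exposure effects with background covariates; because the data are
compositional counts with variable sequencing depth, low-prevalence taxa
and strong taxon–taxon correlation, off-the-shelf two-sample tests mislead.
micrand is for biostatisticians and microbiome researchers who want to ask
*"did this exposure alter the gut microbiome?"* the way a randomized
experiment would, from observational data.

The framework follows the Rubin Causal Model in two stages:

- **Design** — reconstruct a hypothetical pair-randomized experiment:
  each exposed unit is matched to a control satisfying per-covariate
  proximity thresholds `Δ(X_i, X_i⋆) = 0 iff |X_i(k) − X_i⋆(k)| < δ_k ∀k`
  (exact equality for categorical covariates), via maximum bipartite
  matching; balance is diagnosed with standardized mean differences.
  A propensity-score matcher provides the sensitivity design.
- **Analysis** — test Fisher sharp null hypotheses by recomputing test
  statistics over within-pair permutations of the intervention label:
  `p = (1/N_iter) Σ_l 1{T_l ≥ T_obs}`, with the observed assignment always
  included. Five analysis levels, as in the matched-cohort microbiome
  literature: diversity (Chao1 / Shannon with measurement-error-aware
  meta-regression slope as statistic), β-diversity (MiRKAT-style kernel
  score `Q = rᵀKr` over unweighted-UniFrac / Aitchison / Jaccard / Gower
  distances), high-dimensional compositional mean equivalence
  (`T_M = (N_E N_C/(N_E+N_C)) max_a (L̄_Ea − L̄_Ca)²/γ̂_aa` on centered
  log-ratios), per-taxon differential abundance under reference-set
  ratio normalization (DACOMP-style), and differential partial-correlation
  network edges (CLR → graphical lasso → StARS, Fisher-z edge statistic).
  Multiplicity within each family is controlled by a fully
  randomization-based min-p (Westfall–Young-style) adjustment sharing one
  assignment matrix.

A synthetic-cohort generator with known potential outcomes
(`simulate_cohort()`) provides ground truth for calibration and power
studies; no external data are required.

## Worked example

```r
library(micrand)

# a confounded synthetic cohort: 40 exposed, 60 control, 40 taxa,
# five taxa carrying a true 2-fold shift under exposure
cfg    <- two_tier_cohort_config(40, 60, seed = 1, n_taxa = 40,
                                 confounding = default_confounding())
cohort <- simulate_cohort(cfg)

report <- run_pipeline(cohort, analysis_config(
  n_iter = 200, seed = 1,
  ranks = c("Genus", "Phylum"),
  beta_metrics = c("aitchison", "jaccard", "unifrac_unweighted"),
  da_dispersion = 0.85, da_prevalence = 0.9,
  network_lambda = 0.3))
print(report)
```

Output of this exact run:

```
Study report — threshold matching 
  units before matching: 40 exposed / 60 control
  matched pairs: 23 
  assignments: 200 (sampled) 
  covariates with |SMD| > 0.1 after matching: alcohol 
  richness p = 0.12, Shannon p = 0.575
  beta-diversity adjusted p: aitchison=0.08, jaccard=0.925, unifrac_unweighted=0.835 
  compositional mean p by rank: Genus=0.04, Phylum=0.34 
  taxa warranting further scrutiny (adjusted p <= 0.2): taxon_001, taxon_002 
  smallest differential-edge adjusted p: taxon_002/taxon_007=0.76, taxon_027/taxon_029=0.76, taxon_016/taxon_033=0.76 
```

Reading it: threshold matching retained 23 of 40 exposed units with a
control "twin" (covariate proximity: alcohol < 25 g/day, BMI < 4 kg/m²,
age < 5 years, exact sex/diabetes/activity); after matching only alcohol
retains |SMD| > 0.1. At 23 pairs and 200 assignments the tests are
deliberately small-sample: the compositional-mean test at genus rank
(p = 0.04) and the Aitchison kernel test (adjusted p = 0.08) pick up the
injected abundance shifts, and two of the five truly shifted taxa
(`taxon_001`, `taxon_002`) cross the adjusted-p ≤ 0.2 reporting threshold
of the differential-abundance family. No network edge stands out — no edge
effect was injected. Larger designs (the acceptance suite uses 100–150
pairs) recover 4–5 of 5 shifted taxa and deleted network edges reliably.

Every stage is also callable on its own (`match_pairs()`,
`generate_assignments()`, `diversity_randomization_test()`,
`beta_diversity_test()`, `compositional_mean_test()`,
`differential_abundance_test()`, `network_permutation_test()`), and
`exec/micrand` exposes the pipeline as a CLI
(`micrand simulate|match|test-*|run-all`) over counts/metadata/taxonomy
TSVs and a Newick tree.

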