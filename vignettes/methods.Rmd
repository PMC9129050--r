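---
title: "Randomization-based causal inference for matched microbiome cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization-based causal inference for matched microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrand)
```

## The inferential model

micrand asks whether a binary environmental exposure $W_i \in \{0,1\}$
altered the gut microbiome of an observational cohort, in the potential
outcomes framework. Each subject $i$ has two potential count vectors
$Y_{ib}(0)$ and $Y_{ib}(1)$ over taxa $b$, of which only
$Y_{ib}^{obs} = W_i Y_{ib}(1) + (1-W_i) Y_{ib}(0)$ is observed. The package
tests *sharp null hypotheses* of no effect for any unit — under which every
missing potential outcome is known — by Fisherian randomization inference:

1. **Design.** A hypothetical pair-randomized experiment is reconstructed by
   matching each exposed unit to a control whose covariates are close:
   admissible pairs satisfy $|X_i(k) - X_{i^\star}(k)| < \delta_k$ for
   continuous covariates and exact equality for categorical ones (strict
   inequality: a boundary difference is inadmissible). The largest such set
   of pairs is a maximum bipartite matching (`match_pairs()`), optimizing
   cardinality only — no secondary distance minimization — with
   deterministic tie-breaking by input order. Balance is summarized by
   standardized mean differences (`balance_diagnostics()`); a greedy
   propensity-score matcher with a 0.2-SD caliper (`propensity_match()`)
   serves as the sensitivity design.
2. **Analysis.** Test statistics are recomputed over hypothetical
   re-assignments that respect the design: labels are permuted only within
   pairs (`generate_assignments()`). With $P$ pairs there are $2^P$
   assignments; all are enumerated when $2^P \le N_{iter}$ (exact test),
   otherwise $N_{iter}$ unique assignments are sampled. The p-value is
   $\frac{1}{N_{iter}} \sum_l 1\{T_l \ge T^{obs}\}$ (absolute values first
   for two-sided tests). The observed assignment is always included as
   column 1, so $p \ge 1/N_{iter}$ and the printed formula cannot return
   zero.
3. **Multiplicity.** Families of hypotheses sharing one assignment matrix
   are adjusted by the fully randomization-based min-p procedure
   (`minp_adjust()`): every column is in turn treated as observed, the
   minimum p-value across hypotheses per column captures the joint null
   law, and the adjusted p-value is the proportion of those minima at or
   below the unadjusted one. Adjusted $\ge$ unadjusted holds by
   construction; under independence the adjustment approaches the Šidák
   bound, under perfect dependence it vanishes. Families follow the
   analysis levels: the four β-diversity metrics form one family,
   differential-abundance taxa one family per rank, network edges one
   family; taxonomic ranks of the compositional-mean test are reported
   unadjusted.

## The five analysis levels

| level | transformation | statistic |
|---|---|---|
| richness | Chao1 (+ SE) | meta-regression slope of $W$ |
| Shannon α-diversity | plug-in (+ bootstrap SE) | meta-regression slope of $W$ |
| β-diversity | UniFrac/Aitchison/Jaccard/Gower kernels | score statistic $Q = r^\top K r$ |
| compositional mean | CLR | $T_M$: max standardized mean difference |
| abundance | normalization-by-ratio | log-fold arm difference |
| association network | CLR → glasso → StARS | Fisher-z edge difference |

**Diversity.** The model-based estimators of the original workflow
(breakaway, DivNet) are deliberately not re-implemented; they are replaced
by Chao1 ($S_{obs} + f_1^2/2f_2$, bias-corrected when $f_2 = 0$) and the
plug-in Shannon entropy with multinomial-bootstrap standard errors, and
`diversity_randomization_test()` accepts externally computed
(estimate, SE) tables for users of the original estimators. What *is*
preserved exactly is the inferential contribution: the per-sample
(estimate, SE) pairs enter a measurement-error-aware meta-regression
$\hat\alpha_i = \beta_0 + \beta_1 W_i + u_i + \varepsilon_i$ with
$\mathrm{Var}(\varepsilon_i) = \sigma_i^2$ known and $\mathrm{Var}(u_i) =
\sigma_u^2$ estimated by iterated method of moments (truncated at zero,
tolerance $10^{-8}$, ≤100 iterations), and $\hat\beta_1$ is the Fisher test
statistic. With all $\sigma_i = 0$ the fit is exactly OLS. Diversity tests
are one-sided in the direction of diversity *reduction* under exposure;
differential abundance and network edges are two-sided.

**β-diversity.** Kernels are $K = -\tfrac12 J (D \circ D) J$ with $J$ the
centering projector; Jaccard and Gower can yield indefinite kernels, so
negative eigenvalues are truncated to zero (reported via an attribute). The
score statistic uses the intercept-only null model, $r = W - \bar W$.

**Compositional mean.** $T_M = \frac{N_E N_C}{N_E + N_C} \max_a
(\bar L_{Ea} - \bar L_{Ca})^2 / \hat\gamma_{aa}$ on centered log-ratios,
with pooled per-taxon CLR variances. Zero-variance taxa with zero mean
difference are dropped with a warning; with a nonzero difference the
statistic is undefined and an error is raised.

**Differential abundance.** Reference taxa are selected by the median-SD
dispersion score: for taxon $a$, the median over other taxa $a'$ of the SD
across samples of $\log\frac{C_{ia}+pc}{C_{ia'}+pc}$, intersected with a
prevalence floor. Defaults are the genus-level convention (score < 2,
prevalence > 90%; `asv_mode` switches to 3 / 40%), but the thresholds are
*data-calibrated quantities*: the right values depend on the dataset's
score distribution, and analyses of the synthetic two-tier world below use
0.85. Per-sample reference coverage is enforced by relaxing the set with
the next-lowest-dispersion taxa (logged). The per-taxon statistic is the
arm difference of mean $\log(v + \varepsilon)$, $v_i = C_{ia}/(C_{ia} +
\sum_f C_{ir_f})$, with $\varepsilon = 1/(2\,\text{max depth})$ by default.
The ratio is computed directly rather than by rarefied subsampling:
deterministic and matching the printed null hypothesis.

**Networks.** CLR abundances are standardized to a correlation matrix
(partial correlations are invariant to this) and a sparse precision is
estimated by a blockwise-coordinate-descent graphical lasso (tolerance
$10^{-4}$, ≤200 sweeps), with the penalty selected by StARS: 50 subsamples
of fraction 0.8 (or $10\sqrt n/n$ for $n \ge 144$), instability
$\bar D(\lambda)$ monotonized from the sparse end, threshold 0.05, densest
stable model selected. The penalty path is 30 log-spaced values on
$[0.01, 1] \cdot \max |r_{jk}|$ — with correlation-input glasso this upper
bound is exactly the empty-graph penalty. For differential edges, λ is
selected once by StARS on the pooled CLR data of all matched units and held
fixed across permutations (re-running StARS thousands of times is
computationally prohibitive and the original procedure does not state
whether selection was repeated; `lambda_mode = "reselect"` restores full
re-selection). The tested universe defaults to pairs with an edge in at
least one observed arm — testing all $p(p-1)/2$ pairs makes min-p
needlessly conservative — and the per-pair statistic is
$|\mathrm{atanh}\,\hat\rho_E - \mathrm{atanh}\,\hat\rho_C|$ (Fisher-z, for
variance stabilization; absent edges contribute $\rho = 0$).

## The synthetic cohort: what it emulates and what it does not

No real cohort ships with the package; `simulate_cohort()` provides ground
truth instead. The generative model is logistic-normal–multinomial:

- **Covariates** (age, sex, BMI, alcohol, diabetes, physical activity) are
  drawn from distributions emulating a middle-aged European cohort, and
  exposure is assigned to exactly $n_E$ units by weighted sampling with
  logistic-model weights on standardized covariates — a conditional
  logistic assignment that makes confounding real (pre-matching SMDs
  routinely exceed 0.2 under the default coefficients) while honoring the
  configured arm sizes.
- **Latent abundances** per arm are multivariate normal with precision
  matrix from a chain, hub, or random topology; partial correlations have
  magnitude `rho` (default 0.4, per-edge vectors allowed) and *alternating
  signs*. The sign choice is substantive: an all-positive chain carries a
  strong common abundance mode, and after the CLR's row-centering the true
  precision of the observable data becomes dense — no sparse estimator can
  recover it at $p = 15$. Mixed-sign associations, which real gut networks
  exhibit, survive the closure projection.
- **Effects** are applied on the latent log scale before closure, so
  "log-fold" ground truth lives on the same scale as the
  differential-abundance statistic; a diversity effect is an evenness
  temperature (centered latent means scaled by $\tau > 1$ sharpen the
  composition and lower Shannon diversity); network effects delete
  precision entries in the exposed arm (re-symmetrized, diagonally loaded
  back to positive definiteness, with an explicit error naming the edges
  if loading fails).
- **Counts**: softmax to relative abundances, multinomial at a
  negative-binomial depth (mean 10,000, size 5; drawn once per unit — depth
  is a property of the measurement, not the arm).
- **Tree**: random coalescent bifurcation (exponential coalescence times);
  only topology and branch lengths matter for unweighted UniFrac.
- The optional `latent_sds`/`latent_means` fields reshape per-taxon
  variances and abundances without touching the partial-correlation
  network ($\mathrm{diag}(s)\,\Sigma\,\mathrm{diag}(s)$). The exported
  `two_tier_cohort_config()` preset uses them to build the world that
  reference-based differential-abundance testing presupposes: a stable,
  abundant core (latent SD 0.25–0.5) against volatile taxa (SD 0.95–1.7),
  with five designated differential taxa (abundant, SD 0.95) carrying a
  2-fold shift. In that world the dispersion-score distribution is bimodal
  and a threshold of 0.85 cleanly separates the tiers.

What the generator does **not** emulate: sequencing error and chimeras,
batch effects, covariate-dependent abundances (covariates confound the
*exposure* only, so matching addresses assignment bias, not outcome-model
bias), taxonomic misassignment, and overdispersion beyond the
logistic-normal layer. A green calibration test therefore establishes
validity of the inference machinery under exchangeability — which is
exactly what randomization inference claims — not robustness to every
real-data pathology.

## Numerical choices and degenerate inputs

- CLR pseudocount: default 1 (0.5 available); all-zero rows are errors.
  Scale invariance of CLR, $T_M$ and the Aitchison distance is exact only
  at pseudocount 0.
- Assignment sampling uses rejection on a hash set for uniqueness; the
  exhaustive branch activates whenever $2^P \le N_{iter}$ (improving on
  sampling, and capped at $P \le 30$).
- Iteration p-values inside `minp_adjust()` are computed by min-ranks, so
  ties are handled exactly as the counting definition requires.
- Missing covariate values make a pair inadmissible (conservative: the
  unconfoundedness argument rests on verified proximity).
- Zero pooled SD in balance diagnostics reports SMD 0 when means agree and
  flags the covariate as degenerate otherwise.
- glasso warm-starts each block from the previous sweep; convergence is
  declared on the mean absolute change of the working covariance.
- In reports, "warrants further scrutiny" highlights use the thresholds
  0.1 (unadjusted) / 0.2 (adjusted); all p-values are always printed.

## Known limitations

- The meta-regression substitutes moment-based estimation for the original
  ML fit; coefficients agree with OLS in the degenerate case but are not
  numerically identical to the original implementation in general.
- Holding λ fixed across permutations (default) trades some fidelity for
  three orders of magnitude of compute; the flag restores fidelity.
- The min-p family for differential abundance can be conservative when
  many tested taxa are highly dependent.
- At small taxon counts ($p \lesssim 15$) the CLR closure materially
  attenuates association signals; network conclusions at such
  dimensionalities deserve caution regardless of estimator.
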