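#' Configuration for a synthetic paired exposure cohort
#'
#' Describes the generative world for [simulate_cohort()]: cohort size,
#' covariate distributions, the strength of confounding between covariates
#' and exposure assignment, sequencing depth, the latent taxon-taxon
#' association structure, and the injected exposure effects (the ground
#' truth that downstream tests should recover).
#'
#' Counts are generated from a logistic-normal-multinomial model: latent
#' per-arm log-abundances are multivariate normal with covariance equal to
#' the inverse of a sparse precision matrix (so the association network is
#' carried natively), mapped through a softmax to relative abundances and
#' sampled at a negative-binomial sequencing depth.
#'
#' @param n_exposed,n_control Units per arm. Exposure is assigned to exactly
#'   `n_exposed` units, sampled with probability weights from a logistic
#'   model on covariates when `confounding` is nonzero (confounded design).
#' @param n_taxa Number of taxa.
#' @param seed Integer seed; identical configs reproduce bit-identical
#'   cohorts.
#' @param covariates Named list of covariate samplers, each a
#'   `function(n)`. Defaults emulate a middle-aged European cohort: age
#'   (years), sex (0/1), bmi (kg/m^2), alcohol (g/day), diabetes (0/1),
#'   activity (0/1).
#' @param confounding Named numeric, log-odds of exposure per unit of each
#'   covariate (covariates are internally standardized before the logistic
#'   model). Zero vector gives a completely randomized assignment.
#' @param depth_mean,depth_dispersion Mean and negative-binomial size of the
#'   per-unit sequencing depth.
#' @param network Latent association structure: list with `topology`
#'   (`"chain"`, `"hub"` or `"random"`), `rho` (base partial-correlation
#'   magnitude) and for `"random"` an edge probability `prob`.
#' @param effects Exposure effects, see [effect_spec()].
#' @param taxon_sd Standard deviation of base latent log-abundance means
#'   across taxa (controls abundance heterogeneity / rare taxa).
#' @param latent_sds Optional per-taxon scale for the latent log-abundance
#'   fluctuations (recycled to `n_taxa`): the latent covariance becomes
#'   `diag(s) Sigma diag(s)`, which preserves the partial-correlation
#'   network while letting some taxa form a stable low-dispersion core and
#'   others fluctuate strongly (as real cohorts do). `NULL` keeps the unit
#'   scale implied by the precision matrix.
#' @param latent_means Optional per-taxon latent mean log-abundances
#'   (recycled to `n_taxa`), overriding the `N(0, taxon_sd^2)` draw.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()], [effect_spec()]
#' @export
cohort_config <- function(n_exposed, n_control, n_taxa, seed,
                          covariates = default_covariates(),
                          confounding = default_confounding(),
                          depth_mean = 10000, depth_dispersion = 5,
                          network = list(topology = "chain", rho = 0.4),
                          effects = effect_spec(),
                          taxon_sd = 2, latent_sds = NULL,
                          latent_means = NULL) {
  stopifnot(n_exposed >= 1, n_control >= 1, n_taxa >= 2,
            is.numeric(seed), length(seed) == 1,
            depth_mean > 0, depth_dispersion > 0, taxon_sd >= 0)
  if (length(effects$taxa)) {
    if (any(effects$taxa < 1 | effects$taxa > n_taxa))
      stop("affected taxa must lie in 1..n_taxa")
    if (any(!is.finite(effects$logfold)))
      stop("log-fold shifts must be finite")
  }
  if (!is.null(effects$drop_edges) && nrow(effects$drop_edges) > 0 &&
      any(effects$drop_edges < 1 | effects$drop_edges > n_taxa))
    stop("dropped edges must reference taxa in 1..n_taxa")
  bad <- setdiff(names(confounding), names(covariates))
  if (length(bad)) stop("confounding names not in covariates: ",
                        paste(bad, collapse = ", "))
  if (!is.null(latent_sds)) {
    latent_sds <- rep_len(latent_sds, n_taxa)
    stopifnot(all(latent_sds > 0))
  }
  if (!is.null(latent_means)) {
    latent_means <- rep_len(latent_means, n_taxa)
    stopifnot(all(is.finite(latent_means)))
  }
  structure(list(n_exposed = as.integer(n_exposed),
                 n_control = as.integer(n_control),
                 n_taxa = as.integer(n_taxa), seed = as.integer(seed),
                 covariates = covariates, confounding = confounding,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 network = network, effects = effects, taxon_sd = taxon_sd,
                 latent_sds = latent_sds, latent_means = latent_means),
            class = "cohort_config")
}

#' Default covariate samplers for the synthetic cohort
#' @return Named list of `function(n)` samplers.
#' @export
default_covariates <- function() {
  list(age      = function(n) round(rnorm(n, 55, 10), 1),
       sex      = function(n) rbinom(n, 1, 0.5),
       bmi      = function(n) round(rnorm(n, 27, 4), 1),
       alcohol  = function(n) round(rgamma(n, shape = 1.2, scale = 10), 1),
       diabetes = function(n) rbinom(n, 1, 0.06),
       activity = function(n) rbinom(n, 1, 0.55))
}

#' Default confounding coefficients (log-odds of exposure per SD of covariate)
#' @return Named numeric vector.
#' @export
default_confounding <- function() {
  c(age = -0.4, sex = 0.9, bmi = 0.3, alcohol = 0.3,
    diabetes = 0.2, activity = -0.5)
}

#' Exposure effect specification for the synthetic cohort
#'
#' @param taxa Integer indices of differentially abundant taxa.
#' @param logfold Per-taxon log-fold shifts (natural log) applied to the
#'   latent mean log-abundance of the exposed arm, recycled to
#'   `length(taxa)`.
#' @param diversity Evenness temperature applied to the exposed arm's
#'   centered latent means: values > 1 sharpen the composition (lower
#'   Shannon diversity under exposure); 1 = no effect.
#' @param drop_edges Two-column matrix of taxon index pairs whose precision
#'   entries are zeroed in the exposed arm (differential network edges).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(taxa = integer(), logfold = numeric(),
                        diversity = 1, drop_edges = NULL) {
  taxa <- as.integer(taxa)
  if (length(taxa)) logfold <- rep_len(logfold, length(taxa))
  if (!is.null(drop_edges)) {
    drop_edges <- matrix(as.integer(drop_edges), ncol = 2)
    if (any(drop_edges[, 1] == drop_edges[, 2]))
      stop("dropped edges must join distinct taxa")
  }
  stopifnot(diversity > 0)
  structure(list(taxa = taxa, logfold = logfold, diversity = diversity,
                 drop_edges = drop_edges), class = "effect_spec")
}

#' Is an effect specification the sharp null?
#' @param effects An [effect_spec()].
#' @return `TRUE` when no taxon, diversity or edge effect is present.
#' @export
is_null_effect <- function(effects) {
  length(effects$taxa) == 0 && effects$diversity == 1 &&
    (is.null(effects$drop_edges) || nrow(effects$drop_edges) == 0)
}

# Precision matrix for the requested topology, unit diagonal, partial
# correlations of magnitude rho and alternating sign along the edge list
# (mixed-sign associations, as in real relative-abundance networks; an
# all-positive chain would acquire a compositional common mode that makes
# the closure-projected precision dense). Chain keeps PD for |rho| < 0.5.
make_precision <- function(n_taxa, network) {
  topo <- match.arg(network$topology, c("chain", "hub", "random"))
  rho <- if (is.null(network$rho)) 0.4 else network$rho
  omega <- diag(n_taxa)
  edges <- switch(topo,
    chain = cbind(seq_len(n_taxa - 1), seq_len(n_taxa - 1) + 1L),
    hub = {
      hubs <- seq(1L, n_taxa, by = 5L)
      do.call(rbind, lapply(hubs, function(h) {
        sat <- setdiff(h + 1:4, c(hubs, (n_taxa + 1):(n_taxa + 4)))
        if (length(sat)) cbind(h, sat) else NULL
      }))
    },
    random = {
      prob <- if (is.null(network$prob)) 2 / n_taxa else network$prob
      all_pairs <- t(combn(n_taxa, 2))
      all_pairs[runif(nrow(all_pairs)) < prob, , drop = FALSE]
    })
  if (!is.null(edges) && nrow(edges) > 0) {
    sgn <- rep_len(c(-1, 1), nrow(edges))
    mag <- rep_len(rho, nrow(edges))  # per-edge magnitudes allowed
    omega[edges] <- sgn * mag
    omega[edges[, 2:1, drop = FALSE]] <- sgn * mag
  }
  omega <- ensure_pd(omega, "base network")
  list(omega = omega, edges = edges)
}

# Symmetrize and diagonally load until positive definite.
ensure_pd <- function(omega, what, max_load = 10) {
  omega <- (omega + t(omega)) / 2
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8) {
    load <- abs(ev) + 0.05
    if (load > max_load)
      stop("precision matrix for ", what, " cannot be made positive definite")
    diag(omega) <- diag(omega) + load
  }
  omega
}

rmvn_chol <- function(n, mu, R) {
  # R = chol(Sigma); rows are draws
  p <- length(mu)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% R, 2, mu, `+`)
}

#' Simulate a paired observational cohort with known potential outcomes
#'
#' Draws covariates, a confounded binary exposure, latent per-arm
#' log-abundances from a sparse-precision multivariate normal, potential
#' relative abundances via softmax, potential counts via multinomial
#' sampling at a negative-binomial depth, and assembles observed counts as
#' `W * Y(1) + (1 - W) * Y(0)`. A random coalescent tree over the taxa and
#' a nested synthetic taxonomy are attached.
#'
#' @param config A [cohort_config()].
#' @return A list of class `micrand_cohort` with elements `cohort`
#'   (data.frame: unit_id, covariates, exposure), `counts` (samples x taxa
#'   integer matrix of observed counts), `taxonomy` (data.frame of ranks),
#'   `tree` (an [ape::rcoal()] phylo object), and `truth` (potential
#'   relative abundances `Z0`/`Z1`, potential counts `Y0`/`Y1`, latent
#'   log-abundances, assignment propensities, differential taxa/edges, and
#'   per-arm precision matrices).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_exposed + config$n_control
  A <- config$n_taxa

  ## covariates and confounded exposure -----------------------------------
  X <- as.data.frame(lapply(config$covariates, function(f) f(n)))
  eta <- rep(0, n)
  for (nm in names(config$confounding)) {
    x <- X[[nm]]
    s <- sd(x)
    if (s > 0) eta <- eta + config$confounding[[nm]] * (x - mean(x)) / s
  }
  prop <- stats::plogis(eta)
  exposed_idx <- sample.int(n, config$n_exposed, prob = prop)
  W <- integer(n)
  W[exposed_idx] <- 1L

  ## latent structure ------------------------------------------------------
  net <- make_precision(A, config$network)
  omega0 <- net$omega
  omega1 <- omega0
  eff <- config$effects
  if (!is.null(eff$drop_edges) && nrow(eff$drop_edges) > 0) {
    omega1[eff$drop_edges] <- 0
    omega1[eff$drop_edges[, 2:1, drop = FALSE]] <- 0
    omega1 <- ensure_pd(omega1, paste("dropped edges",
      paste(apply(eff$drop_edges, 1, paste, collapse = "-"), collapse = ", ")))
  }
  sigma0 <- solve(omega0)
  sigma1 <- solve(omega1)
  if (!is.null(config$latent_sds)) {
    s <- config$latent_sds
    sigma0 <- s * t(s * sigma0)   # diag(s) Sigma diag(s)
    sigma1 <- s * t(s * sigma1)
    omega0 <- (1 / s) * t((1 / s) * omega0)
    omega1 <- (1 / s) * t((1 / s) * omega1)
  }
  R0 <- chol(sigma0)
  R1 <- chol(sigma1)

  mu0 <- if (is.null(config$latent_means)) {
    rnorm(A, 0, config$taxon_sd)
  } else config$latent_means
  mu1 <- eff$diversity * (mu0 - mean(mu0)) + mean(mu0)
  if (length(eff$taxa)) mu1[eff$taxa] <- mu1[eff$taxa] + eff$logfold

  lat0 <- rmvn_chol(n, mu0, R0)
  lat1 <- rmvn_chol(n, mu1, R1)
  Z0 <- exp(lat0 - apply(lat0, 1, max))
  Z0 <- Z0 / rowSums(Z0)
  Z1 <- exp(lat1 - apply(lat1, 1, max))
  Z1 <- Z1 / rowSums(Z1)

  depth <- pmax(rnbinom(n, mu = config$depth_mean,
                        size = config$depth_dispersion), 100L)
  Y0 <- t(vapply(seq_len(n),
                 function(i) rmultinom(1, depth[i], Z0[i, ])[, 1],
                 integer(A)))
  Y1 <- t(vapply(seq_len(n),
                 function(i) rmultinom(1, depth[i], Z1[i, ])[, 1],
                 integer(A)))
  counts <- W * Y1 + (1L - W) * Y0
  storage.mode(counts) <- "integer"

  taxon_ids <- sprintf("taxon_%03d", seq_len(A))
  sample_ids <- sprintf("unit_%03d", seq_len(n))
  dimnames(counts) <- dimnames(Y0) <- dimnames(Y1) <-
    dimnames(Z0) <- dimnames(Z1) <- list(sample_ids, taxon_ids)

  tree <- ape::rcoal(A, tip.label = taxon_ids)
  taxonomy <- synthetic_taxonomy(taxon_ids)

  cohort <- data.frame(unit_id = sample_ids, X,
                       exposure = W, stringsAsFactors = FALSE)

  truth <- list(Z0 = Z0, Z1 = Z1, Y0 = Y0, Y1 = Y1,
                latent0 = lat0, latent1 = lat1,
                mu0 = mu0, mu1 = mu1,
                propensity = prop, depth = depth,
                differential_taxa = eff$taxa,
                differential_edges = eff$drop_edges,
                precision0 = omega0, precision1 = omega1,
                network_edges = net$edges)

  structure(list(cohort = cohort, counts = counts, taxonomy = taxonomy,
                 tree = tree, truth = truth, config = config),
            class = "micrand_cohort")
}

# Random nested taxonomy: each rank coarsens the one below it.
synthetic_taxonomy <- function(taxon_ids) {
  A <- length(taxon_ids)
  n_levels <- c(Genus = max(2L, ceiling(A / 2.5)),
                Family = max(2L, ceiling(A / 5)),
                Order = max(2L, ceiling(A / 10)),
                Class = max(2L, ceiling(A / 15)),
                Phylum = max(2L, ceiling(A / 20)))
  genus <- sample.int(n_levels["Genus"], A, replace = TRUE)
  g2f <- sample.int(n_levels["Family"], n_levels["Genus"], replace = TRUE)
  f2o <- sample.int(n_levels["Order"], n_levels["Family"], replace = TRUE)
  o2c <- sample.int(n_levels["Class"], n_levels["Order"], replace = TRUE)
  c2p <- sample.int(n_levels["Phylum"], n_levels["Class"], replace = TRUE)
  fam <- g2f[genus]; ord <- f2o[fam]; cls <- o2c[ord]; phy <- c2p[cls]
  data.frame(taxon_id = taxon_ids,
             Phylum = sprintf("P%02d", phy),
             Class = sprintf("C%02d", cls),
             Order = sprintf("O%02d", ord),
             Family = sprintf("F%02d", fam),
             Genus = sprintf("G%03d", genus),
             Species = taxon_ids,
             stringsAsFactors = FALSE)
}

#' Two-tier cohort preset for differential-abundance benchmarking
#'
#' A frozen generative world emulating the structure that reference-based
#' differential abundance testing presupposes: a stable, abundant core of
#' taxa (latent SD 0.25-0.5, the reference candidates) alongside volatile
#' taxa (latent SD 0.95-1.7), with a designated set of differential taxa -
#' abundant, moderately volatile (SD 0.95, latent mean 0.8) - carrying a
#' common log-fold shift under exposure. Sequencing depth 20,000 reads.
#' The tier layout is drawn reproducibly from `seed`.
#'
#' With this world the dispersion-score distribution is bimodal; a
#' reference dispersion threshold of about 0.85 separates the stable core
#' from everything else (see the methods vignette).
#'
#' @param n_exposed,n_control Units per arm.
#' @param seed Integer seed.
#' @param n_taxa Total taxa (>= 20).
#' @param n_differential Number of differential taxa (placed at indices
#'   `1:n_differential`).
#' @param logfold Latent log-fold shift under exposure (default `log(2)`).
#' @param confounding Passed to [cohort_config()]; defaults to none
#'   (randomized benchmark).
#' @return A [cohort_config()].
#' @export
two_tier_cohort_config <- function(n_exposed, n_control, seed,
                                   n_taxa = 60, n_differential = 5,
                                   logfold = log(2),
                                   confounding = setNames(
                                     rep(0, 6), names(default_covariates()))) {
  stopifnot(n_taxa >= 20, n_differential < n_taxa / 3)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed + 5000L)
  aff <- seq_len(n_differential)
  n_rest <- n_taxa - n_differential
  n_stable <- round(0.55 * n_taxa)
  tier <- c(rep(1L, n_differential),
            sample(rep(c(0L, 1L), c(n_stable, n_rest - n_stable))))
  sds <- ifelse(tier == 1, runif(n_taxa, 0.95, 1.7),
                runif(n_taxa, 0.25, 0.5))
  mus <- ifelse(tier == 1, rnorm(n_taxa, -0.5, 1.3),
                rnorm(n_taxa, 1.5, 0.8))
  sds[aff] <- 0.95
  mus[aff] <- 0.8
  cohort_config(n_exposed, n_control, n_taxa, seed = seed,
                confounding = confounding,
                depth_mean = 20000, latent_sds = sds, latent_means = mus,
                effects = effect_spec(taxa = aff, logfold = logfold))
}

#' Treat a balanced simulated cohort as a pair-randomized experiment
#'
#' Convenience for simulation studies: pairs the i-th exposed unit with the
#' i-th control unit. This is the hypothetical randomized experiment the
#' generator emulates; for observational designs use [match_pairs()].
#'
#' @param cohort A `micrand_cohort` (or any data.frame with `unit_id` and
#'   `exposure`).
#' @return A `matched_design` (see [maximum_matching()]).
#' @export
as_matched_design <- function(cohort) {
  tab <- if (inherits(cohort, "micrand_cohort")) cohort$cohort else cohort
  e <- tab$unit_id[tab$exposure == 1]
  c_ <- tab$unit_id[tab$exposure == 0]
  if (length(e) != length(c_))
    stop("arms are unbalanced (", length(e), " exposed, ", length(c_),
         " control); use match_pairs()")
  new_matched_design(data.frame(pair_id = seq_along(e), exposed_id = e,
                                control_id = c_, stringsAsFactors = FALSE),
                     provenance = "paired-randomized (simulation)")
}
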