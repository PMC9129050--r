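#' Plug-in Shannon entropy of a count vector
#'
#' `-sum(z * log z)` in nats with `z` the observed relative abundances;
#' zero-count taxa contribute nothing. Bounded by `log` of the observed
#' richness, attained at uniformity.
#'
#' @param counts_row Non-negative count vector with positive sum.
#' @return Shannon entropy in nats.
#' @export
plugin_shannon <- function(counts_row) {
  tot <- sum(counts_row)
  if (tot <= 0) stop("all-zero count row")
  z <- counts_row[counts_row > 0] / tot
  -sum(z * log(z))
}

#' Observed richness of a count vector
#' @param counts_row Non-negative count vector.
#' @return Number of taxa with positive count.
#' @export
observed_richness <- function(counts_row) sum(counts_row > 0)

#' Chao1 richness estimate with classical standard error
#'
#' `S_obs + f1^2 / (2 f2)` from the singleton and doubleton counts, with
#' the bias-corrected form `S_obs + f1 (f1 - 1) / 2` when no doubletons are
#' observed. Serves as the stand-in uncertainty model where model-based
#' richness estimators would be plugged in.
#'
#' @param counts_row Non-negative count vector with positive sum.
#' @return List with `estimate`, `se`, `f1`, `f2`, `s_obs`.
#' @export
chao1_richness <- function(counts_row) {
  if (sum(counts_row) <= 0) stop("all-zero count row")
  s_obs <- sum(counts_row > 0)
  f1 <- sum(counts_row == 1)
  f2 <- sum(counts_row == 2)
  if (f2 > 0) {
    est <- s_obs + f1^2 / (2 * f2)
    r <- f1 / f2
    v <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else {
    est <- s_obs + f1 * (f1 - 1) / 2
    v <- if (f1 > 0) {
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    } else 0
  }
  list(estimate = est, se = sqrt(max(v, 0)), f1 = f1, f2 = f2,
       s_obs = s_obs)
}

#' Multinomial bootstrap standard error of a per-sample statistic
#'
#' Resamples the count row from a multinomial at its own depth and returns
#' the SD of the statistic over resamples.
#'
#' @param counts_row Count vector.
#' @param statistic `function(counts_row)` returning a scalar.
#' @param n_boot Number of resamples (>= 50).
#' @param seed Integer seed.
#' @return Standard error (0 for degenerate rows).
#' @export
bootstrap_se <- function(counts_row, statistic = plugin_shannon,
                         n_boot = 200, seed = 1L) {
  stopifnot(n_boot >= 50)
  tot <- sum(counts_row)
  if (tot <= 0 || sum(counts_row > 0) < 2) return(0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  draws <- rmultinom(n_boot, tot, counts_row / tot)
  stats <- apply(draws, 2, statistic)
  sd(stats)
}

#' Measurement-error-aware meta-regression coefficient
#'
#' Fits `estimate_i = x_i' beta + u_i + e_i` with known per-sample error
#' variances `Var(e_i) = se_i^2` and a homogeneous extra-variance component
#' `Var(u_i) = sigma_u^2` estimated by iterated method of moments
#' (truncated at zero), alternating with generalized least squares under
#' weights `1 / (se_i^2 + sigma_u^2)` until the variance component is
#' stable (tolerance 1e-8, at most 100 iterations). With all `se_i = 0`
#' the fit degenerates to ordinary least squares exactly.
#'
#' @param estimates Per-sample diversity estimates.
#' @param se Per-sample standard errors (same length).
#' @param w Binary intervention indicator.
#' @param covariates Optional numeric matrix/data.frame of additional
#'   regressors.
#' @return List with `coefficient` (of `w`), `coefficients`, `sigma_u2`,
#'   `iterations`.
#' @export
betta_coefficient <- function(estimates, se, w, covariates = NULL) {
  n <- length(estimates)
  stopifnot(length(se) == n, length(w) == n, all(se >= 0))
  X <- cbind(`(Intercept)` = 1, w = as.numeric(w))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  se2 <- se^2
  sigma_u2 <- 0
  beta <- NULL
  it <- 0
  repeat {
    it <- it + 1
    denom <- se2 + sigma_u2
    wts <- if (max(denom) <= 0) rep(1, n) else 1 / denom
    fit <- stats::lm.wfit(X, estimates, wts)
    beta <- fit$coefficients
    r <- estimates - X %*% beta
    new_s2 <- max(0, sum(r^2) / max(n - ncol(X), 1) - mean(se2))
    if (abs(new_s2 - sigma_u2) < 1e-8 * (1 + sigma_u2) || it >= 100) {
      sigma_u2 <- new_s2
      break
    }
    sigma_u2 <- new_s2
  }
  list(coefficient = unname(beta["w"]), coefficients = beta,
       sigma_u2 = sigma_u2, iterations = it)
}

# Per-sample diversity estimates and SEs for the randomization test.
diversity_estimates <- function(counts, which = c("shannon", "richness"),
                                n_boot = 200, seed = 1L) {
  which <- match.arg(which)
  n <- nrow(counts)
  if (which == "shannon") {
    est <- apply(counts, 1, plugin_shannon)
    se <- vapply(seq_len(n), function(i)
      bootstrap_se(counts[i, ], plugin_shannon, n_boot, seed + i),
      numeric(1))
  } else {
    ch <- lapply(seq_len(n), function(i) chao1_richness(counts[i, ]))
    est <- vapply(ch, `[[`, numeric(1), "estimate")
    se <- vapply(ch, `[[`, numeric(1), "se")
  }
  data.frame(sample_id = rownames(counts), estimate = est, se = se,
             estimator = which, stringsAsFactors = FALSE)
}

#' Randomization test for within-subject diversity
#'
#' Per-sample diversity estimates and standard errors are computed once
#' (plug-in Shannon with multinomial-bootstrap SEs, or Chao1 richness with
#' its classical SE); the meta-regression coefficient of the intervention
#' indicator ([betta_coefficient()]) is then recomputed under every
#' hypothetical assignment. One-sided by default in the direction of
#' diversity reduction under exposure (`"less"`).
#'
#' @param counts Samples x taxa count matrix (rownames = unit ids covering
#'   the design).
#' @param assignments An `assignment_matrix` from [generate_assignments()].
#' @param which `"shannon"` or `"richness"`.
#' @param estimates Optional externally computed estimate table
#'   (data.frame: sample_id, estimate, se) to substitute for the built-in
#'   estimators.
#' @param n_boot Bootstrap resamples for Shannon SEs.
#' @param sidedness Test direction; default `"less"`.
#' @param seed Seed for the bootstrap.
#' @return A `micrand_test`.
#' @export
diversity_randomization_test <- function(counts, assignments,
                                         which = c("shannon", "richness"),
                                         estimates = NULL, n_boot = 200,
                                         sidedness = "less", seed = 1L) {
  which <- match.arg(which)
  E <- assignment_exposures(assignments)
  ids <- rownames(E)
  missing_ids <- setdiff(ids, rownames(counts))
  if (length(missing_ids))
    stop("design units absent from counts: ",
         paste(missing_ids, collapse = ", "))
  if (is.null(estimates))
    estimates <- diversity_estimates(counts[ids, , drop = FALSE], which,
                                     n_boot, seed)
  idx <- match(ids, estimates$sample_id)
  if (any(is.na(idx))) stop("estimate table does not cover the design")
  est <- estimates$estimate[idx]
  se2 <- estimates$se[idx]^2
  stats_l <- as.numeric(.betta_slope_cols(est, se2, E))
  new_micrand_test(stats_l, sidedness, assignments,
                   label = paste0(which, " (betta coefficient)"))
}

#' Kernel association score statistic
#'
#' `Q = r' K r` with `r = w - mean(w)`, the variance-component score
#' statistic of kernel machine regression under the intercept-only null
#' model. Invariant to adding a constant to `w`.
#'
#' @param K Centered kernel matrix (e.g. from [distance_to_kernel()]).
#' @param w Binary exposure vector aligned with `K`'s rows.
#' @return Scalar `Q >= 0`.
#' @export
mirkat_score <- function(K, w) {
  if (max(abs(rowSums(K))) > 1e-6 * max(abs(K), 1))
    stop("kernel is not centered")
  r <- w - mean(w)
  drop(crossprod(r, K %*% r))
}

#' Beta-diversity kernel battery with min-p adjustment
#'
#' For each requested distance metric, builds the centered kernel over the
#' matched units and recomputes the kernel score statistic under every
#' assignment; the per-metric p-values are then jointly adjusted with the
#' fully randomization-based min-p procedure ([minp_adjust()]), all
#' metrics sharing the one assignment matrix.
#'
#' @param counts Samples x taxa count matrix.
#' @param assignments An `assignment_matrix`.
#' @param metrics Character vector of metric names (see
#'   [beta_distance()]).
#' @param tree Phylogenetic tree (needed for UniFrac).
#' @param pseudocount For CLR-based metrics.
#' @return List of class `micrand_beta_test`: per-metric observed
#'   statistics, unadjusted and adjusted one-sided p-values, and the raw
#'   statistic matrix.
#' @export
beta_diversity_test <- function(counts, assignments,
                                metrics = c("aitchison", "jaccard",
                                            "gower_clr",
                                            "unifrac_unweighted"),
                                tree = NULL, pseudocount = 1) {
  E <- assignment_exposures(assignments)
  ids <- rownames(E)
  C <- counts[ids, , drop = FALSE]
  L <- ncol(E)
  stats <- matrix(NA_real_, length(metrics), L,
                  dimnames = list(metrics, NULL))
  Rc <- scale(E, center = TRUE, scale = FALSE)
  for (m in metrics) {
    D <- beta_distance(C, metric = m, tree = tree,
                       pseudocount = pseudocount)
    K <- distance_to_kernel(D)
    stats[m, ] <- colSums(Rc * (K %*% Rc))
  }
  adj <- minp_adjust(stats, sidedness = "greater")
  structure(list(observed = stats[, 1],
                 p = adj$unadjusted, p_adjusted = adj$adjusted,
                 stats = stats, n_iter = L,
                 metrics = metrics), class = "micrand_beta_test")
}

#' @export
print.micrand_beta_test <- function(x, ...) {
  cat("Beta-diversity kernel score tests (", x$n_iter, "assignments )\n")
  print(data.frame(statistic = signif(x$observed, 5),
                   p = signif(x$p, 4),
                   p_adjusted = signif(x$p_adjusted, 4)))
  invisible(x)
}
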