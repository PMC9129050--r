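test_that("plug-in Shannon entropy matches hand arithmetic", {
  expect_equal(plugin_shannon(rep(5, 8)), log(8), tolerance = 1e-12)
  expect_identical(plugin_shannon(c(0, 42, 0)), 0)
  expect_equal(plugin_shannon(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)),
               tolerance = 1e-12)
  expect_error(plugin_shannon(c(0, 0)), "all-zero")
  # bounded by log of observed richness, attained only at uniformity
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(12, 20) + 1
    expect_lte(plugin_shannon(x), log(observed_richness(x)) + 1e-12)
  }
})

test_that("Chao1 richness follows the frequency-count formula", {
  # f1 = 4, f2 = 2, S_obs = 10 -> 10 + 16/4 = 14
  x <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  ch <- chao1_richness(x)
  expect_identical(ch$estimate, 14)
  expect_gt(ch$se, 0)
  # no singletons or doubletons: estimate = observed richness, SE ~ 0
  y <- rep(10, 6)
  ch2 <- chao1_richness(y)
  expect_identical(ch2$estimate, 6)
  expect_identical(ch2$se, 0)
  expect_gte(ch$estimate, observed_richness(x))
})

test_that("bootstrap SEs behave like multinomial noise", {
  expect_identical(bootstrap_se(c(30, 0, 0)), 0)  # degenerate row
  # asymmetric row so the entropy has a nonzero first-order term
  row <- c(30, 70)
  se1 <- bootstrap_se(row, plugin_shannon, n_boot = 400, seed = 9)
  expect_identical(se1, bootstrap_se(row, plugin_shannon, 400, seed = 9))
  # scaling: SE shrinks roughly as 1/sqrt(depth) as depth x100
  se2 <- bootstrap_se(row * 100, plugin_shannon, n_boot = 400, seed = 9)
  expect_gt(se1 / se2, 4)
  expect_lt(se1 / se2, 25)
  # deterministic statistic: zero SE
  expect_identical(bootstrap_se(c(5, 5), statistic = sum, n_boot = 50), 0)
})

test_that("the meta-regression slope degenerates to OLS without errors", {
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(1.2, 0.8, 1.0, 2.2, 2.0, 1.8)
  fit <- betta_coefficient(y, se = rep(0, 6), w = x)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_equal(fit$coefficient, ols, tolerance = 1e-10)
  # equal arm means with equal errors: slope 0 by symmetry
  y2 <- c(1, 2, 3, 3, 2, 1)
  fit2 <- betta_coefficient(y2, se = rep(0.5, 6), w = x)
  expect_equal(fit2$coefficient, 0, tolerance = 1e-12)
  expect_error(betta_coefficient(y, se = rep(0, 6), w = rep(1, 6)),
               "singular")
})

test_that("the meta-regression matches an independent fixed-point solve", {
  set.seed(21)
  w <- rep(c(0, 1), each = 8)
  se <- runif(16, 0.1, 0.9)
  y <- 1 + 0.6 * w + rnorm(16, 0, sqrt(se^2 + 0.3))
  fit <- betta_coefficient(y, se, w)
  # independent oracle: iterate the same moment equations via lm()
  s2u <- 0
  for (i in 1:200) {
    wt <- 1 / (se^2 + s2u)
    m <- lm(y ~ w, weights = wt)
    r <- residuals(m)
    s2u_new <- max(0, sum(r^2) / (16 - 2) - mean(se^2))
    if (abs(s2u_new - s2u) < 1e-12) break
    s2u <- s2u_new
  }
  expect_equal(fit$coefficient, unname(coef(m)[2]), tolerance = 1e-6)
  expect_equal(fit$sigma_u2, s2u, tolerance = 1e-6)
  # and the compiled per-column path agrees with the R implementation
  cols <- cbind(w, rev(w), rep(c(1, 0), 8))
  fast <- as.numeric(micrand:::.betta_slope_cols(y, se^2, cols))
  slow <- vapply(1:3, function(j)
    betta_coefficient(y, se, cols[, j])$coefficient, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-8)
})

test_that("diversity randomization tests are invariant to pair order", {
  # exhaustive enumeration so the assignment set is order-free
  world <- small_null_world(n_pairs = 7, n_taxa = 15, seed = 6,
                           n_iter = 128)
  t1 <- diversity_randomization_test(world$cohort$counts,
                                     world$assignments, "richness")
  # permute pair order: same p-value
  d2 <- world$design
  perm <- c(3, 1, 2, 7, 5, 6, 4)
  d2$pairs <- d2$pairs[perm, ]
  d2$pairs$pair_id <- seq_len(7)
  a2 <- generate_assignments(d2, 128, seed = 7)
  t2 <- diversity_randomization_test(world$cohort$counts, a2, "richness")
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  expect_equal(t1$observed, t2$observed, tolerance = 1e-10)
  expect_identical(t1$sidedness, "less")
})

test_that("an evenness-sharpening exposure is detected", {
  cfg <- cohort_config(60, 60, 40, seed = 13,
                       confounding = zero_confounding,
                       effects = effect_spec(diversity = 1.6))
  ch <- simulate_cohort(cfg)
  a <- generate_assignments(as_matched_design(ch), 400, seed = 14)
  tt <- diversity_randomization_test(ch$counts, a, "shannon",
                                     n_boot = 100, seed = 15)
  expect_lt(tt$p, 0.05)
  expect_lt(tt$observed, 0)  # exposed arm less diverse
})

test_that("external estimate tables can replace the built-in estimators", {
  world <- small_null_world(n_pairs = 6, n_taxa = 10, seed = 8,
                           n_iter = 64)
  est <- data.frame(sample_id = rownames(world$cohort$counts),
                    estimate = rnorm(12, 5), se = runif(12, 0.1, 0.3))
  tt <- diversity_randomization_test(world$cohort$counts,
                                     world$assignments,
                                     "shannon", estimates = est)
  expect_s3_class(tt, "micrand_test")
  expect_error(diversity_randomization_test(
    world$cohort$counts, world$assignments, "shannon",
    estimates = est[1:3, ]), "cover")
})

test_that("the kernel score statistic is the quadratic form it claims", {
  x <- c(0, 1, 3, 6)
  K <- distance_to_kernel(abs(outer(x, x, "-")))
  w <- c(1, 0, 1, 0)
  r <- w - mean(w)
  xc <- x - mean(x)
  expect_equal(mirkat_score(K, w), sum(r * xc)^2, tolerance = 1e-10)
  expect_identical(mirkat_score(matrix(0, 4, 4), w), 0)
  # invariance to adding a constant to w
  expect_equal(mirkat_score(K, w + 5), mirkat_score(K, w),
               tolerance = 1e-10)
  # r orthogonal to the kernel range gives zero
  expect_equal(mirkat_score(K, c(1, 0, 0, 1) * 0 + c(0.5, 0.5, 0.5, 0.5)),
               0, tolerance = 1e-12)
  expect_error(mirkat_score(matrix(1, 4, 4), w), "centered")
})

test_that("the beta-diversity battery shares one joint null", {
  world <- small_null_world(n_pairs = 12, n_taxa = 25, seed = 19,
                           n_iter = 150)
  bt <- beta_diversity_test(world$cohort$counts, world$assignments,
                            metrics = c("aitchison", "jaccard",
                                        "gower_clr",
                                        "unifrac_unweighted"),
                            tree = world$cohort$tree)
  expect_identical(dim(bt$stats), c(4L, 150L))
  expect_true(all(bt$p_adjusted >= bt$p))
  expect_true(all(bt$p >= 1 / 150))
  # observed column reproduces mirkat_score directly
  E <- assignment_exposures(world$assignments)
  K <- distance_to_kernel(
    beta_distance(world$cohort$counts[rownames(E), ], "aitchison"))
  expect_equal(unname(bt$observed["aitchison"]),
               mirkat_score(K, E[, 1]), tolerance = 1e-8)
})
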