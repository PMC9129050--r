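chain_mvn <- function(n, p, rho = 0.4, seed = 1) {
  omega <- diag(p)
  sgn <- rep_len(c(-1, 1), p - 1)
  for (i in seq_len(p - 1)) {
    omega[i, i + 1] <- sgn[i] * rho
    omega[i + 1, i] <- sgn[i] * rho
  }
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p) %*% chol(solve(omega))
  colnames(x) <- sprintf("t%02d", seq_len(p))
  list(x = x, omega = omega)
}

test_that("the graphical lasso honors its optimality conditions", {
  sim <- chain_mvn(200, 8, seed = 3)
  S <- cor(sim$x)
  for (lam in c(0.05, 0.2, 0.5)) {
    fit <- micrand:::.glasso_cpp(S, lam)
    theta <- fit$theta
    W <- fit$w
    # primal feasibility: W agrees with S within the penalty box
    off <- abs(W - S)[upper.tri(S)]
    expect_lt(max(off), lam + 1e-4)
    # estimated precision is positive definite, W its near-inverse
    expect_gt(min(eigen(theta, only.values = TRUE)$values), 0)
    expect_lt(max(abs(W %*% theta - diag(8))), 0.05)
  }
})

test_that("penalty extremes give the expected graphs", {
  sim <- chain_mvn(300, 6, seed = 4)
  # heavy shrinkage: empty edge set
  net_big <- graphical_lasso_network(sim$x, 2)
  expect_identical(nrow(net_big$edges), 0L)
  # vanishing penalty, n >> p: precision approaches the sample inverse
  net_small <- graphical_lasso_network(sim$x, 1e-4)
  inv <- solve(cor(sim$x))
  expect_lt(max(abs(net_small$precision - inv)), 0.05)
  # edge sets shrink monotonically along an increasing penalty path
  sizes <- vapply(c(0.02, 0.1, 0.2, 0.4, 0.8), function(l)
    nrow(graphical_lasso_network(sim$x, l)$edges), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # partial correlations bounded, symmetric, no self-edges
  net <- graphical_lasso_network(sim$x, 0.1)
  expect_lt(max(abs(net$pcor)), 1)
  expect_identical(max(abs(diag(net$pcor))), 0)
  expect_true(isSymmetric(net$pcor))
})

test_that("StARS selection responds to subsampling noise", {
  sim <- chain_mvn(120, 6, seed = 5)
  # subsample fraction 1: no sampling noise, zero instability everywhere,
  # densest (smallest) penalty selected
  lam <- stars_select(sim$x, n_subsamples = 20, subsample_fraction = 1)
  expect_identical(max(attr(lam, "instability")), 0)
  expect_identical(as.numeric(lam), min(attr(lam, "path")))
  # independent noise: selection stays near the sparse end
  set.seed(9)
  noise <- matrix(rnorm(150 * 6), 150, 6)
  colnames(noise) <- paste0("n", 1:6)
  lam2 <- suppressWarnings(stars_select(noise, n_subsamples = 30, seed = 2))
  path2 <- attr(lam2, "path")
  expect_gte(as.numeric(lam2), sort(path2, decreasing = TRUE)[8])
  # reproducibility under a fixed seed (fallback warning expected at
  # this small n)
  lam3 <- suppressWarnings(stars_select(sim$x, n_subsamples = 25, seed = 4))
  lam4 <- suppressWarnings(stars_select(sim$x, n_subsamples = 25, seed = 4))
  expect_identical(as.numeric(lam3), as.numeric(lam4))
})

test_that("the Fisher-z differential statistic has its closed form", {
  sim <- chain_mvn(100, 5, seed = 6)
  net_a <- graphical_lasso_network(sim$x, 0.2)
  net_b <- graphical_lasso_network(sim$x, 0.2)
  pair <- c("t01", "t02")
  expect_identical(differential_association_statistic(net_a, net_b, pair),
                   0)
  # rho_E = 0.5, rho_C = 0 -> atanh(0.5)
  net_c <- net_b
  net_c$pcor["t01", "t02"] <- 0.5
  net_c$pcor["t02", "t01"] <- 0.5
  net_d <- net_b
  net_d$pcor["t01", "t02"] <- 0
  net_d$pcor["t02", "t01"] <- 0
  expect_equal(differential_association_statistic(net_c, net_d, pair),
               atanh(0.5), tolerance = 1e-12)
  # symmetric in the arms
  expect_equal(differential_association_statistic(net_d, net_c, pair),
               atanh(0.5), tolerance = 1e-12)
  net_e <- net_b
  net_e$nodes <- rev(net_e$nodes)
  expect_error(differential_association_statistic(net_e, net_b, pair),
               "node set")
})

test_that("the permutation test reproduces observed statistics at column 1", {
  cfg <- cohort_config(25, 25, 10, seed = 33,
                       confounding = zero_confounding)
  ch <- simulate_cohort(cfg)
  a <- generate_assignments(as_matched_design(ch), 60, seed = 3)
  nt <- network_permutation_test(ch$counts, a, lambda = 0.3)
  ne <- attr(nt, "network_exposed")
  nc <- attr(nt, "network_control")
  direct <- differential_association_statistic(
    ne, nc, as.matrix(nt[, c("taxon_i", "taxon_j")]))
  expect_equal(nt$statistic, unname(direct), tolerance = 1e-12)
  expect_true(all(nt$p_adjusted >= nt$p))
  expect_true(all(nt$p >= 1 / 60))
  # disappearance flag: edge in exactly one arm
  flag <- xor(abs(nt$rho_exposed) > 0, abs(nt$rho_control) > 0)
  expect_identical(nt$disappearance, flag)
})

test_that("connected components are reported largest-first", {
  sim <- chain_mvn(50, 6, seed = 8)
  net <- graphical_lasso_network(sim$x, 5)  # empty graph
  comps <- connected_components(net)
  expect_length(comps, 6)
  expect_true(all(lengths(comps) == 1))
  # hand-built two-cluster graph
  net$edges <- data.frame(taxon_i = c("t01", "t02", "t04"),
                          taxon_j = c("t02", "t03", "t05"),
                          rho = c(0.2, 0.3, -0.1))
  comps2 <- connected_components(net)
  expect_identical(unname(lengths(comps2)), c(3L, 2L, 1L))
  expect_setequal(comps2[[1]], c("t01", "t02", "t03"))
  expect_true("t06" %in% unlist(comps2[lengths(comps2) == 1]))
})
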