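fake_design <- function(P) {
  new_matched_design <- micrand:::new_matched_design
  new_matched_design(data.frame(pair_id = seq_len(P),
                                exposed_id = paste0("E", seq_len(P)),
                                control_id = paste0("C", seq_len(P))))
}

test_that("assignment generation enumerates or samples uniquely", {
  d3 <- fake_design(3)
  a <- generate_assignments(d3, n_iter = 100, seed = 1)
  expect_true(attr(a, "exhaustive"))
  expect_identical(dim(unclass(a)), c(3L, 8L))
  expect_identical(a[, 1], rep(0L, 3))
  keys <- apply(a, 2, paste, collapse = "")
  expect_identical(anyDuplicated(keys), 0L)

  d20 <- fake_design(20)
  b <- generate_assignments(d20, n_iter = 10000, seed = 2)
  expect_false(attr(b, "exhaustive"))
  expect_identical(ncol(b), 10000L)
  expect_identical(anyDuplicated(apply(b, 2, paste, collapse = "")), 0L)
  expect_identical(b[, 1], rep(0L, 20))
  b2 <- generate_assignments(d20, n_iter = 10000, seed = 2)
  expect_identical(unclass(b), unclass(b2))
  expect_error(generate_assignments(d3, n_iter = 1), "at least 2")
})

test_that("exposure labels follow the pair flips", {
  d <- fake_design(2)
  a <- generate_assignments(d, 10, seed = 1)
  E <- assignment_exposures(a)
  expect_identical(rownames(E), c("E1", "E2", "C1", "C2"))
  expect_identical(E[, 1], c(E1 = 1L, E2 = 1L, C1 = 0L, C2 = 0L))
  # every column assigns exactly one exposed unit per pair
  expect_true(all(E[1, ] + E[3, ] == 1L))
  expect_true(all(E[2, ] + E[4, ] == 1L))
})

test_that("randomization p-values count the observed assignment", {
  expect_identical(randomization_pvalue(c(3, 1, 2, 5)), 2 / 4)
  expect_identical(randomization_pvalue(c(5, 1, 2, 3)), 1 / 4)
  expect_identical(randomization_pvalue(rep(2, 8)), 1)
  # strictly largest observed statistic in an exhaustive set of 8
  expect_identical(randomization_pvalue(c(9, 1:7)), 1 / 8)
  # two-sided takes absolute values first
  expect_identical(randomization_pvalue(c(-3, 1, -2, 2),
                                        sidedness = "two.sided"), 1 / 4)
  # "less": count T_l <= T_obs, the observed value included
  expect_identical(randomization_pvalue(c(-1, 3, -2, 2),
                                        sidedness = "less"), 2 / 4)
  expect_error(randomization_pvalue(c(1, NA, 2)), "iteration")
})

test_that("min-p adjustment matches its dependence limits", {
  set.seed(7)
  # single hypothesis: adjusted equals unadjusted up to discreteness
  x <- rnorm(400)
  a1 <- minp_adjust(matrix(x, 1))
  expect_equal(a1$adjusted, a1$unadjusted, tolerance = 1e-12)
  # perfect dependence: identical rows leave p-values unchanged
  a2 <- minp_adjust(rbind(x, x))
  expect_equal(a2$adjusted, a2$unadjusted, tolerance = 1e-12)
  # independence: adjusted tracks Sidak 1 - (1-p)^H
  H <- 20
  S <- matrix(rnorm(H * 2000), H)
  a3 <- minp_adjust(S, sidedness = "two.sided")
  sidak <- 1 - (1 - a3$unadjusted)^H
  expect_lt(max(abs(a3$adjusted - sidak)), 0.06)
  # monotonicity everywhere
  expect_true(all(a3$adjusted >= a3$unadjusted))
})

test_that("run_test reproduces exhaustive enumeration by hand", {
  # 4 pairs with outcome differences d_p; statistic = sum of
  # (exposed - control) outcomes; flips change signs pair-wise
  d <- fake_design(4)
  y <- c(E1 = 5, E2 = 3, E3 = 2, E4 = 7, C1 = 1, C2 = 4, C3 = 2, C4 = 3)
  stat_fn <- function(w) sum(y[w == 1]) - sum(y[w == 0])
  a <- generate_assignments(d, 16, seed = 1)
  res <- run_test(stat_fn, a, sidedness = "greater")
  # independent enumeration over all 16 sign patterns
  dp <- c(4, -1, 0, 4)
  all_t <- apply(expand.grid(c(1, -1), c(1, -1), c(1, -1), c(1, -1)), 1,
                 function(s) sum(s * dp))
  t_obs <- sum(dp)
  expect_identical(res$observed, t_obs)
  expect_identical(res$p, mean(all_t >= t_obs))
  expect_identical(sort(res$null), sort(all_t))
  # a constant statistic yields p = 1
  expect_identical(run_test(function(w) 1, a)$p, 1)
  # failures propagate with the column index
  expect_error(run_test(function(w) if (w[["C1"]] == 1) stop("boom") else 1,
                        a),
               "assignment column")
})

test_that("exhaustive p-values are valid under the sharp null (property)", {
  # permutation-invariant data: p uniform on the achievable grid
  d <- fake_design(6)
  set.seed(11)
  pvals <- replicate(150, {
    y <- setNames(rnorm(12), c(paste0("E", 1:6), paste0("C", 1:6)))
    a <- generate_assignments(d, 64, seed = 1)
    run_test(function(w) sum(y[w == 1]) - sum(y[w == 0]), a)$p
  })
  for (alpha in c(0.1, 0.25, 0.5))
    expect_lt(mean(pvals <= alpha), alpha + 0.12)
  expect_gt(mean(pvals), 0.40)
})

test_that("assignment matrices survive the TSV round trip", {
  d <- fake_design(3)
  a <- generate_assignments(d, 8, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_assignment_matrix(a, path)
  b <- import_assignment_matrix(path, d)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
  expect_true(attr(b, "exhaustive"))

  bad <- cbind(a[, 1], a[, 2], a[, 2])
  write.table(bad, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_error(import_assignment_matrix(path, d), "duplicate")
  write.table(matrix(c(0, 2, 1), 3, 4), path, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  expect_error(import_assignment_matrix(path, d), "0/1")
})
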