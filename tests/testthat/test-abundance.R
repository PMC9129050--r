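test_that("the compositional mean statistic matches direct arithmetic", {
  # 4 samples x 2 taxa, computed by hand
  L <- rbind(c(1, -1), c(2, -2), c(0.5, -0.5), c(1.5, -1.5))
  w <- c(1, 1, 0, 0)
  tm <- tm_statistic(L, w)
  # arm means: E = (1.5, -1.5), C = (1, -1); pooled var per taxon:
  # varE = 0.5, varC = 0.5 -> gamma = 0.5; (0.5)^2/0.5 = 0.5; N-factor 1
  expect_equal(as.numeric(tm), 1 * 0.5, tolerance = 1e-12)
  # duplicating all samples doubles the N-factor and shifts the pooled
  # variance denominator from n-1 to 2n-1: by hand gamma drops from 0.5
  # to 1/3, so T_M goes from 0.5 to 2 * 0.25/(1/3) = 1.5
  tm2 <- tm_statistic(rbind(L, L), c(w, w))
  expect_equal(as.numeric(tm2), 1.5, tolerance = 1e-12)
  # identical arms give zero
  Lid <- rbind(L[1:2, ], L[1:2, ])
  expect_equal(as.numeric(tm_statistic(Lid, c(1, 1, 0, 0))), 0,
               tolerance = 1e-12)
  # degenerate taxon with conflicting means is an error
  Lbad <- cbind(c(1, 1, 0, 0), c(2, 2, 2, 2))
  expect_error(tm_statistic(Lbad, w), "undefined")
})

test_that("the vectorized T_M path agrees with the scalar one", {
  set.seed(8)
  L <- matrix(rnorm(12 * 6), 12, 6)
  L <- L - rowMeans(L)
  colnames(L) <- paste0("t", 1:6)
  E <- replicate(20, sample(rep(c(1L, 0L), 6)))
  fast <- micrand:::tm_statistic_cols(L, E)
  slow <- apply(E, 2, function(w) as.numeric(tm_statistic(L, w)))
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("T_M inherits compositional scale invariance", {
  C <- toy_counts(8, 5, seed = 3)
  w <- rep(c(1, 0), 4)
  scale <- diag(runif(8, 0.5, 3))
  t1 <- tm_statistic(clr_transform(C, 0), w)
  t2 <- tm_statistic(clr_transform(round(scale %*% C * 100), 0), w)
  # per-sample rescaling (up to integer rounding) leaves T_M unchanged
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 0.05)
})

test_that("reference selection implements the median log-ratio SD score", {
  set.seed(5)
  base <- rpois(8, 200) + 50
  C <- cbind(a = base, b = 2L * base, c = rpois(8, 60) + 1L,
             d = as.integer(round(base * exp(rnorm(8, 0, 1.5)))))
  rownames(C) <- paste0("s", 1:8)
  refs <- select_references(C, dispersion_threshold = 1,
                            prevalence_threshold = 0.5, pseudocount = 0)
  # independent oracle: double loop over pairwise log-ratio SDs
  oracle <- vapply(1:4, function(a) {
    median(vapply(setdiff(1:4, a), function(b)
      sd(log(C[, a] / C[, b])), numeric(1)))
  }, numeric(1))
  expect_equal(unname(refs$scores), oracle, tolerance = 1e-10)
  # taxa exactly proportional to each other have zero mutual dispersion
  expect_lt(refs$scores["a"], 0.8)
  expect_true(all(c("a", "b") %in% refs$taxa))
  expect_false("d" %in% refs$taxa)
})

test_that("low-prevalence taxa cannot become references", {
  C <- matrix(50L, 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  C[1:14, "z"] <- 0L  # 30% prevalence
  refs <- select_references(C, dispersion_threshold = 2,
                            prevalence_threshold = 0.9)
  expect_false("z" %in% refs$taxa)
  expect_true(all(c("x", "y") %in% refs$taxa))
})

test_that("ratio normalization and the log-fold statistic are exact", {
  C <- cbind(a = c(0L, 9L, 3L), r1 = c(4L, 5L, 4L), r2 = c(6L, 4L, 5L))
  rownames(C) <- paste0("s", 1:3)
  v <- normalize_by_ratio(C, "a", c("r1", "r2"))
  expect_identical(unname(v), c(0, 9 / 18, 3 / 12))
  expect_error(normalize_by_ratio(C, "r1", c("r1", "r2")), "reference")

  # six-sample hand table
  v6 <- c(0.1, 0.2, 0.4, 0.2, 0.4, 0.8)
  w6 <- c(0, 0, 0, 1, 1, 1)
  eps <- 1e-9
  got <- logfold_statistic(v6, w6, eps)
  want <- mean(log(c(0.2, 0.4, 0.8) + eps)) -
    mean(log(c(0.1, 0.2, 0.4) + eps))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, log(2), tolerance = 1e-6)  # exact doubling
  expect_identical(logfold_statistic(v6, w6[c(4:6, 1:3)], eps), -got)
  expect_error(logfold_statistic(v6, w6, 0), "eps")
})

test_that("differential abundance testing excludes references and is monotone", {
  world <- small_null_world(n_pairs = 12, n_taxa = 20, seed = 23,
                           n_iter = 200)
  counts <- prevalence_filter(world$cohort$counts, 0.05)
  refs <- select_references(counts, dispersion_threshold = 2,
                            prevalence_threshold = 0.5)
  da <- differential_abundance_test(counts, world$assignments, refs)
  expect_false(any(da$taxon %in% refs$taxa))
  expect_setequal(da$taxon, setdiff(colnames(counts), refs$taxa))
  expect_true(all(da$p_adjusted >= da$p))
  expect_true(all(da$p >= 1 / 200))
  expect_identical(attr(da, "eps"),
                   1 / (2 * max(rowSums(counts))))
  # observed column equals a direct statistic computation
  E <- assignment_exposures(world$assignments)
  v <- normalize_by_ratio(counts, da$taxon[1], refs)
  expect_equal(da$statistic[1],
               logfold_statistic(v[rownames(E)], E[, 1], attr(da, "eps")),
               tolerance = 1e-10)
})

test_that("per-rank compositional mean tests run the aggregation chain", {
  world <- small_null_world(n_pairs = 10, n_taxa = 30, seed = 29,
                           n_iter = 100)
  cm <- compositional_mean_test(world$cohort$counts,
                                world$cohort$taxonomy,
                                world$assignments,
                                ranks = c("ASV", "Genus", "Phylum"))
  expect_identical(cm$rank, c("ASV", "Genus", "Phylum"))
  expect_identical(cm$n_taxa[1], 30L)
  expect_true(all(cm$p >= 1 / 100 & cm$p <= 1))
  tests <- attr(cm, "tests")
  expect_identical(tests$ASV$observed, cm$statistic[1])
})
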