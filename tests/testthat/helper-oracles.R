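# Shared fixtures and independent oracles used across the suite.

zero_confounding <- stats::setNames(rep(0, 6), names(default_covariates()))

# Exhaustive maximum-matching oracle: recursion over exposed nodes, trying
# every free partner (feasible up to ~8+8 nodes).
brute_force_matching <- function(edges, exposed_ids) {
  adj <- split(edges$control_id, edges$exposed_id)
  rec <- function(i, used) {
    if (i > length(exposed_ids)) return(0L)
    best <- rec(i + 1L, used)  # leave unit i unmatched
    for (ctrl in adj[[exposed_ids[i]]]) {
      if (!ctrl %in% used)
        best <- max(best, 1L + rec(i + 1L, c(used, ctrl)))
    }
    best
  }
  rec(1L, character(0))
}

# Random bipartite matching instance as a cohort-free edge list.
random_bipartite <- function(n_e, n_c, prob, seed) {
  set.seed(seed)
  e_ids <- paste0("E", seq_len(n_e))
  c_ids <- paste0("C", seq_len(n_c))
  g <- expand.grid(exposed_id = e_ids, control_id = c_ids,
                   stringsAsFactors = FALSE)
  g[stats::runif(nrow(g)) < prob, , drop = FALSE]
}

# Tiny deterministic count fixture: s samples x t taxa, no zeros.
toy_counts <- function(s = 4, t = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(s * t, 50) + 1L, s, t,
              dimnames = list(paste0("s", seq_len(s)),
                              paste0("t", seq_len(t))))
  m
}

# Small null cohort + paired design + assignments, shared by several tests.
small_null_world <- function(n_pairs = 15, n_taxa = 20, seed = 1,
                             n_iter = 200) {
  cfg <- cohort_config(n_pairs, n_pairs, n_taxa, seed = seed,
                       confounding = zero_confounding)
  ch <- simulate_cohort(cfg)
  d <- as_matched_design(ch)
  a <- generate_assignments(d, n_iter, seed = seed + 999)
  list(cohort = ch, design = d, assignments = a)
}
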