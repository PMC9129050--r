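#' Within-pair intervention assignment matrix
#'
#' Enumerates or samples hypothetical re-assignments of the intervention
#' that respect the matched-pair design: each column flips a subset of the
#' pairs (entry 1 = the pair's labels are swapped relative to the observed
#' assignment). Column 1 is always the observed assignment (all zeros), so
#' every randomization p-value is at least `1/n_iter`.
#'
#' When `2^P <= n_iter` all `2^P` assignments are enumerated exactly once
#' (exact test); otherwise `n_iter` unique columns are drawn uniformly
#' without replacement.
#'
#' @param design A `matched_design`.
#' @param n_iter Number of assignments (columns), observed included.
#' @param seed Integer seed for the sampling branch.
#' @return Integer matrix `P x L` of class `assignment_matrix` with
#'   attributes `exhaustive`, `seed` and `design`.
#' @export
generate_assignments <- function(design, n_iter = 10000, seed = 1L) {
  stopifnot(inherits(design, "matched_design"))
  P <- design$n_pairs
  if (P < 1) stop("design has no pairs")
  if (n_iter < 2) stop("n_iter must be at least 2")
  exhaustive <- P <= 30 && 2^P <= n_iter
  if (exhaustive) {
    L <- as.integer(2^P)
    M <- vapply(seq_len(L) - 1L,
                function(v) as.integer(bitwAnd(bitwShiftR(v, seq_len(P) - 1L),
                                               1L)),
                integer(P))
    M <- matrix(M, nrow = P)
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    seen <- new.env(hash = TRUE)
    assign(paste(rep(0L, P), collapse = ""), TRUE, envir = seen)
    cols <- vector("list", n_iter)
    cols[[1]] <- rep(0L, P)
    got <- 1L
    while (got < n_iter) {
      draw <- matrix(sample(0:1, P * 256L, replace = TRUE), nrow = P)
      for (j in seq_len(ncol(draw))) {
        key <- paste(draw[, j], collapse = "")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          got <- got + 1L
          cols[[got]] <- draw[, j]
          if (got == n_iter) break
        }
      }
    }
    M <- do.call(cbind, cols)
  }
  structure(M, exhaustive = exhaustive, seed = as.integer(seed),
            design = design, class = c("assignment_matrix", "matrix"))
}

#' Per-unit exposure labels implied by each assignment column
#'
#' @param assignments An `assignment_matrix`.
#' @return Integer matrix (2P units x L columns) of 0/1 exposure labels,
#'   rownames = unit ids; column 1 reproduces the observed exposure.
#' @export
assignment_exposures <- function(assignments) {
  design <- attr(assignments, "design")
  ids <- c(design$pairs$exposed_id, design$pairs$control_id)
  P <- design$n_pairs
  E <- rbind(1L - assignments, assignments)  # exposed block, control block
  rownames(E) <- ids
  E
}

#' Randomization p-value from a null distribution of statistics
#'
#' `p = (1/N) * sum(T_l >= T_obs)` over all assignment columns (observed
#' included). Sidedness: `"greater"` uses the statistic as is, `"less"`
#' negates it, `"two.sided"` takes absolute values of both the null draws
#' and the observed value first.
#'
#' @param null_stats Numeric vector of statistics, one per assignment
#'   column; element 1 must be the observed statistic unless `t_obs` is
#'   given.
#' @param t_obs Observed statistic (defaults to `null_stats[1]`).
#' @param sidedness One of `"greater"`, `"less"`, `"two.sided"`.
#' @return p-value in `[1/N, 1]`.
#' @export
randomization_pvalue <- function(null_stats,
                                 t_obs = null_stats[1],
                                 sidedness = c("greater", "less",
                                               "two.sided")) {
  sidedness <- match.arg(sidedness)
  if (any(is.na(null_stats)))
    stop("NaN/NA statistic at iteration(s) ",
         paste(which(is.na(null_stats)), collapse = ", "))
  x <- switch(sidedness,
              greater = null_stats, less = -null_stats,
              two.sided = abs(null_stats))
  t0 <- switch(sidedness, greater = t_obs, less = -t_obs,
               two.sided = abs(t_obs))
  mean(x >= t0)
}

# Per-iteration p-values for one row of a null-distribution matrix:
# p_l = (1/N) #{m : x_m >= x_l}, computed via min-ranks.
row_iteration_pvalues <- function(x) {
  N <- length(x)
  (N - rank(x, ties.method = "min") + 1) / N
}

#' Fully randomization-based min-p multiple-comparison adjustment
#'
#' All `H` hypotheses must share one assignment matrix so that the rows of
#' `stats` form draws from the joint null randomization distribution.
#' For every hypothesis an unadjusted p-value is computed from the observed
#' column; then every column is in turn treated as observed, yielding
#' per-iteration p-values whose column-wise minimum captures the joint law
#' of the smallest p-value; the adjusted p-value is the proportion of these
#' minima at or below the hypothesis' unadjusted p-value.
#'
#' @param stats Numeric matrix `H x L`; column 1 corresponds to the
#'   observed assignment. A vector is treated as a single row.
#' @param sidedness Character scalar or length-`H` vector.
#' @return List with `unadjusted`, `adjusted` (both length `H`, named from
#'   `rownames(stats)`) and `min_p` (length `L`).
#' @export
minp_adjust <- function(stats, sidedness = "greater") {
  if (is.vector(stats)) stats <- matrix(stats, nrow = 1)
  H <- nrow(stats); L <- ncol(stats)
  if (L < 2) stop("need at least two assignment columns")
  if (any(!is.finite(stats))) stop("non-finite statistics in null matrix")
  sidedness <- rep_len(sidedness, H)
  Pmat <- matrix(0, H, L)
  for (h in seq_len(H)) {
    x <- switch(sidedness[h],
                greater = stats[h, ], less = -stats[h, ],
                two.sided = abs(stats[h, ]),
                stop("unknown sidedness: ", sidedness[h]))
    Pmat[h, ] <- row_iteration_pvalues(x)
  }
  m <- apply(Pmat, 2, min)
  unadj <- Pmat[, 1]
  adj <- vapply(unadj, function(p) mean(m <= p), numeric(1))
  names(unadj) <- names(adj) <- rownames(stats)
  list(unadjusted = unadj, adjusted = adj, min_p = m)
}

#' Run a statistic under every hypothetical assignment
#'
#' The workhorse harness: applies `statistic_fn` to the exposure labels of
#' each assignment column and assembles the null randomization
#' distribution, observed statistic and p-value.
#'
#' @param statistic_fn `function(w)` where `w` is a named 0/1 exposure
#'   vector over the matched units; must be deterministic in `w`.
#' @param assignments An `assignment_matrix`.
#' @param sidedness Passed to [randomization_pvalue()].
#' @param label Optional hypothesis label.
#' @return Object of class `micrand_test`: observed statistic, p-value,
#'   null sample vector, sidedness, n_iter, exhaustive flag.
#' @export
run_test <- function(statistic_fn, assignments,
                     sidedness = c("greater", "less", "two.sided"),
                     label = NULL) {
  sidedness <- match.arg(sidedness)
  E <- assignment_exposures(assignments)
  stats_l <- numeric(ncol(E))
  for (l in seq_len(ncol(E))) {
    t_l <- tryCatch(statistic_fn(E[, l]),
                    error = function(e)
                      stop("statistic failed at assignment column ", l,
                           ": ", conditionMessage(e)))
    if (is.na(t_l)) stop("NaN statistic at assignment column ", l)
    stats_l[l] <- t_l
  }
  new_micrand_test(stats_l, sidedness, assignments, label)
}

new_micrand_test <- function(null_stats, sidedness, assignments,
                             label = NULL) {
  structure(list(label = label,
                 observed = null_stats[1],
                 p = randomization_pvalue(null_stats,
                                          sidedness = sidedness),
                 null = null_stats,
                 sidedness = sidedness,
                 n_iter = length(null_stats),
                 exhaustive = isTRUE(attr(assignments, "exhaustive"))),
            class = "micrand_test")
}

#' @export
print.micrand_test <- function(x, ...) {
  cat("Randomization test", if (!is.null(x$label)) paste0("(", x$label, ")"),
      "\n  observed statistic:", format(x$observed, digits = 5),
      "\n  sidedness:", x$sidedness,
      "\n  p-value:", format(x$p, digits = 4),
      sprintf("(%s, %d assignments)\n",
              if (x$exhaustive) "exact" else "sampled", x$n_iter))
  invisible(x)
}

#' Export / import an assignment matrix as TSV
#'
#' Round-trippable plain-text representation (pairs as rows, iterations as
#' columns, 0/1 entries). On import the matrix is validated: binary
#' entries, unique columns, observed (all-zero) column first.
#'
#' @param assignments An `assignment_matrix`.
#' @param path File path.
#' @param design A `matched_design` to re-attach on import.
#' @return `import_assignment_matrix` returns an `assignment_matrix`.
#' @export
export_assignment_matrix <- function(assignments, path) {
  write.table(unclass(assignments), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname export_assignment_matrix
#' @export
import_assignment_matrix <- function(path, design) {
  M <- as.matrix(read.delim(path, header = FALSE))
  dimnames(M) <- NULL
  if (!all(M %in% 0:1)) stop("assignment matrix entries must be 0/1")
  storage.mode(M) <- "integer"
  keys <- apply(M, 2, paste, collapse = "")
  if (anyDuplicated(keys)) stop("duplicate assignment columns")
  if (any(M[, 1] != 0L))
    stop("column 1 must be the observed (all-zero) assignment")
  if (nrow(M) != design$n_pairs)
    stop("row count does not match the design's number of pairs")
  exhaustive <- nrow(M) <= 30 && ncol(M) == 2^nrow(M)
  structure(M, exhaustive = exhaustive, seed = NA_integer_, design = design,
            class = c("assignment_matrix", "matrix"))
}
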