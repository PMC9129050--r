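#' Sparse partial-correlation network via the graphical lasso
#'
#' Estimates a penalized inverse covariance of the CLR abundances
#' (blockwise coordinate descent) and reports edges where the precision
#' entry exceeds numerical zero, weighted by partial correlations
#' `rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)`.
#'
#' @param L CLR matrix (samples x taxa).
#' @param lambda Penalty `> 0`.
#' @param tol,maxit Convergence tolerance and outer-iteration cap of the
#'   solver.
#' @return Object of class `association_network`: `nodes`, `edges`
#'   (data.frame taxon_i, taxon_j, rho), `pcor` and `precision` matrices,
#'   `lambda`.
#' @export
graphical_lasso_network <- function(L, lambda, tol = 1e-4, maxit = 200) {
  stopifnot(lambda > 0, nrow(L) >= 3)
  # standardize to the correlation matrix (the convention of sparse
  # microbiome network estimation); partial correlations are invariant
  S <- stats::cor(unclass(L))
  fit <- .glasso_cpp(S, lambda, tol, maxit)
  if (!fit$converged)
    stop("graphical lasso did not converge at lambda = ", lambda)
  theta <- fit$theta
  d <- sqrt(diag(theta))
  pcor <- -theta / tcrossprod(d)
  diag(pcor) <- 0
  nodes <- colnames(L)
  dimnames(pcor) <- dimnames(theta) <- list(nodes, nodes)
  idx <- which(upper.tri(theta) & abs(theta) > 1e-8, arr.ind = TRUE)
  edges <- data.frame(taxon_i = nodes[idx[, 1]], taxon_j = nodes[idx[, 2]],
                      rho = pcor[idx], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, pcor = pcor,
                 precision = theta, lambda = lambda),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat("Association network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (lambda =", format(x$lambda, digits = 4), ")\n")
  invisible(x)
}

#' Default penalty path for network estimation
#'
#' 30 log-spaced values spanning `[0.01, 1]` times the largest absolute
#' off-diagonal correlation of the data (the smallest penalty that forces
#' an empty graph under correlation-input glasso).
#'
#' @param L CLR matrix.
#' @param n_lambda Path length.
#' @return Decreasing numeric vector.
#' @export
lambda_path <- function(L, n_lambda = 30) {
  R <- stats::cor(unclass(L))
  mx <- max(abs(R[upper.tri(R)]))
  exp(seq(log(mx), log(0.01 * mx), length.out = n_lambda))
}

#' StARS regularization selection
#'
#' Stability Approach to Regularization Selection: for each penalty on a
#' decreasing path, edge-selection frequencies are estimated over random
#' subsamples; total instability is the mean over node pairs of
#' `2 * theta * (1 - theta)`. After monotonizing from the sparse end, the
#' smallest penalty whose instability stays at or below the threshold is
#' selected (the densest stable model).
#'
#' @param L CLR matrix.
#' @param path Decreasing penalty path (default [lambda_path()]).
#' @param n_subsamples Number of subsamples (>= 20; default 50).
#' @param subsample_fraction Subsample size fraction; default 0.8 for
#'   `n < 144`, else `10 * sqrt(n) / n`.
#' @param instability_threshold Default 0.05.
#' @param seed Integer seed for the subsampling.
#' @return Selected penalty, with attributes `instability` (per-path) and
#'   `path`.
#' @export
stars_select <- function(L, path = NULL, n_subsamples = 50,
                         subsample_fraction = NULL,
                         instability_threshold = 0.05, seed = 1L) {
  stopifnot(n_subsamples >= 20)
  L <- unclass(L)
  n <- nrow(L); p <- ncol(L)
  if (is.null(path)) path <- lambda_path(L)
  path <- sort(path, decreasing = TRUE)
  if (is.null(subsample_fraction))
    subsample_fraction <- if (n < 144) 0.8 else 10 * sqrt(n) / n
  b <- max(4, floor(subsample_fraction * n))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  up <- upper.tri(matrix(0, p, p))
  freq <- matrix(0, length(path), sum(up))
  for (s in seq_len(n_subsamples)) {
    rows <- sample.int(n, b)
    S <- stats::cor(L[rows, , drop = FALSE])
    for (k in seq_along(path)) {
      fit <- .glasso_cpp(S, path[k], 1e-4, 200)
      freq[k, ] <- freq[k, ] + (abs(fit$theta[up]) > 1e-8)
    }
  }
  theta_hat <- freq / n_subsamples
  D <- rowMeans(2 * theta_hat * (1 - theta_hat))
  Dbar <- cummax(D)  # path is decreasing: monotonize from the sparse end
  ok <- Dbar <= instability_threshold
  if (!any(ok)) {
    warning("no penalty met the instability threshold; returning the ",
            "largest penalty")
    lam <- path[1]
  } else lam <- path[max(which(ok))]
  structure(lam, instability = D, path = path)
}

#' Fisher-z differential association statistic
#'
#' `|atanh(rho_E) - atanh(rho_C)|` for one taxon pair; an absent edge
#' contributes `rho = 0`. Symmetric in the arms.
#'
#' @param net_e,net_c `association_network` objects over identical node
#'   sets.
#' @param pair Character vector of two taxon ids (or 2-column matrix for
#'   several pairs).
#' @return Numeric statistic(s).
#' @export
differential_association_statistic <- function(net_e, net_c, pair) {
  if (!identical(net_e$nodes, net_c$nodes))
    stop("networks must share an identical node set")
  pair <- matrix(pair, ncol = 2)
  re <- net_e$pcor[pair]; rc <- net_c$pcor[pair]
  if (any(abs(c(re, rc)) >= 1))
    stop("|rho| = 1 encountered; Fisher z undefined")
  abs(atanh(re) - atanh(rc))
}

# Partial-correlation matrix of a row subset at a fixed penalty.
fit_pcor <- function(L, rows, lambda) {
  S <- stats::cor(L[rows, , drop = FALSE])
  theta <- .glasso_cpp(S, lambda, 1e-4, 200)$theta
  d <- sqrt(diag(theta))
  pc <- -theta / tcrossprod(d)
  diag(pc) <- 0
  pc <- pc * (abs(theta) > 1e-8)
  dimnames(pc) <- list(colnames(L), colnames(L))
  pc
}

#' Differential-edge permutation test preserving the matched-pair design
#'
#' Fits one association network per observed arm (penalty selected by
#' StARS on the pooled data and held fixed across permutations, unless
#' `lambda_mode = "reselect"`), takes as hypothesis universe the taxon
#' pairs with an edge in at least one observed arm (or all pairs), and for
#' every within-pair permutation of the intervention labels refits both
#' networks and recomputes the Fisher-z differential statistic per pair.
#' Two-sided p-values are jointly adjusted with [minp_adjust()].
#'
#' @param counts Samples x taxa count matrix.
#' @param assignments An `assignment_matrix`.
#' @param lambda Penalty; `NULL` selects it by StARS on the pooled CLR.
#' @param lambda_mode `"fixed"` (default) or `"reselect"` (StARS per
#'   permutation and arm; much slower).
#' @param universe `"observed_edges"` (default) or `"all_pairs"`.
#' @param pseudocount For the CLR.
#' @param stars_args List of extra arguments for [stars_select()].
#' @return Data.frame of class `differential_edges`: one row per tested
#'   pair with observed per-arm partial correlations, statistic, p,
#'   p_adjusted, and a disappearance flag (edge present in exactly one
#'   arm). Networks and lambda attached as attributes.
#' @export
network_permutation_test <- function(counts, assignments, lambda = NULL,
                                     lambda_mode = c("fixed", "reselect"),
                                     universe = c("observed_edges",
                                                  "all_pairs"),
                                     pseudocount = 1,
                                     stars_args = list()) {
  lambda_mode <- match.arg(lambda_mode)
  universe <- match.arg(universe)
  E <- assignment_exposures(assignments)
  ids <- rownames(E)
  L <- unclass(clr_transform(counts[ids, , drop = FALSE], pseudocount))
  p <- ncol(L)
  if (is.null(lambda))
    lambda <- as.numeric(do.call(stars_select, c(list(L), stars_args)))
  sel_lambda <- function(rows)
    as.numeric(do.call(stars_select,
                       c(list(L[rows, , drop = FALSE]), stars_args)))
  net_e <- graphical_lasso_network(L[E[, 1] == 1, , drop = FALSE],
    if (lambda_mode == "fixed") lambda else sel_lambda(which(E[, 1] == 1)))
  net_c <- graphical_lasso_network(L[E[, 1] == 0, , drop = FALSE],
    if (lambda_mode == "fixed") lambda else sel_lambda(which(E[, 1] == 0)))
  pairs <- if (universe == "all_pairs") {
    t(combn(colnames(L), 2))
  } else {
    u <- unique(rbind(as.matrix(net_e$edges[, 1:2]),
                      as.matrix(net_c$edges[, 1:2])))
    if (nrow(u) == 0) stop("no edges in either observed network")
    u
  }
  nh <- nrow(pairs)
  Lcols <- ncol(E)
  stats <- matrix(NA_real_, nh, Lcols)
  stats[, 1] <- differential_association_statistic(net_e, net_c, pairs)
  for (l in seq_len(Lcols)[-1]) {
    rows_e <- which(E[, l] == 1); rows_c <- which(E[, l] == 0)
    le <- if (lambda_mode == "fixed") lambda else sel_lambda(rows_e)
    lc <- if (lambda_mode == "fixed") lambda else sel_lambda(rows_c)
    pe <- fit_pcor(L, rows_e, le)
    pc <- fit_pcor(L, rows_c, lc)
    stats[, l] <- abs(atanh(pe[pairs]) - atanh(pc[pairs]))
  }
  # the statistic is an absolute difference, so the two-sided test is the
  # right-tail test on |T|
  adj <- minp_adjust(stats, sidedness = "greater")
  present_e <- abs(net_e$pcor[pairs]) > 0
  present_c <- abs(net_c$pcor[pairs]) > 0
  out <- data.frame(taxon_i = pairs[, 1], taxon_j = pairs[, 2],
                    rho_exposed = net_e$pcor[pairs],
                    rho_control = net_c$pcor[pairs],
                    statistic = stats[, 1],
                    p = adj$unadjusted, p_adjusted = adj$adjusted,
                    disappearance = xor(present_e, present_c),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adjusted, out$p), ]
  rownames(out) <- NULL
  attr(out, "network_exposed") <- net_e
  attr(out, "network_control") <- net_c
  attr(out, "lambda") <- lambda
  class(out) <- c("differential_edges", "data.frame")
  out
}

#' Connected components of an association network
#'
#' @param net An `association_network`.
#' @return List of components (character vectors of node ids), sorted by
#'   decreasing size; singleton nodes included.
#' @export
connected_components <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$nodes)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members[order(-vapply(members, length, integer(1)))]
}
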