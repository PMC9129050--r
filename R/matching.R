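#' Covariate proximity thresholds for constrained pair matching
#'
#' A treated unit may be matched to a control only when every continuous
#' covariate differs by strictly less than its threshold and every
#' categorical covariate is identical (threshold 0, "no male and female
#' could be matched"). Boundary differences exactly equal to the threshold
#' are inadmissible.
#'
#' @param continuous Named numeric vector of per-covariate maximum absolute
#'   differences, in the covariate's own units (e.g. `c(age = 5, bmi = 4,
#'   alcohol = 25)`).
#' @param categorical Character vector of covariate names requiring exact
#'   equality.
#' @return An object of class `matching_thresholds`.
#' @export
matching_thresholds <- function(continuous = numeric(), categorical = character()) {
  stopifnot(all(continuous >= 0))
  if (length(continuous) && is.null(names(continuous)))
    stop("continuous thresholds must be named")
  structure(list(continuous = continuous, categorical = categorical),
            class = "matching_thresholds")
}

#' Default thresholds mirroring a smoking-style exposure design
#' @return A [matching_thresholds()] with alcohol 25 g/day, BMI 4 kg/m^2,
#'   age 5 years, and exact matching on sex, diabetes and activity.
#' @export
default_thresholds <- function() {
  matching_thresholds(continuous = c(alcohol = 25, bmi = 4, age = 5),
                      categorical = c("diabetes", "sex", "activity"))
}

#' Constrained covariate distance between two units
#'
#' Returns 0 when the pair satisfies every proximity constraint and `Inf`
#' otherwise. A missing value on any thresholded covariate makes the pair
#' inadmissible (with a warning): unconfoundedness rests on verified
#' proximity.
#'
#' @param x_i,x_j Named vectors (or 1-row data.frames) of covariates.
#' @param thr A [matching_thresholds()].
#' @return 0 or `Inf`.
#' @export
pair_admissible <- function(x_i, x_j, thr) {
  x_i <- as.list(x_i); x_j <- as.list(x_j)
  vars <- c(names(thr$continuous), thr$categorical)
  for (v in vars) {
    a <- x_i[[v]]; b <- x_j[[v]]
    if (is.null(a) || is.null(b))
      stop("covariate '", v, "' missing from unit vector")
    if (is.na(a) || is.na(b)) {
      warning("missing value on covariate '", v, "': pair inadmissible")
      return(Inf)
    }
  }
  for (v in names(thr$continuous))
    if (abs(as.numeric(x_i[[v]]) - as.numeric(x_j[[v]])) >= thr$continuous[[v]])
      return(Inf)
  for (v in thr$categorical)
    if (x_i[[v]] != x_j[[v]]) return(Inf)
  0
}

#' Admissible-pair bipartite graph
#'
#' One node per unit, partitioned by exposure; an edge joins exposed unit i
#' and control unit j iff their constrained distance is 0.
#'
#' @param cohort Data.frame with `unit_id`, covariates and binary
#'   `exposure` (or a `micrand_cohort`).
#' @param thr A [matching_thresholds()].
#' @return Data.frame with columns `exposed_id`, `control_id` (possibly 0
#'   rows), with attributes `exposed_ids` and `control_ids`.
#' @export
build_match_graph <- function(cohort, thr) {
  tab <- if (inherits(cohort, "micrand_cohort")) cohort$cohort else cohort
  stopifnot(all(tab$exposure %in% 0:1))
  ei <- which(tab$exposure == 1); ci <- which(tab$exposure == 0)
  if (!length(ei) || !length(ci))
    stop("need at least one exposed and one control unit")
  ok <- matrix(TRUE, length(ei), length(ci))
  for (v in names(thr$continuous)) {
    x <- as.numeric(tab[[v]])
    d <- abs(outer(x[ei], x[ci], `-`))
    d[is.na(d)] <- Inf
    ok <- ok & (d < thr$continuous[[v]])
  }
  for (v in thr$categorical) {
    x <- tab[[v]]
    eq <- outer(x[ei], x[ci], `==`)
    eq[is.na(eq)] <- FALSE
    ok <- ok & eq
  }
  idx <- which(ok, arr.ind = TRUE)
  edges <- data.frame(exposed_id = tab$unit_id[ei][idx[, 1]],
                      control_id = tab$unit_id[ci][idx[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$exposed_id, tab$unit_id[ei]),
                       match(edges$control_id, tab$unit_id[ci])), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "exposed_ids") <- tab$unit_id[ei]
  attr(edges, "control_ids") <- tab$unit_id[ci]
  edges
}

new_matched_design <- function(pairs, provenance = "unspecified") {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "exposed_id", "control_id") %in% names(pairs)))
  ids <- c(pairs$exposed_id, pairs$control_id)
  if (anyDuplicated(ids)) stop("a unit appears in more than one pair")
  structure(list(pairs = pairs, n_pairs = nrow(pairs),
                 N_E = nrow(pairs), N_C = nrow(pairs),
                 provenance = provenance),
            class = "matched_design")
}

#' @export
print.matched_design <- function(x, ...) {
  cat("Matched design:", x$n_pairs, "pairs (N_E = N_C =", x$n_pairs, ")\n")
  cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' Maximum-cardinality bipartite matching
#'
#' Extracts the largest set of matched pairs from an admissible-pair graph.
#' Cardinality only is optimized (no secondary distance minimization); the
#' result is deterministic given input ordering.
#'
#' @param edges Edge list from [build_match_graph()] (columns `exposed_id`,
#'   `control_id`).
#' @return A `matched_design` with ordered pairs.
#' @export
maximum_matching <- function(edges) {
  if (nrow(edges) == 0)
    return(new_matched_design(
      data.frame(pair_id = integer(), exposed_id = character(),
                 control_id = character(), stringsAsFactors = FALSE),
      provenance = "threshold matching"))
  enodes <- unique(edges$exposed_id)
  cnodes <- unique(edges$control_id)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(
                                       name = c(enodes, cnodes),
                                       type = rep(c(TRUE, FALSE),
                                                  c(length(enodes),
                                                    length(cnodes)))))
  m <- igraph::max_bipartite_match(g)$matching
  matched_e <- enodes[!is.na(m[enodes])]
  pairs <- data.frame(pair_id = seq_along(matched_e),
                      exposed_id = matched_e,
                      control_id = unname(m[matched_e]),
                      stringsAsFactors = FALSE)
  new_matched_design(pairs, provenance = "threshold matching")
}

#' Match exposed to control units under covariate proximity constraints
#'
#' Convenience wrapper: [build_match_graph()] then [maximum_matching()].
#'
#' @inheritParams build_match_graph
#' @return A `matched_design`.
#' @export
match_pairs <- function(cohort, thr = default_thresholds()) {
  maximum_matching(build_match_graph(cohort, thr))
}

#' Covariate balance diagnostics
#'
#' Standardized mean differences (exposed minus control over pooled SD) for
#' continuous covariates and proportion differences for categorical ones,
#' before matching (full cohort) or after (restricted to the design's
#' units). |SMD| > 0.1 is flagged.
#'
#' @param cohort Data.frame (or `micrand_cohort`) with `unit_id`,
#'   covariates and `exposure`.
#' @param design Optional `matched_design`; when supplied, diagnostics are
#'   computed on matched units only.
#' @param covariates Covariate names; defaults to everything except
#'   `unit_id` and `exposure`.
#' @return Data.frame: covariate, kind, mean/proportion per arm, smd, flag.
#' @export
balance_diagnostics <- function(cohort, design = NULL, covariates = NULL) {
  tab <- if (inherits(cohort, "micrand_cohort")) cohort$cohort else cohort
  if (!is.null(design)) {
    if (design$n_pairs == 0) stop("design has no pairs")
    tab <- tab[tab$unit_id %in% c(design$pairs$exposed_id,
                                  design$pairs$control_id), , drop = FALSE]
  }
  if (is.null(covariates))
    covariates <- setdiff(names(tab), c("unit_id", "exposure"))
  e <- tab$exposure == 1
  rows <- lapply(covariates, function(v) {
    x <- tab[[v]]
    continuous <- is.numeric(x) && length(unique(x[!is.na(x)])) > 2
    if (continuous) {
      m1 <- mean(x[e], na.rm = TRUE); m0 <- mean(x[!e], na.rm = TRUE)
      s1 <- var(x[e], na.rm = TRUE); s0 <- var(x[!e], na.rm = TRUE)
      pooled <- sqrt((s1 + s0) / 2)
      smd <- if (pooled == 0) {
        if (isTRUE(all.equal(m1, m0))) 0 else Inf
      } else (m1 - m0) / pooled
      data.frame(covariate = v, kind = "continuous", mean_exposed = m1,
                 mean_control = m0, smd = smd,
                 flag = abs(smd) > 0.1, stringsAsFactors = FALSE)
    } else {
      lev <- sort(unique(as.character(x)))
      pd <- vapply(lev, function(l)
        mean(x[e] == l, na.rm = TRUE) - mean(x[!e] == l, na.rm = TRUE),
        numeric(1))
      worst <- which.max(abs(pd))
      data.frame(covariate = v, kind = "categorical",
                 mean_exposed = mean(as.character(x[e]) == lev[worst],
                                     na.rm = TRUE),
                 mean_control = mean(as.character(x[!e]) == lev[worst],
                                     na.rm = TRUE),
                 smd = pd[worst], flag = abs(pd[worst]) > 0.1,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Greedy propensity-score matching (sensitivity design)
#'
#' Logistic propensity model on the declared covariates; greedy 1:1
#' nearest-neighbor matching on the linear predictor without replacement,
#' within a caliper expressed in standard deviations of the score. Exposed
#' units are processed in random order under the given seed.
#'
#' @inheritParams balance_diagnostics
#' @param caliper Caliper width in SDs of the linear predictor
#'   (default 0.2, the common convention).
#' @param seed Seed controlling the processing order of exposed units.
#' @return A `matched_design`.
#' @export
propensity_match <- function(cohort, covariates = NULL, caliper = 0.2,
                             seed = 1L) {
  tab <- if (inherits(cohort, "micrand_cohort")) cohort$cohort else cohort
  if (is.null(covariates))
    covariates <- setdiff(names(tab), c("unit_id", "exposure"))
  if (min(table(tab$exposure)) < length(covariates) + 2)
    stop("too few units per arm to fit the propensity model")
  f <- stats::as.formula(paste("exposure ~",
                               paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(f, data = tab, family = binomial()))
  lp <- stats::predict(fit, type = "link")
  if (any(abs(lp) > 20) || !fit$converged)
    stop("separation in the propensity model; consider threshold matching")
  width <- caliper * sd(lp)
  ei <- which(tab$exposure == 1); ci <- which(tab$exposure == 0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  order_e <- sample(ei)
  avail <- rep(TRUE, length(ci))
  me <- character(0); mc <- character(0)
  for (i in order_e) {
    d <- abs(lp[ci] - lp[i])
    d[!avail] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= width) {
      avail[j] <- FALSE
      me <- c(me, tab$unit_id[i]); mc <- c(mc, tab$unit_id[ci[j]])
    }
  }
  ord <- order(match(me, tab$unit_id))
  new_matched_design(data.frame(pair_id = seq_along(me),
                                exposed_id = me[ord], control_id = mc[ord],
                                stringsAsFactors = FALSE),
                     provenance = sprintf("propensity (caliper %.2f SD)",
                                          caliper))
}
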