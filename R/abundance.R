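#' Compositional mean-equivalence statistic
#'
#' `T_M = N_E N_C / (N_E + N_C) * max_a (Lbar_Ea - Lbar_Ca)^2 / gamma_aa`
#' over taxa `a`, where `Lbar` are arm means of the centered log-ratios and
#' `gamma_aa` the pooled-sample CLR variances. Scale invariant (inherited
#' from the CLR); sensitive to a sparse set of shifted taxa through the
#' max.
#'
#' @param L CLR matrix (samples x taxa), e.g. from [clr_transform()].
#' @param w Binary exposure vector aligned with rows of `L`.
#' @return Scalar statistic with attribute `argmax_taxon`.
#' @export
tm_statistic <- function(L, w) {
  w <- as.numeric(w)
  stopifnot(length(w) == nrow(L), all(w %in% 0:1))
  nE <- sum(w); nC <- sum(1 - w)
  if (nE == 0 || nC == 0) stop("both arms must be nonempty")
  LE <- L[w == 1, , drop = FALSE]; LC <- L[w == 0, , drop = FALSE]
  dbar <- colMeans(LE) - colMeans(LC)
  vE <- apply(LE, 2, var); vC <- apply(LC, 2, var)
  gamma <- ((nE - 1) * vE + (nC - 1) * vC) / (nE + nC - 2)
  bad <- gamma <= 0
  if (any(bad & abs(dbar) > 1e-12))
    stop("zero pooled variance with nonzero mean difference: statistic undefined")
  if (any(bad)) {
    warning("dropping ", sum(bad), " degenerate taxa with zero pooled variance")
    dbar <- dbar[!bad]; gamma <- gamma[!bad]
  }
  ratio <- dbar^2 / gamma
  structure(nE * nC / (nE + nC) * max(ratio),
            argmax_taxon = colnames(L)[!bad][which.max(ratio)])
}

# T_M for every assignment column at once (matrix algebra fast path).
tm_statistic_cols <- function(L, Ecols) {
  n <- nrow(L); L2 <- L^2
  nE <- colSums(Ecols); nC <- n - nE
  ME <- crossprod(L, Ecols)                      # taxa x cols: sums exposed
  MA <- matrix(colSums(L), ncol(L), ncol(Ecols)) # total sums
  SE2 <- crossprod(L2, Ecols)
  SA2 <- matrix(colSums(L2), ncol(L), ncol(Ecols))
  mE <- sweep(ME, 2, nE, `/`)
  mC <- sweep(MA - ME, 2, nC, `/`)
  vE <- sweep(SE2 - sweep(mE^2, 2, nE, `*`), 2, pmax(nE - 1, 1), `/`)
  vC <- sweep(SA2 - SE2 - sweep(mC^2, 2, nC, `*`), 2, pmax(nC - 1, 1), `/`)
  gamma <- sweep(sweep(vE, 2, nE - 1, `*`) + sweep(vC, 2, nC - 1, `*`),
                 2, nE + nC - 2, `/`)
  ratio <- (mE - mC)^2 / gamma
  ratio[gamma <= 0] <- 0
  nE * nC / (nE + nC) * apply(ratio, 2, max)
}

#' Randomization test of compositional mean equivalence across ranks
#'
#' Per requested taxonomic rank: aggregate counts, CLR-transform, and
#' recompute the max-type mean statistic under every assignment. One-sided
#' p-values per rank (ranks are reported unadjusted, each rank its own
#' test).
#'
#' @param counts Samples x taxa count matrix.
#' @param taxonomy Taxonomy table (see [aggregate_rank()]).
#' @param assignments An `assignment_matrix`.
#' @param ranks Character vector of ranks (`"ASV"` = no aggregation).
#' @param pseudocount For the CLR.
#' @return Data.frame with rank, number of taxa, observed statistic and
#'   p-value; the per-rank `micrand_test` objects as attribute `tests`.
#' @export
compositional_mean_test <- function(counts, taxonomy, assignments,
                                    ranks = c("Genus", "Family", "Phylum"),
                                    pseudocount = 1) {
  E <- assignment_exposures(assignments)
  ids <- rownames(E)
  tests <- list()
  rows <- lapply(ranks, function(rk) {
    Crk <- aggregate_rank(counts[ids, , drop = FALSE], taxonomy, rk)
    L <- unclass(clr_transform(Crk, pseudocount))
    stats_l <- tm_statistic_cols(L, E)
    tst <- new_micrand_test(stats_l, "greater", assignments,
                            label = paste0("T_M @ ", rk))
    tests[[rk]] <<- tst
    data.frame(rank = rk, n_taxa = ncol(Crk), statistic = tst$observed,
               p = tst$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tests") <- tests
  out
}

#' Reference taxon selection for ratio normalization
#'
#' A taxon's dispersion score is the median, over all other taxa, of the
#' standard deviation across samples of the pairwise log-ratios
#' `log((C_a + pc) / (C_a' + pc))`. Taxa with score below
#' `dispersion_threshold` and prevalence above `prevalence_threshold`
#' form the reference set (presumed non-differential). If some sample has a
#' zero reference sum, the set is relaxed by admitting the
#' next-lowest-dispersion taxa (among those above half the prevalence
#' threshold) until every sample is covered; any relaxation is messaged.
#'
#' Defaults follow the genus-level convention (score < 2, prevalence >
#' 90%); `asv_mode = TRUE` switches to the ASV-level convention (< 3,
#' > 40%).
#'
#' @param counts Samples x taxa count matrix.
#' @param dispersion_threshold Upper bound on the dispersion score.
#' @param prevalence_threshold Lower bound on the fraction of samples with
#'   a positive count.
#' @param pseudocount Pseudocount inside the log-ratios.
#' @param asv_mode Use the ASV-level thresholds (3, 0.4).
#' @return Object of class `reference_set`: `taxa`, `scores`,
#'   `prevalence`, `thresholds`, `relaxed`.
#' @export
select_references <- function(counts, dispersion_threshold = 2,
                              prevalence_threshold = 0.9,
                              pseudocount = 1, asv_mode = FALSE) {
  stopifnot(dispersion_threshold > 0, prevalence_threshold > 0)
  if (asv_mode) {
    dispersion_threshold <- 3
    prevalence_threshold <- 0.4
  }
  counts <- as.matrix(counts)
  A <- ncol(counts)
  M <- log(counts + pseudocount)
  V <- stats::cov(M)
  dv <- diag(V)
  sd_lr <- sqrt(pmax(outer(dv, dv, `+`) - 2 * V, 0))
  diag(sd_lr) <- NA
  scores <- apply(sd_lr, 1, median, na.rm = TRUE)
  prevalence <- colMeans(counts > 0)
  names(scores) <- names(prevalence) <- colnames(counts)
  in_ref <- scores < dispersion_threshold & prevalence > prevalence_threshold
  relaxed <- character(0)
  cover_ok <- function(sel) length(sel) > 0 &&
    all(rowSums(counts[, sel, drop = FALSE]) > 0)
  if (!cover_ok(which(in_ref))) {
    candidates <- order(scores)
    candidates <- candidates[prevalence[candidates] >
                               prevalence_threshold / 2]
    for (a in candidates) {
      if (in_ref[a]) next
      in_ref[a] <- TRUE
      relaxed <- c(relaxed, colnames(counts)[a])
      if (cover_ok(which(in_ref))) break
    }
    if (!cover_ok(which(in_ref)))
      stop("no admissible reference set: some sample has zero reference sum")
    message("reference set relaxed with ", length(relaxed),
            " additional taxa to cover all samples")
  }
  structure(list(taxa = colnames(counts)[in_ref], scores = scores,
                 prevalence = prevalence,
                 thresholds = c(dispersion = dispersion_threshold,
                                prevalence = prevalence_threshold),
                 relaxed = relaxed),
            class = "reference_set")
}

#' Ratio normalization of one taxon against the reference set
#'
#' `v_i = C_ia / (C_ia + sum_f C_i r_f)`, in `[0, 1]`, 0 when the taxon is
#' absent; monotone in `C_ia` for a fixed reference sum.
#'
#' @param counts Samples x taxa count matrix.
#' @param taxon Taxon id (must not be in the reference set).
#' @param refs A `reference_set` (or character vector of reference ids).
#' @return Numeric vector of per-sample normalized values.
#' @export
normalize_by_ratio <- function(counts, taxon, refs) {
  ref_taxa <- if (inherits(refs, "reference_set")) refs$taxa else refs
  if (taxon %in% ref_taxa) stop("taxon '", taxon, "' is in the reference set")
  ref_sum <- rowSums(counts[, ref_taxa, drop = FALSE])
  ca <- counts[, taxon]
  denom <- ca + ref_sum
  if (any(denom == 0))
    stop("zero denominator: reference set does not cover all samples")
  ca / denom
}

#' Log-fold difference of arm means of normalized abundances
#'
#' `mean(log(v + eps) | exposed) - mean(log(v + eps) | control)`.
#'
#' @param v Normalized values from [normalize_by_ratio()].
#' @param w Binary exposure vector.
#' @param eps Positive offset inside the log (default
#'   `1 / (2 * max depth)` chosen data-adaptively by the caller).
#' @return Scalar log-fold statistic.
#' @export
logfold_statistic <- function(v, w, eps) {
  stopifnot(eps > 0)
  lv <- log(v + eps)
  mean(lv[w == 1]) - mean(lv[w == 0])
}

#' Per-taxon differential abundance with randomization min-p adjustment
#'
#' Every non-reference taxon is ratio-normalized against the reference set
#' and its log-fold statistic recomputed under each assignment column;
#' two-sided p-values are jointly adjusted by [minp_adjust()], all taxa
#' sharing the one assignment matrix.
#'
#' @param counts Samples x taxa count matrix.
#' @param assignments An `assignment_matrix`.
#' @param refs A `reference_set` from [select_references()].
#' @param eps Offset for the log; default `1 / (2 * max(rowSums(counts)))`.
#' @return Data.frame (one row per tested taxon): statistic, sign, p,
#'   p_adjusted; the `eps` used and the reference set as attributes.
#' @export
differential_abundance_test <- function(counts, assignments, refs,
                                        eps = NULL) {
  E <- assignment_exposures(assignments)
  ids <- rownames(E)
  C <- as.matrix(counts[ids, , drop = FALSE])
  if (is.null(eps)) eps <- 1 / (2 * max(rowSums(C)))
  ref_taxa <- refs$taxa
  test_taxa <- setdiff(colnames(C), ref_taxa)
  if (!length(test_taxa)) stop("no non-reference taxa to test")
  ref_sum <- rowSums(C[, ref_taxa, drop = FALSE])
  V <- C[, test_taxa, drop = FALSE] /
    (C[, test_taxa, drop = FALSE] + ref_sum)
  LV <- log(V + eps)
  nE <- colSums(E); nC <- nrow(E) - nE
  contrast <- sweep(E, 2, nE, `/`) - sweep(1 - E, 2, nC, `/`)
  stats <- crossprod(LV, contrast)  # taxa x L
  rownames(stats) <- test_taxa
  adj <- minp_adjust(stats, sidedness = "two.sided")
  out <- data.frame(taxon = test_taxa,
                    statistic = stats[, 1],
                    sign = sign(stats[, 1]),
                    p = adj$unadjusted,
                    p_adjusted = adj$adjusted,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "eps") <- eps
  attr(out, "reference_set") <- refs
  attr(out, "stats") <- stats
  out
}
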