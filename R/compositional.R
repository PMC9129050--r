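#' Centered log-ratio transform of a count matrix
#'
#' `L_ia = log((C_ia + pc) / g(C_i + pc))` with `g` the row geometric mean.
#' Rows sum to zero; the transform is invariant to per-sample count scaling
#' when `pseudocount = 0`.
#'
#' @param counts Samples x taxa matrix of non-negative counts.
#' @param pseudocount Added to every cell before taking logs; must be
#'   positive when zeros are present (default 1, the convention of sparse
#'   network estimation frameworks; 0.5 is a common alternative).
#' @return Matrix of class `clr_matrix` with attribute `pseudocount`.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0)) stop("all-zero sample row(s)")
  if (any(counts == 0) && pseudocount <= 0)
    stop("pseudocount must be > 0 when zeros are present")
  lc <- log(counts + pseudocount)
  L <- lc - rowMeans(lc)
  structure(L, pseudocount = pseudocount,
            class = c("clr_matrix", "matrix"))
}

#' Aggregate a count matrix to a taxonomic rank
#'
#' Cells are summed over taxa sharing the rank label; per-sample totals are
#' conserved exactly. Taxa with an unassigned (`NA`) label are pooled per
#' parent lineage (the next higher assigned rank).
#'
#' @param counts Samples x taxa count matrix, column names = taxon ids.
#' @param taxonomy Data.frame with `taxon_id` and rank columns
#'   (Phylum...Species).
#' @param rank Rank column name, or `"ASV"` for the identity.
#' @return Aggregated count matrix (samples x rank labels).
#' @export
aggregate_rank <- function(counts, taxonomy, rank) {
  counts <- as.matrix(counts)
  if (identical(rank, "ASV") || identical(rank, "taxon_id")) return(counts)
  if (!rank %in% names(taxonomy)) stop("rank '", rank, "' not in taxonomy")
  missing_tax <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(missing_tax))
    stop("taxa missing from taxonomy: ", paste(missing_tax, collapse = ", "))
  lab <- taxonomy[[rank]][match(colnames(counts), taxonomy$taxon_id)]
  ranks <- intersect(c("Phylum", "Class", "Order", "Family", "Genus",
                       "Species"), names(taxonomy))
  pos <- match(rank, ranks)
  if (any(is.na(lab)) && pos > 1) {
    for (i in which(is.na(lab))) {
      for (r in rev(ranks[seq_len(pos - 1)])) {
        parent <- taxonomy[[r]][match(colnames(counts)[i],
                                      taxonomy$taxon_id)]
        if (!is.na(parent)) {
          lab[i] <- paste0("unassigned_", parent)
          break
        }
      }
    }
  }
  lab[is.na(lab)] <- "unassigned"
  agg <- t(rowsum(t(counts), group = lab))
  agg[, order(colnames(agg)), drop = FALSE]
}

#' Filter taxa by prevalence
#'
#' Keeps taxa with a positive count in at least `min_prevalence` of the
#' samples (e.g. 0.05 for the common "present in at least 5% of samples"
#' rule).
#'
#' @param counts Samples x taxa count matrix.
#' @param min_prevalence Fraction in `[0, 1]`.
#' @return Filtered count matrix.
#' @export
prevalence_filter <- function(counts, min_prevalence) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  counts <- as.matrix(counts)
  keep <- colMeans(counts > 0) >= min_prevalence
  if (!any(keep)) stop("prevalence filter removed every taxon")
  counts[, keep, drop = FALSE]
}

#' Pairwise beta-diversity distances
#'
#' Four metrics: `"aitchison"` (Euclidean distance between CLR rows),
#' `"jaccard"` (1 - intersection/union of presence sets),
#' `"gower_clr"` (Gower's range-normalized mean absolute difference on CLR
#' columns) and `"unifrac_unweighted"` (branch length unique to either
#' sample's tip set over total spanned branch length; presence only).
#'
#' @param counts Samples x taxa count matrix (column names must match tree
#'   tips for UniFrac).
#' @param metric One of the four metric names.
#' @param tree Rooted `phylo` tree, required for UniFrac.
#' @param pseudocount Passed to [clr_transform()] for CLR-based metrics.
#' @return Symmetric distance matrix with zero diagonal, attribute
#'   `metric`.
#' @export
beta_distance <- function(counts,
                          metric = c("aitchison", "jaccard", "gower_clr",
                                     "unifrac_unweighted"),
                          tree = NULL, pseudocount = 1) {
  metric <- match.arg(metric)
  counts <- as.matrix(counts)
  n <- nrow(counts)
  D <- switch(metric,
    aitchison = {
      L <- clr_transform(counts, pseudocount)
      as.matrix(stats::dist(L))
    },
    jaccard = {
      Pres <- counts > 0
      inter <- tcrossprod(Pres * 1)
      sizes <- rowSums(Pres)
      uni <- outer(sizes, sizes, `+`) - inter
      d <- 1 - inter / uni
      d[uni == 0] <- 0
      d
    },
    gower_clr = {
      L <- clr_transform(counts, pseudocount)
      rng <- apply(L, 2, function(x) diff(range(x)))
      use <- rng > 0
      d <- matrix(0, n, n)
      for (a in which(use))
        d <- d + abs(outer(L[, a], L[, a], `-`)) / rng[a]
      d / max(sum(use), 1)
    },
    unifrac_unweighted = {
      if (is.null(tree)) stop("unweighted UniFrac requires a tree")
      unifrac_unweighted(counts, tree)
    })
  diag(D) <- 0
  dimnames(D) <- list(rownames(counts), rownames(counts))
  structure(D, metric = metric, class = c("beta_dist", "matrix"))
}

# Unweighted UniFrac: per tree edge, the edge is "spanned" by a sample if
# any descendant tip is present. d = unique branch length / union length.
unifrac_unweighted <- function(counts, tree) {
  absent <- setdiff(colnames(counts), tree$tip.label)
  if (length(absent))
    stop("taxa absent from tree: ", paste(absent, collapse = ", "))
  ntip <- length(tree$tip.label)
  # indicator of tip descendants per edge
  desc <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) desc[[t]] <- t
  for (e in ape::postorder(tree)) {  # children visited before parents
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  nedge <- nrow(tree$edge)
  edge_tip <- matrix(FALSE, nedge, ntip)
  for (e in seq_len(nedge))
    edge_tip[e, desc[[tree$edge[e, 2]]]] <- TRUE
  pres <- t(counts[, tree$tip.label, drop = FALSE] > 0)  # tips x samples
  spanned <- (edge_tip %*% pres) > 0                     # edges x samples
  bl <- tree$edge.length
  n <- ncol(spanned)
  D <- matrix(0, n, n)
  shared_len <- crossprod(spanned * bl, spanned * 1)  # sum bl over both
  either_len <- matrix(colSums(bl * spanned), n, n) +
    matrix(colSums(bl * spanned), n, n, byrow = TRUE) - shared_len
  uniq_len <- either_len - shared_len
  D <- ifelse(either_len > 0, uniq_len / either_len, 0)
  D
}

#' Centered kernel from a distance matrix
#'
#' `K = -1/2 * J (D * D) J` with `J = I - 11'/n` the centering projector
#' (the construction used by kernel association score tests). Negative
#' eigenvalues, which arise for non-Euclidean distances, are truncated to
#' zero; the number truncated is reported as an attribute.
#'
#' @param D Symmetric distance matrix.
#' @return Centered positive semi-definite kernel matrix (rows/columns sum
#'   to zero) with attribute `n_truncated`.
#' @export
distance_to_kernel <- function(D) {
  D <- unclass(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  K <- -0.5 * J %*% (D * D) %*% J
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  neg <- ev$values < -1e-10 * max(abs(ev$values), 1)
  if (any(neg)) {
    vals <- pmax(ev$values, 0)
    K <- ev$vectors %*% (vals * t(ev$vectors))
    K <- (K + t(K)) / 2
  }
  structure(K, n_truncated = sum(neg))
}
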