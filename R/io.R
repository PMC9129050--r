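#' Write a cohort to plain-text files
#'
#' Emits counts (TSV, first column `sample_id`), metadata (covariates +
#' exposure), taxonomy, the Newick tree, and — for simulated cohorts — a
#' ground-truth ledger (JSON with differential taxa/edges, propensities
#' and depths).
#'
#' @param cohort A `micrand_cohort` (or a list with `cohort`, `counts`,
#'   `taxonomy`, optionally `tree`, `truth`).
#' @param dir Output directory (created if missing).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Invisibly, the named vector of paths written.
#' @export
emit_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  existing <- paths[file.exists(paths)]
  if (length(existing) && !overwrite)
    stop("refusing to overwrite: ", paste(existing, collapse = ", "))
  cts <- data.frame(sample_id = rownames(cohort$counts),
                    as.data.frame(cohort$counts), check.names = FALSE)
  write.table(cts, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$cohort, paths["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$taxonomy, paths["taxonomy"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  written <- paths[c("counts", "metadata", "taxonomy")]
  if (!is.null(cohort$tree)) {
    ape::write.tree(cohort$tree, paths["tree"])
    written <- c(written, paths["tree"])
  }
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    ledger <- list(
      differential_taxa = colnames(cohort$counts)[tr$differential_taxa],
      differential_edges = if (!is.null(tr$differential_edges))
        apply(tr$differential_edges, 1, function(e)
          colnames(cohort$counts)[e], simplify = FALSE) else list(),
      propensity = unname(tr$propensity),
      depth = unname(tr$depth),
      seed = cohort$config$seed)
    jsonlite::write_json(ledger, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, paths["truth"])
  }
  invisible(written)
}

#' Read a cohort from plain-text files
#'
#' Counterpart of [emit_cohort()]: reads counts, metadata and taxonomy
#' TSVs plus an optional Newick tree.
#'
#' @param counts,metadata,taxonomy,tree File paths (`tree` optional).
#' @return A list of class `micrand_cohort` (without `truth`).
#' @export
read_cohort <- function(counts, metadata, taxonomy = NULL, tree = NULL) {
  cts <- read.delim(counts, check.names = FALSE)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts[[1]]
  storage.mode(m) <- "integer"
  meta <- read.delim(metadata, check.names = FALSE)
  if (!all(c("unit_id", "exposure") %in% names(meta)))
    stop("metadata must contain unit_id and exposure columns")
  if (!all(meta$exposure %in% 0:1)) stop("exposure must be binary 0/1")
  tax <- if (!is.null(taxonomy)) read.delim(taxonomy, check.names = FALSE)
  tr <- if (!is.null(tree)) ape::read.tree(tree)
  structure(list(cohort = meta, counts = m, taxonomy = tax, tree = tr,
                 truth = NULL, config = NULL),
            class = "micrand_cohort")
}
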