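#' End-to-end analysis configuration
#'
#' Serializable description of one full analysis run: design settings,
#' permutation budget, per-stage parameters, and stage toggles. Every
#' report embeds its resolved configuration so a run can be reproduced.
#'
#' @param thresholds A [matching_thresholds()], or `NULL` with
#'   `use_propensity = TRUE`.
#' @param use_propensity Use greedy propensity matching instead of
#'   threshold matching.
#' @param caliper Propensity caliper (SD units of the score).
#' @param n_iter Number of hypothetical assignments.
#' @param seed Master seed (assignments, bootstraps, subsampling).
#' @param pseudocount CLR pseudocount.
#' @param prevalence Prevalence filter applied before analysis.
#' @param beta_metrics Distance metrics for the beta-diversity battery.
#' @param ranks Taxonomic ranks for the compositional mean test.
#' @param da_dispersion,da_prevalence Reference-selection thresholds.
#' @param network_lambda Fixed penalty, or `NULL` for StARS selection.
#' @param stages Character subset of
#'   `c("diversity", "beta", "composition", "abundance", "network")`.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = default_thresholds(),
                            use_propensity = FALSE, caliper = 0.2,
                            n_iter = 1000, seed = 1L, pseudocount = 1,
                            prevalence = 0.05,
                            beta_metrics = c("aitchison", "jaccard",
                                             "gower_clr",
                                             "unifrac_unweighted"),
                            ranks = c("Genus", "Family", "Phylum"),
                            da_dispersion = 2, da_prevalence = 0.9,
                            network_lambda = NULL,
                            stages = c("diversity", "beta", "composition",
                                       "abundance", "network")) {
  structure(list(thresholds = thresholds, use_propensity = use_propensity,
                 caliper = caliper, n_iter = n_iter, seed = as.integer(seed),
                 pseudocount = pseudocount, prevalence = prevalence,
                 beta_metrics = beta_metrics, ranks = ranks,
                 da_dispersion = da_dispersion,
                 da_prevalence = da_prevalence,
                 network_lambda = network_lambda, stages = stages),
            class = "analysis_config")
}

#' Run the full causal analysis battery on a cohort
#'
#' Design stage (threshold or propensity matching plus balance
#' diagnostics), one shared assignment matrix, then the toggled analysis
#' stages: diversity (richness + Shannon), beta-diversity kernel battery,
#' compositional mean per rank, reference-normalized differential
#' abundance, and differential network edges. A stage failure is recorded
#' and downstream stages still run; the partial report is returned.
#'
#' @param cohort A `micrand_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config An [analysis_config()].
#' @param design Optional pre-built `matched_design` (skips matching).
#' @return List of class `study_report`: design summary, balance table,
#'   per-stage results, errors, and the resolved config.
#' @export
run_pipeline <- function(cohort, config = analysis_config(),
                         design = NULL) {
  report <- list(config = config, errors = list())
  t0 <- Sys.time()

  if (is.null(design)) {
    design <- if (config$use_propensity) {
      propensity_match(cohort, caliper = config$caliper,
                       seed = config$seed)
    } else match_pairs(cohort, config$thresholds)
  }
  if (design$n_pairs == 0) stop("design stage produced no matched pairs")
  tab <- cohort$cohort
  report$design <- list(
    n_before = c(exposed = sum(tab$exposure == 1),
                 control = sum(tab$exposure == 0)),
    n_after = c(exposed = design$N_E, control = design$N_C),
    pairs = design$pairs, provenance = design$provenance)
  report$balance <- balance_diagnostics(cohort, design)

  counts <- prevalence_filter(cohort$counts, config$prevalence)
  assignments <- generate_assignments(design, config$n_iter, config$seed)
  report$assignments <- list(n_iter = ncol(assignments),
                             exhaustive = attr(assignments, "exhaustive"),
                             seed = config$seed)

  stage <- function(name, expr) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    report[[name]] <<- res
    invisible(NULL)
  }

  stage("diversity", list(
    richness = diversity_randomization_test(counts, assignments,
                                            "richness"),
    shannon = diversity_randomization_test(counts, assignments, "shannon",
                                           seed = config$seed)))
  stage("beta", beta_diversity_test(counts, assignments,
                                    metrics = config$beta_metrics,
                                    tree = cohort$tree,
                                    pseudocount = config$pseudocount))
  stage("composition", compositional_mean_test(counts, cohort$taxonomy,
                                               assignments,
                                               ranks = config$ranks,
                                               pseudocount =
                                                 config$pseudocount))
  stage("abundance", {
    refs <- select_references(counts, config$da_dispersion,
                              config$da_prevalence,
                              pseudocount = config$pseudocount)
    differential_abundance_test(counts, assignments, refs)
  })
  stage("network", network_permutation_test(counts, assignments,
                                            lambda =
                                              config$network_lambda,
                                            pseudocount =
                                              config$pseudocount))
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report —", x$design$provenance, "\n")
  cat("  units before matching:", x$design$n_before["exposed"], "exposed /",
      x$design$n_before["control"], "control\n")
  cat("  matched pairs:", x$design$n_after["exposed"], "\n")
  cat("  assignments:", x$assignments$n_iter,
      if (x$assignments$exhaustive) "(exhaustive)" else "(sampled)", "\n")
  flagged <- x$balance$covariate[x$balance$flag]
  cat("  covariates with |SMD| > 0.1 after matching:",
      if (length(flagged)) paste(flagged, collapse = ", ") else "none",
      "\n")
  if (!is.null(x$diversity))
    cat(sprintf("  richness p = %.4g, Shannon p = %.4g\n",
                x$diversity$richness$p, x$diversity$shannon$p))
  if (!is.null(x$beta))
    cat("  beta-diversity adjusted p:",
        paste(sprintf("%s=%.4g", names(x$beta$p_adjusted),
                      x$beta$p_adjusted), collapse = ", "), "\n")
  if (!is.null(x$composition)) {
    cat("  compositional mean p by rank:",
        paste(sprintf("%s=%.4g", x$composition$rank, x$composition$p),
              collapse = ", "), "\n")
  }
  if (!is.null(x$abundance)) {
    hits <- x$abundance$taxon[x$abundance$p_adjusted <= 0.2]
    cat("  taxa warranting further scrutiny (adjusted p <= 0.2):",
        if (length(hits)) paste(hits, collapse = ", ") else "none", "\n")
  }
  if (!is.null(x$network)) {
    top <- head(x$network, 3)
    cat("  smallest differential-edge adjusted p:",
        paste(sprintf("%s/%s=%.4g", top$taxon_i, top$taxon_j,
                      top$p_adjusted), collapse = ", "), "\n")
  }
  for (nm in names(x$errors))
    cat("  stage", nm, "FAILED:", x$errors[[nm]], "\n")
  invisible(x)
}

#' Write a study report to a directory of TSV/JSON files
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @param overwrite Clobber existing files.
#' @return Invisibly, the index path.
#' @export
write_report <- function(report, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- file.path(dir, "report.json")
  if (file.exists(idx) && !overwrite) stop("refusing to overwrite ", idx)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(report$design$pairs, "pairs.tsv")
  wt(report$balance, "balance.tsv")
  summary <- list(
    n_before = as.list(report$design$n_before),
    n_pairs = unname(report$design$n_after["exposed"]),
    provenance = report$design$provenance,
    n_iter = report$assignments$n_iter,
    exhaustive = report$assignments$exhaustive,
    seed = report$assignments$seed,
    errors = report$errors)
  if (!is.null(report$diversity))
    summary$diversity <- lapply(report$diversity, function(t)
      list(statistic = t$observed, p = t$p, sidedness = t$sidedness))
  if (!is.null(report$beta))
    summary$beta <- list(statistic = as.list(report$beta$observed),
                         p = as.list(report$beta$p),
                         p_adjusted = as.list(report$beta$p_adjusted))
  if (!is.null(report$composition))
    wt(report$composition, "composition.tsv")
  if (!is.null(report$abundance))
    wt(report$abundance, "differential_abundance.tsv")
  if (!is.null(report$network))
    wt(report$network, "differential_edges.tsv")
  jsonlite::write_json(summary, idx, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(idx)
}
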