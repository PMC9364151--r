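# End-to-end orchestration: simulate -> normalize -> ratios -> calibrate +
# ES -> moderated test -> annotate, with a machine-readable run report.

#' Default pipeline configuration
#'
#' @param seed Integer seed (mandatory, drives every stochastic stage).
#' @param sim Named list of [sim_config()] overrides.
#' @param target_fpr FPR target for cutoff calibration (default 0.1).
#' @param min_es Minimum ES for the ES-path hit call (default 5).
#' @param alpha Adjusted-p threshold for the test path (default 0.05).
#' @param fc_threshold Log2 fold-change threshold (default 1).
#' @param stages Character vector of stages to run, a subset of
#'   `c("es", "test", "annotate")`; simulation, normalization and ratio
#'   formation always run.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, sim = list(), target_fpr = 0.1, min_es = 5L,
                       alpha = 0.05, fc_threshold = 1.0,
                       stages = c("es", "test", "annotate")) {
  if (missing(seed)) stop("'seed' is mandatory")
  bad <- setdiff(stages, c("es", "test", "annotate"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), sim = sim,
                 target_fpr = target_fpr, min_es = as.integer(min_es),
                 alpha = alpha, fc_threshold = fc_threshold,
                 stages = stages),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `sim:` holds
#' [sim_config()] overrides.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set 'seed'")
  do.call(run_config, c(list(seed = y$seed),
                        y[intersect(names(y),
                                    c("sim", "target_fpr", "min_es", "alpha",
                                      "fc_threshold", "stages"))]))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates an experiment, median-normalizes it, forms all pairwise
#' ratios, then (per the configured stages) calibrates cutoffs and scores
#' ES, runs the moderated-test path, summarizes annotation fractions, and
#' compares the two hit paths. Intermediate tables are written to
#' `out_dir` when given. The report excludes timestamps, so identical
#' config + seed reproduce an identical report hash.
#'
#' @param config A [run_config()] (or a path to a YAML config).
#' @param out_dir Optional output directory for intermediate TSV/JSON
#'   artifacts.
#' @return A `run_report` list: per-stage row counts, calibration
#'   cutoffs, hit counts by method and their overlap, annotation
#'   fractions, package version, config and report hashes.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  # a failing stage aborts the run, naming itself; partial outputs already
  # written are retained alongside a .partial marker
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) file.create(file.path(out_dir, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    simulate_experiment(cfg)
  })
  emit("simulated", function(p) write_simulated_experiment(sim, p))

  norm <- stage("normalize", median_normalize(sim$table))
  rm <- stage("ratios", compute_ratio_matrix(norm))
  emit("ratios.tsv", function(p) write_ratio_matrix(rm, p))

  report <- list(
    config = unclass(config),
    n_proteins = nrow(sim$table$intensity),
    n_channels = ncol(sim$table$intensity),
    n_ratio_columns = ncol(rm$ratios)
  )

  es_hits <- test_hits <- NULL
  if ("es" %in% config$stages) {
    es_stage <- stage("es", {
      controls <- label_controls(rownames(rm$ratios),
                                 sim$control_lists$pc, sim$control_lists$nc)
      calib <- calibrate_cutoffs(rm, controls,
                                 target_fpr = config$target_fpr)
      list(es = call_hits(enrichment_score(rm, calib),
                          min_es = config$min_es),
           calib = calib)
    })
    es <- es_stage$es
    calib <- es_stage$calib
    es_hits <- es$protein_id[es$hit]
    emit("es.tsv", function(p)
      utils::write.table(es, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    report$calibration <- data.frame(column = calib$column,
                                     cutoff = calib$cutoff,
                                     achieved_fpr = calib$achieved_fpr)
    report$n_es_hits <- length(es_hits)
  }
  if ("test" %in% config$stages) {
    mt <- stage("test",
                moderated_test(norm, fc_threshold = config$fc_threshold,
                               alpha = config$alpha))
    test_hits <- mt$protein_id[mt$enriched]
    emit("moderated_test.tsv", function(p)
      utils::write.table(
        mt[, c("protein_id", "log2fc", "t_mod", "p", "adj_p", "enriched")],
        p, sep = "\t", quote = FALSE, row.names = FALSE))
    report$n_test_hits <- length(test_hits)
    report$n_test_excluded <- length(attr(mt, "excluded"))
  }
  if (!is.null(es_hits) && !is.null(test_hits))
    report$hit_path_comparison <- compare_hit_paths(es_hits, test_hits)
  if ("annotate" %in% config$stages) {
    ann <- sim$annotation
    ann_df <- data.frame(protein_id = ann$protein_id,
                         secreted = as.logical(ann$secreted),
                         signalp = as.logical(ann$signalp),
                         tmh = as.logical(ann$tmh))
    for (nm in c("es", "test")) {
      hits <- if (nm == "es") es_hits else test_hits
      if (!is.null(hits) && length(hits)) {
        fr <- fraction_flagged(hits, ann_df, "signalp_or_tmh")
        report[[paste0(nm, "_hits_signalp_tmh_fraction")]] <- fr$fraction
      }
    }
  }
  report$package_version <- as.character(utils::packageVersion("secretoscore"))
  report$config_hash <- hash_object(unclass(config))
  report$report_hash <- hash_object(report)
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

# Content hash of an R object via its canonical JSON serialization.
hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (secretoscore ", x$package_version, ")\n", sep = "")
  cat("  proteins: ", x$n_proteins, ", channels: ", x$n_channels,
      ", ratio columns: ", x$n_ratio_columns, "\n", sep = "")
  if (!is.null(x$calibration))
    cat("  calibrated cutoffs: ",
        paste(sprintf("%.3g", x$calibration$cutoff), collapse = ", "),
        "\n", sep = "")
  if (!is.null(x$n_es_hits))
    cat("  ES-path hits: ", x$n_es_hits, "\n", sep = "")
  if (!is.null(x$n_test_hits))
    cat("  test-path hits: ", x$n_test_hits, "\n", sep = "")
  if (!is.null(x$hit_path_comparison))
    cat("  shared hits: ", x$hit_path_comparison$n_shared,
        " (Jaccard ", sprintf("%.3f", x$hit_path_comparison$jaccard),
        ")\n", sep = "")
  cat("  report hash: ", x$report_hash, "\n", sep = "")
  invisible(x)
}

#' Compare the two hit-calling paths
#'
#' The ES path (FPR-calibrated ratio-count score) and the moderated-test
#' path (adjusted p + fold change) address the same question with
#' different statistics; this summarizes their agreement.
#'
#' @param es_hits Character vector of ES-path hit IDs.
#' @param test_hits Character vector of test-path hit IDs.
#' @param universe_es,universe_test Optional ID universes each list was
#'   called from; if both are given and disjoint, that is an error (the
#'   comparison would be meaningless).
#' @return List `n_es`, `n_test`, `n_shared`, `n_es_only`, `n_test_only`,
#'   `jaccard` (0 when both lists are empty).
#' @export
compare_hit_paths <- function(es_hits, test_hits,
                              universe_es = NULL, universe_test = NULL) {
  if (!is.null(universe_es) && !is.null(universe_test) &&
      !length(intersect(universe_es, universe_test)))
    stop("hit lists come from disjoint protein universes")
  es_hits <- unique(es_hits)
  test_hits <- unique(test_hits)
  shared <- intersect(es_hits, test_hits)
  un <- union(es_hits, test_hits)
  list(n_es = length(es_hits), n_test = length(test_hits),
       n_shared = length(shared),
       n_es_only = length(setdiff(es_hits, test_hits)),
       n_test_only = length(setdiff(test_hits, es_hits)),
       jaccard = if (length(un)) length(shared) / length(un) else 0)
}
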