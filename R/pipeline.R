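# End-to-end orchestration: simulate -> clean -> featurize -> grouped CV,
# with a single global seed, per-stage derived seeds, and a run manifest.

# deterministic per-stage seed derived from the global seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' Flat, manifest-friendly configuration for [run_pipeline()]. Every stage's
#' defaults equal the analysis defaults (design 3 x 5 x 3 x 3, threshold
#' 700 a.u., 1-dp featurization, 10 donor-grouped folds, the four fixed
#' model specs).
#'
#' @param seed Global seed; all stage seeds derive from it.
#' @param design A [cohort_design()].
#' @param panel_path Optional path to a panel YAML (default: shipped panel).
#' @param models Character vector of model kinds to evaluate.
#' @param n_folds Folds for the grouped CV.
#' @param intensity_threshold Minimum peak intensity carried into
#'   featurization (a.u.).
#' @param out_dir Optional output directory; if `NULL` nothing is written.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, design = cohort_design(),
                       panel_path = NULL, models = "knn", n_folds = 10L,
                       intensity_threshold = 700, out_dir = NULL) {
  structure(list(seed = as.integer(seed), design = design,
                 panel_path = panel_path, models = models,
                 n_folds = as.integer(n_folds),
                 intensity_threshold = intensity_threshold,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate -> contaminant removal and sub-threshold filtering -> 1-dp
#' round/collapse featurization -> donor-grouped stratified CV for each
#' requested model. If `out_dir` is set, writes `metadata.csv`,
#' `matrix.csv`, `folds.csv`, one confusion CSV per model, and a
#' `manifest.yaml` recording all effective parameters and seeds from which
#' the run can be replayed.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `cohort`, `features`
#'   (`feature_matrix`), `plan`, `results` (named list of `pooled_result`),
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$design$donors_per_class < 1L) {
    stop("design stage: donors_per_class must be >= 1 to run the pipeline",
         call. = FALSE)
  }
  panel <- load_panel(config$panel_path)
  cohort <- simulate_cohort(config$design, panel,
                            seed = stage_seed(config$seed, "simulate"))
  exclusions <- read_exclusion_list()
  rows <- lapply(names(cohort$samples), function(id) {
    peaks <- cohort$samples[[id]]
    peaks <- remove_contaminants(peaks, exclusions, tol_ppm = 10)
    peaks <- peaks[peaks$intensity >= config$intensity_threshold, ,
                   drop = FALSE]
    round_collapse(peaks, sample_id = id)
  })
  features <- assemble_matrix(rows, cohort$metadata)
  plan <- plan_folds(cohort$metadata, n_folds = config$n_folds,
                     seed = stage_seed(config$seed, "folds"))
  results <- list()
  for (kind in config$models) {
    results[[kind]] <- run_grouped_cv(features, model_spec(kind), plan,
                                      seed = stage_seed(config$seed, kind))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("maldiscreen")),
    panel_version = panel$version, seed = config$seed,
    stage_seeds = list(simulate = stage_seed(config$seed, "simulate"),
                       folds = stage_seed(config$seed, "folds")),
    design = unclass(config$design),
    panel_path = if (is.null(config$panel_path)) "default" else
      config$panel_path,
    models = config$models, n_folds = config$n_folds,
    intensity_threshold = config$intensity_threshold,
    n_samples = nrow(cohort$metadata),
    n_sparse_positions = features$n_sparse_positions,
    n_dense_positions = features$n_dense_positions,
    accuracy = lapply(results, function(r) r$accuracy)
  )
  out <- structure(list(cohort = cohort, features = features, plan = plan,
                        results = results, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$cohort$metadata,
                   file.path(config$out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  write_matrix_csv(result$features, file.path(config$out_dir, "matrix.csv"))
  utils::write.csv(result$plan$donor_fold,
                   file.path(config$out_dir, "folds.csv"),
                   row.names = FALSE, quote = FALSE)
  for (kind in names(result$results)) {
    utils::write.csv(as.data.frame(result$results[[kind]]$confusion),
                     file.path(config$out_dir,
                               sprintf("confusion_%s.csv", kind)),
                     row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(result$manifest,
                   file.path(config$out_dir, "manifest.yaml"))
  invisible(config$out_dir)
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] with the parameters and seeds recorded in a
#' `manifest.yaml`; artifacts are reproducible regardless of where the
#' manifest now lives.
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [run_pipeline()].
#' @param out_dir Optional new output directory.
#' @return A `pipeline_result`.
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  m <- yaml::read_yaml(manifest_path)
  design <- cohort_design(classes = unlist(m$design$classes),
                          donors_per_class = m$design$donors_per_class,
                          fingers_per_donor = m$design$fingers_per_donor,
                          replicates_per_finger =
                            m$design$replicates_per_finger,
                          mz_min = m$design$mz_min, mz_max = m$design$mz_max)
  config <- run_config(seed = m$seed, design = design,
                       panel_path = if (identical(m$panel_path, "default"))
                         NULL else m$panel_path,
                       models = unlist(m$models), n_folds = m$n_folds,
                       intensity_threshold = m$intensity_threshold,
                       out_dir = out_dir)
  run_pipeline(config)
}
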