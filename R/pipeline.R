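#' End-to-end pipeline configuration
#'
#' A single global seed deterministically derives every stage seed
#' (generation, clustering, case sampling, rater panel), so a rerun with
#' the same configuration reproduces identical artifacts.
#'
#' @param seed Global integer seed.
#' @param generator A `generator_config` (default: the study-calibrated
#'   cohort, re-seeded from `seed`).
#' @param preprocess A `preprocess_config`.
#' @param tau PCA variance retention threshold.
#' @param algorithms Clustering algorithms for the selection grid.
#' @param k_range Cluster counts for the selection grid.
#' @param weights A `weight_config`.
#' @param n_cases Validation sample size (default 120).
#' @param raters Panel size (default 5).
#' @param echo Rater echo probability for the simulated panel (default 0.8).
#' @param out_dir Optional artifact directory; `NULL` skips writing.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, generator = NULL,
                            preprocess = preprocess_config(), tau = 0.90,
                            algorithms = c("kmeans", "hac", "gmm"),
                            k_range = 3:6, weights = weight_config(),
                            n_cases = 120L, raters = 5L, echo = 0.8,
                            out_dir = NULL) {
  if (is.null(generator)) generator <- default_study_config(seed = seed)
  structure(list(seed = as.integer(seed), generator = generator,
                 preprocess = preprocess, tau = tau,
                 algorithms = algorithms, k_range = k_range,
                 weights = weights, n_cases = as.integer(n_cases),
                 raters = as.integer(raters), echo = echo,
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_artifact <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, name)
  if (grepl("\\.json$", name)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}

#' Run the full stratification + recommendation + validation pipeline
#'
#' Stages run in fixed order: cohort generation (or a supplied cohort),
#' preprocessing, z-score standardization of the clustering features, PCA
#' at the configured retention threshold, model selection over the
#' algorithm x k grid, cluster profiling, dual-weighted recommendation, and
#' an expert-agreement evaluation against a simulated rater panel echoing
#' the system's recommendations on a stratified case sample. When
#' `config$out_dir` is set, every artifact is written as JSON/CSV together
#' with the seeds used.
#'
#' @param config A `pipeline_config`.
#' @param cohort Optional pre-built `cohort_table`; when supplied, the
#'   generation stage is skipped and ground truth is unavailable.
#' @param kb Knowledge base (default [default_kb()]).
#' @return A `pipeline_bundle` list: `cohort` (clean), `truth` (or NULL),
#'   `preprocess_report`, `pca`, `selection`, `model`, `profiles`,
#'   `recommendations`, `validation_sample`, `panel`, `agreement`, `seeds`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         kb = default_kb()) {
  seeds <- list(generate = config$seed, cluster = config$seed + 1L,
                sample = config$seed + 2L, panel = config$seed + 3L)
  truth <- NULL
  if (is.null(cohort)) {
    gen <- generate_cohort(config$generator)
    cohort <- gen$cohort
    truth <- gen$truth
  }
  pp <- preprocess_cohort(cohort, config$preprocess)
  clean <- pp$cohort
  feats <- schema_role(clean$schema, "clustering_feature")
  sm <- zscore_standardize(clean, feats)
  pca <- fit_pca(sm, tau = config$tau)
  scores <- pca_scores(pca)
  selection <- select_model(scores, config$algorithms, config$k_range,
                            seed = seeds$cluster)
  model <- selection$chosen_model
  profiles <- profile_clusters(clean, model$labels)
  recs <- recommend_cohort(clean, model$labels, profiles, kb, config$weights)

  sel_idx <- stratified_sample(model$labels, min(config$n_cases, nrow(clean$data)),
                               seed = seeds$sample)
  truth_df <- recs$levels[sel_idx, , drop = FALSE]
  panel <- simulate_rater_panel(truth_df[setdiff(names(truth_df), "cluster")],
                                echo = config$echo, raters = config$raters,
                                seed = seeds$panel)
  agreement <- agreement_report(recs$levels, panel)

  bundle <- structure(list(cohort = clean, truth = truth,
                           preprocess_report = pp$report, pca = pca,
                           selection = selection, model = model,
                           profiles = profiles, recommendations = recs,
                           validation_sample = sel_idx, panel = panel,
                           agreement = agreement, seeds = seeds),
                      class = "pipeline_bundle")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_artifact(list(seeds = seeds,
                        rows = nrow(clean$data),
                        rows_dropped = pp$report$rows_dropped,
                        unit_corrections = pp$report$unit_corrections,
                        numeric_cells_imputed = pp$report$numeric_cells_imputed),
                   config$out_dir, "preprocess_report.json")
    write_artifact(list(eigenvalues = pca$eigenvalues,
                        explained_variance_ratios = pca$explained_variance_ratios,
                        retained_m = pca$retained_m, tau = pca$tau),
                   config$out_dir, "pca_model.json")
    write_artifact(selection$grid, config$out_dir, "selection_grid.csv")
    write_artifact(list(algorithm = model$algorithm, k = model$k,
                        sizes = model$sizes,
                        rationale = selection$rationale),
                   config$out_dir, "selection_report.json")
    write_artifact(data.frame(cluster = profiles$clusters,
                              name = profiles$names),
                   config$out_dir, "cluster_names.csv")
    write_artifact(recs$matrix, config$out_dir, "recommendation_matrix.csv")
    write_artifact(recs$levels, config$out_dir, "recommendation_levels.csv")
    write_artifact(list(overall = agreement$overall,
                        per_domain = agreement$per_domain,
                        excluded_ties = agreement$excluded_ties),
                   config$out_dir, "agreement_report.json")
  }
  bundle
}
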