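# End-to-end analysis: eligibility filter -> preprocessing -> per-arm
# ensembles with feature reduction -> validation -> recommendations ->
# surrogate tree.

#' Run the full recommendation pipeline on a cohort
#'
#' Chains every stage of the analysis: eligibility filtering, train/test
#' partitioning (stratified holdout or leave-EVIDENT-out with SMOTE
#' augmentation), median imputation and PWV standardization fitted on the
#' training partition, per-arm forest fitting with dual-importance top-k
#' feature reduction, per-arm held-out validation, counterfactual argmax
#' recommendations for every eligible patient, match-rate and distribution
#' summaries, and a surrogate decision tree distilled from the
#' recommendations.
#'
#' @param cohort Cohort tibble (see [generate_cohort()] for the layout).
#' @param scheme `"internal"` (stratified holdout) or `"external"`
#'   (EVIDENT cohort reserved; EVA+LOD training, SMOTE-augmented).
#' @param schema Covariate schema.
#' @param train_frac Training fraction for the internal holdout.
#' @param hyperparams Forest hyperparameters, see [default_hyperparams()].
#' @param k_features Features kept per arm after importance reduction.
#' @param n_repeats Permutation-importance shuffles.
#' @param measure Importance measure for selection (see
#'   [select_top_features()]).
#' @param modality PWV-change target convention (see
#'   [build_arm_datasets()]).
#' @param min_group_size Eligibility threshold on arm size.
#' @param augment Apply SMOTE in the external scheme?
#' @param surrogate_depth,surrogate_gini_stop Surrogate tree settings.
#' @param seed Master seed driving every random stage.
#' @return Object of class `pwv_pipeline`: list with `bundles`,
#'   `importance`, `validation` (per-arm report), `recommendations`,
#'   `match`, `distribution`, `surrogate`, `fidelity` (in-sample and
#'   held-out), `split` (train/test patient ids), preprocessing parameters,
#'   and the configuration.
#' @export
#' @examples
#' \donttest{
#' sim <- generate_cohort(n = 400, seed = 7)
#' res <- pwv_pipeline(sim$cohort, seed = 7,
#'                     hyperparams = default_hyperparams(n_trees = 100),
#'                     n_repeats = 2)
#' res$validation
#' }
pwv_pipeline <- function(cohort,
                         scheme = c("internal", "external"),
                         schema = feature_schema(),
                         train_frac = 0.8,
                         hyperparams = default_hyperparams(),
                         k_features = 10,
                         n_repeats = 10,
                         measure = "consensus",
                         modality = "both",
                         min_group_size = 10,
                         augment = TRUE,
                         surrogate_depth = 10,
                         surrogate_gini_stop = 0.20,
                         seed = 1) {
  scheme <- match.arg(scheme)
  cohort <- filter_eligible(cohort, min_group_size = min_group_size)

  if (scheme == "internal") {
    split <- holdout_split(cohort, train_frac = train_frac, seed = seed)
    train_arms <- build_arm_datasets(split$train, schema = schema,
                                     modality = modality)
    test_arms <- build_arm_datasets(
      split$test, schema = schema,
      standardization = train_arms$standardization,
      medians = train_arms$medians, modality = modality)
    provenance <- NULL
  } else {
    ext <- external_scheme(cohort, schema = schema, augment = augment,
                           modality = modality, seed = seed)
    train_arms <- ext$train_arms
    test_arms <- ext$test_arms
    provenance <- ext$provenance
    split <- list(
      train = dplyr::filter(cohort, .data$cohort_id != "EVIDENT"),
      test = dplyr::filter(cohort, .data$cohort_id == "EVIDENT"))
  }

  fits <- fit_arm_bundles(train_arms, hyperparams = hyperparams,
                          k_features = k_features, n_repeats = n_repeats,
                          measure = measure, seed = seed)
  report <- evaluate_bundles(fits, test_arms, scheme = scheme)

  features_all <- impute_median(
    cohort[intersect(schema$name, names(cohort))],
    medians = train_arms$medians)$data
  preds <- predict_all_arms(fits, features_all)
  recs <- recommend(preds, actual_drugs = cohort$drug_class,
                    patient_ids = cohort$patient_id)

  surrogate <- fit_surrogate(features_all, recs$recommended_drug,
                             max_depth = surrogate_depth,
                             gini_stop = surrogate_gini_stop)
  test_rows <- cohort$patient_id %in% split$test$patient_id
  fidelity <- c(
    in_sample = surrogate_fidelity(surrogate, features_all,
                                   recs$recommended_drug),
    held_out = if (any(test_rows)) {
      surrogate_fidelity(surrogate, features_all[test_rows, ],
                         recs$recommended_drug[test_rows])
    } else NA_real_
  )

  structure(
    list(bundles = fits, importance = fits$importance,
         validation = report, recommendations = recs,
         match = match_rate(recs),
         distribution = recommendation_distribution(recs),
         surrogate = surrogate, fidelity = fidelity,
         provenance = provenance,
         split = list(train_ids = split$train$patient_id,
                      test_ids = split$test$patient_id),
         standardization = train_arms$standardization,
         medians = train_arms$medians,
         config = list(scheme = scheme, train_frac = train_frac,
                       hyperparams = hyperparams, k_features = k_features,
                       n_repeats = n_repeats, measure = measure,
                       modality = modality,
                       min_group_size = min_group_size,
                       augment = augment,
                       surrogate_depth = surrogate_depth,
                       surrogate_gini_stop = surrogate_gini_stop,
                       seed = seed)),
    class = "pwv_pipeline"
  )
}

#' @export
print.pwv_pipeline <- function(x, ...) {
  cat("<pwv_pipeline>", x$config$scheme, "validation, seed",
      x$config$seed, "\n\nPer-arm validation:\n")
  print(tibble::as_tibble(x$validation))
  cat("\nOverall match rate:", round(x$match$overall, 3),
      "| surrogate fidelity (in-sample):",
      round(x$fidelity[["in_sample"]], 3), "\n")
  invisible(x)
}

#' Write the pipeline's reports to disk
#'
#' Serializes the recommendation table and importance tables as CSV and the
#' validation metrics, match rates, distribution, surrogate tree, and
#' configuration as JSON. Output is deterministic given the pipeline
#' result, so re-running the pipeline under one seed reproduces the files
#' byte for byte.
#'
#' @param result A `pwv_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  stopifnot(inherits(result, "pwv_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    recommendations = file.path(dir, "recommendations.csv"),
    importance = file.path(dir, "importance.csv"),
    summary = file.path(dir, "summary.json"),
    surrogate = file.path(dir, "surrogate.json")
  )
  utils::write.csv(result$recommendations, paths[["recommendations"]],
                   row.names = FALSE)
  imp <- dplyr::bind_rows(purrr::imap(result$importance,
                                      ~ dplyr::mutate(.x, drug = .y)))
  utils::write.csv(imp, paths[["importance"]], row.names = FALSE)
  jsonlite::write_json(
    list(validation = tibble::as_tibble(result$validation),
         match = result$match,
         distribution = result$distribution,
         fidelity = as.list(result$fidelity),
         selected_features = purrr::map(result$bundles$bundles,
                                        "selected_features"),
         config = result$config),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(levels = result$surrogate$levels,
         gini_stop = result$surrogate$gini_stop,
         max_depth = result$surrogate$max_depth,
         nodes = result$surrogate$nodes),
    paths[["surrogate"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
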