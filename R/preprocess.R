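# Eligibility filtering, median imputation, PWV standardization, and
# construction of the six per-arm modelling datasets.

#' Filter patients to eligible drug classes
#'
#' Removes the `OTHER` pseudo-class (drugs outside the six modelled groups)
#' and any drug class observed in fewer than `min_group_size` patients.
#' A class with exactly `min_group_size` patients is retained (the exclusion
#' rule is strictly "fewer than"). Row order is preserved.
#'
#' @param cohort Cohort tibble with a `drug_class` column.
#' @param min_group_size Minimum arm size to keep; default 10.
#' @return The filtered cohort tibble.
#' @export
filter_eligible <- function(cohort, min_group_size = 10) {
  stopifnot(min_group_size >= 1)
  keep_classes <- cohort |>
    dplyr::filter(.data$drug_class %in% drug_classes()) |>
    dplyr::count(.data$drug_class) |>
    dplyr::filter(.data$n >= min_group_size) |>
    dplyr::pull(.data$drug_class)
  out <- dplyr::filter(cohort, .data$drug_class %in% keep_classes)
  if (nrow(out) == 0) {
    stop("No drug class reaches min_group_size = ", min_group_size, ".",
         call. = FALSE)
  }
  out
}

#' Median imputation of covariates
#'
#' Replaces missing cells by the per-column median of the observed values
#' (midpoint convention for even counts). Binary 0/1 covariates are imputed
#' with the median as well, i.e. the majority value. Supplying `medians`
#' (e.g. estimated on a training partition) reuses those values instead of
#' re-estimating, so test data never informs the imputation.
#'
#' @param data Data frame / tibble of numeric covariates, possibly with `NA`.
#' @param medians Optional named numeric vector of per-column medians.
#' @return List with `data` (completed tibble) and `medians` (named vector
#'   usable for held-out data).
#' @export
impute_median <- function(data, medians = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(medians)) {
    all_na <- names(data)[purrr::map_lgl(data, ~ all(is.na(.x)))]
    if (length(all_na) > 0) {
      stop("Column(s) fully missing, cannot estimate a median: ",
           paste(all_na, collapse = ", "), call. = FALSE)
    }
    medians <- purrr::map_dbl(data, stats::median, na.rm = TRUE)
  } else {
    missing_cols <- setdiff(names(data), names(medians))
    if (length(missing_cols) > 0) {
      stop("No median supplied for column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  completed <- purrr::imap(data, function(x, nm) {
    x[is.na(x)] <- medians[[nm]]
    x
  })
  list(data = tibble::as_tibble(completed), medians = medians[names(data)])
}

#' Standardize the two PWV modalities
#'
#' Fits per-modality standardization parameters (mean and population SD of
#' the baseline values) and converts baseline and follow-up carotid-femoral
#' and brachial-ankle PWV to z-scores on a common scale. Both time points of
#' a modality use the *baseline* parameters so that the change score is
#' expressed on one scale. Parameters fitted on training data can be reused
#' on held-out data via `params`.
#'
#' @param cohort Tibble with columns `cfpwv_baseline`, `bapwv_baseline`,
#'   `cfpwv_followup`, `bapwv_followup` (and `patient_id`).
#' @param params Optional `pwv_standardization` object to reuse.
#' @return List with `scores` (tibble of z-scored values per patient) and
#'   `params` (`pwv_standardization`: `cf` and `ba`, each `mean` and `sd`).
#' @export
standardize_pwv <- function(cohort, params = NULL) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  if (is.null(params)) {
    fit_one <- function(x) {
      s <- pop_sd(x[!is.na(x)])
      if (!is.finite(s) || s <= 0) {
        stop("Zero variance in baseline PWV; cannot standardize.",
             call. = FALSE)
      }
      list(mean = mean(x, na.rm = TRUE), sd = s)
    }
    params <- structure(
      list(cf = fit_one(cohort$cfpwv_baseline),
           ba = fit_one(cohort$bapwv_baseline)),
      class = "pwv_standardization"
    )
  }
  z <- function(x, p) (x - p$mean) / p$sd
  scores <- tibble::tibble(
    patient_id = cohort$patient_id,
    cf_baseline_z = z(cohort$cfpwv_baseline, params$cf),
    cf_followup_z = z(cohort$cfpwv_followup, params$cf),
    ba_baseline_z = z(cohort$bapwv_baseline, params$ba),
    ba_followup_z = z(cohort$bapwv_followup, params$ba)
  )
  list(scores = scores, params = params)
}

#' Build the six per-arm outcome datasets
#'
#' Produces, for each drug class, the completed feature matrix and the
#' standardized PWV-change target of the patients who took that drug. The
#' target is `z(baseline) - z(followup)` per modality — positive values mean
#' PWV reduction — averaged over the two modalities (or a single modality
#' via `modality`). Patients missing any outcome PWV are excluded with a
#' warning; outcome values are never imputed. Covariates are median-imputed.
#'
#' @param cohort Eligible cohort tibble (see [filter_eligible()]).
#' @param schema Covariate schema naming the feature columns.
#' @param standardization Optional `pwv_standardization` to reuse (training
#'   parameters applied to held-out data); fitted on `cohort` when `NULL`.
#' @param medians Optional named vector of imputation medians to reuse.
#' @param modality `"both"` (average of the two standardized changes,
#'   default), `"cf"`, or `"ba"`.
#' @return Object of class `pwv_arm_data`: list with `arms` (named list of
#'   `pwv_arm_dataset`, each holding `drug`, `x`, `y`, `patient_ids`,
#'   `feature_names`), `standardization`, `medians`, `modality`, and
#'   `excluded` (patient ids dropped for incomplete outcomes).
#' @export
build_arm_datasets <- function(cohort,
                               schema = feature_schema(),
                               standardization = NULL,
                               medians = NULL,
                               modality = c("both", "cf", "ba")) {
  modality <- match.arg(modality)
  unknown <- setdiff(unique(cohort$drug_class), drug_classes())
  if (length(unknown) > 0) {
    stop("Unknown drug class(es): ", paste(unknown, collapse = ", "),
         ". Run filter_eligible() first.", call. = FALSE)
  }

  outcome_cols <- c("cfpwv_baseline", "bapwv_baseline",
                    "cfpwv_followup", "bapwv_followup")
  complete <- stats::complete.cases(cohort[outcome_cols])
  excluded <- cohort$patient_id[!complete]
  if (length(excluded) > 0) {
    warning(length(excluded),
            " patient(s) excluded for incomplete outcome PWV.", call. = FALSE)
    cohort <- cohort[complete, ]
  }

  std <- standardize_pwv(cohort, params = standardization)
  imp <- impute_median(cohort[intersect(schema$name, names(cohort))],
                       medians = medians)

  delta_cf <- std$scores$cf_baseline_z - std$scores$cf_followup_z
  delta_ba <- std$scores$ba_baseline_z - std$scores$ba_followup_z
  target <- switch(modality,
    both = (delta_cf + delta_ba) / 2,
    cf = delta_cf,
    ba = delta_ba
  )

  arms <- list()
  for (d in intersect(drug_classes(), unique(cohort$drug_class))) {
    idx <- which(cohort$drug_class == d)
    arms[[d]] <- structure(
      list(drug = d,
           x = imp$data[idx, , drop = FALSE],
           y = target[idx],
           patient_ids = cohort$patient_id[idx],
           feature_names = names(imp$data)),
      class = "pwv_arm_dataset"
    )
  }
  structure(
    list(arms = arms,
         standardization = std$params,
         medians = imp$medians,
         modality = modality,
         excluded = excluded),
    class = "pwv_arm_data"
  )
}

#' @export
print.pwv_arm_data <- function(x, ...) {
  cat("<pwv_arm_data> per-arm modelling datasets (modality:",
      x$modality, ")\n")
  for (a in x$arms) {
    cat(sprintf("  %-8s n = %d\n", a$drug, length(a$y)))
  }
  if (length(x$excluded) > 0) {
    cat("  excluded for incomplete outcomes:", length(x$excluded), "\n")
  }
  invisible(x)
}

#' True standardized effect matrix
#'
#' Converts the raw-scale (m/s) true-effect matrix of a synthetic truth to
#' the standardized-change scale used by the models: with the target defined
#' as the average of the two modality z-changes, a raw reduction of `g` m/s
#' maps to `g * (1/sd_cf + 1/sd_ba) / 2` standardized units.
#'
#' @param truth `pwv_truth` object.
#' @param features Feature table to evaluate the effect functions on.
#' @param standardization `pwv_standardization` parameters in force.
#' @param modality Target modality convention, as in [build_arm_datasets()].
#' @return Matrix on the standardized-change scale, columns =
#'   [drug_classes()].
#' @export
true_standardized_effects <- function(truth, features, standardization,
                                      modality = "both") {
  g <- true_effect_matrix(truth, features)
  scale <- switch(modality,
    both = (1 / standardization$cf$sd + 1 / standardization$ba$sd) / 2,
    cf = 1 / standardization$cf$sd,
    ba = 1 / standardization$ba$sd
  )
  g * scale
}
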