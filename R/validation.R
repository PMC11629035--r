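# Internal (stratified holdout) and external (leave-EVIDENT-out, SMOTE
# augmented training) validation schemes, with R^2 / MSE reporting.

#' Coefficient of determination
#'
#' `r_squared(y, yhat) = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#' Undefined (error) for constant `y`.
#'
#' @param y Observed values (length >= 2).
#' @param yhat Predicted values of the same length.
#' @return A single number, at most 1.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("Length mismatch.", call. = FALSE)
  if (length(y) < 2) stop("Need at least 2 observations.", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("R^2 undefined for a constant outcome.", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Mean squared error
#'
#' @inheritParams r_squared
#' @return Mean of squared residuals (>= 0).
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("Length mismatch.", call. = FALSE)
  mean((y - yhat)^2)
}

#' Stratified holdout split
#'
#' Randomly partitions the cohort into training and test folds with
#' `round(train_frac * n)` training rows overall, stratifying by drug class
#' so every arm appears in both folds whenever its size allows. A
#' single-patient arm goes to training with a warning.
#'
#' @param cohort Cohort tibble with a `drug_class` column.
#' @param train_frac Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles (disjoint, union = input).
#' @export
holdout_split <- function(cohort, train_frac = 0.8, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1, nrow(cohort) >= 2)
  local_seed_eval(seed, {
    n <- nrow(cohort)
    target_train <- round(train_frac * n)
    idx_by_arm <- split(seq_len(n), cohort$drug_class)
    train_idx <- integer(0)
    for (idx in idx_by_arm) {
      m <- length(idx)
      if (m == 1) {
        warning("Single-patient arm placed in training.", call. = FALSE)
        train_idx <- c(train_idx, idx)
        next
      }
      k <- round(train_frac * m)
      k <- min(max(k, 1), m - 1) # both folds nonempty per arm
      train_idx <- c(train_idx, sample(idx, k))
    }
    # nudge to the exact overall count while keeping strata nonempty
    excess <- length(train_idx) - target_train
    if (excess > 0) {
      movable <- train_idx[!train_idx %in%
        unlist(purrr::map(idx_by_arm, function(idx) {
          inside <- intersect(idx, train_idx)
          if (length(inside) <= 1) inside else integer(0)
        }))]
      drop <- sample(movable, min(excess, length(movable)))
      train_idx <- setdiff(train_idx, drop)
    } else if (excess < 0) {
      pool <- setdiff(seq_len(n), train_idx)
      movable <- pool[!pool %in%
        unlist(purrr::map(idx_by_arm, function(idx) {
          outside <- setdiff(idx, train_idx)
          if (length(outside) <= 1) outside else integer(0)
        }))]
      add <- sample(movable, min(-excess, length(movable)))
      train_idx <- c(train_idx, add)
    }
    train_idx <- sort(train_idx)
    list(train = cohort[train_idx, ],
         test = cohort[setdiff(seq_len(n), train_idx), ])
  })
}

#' External validation scheme: hold out the EVIDENT cohort
#'
#' Reserves every EVIDENT-labelled patient as the external test set
#' (untouched by augmentation) and builds the training data from the pooled
#' EVA and LOD cohorts, optionally enlarged by SMOTE interpolation to about
#' four times the test size (see [plan_external_counts()]). Preprocessing
#' parameters (imputation medians, PWV standardization) are fitted on the
#' training cohort only and reused on the test set.
#'
#' @param cohort Eligible cohort tibble with `cohort_id` labels.
#' @param schema Covariate schema.
#' @param augment Apply SMOTE augmentation to the training arms?
#' @param k_neighbors SMOTE neighborhood size.
#' @param modality Target modality, as in [build_arm_datasets()].
#' @param seed Integer seed for the augmentation draws.
#' @return List with `train_arms` (`pwv_arm_data`-style, augmented),
#'   `test_arms`, `provenance` (SMOTE parentage tibble), and the shared
#'   preprocessing parameters.
#' @export
external_scheme <- function(cohort, schema = feature_schema(),
                            augment = TRUE, k_neighbors = 5,
                            modality = "both", seed = 1) {
  missing_lbl <- setdiff(cohort_labels(), unique(cohort$cohort_id))
  if (length(missing_lbl) > 0) {
    stop("Cohort label(s) absent: ", paste(missing_lbl, collapse = ", "),
         call. = FALSE)
  }
  test <- dplyr::filter(cohort, .data$cohort_id == "EVIDENT")
  train <- dplyr::filter(cohort, .data$cohort_id != "EVIDENT")

  train_arms <- build_arm_datasets(train, schema = schema,
                                   modality = modality)
  test_arms <- build_arm_datasets(test, schema = schema,
                                  standardization = train_arms$standardization,
                                  medians = train_arms$medians,
                                  modality = modality)
  provenance <- NULL
  if (augment) {
    counts <- plan_external_counts(
      purrr::map_int(train_arms$arms, ~ length(.x$y)), nrow(test))
    aug <- smote_augment(train_arms, k_neighbors = k_neighbors,
                         target_counts = counts, seed = seed,
                         schema = schema)
    train_arms$arms <- aug$arms
    provenance <- aug$provenance
  }
  list(train_arms = train_arms, test_arms = test_arms,
       provenance = provenance,
       standardization = train_arms$standardization,
       medians = train_arms$medians)
}

#' Evaluate fitted bundles on held-out arm datasets
#'
#' Computes per-arm R^2 and MSE of the predicted versus observed
#' standardized PWV change, each arm scored on its own held-out patients.
#'
#' @param bundles A `pwv_bundles` object or named list of bundles.
#' @param test_arms A `pwv_arm_data` object (or its `arms` list) of held-out
#'   patients.
#' @param scheme Label recorded in the report (`"internal"` or
#'   `"external"`).
#' @return Object of class `pwv_validation_report`: tibble with columns
#'   `drug`, `r2`, `mse`, `n_test`, plus a `scheme` attribute. Arms with a
#'   constant observed outcome get `NA` R^2.
#' @export
evaluate_bundles <- function(bundles, test_arms,
                             scheme = c("internal", "external")) {
  scheme <- match.arg(scheme)
  if (inherits(bundles, "pwv_bundles")) bundles <- bundles$bundles
  arms <- if (inherits(test_arms, "pwv_arm_data")) test_arms$arms else test_arms
  rows <- purrr::map(names(bundles), function(d) {
    arm <- arms[[d]]
    if (is.null(arm) || length(arm$y) == 0) {
      return(tibble::tibble(drug = d, r2 = NA_real_, mse = NA_real_,
                            n_test = 0L))
    }
    yhat <- predict(bundles[[d]], arm$x)
    r2 <- if (length(arm$y) >= 2 && stats::var(arm$y) > 0) {
      r_squared(arm$y, yhat)
    } else NA_real_
    tibble::tibble(drug = d, r2 = r2, mse = mse(arm$y, yhat),
                   n_test = length(arm$y))
  })
  report <- dplyr::bind_rows(rows)
  structure(report, scheme = scheme,
            class = c("pwv_validation_report", class(report)))
}

#' @export
print.pwv_validation_report <- function(x, ...) {
  cat("<pwv_validation_report>", attr(x, "scheme"), "validation\n")
  NextMethod()
}
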