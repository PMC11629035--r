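# Per-arm random-forest outcome models: fitting, dual importance measures,
# top-k feature reduction, and counterfactual prediction across all arms.

#' Default ensemble hyperparameters
#'
#' @param n_trees Number of trees per forest.
#' @param mtry_frac Fraction of features tried per split (regression
#'   convention p/3); at least one feature.
#' @param min_node_size Minimal node size of the regression trees.
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function(n_trees = 300, mtry_frac = 1 / 3,
                                min_node_size = 5) {
  list(n_trees = n_trees, mtry_frac = mtry_frac,
       min_node_size = min_node_size)
}

#' Fit one arm's outcome ensemble
#'
#' Fits a bagged regression forest (feature-subsampled splits, bootstrap
#' resampling) predicting the standardized PWV change of the patients in one
#' drug arm. A degenerate, constant target yields a constant predictor with
#' a warning rather than an error.
#'
#' @param data A `pwv_arm_dataset` (see [build_arm_datasets()]).
#' @param hyperparams See [default_hyperparams()].
#' @param seed Integer seed; fits are reproducible.
#' @return Object of class `pwv_arm_model`: the fitted ensemble plus the
#'   feature names and training metadata.
#' @export
fit_arm_model <- function(data, hyperparams = default_hyperparams(),
                          seed = 1) {
  stopifnot(inherits(data, "pwv_arm_dataset"))
  if (hyperparams$n_trees < 1) stop("n_trees must be >= 1.", call. = FALSE)
  p <- ncol(data$x)
  if (stats::var(data$y) == 0) {
    warning("Constant target in arm ", data$drug,
            "; returning a constant predictor.", call. = FALSE)
    fit <- NULL
  } else {
    fit <- ranger::ranger(
      x = as.data.frame(data$x), y = data$y,
      num.trees = hyperparams$n_trees,
      mtry = max(1L, floor(p * hyperparams$mtry_frac)),
      min.node.size = hyperparams$min_node_size,
      importance = "impurity",
      seed = seed,
      num.threads = 1
    )
  }
  structure(
    list(drug = data$drug, fit = fit,
         constant = if (is.null(fit)) data$y[1] else NULL,
         feature_names = data$feature_names,
         n = length(data$y), hyperparams = hyperparams, seed = seed),
    class = "pwv_arm_model"
  )
}

#' @export
predict.pwv_arm_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0) {
    stop("Arm ", object$drug, ": missing feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(object$fit)) {
    return(rep(object$constant, nrow(newdata)))
  }
  newdata <- as.data.frame(newdata)[object$feature_names]
  stats::predict(object$fit, data = newdata, num.threads = 1)$predictions
}

#' Mean-decrease-in-impurity feature importance
#'
#' Variance-reduction credit each feature accumulates over the ensemble's
#' splits, normalized to sum to one.
#'
#' @param model A fitted `pwv_arm_model`.
#' @return Named numeric vector over the model's features, summing to 1.
#' @export
mdi_importance <- function(model) {
  stopifnot(inherits(model, "pwv_arm_model"))
  if (is.null(model$fit)) {
    stop("Constant predictor has no split-based importance.", call. = FALSE)
  }
  imp <- ranger::importance(model$fit)
  total <- sum(imp)
  if (total <= 0) {
    # forest made no informative splits: spread credit uniformly
    return(stats::setNames(rep(1 / length(imp), length(imp)), names(imp)))
  }
  imp / total
}

#' Permutation feature importance
#'
#' Mean increase in squared-error loss when one feature column is shuffled,
#' over `n_repeats` independent shuffles; the baseline error is computed
#' once. A feature the ensemble never uses scores exactly zero. Unlike
#' impurity credit, this measure does not favor features with many distinct
#' values.
#'
#' @param model A fitted `pwv_arm_model`.
#' @param x,y Evaluation data (training partition by default usage).
#' @param n_repeats Number of shuffles per feature.
#' @param seed Integer seed for the shuffles.
#' @return Named numeric vector of importance scores (loss increase).
#' @export
permutation_importance <- function(model, x, y, n_repeats = 10, seed = 1) {
  stopifnot(inherits(model, "pwv_arm_model"), n_repeats >= 1)
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) {
    stop("`x` and `y` lengths differ.", call. = FALSE)
  }
  baseline <- mean((y - predict(model, x))^2)
  n <- nrow(x)
  local_seed_eval(seed, {
    scores <- purrr::map_dbl(model$feature_names, function(f) {
      # one batched predict over all repeats of this feature's shuffle
      big <- x[rep(seq_len(n), n_repeats), , drop = FALSE]
      perm <- unlist(lapply(seq_len(n_repeats), function(r) sample.int(n)))
      big[[f]] <- x[[f]][perm]
      pred <- predict(model, big)
      errs <- (rep(y, n_repeats) - pred)^2
      mean(colMeans(matrix(errs, nrow = n)) - baseline)
    })
    stats::setNames(scores, model$feature_names)
  })
}

#' Consensus importance table for one arm
#'
#' Combines the impurity and permutation importances into one table with
#' per-measure ranks and a consensus rank (mean of the two ranks; ties
#' broken by the better impurity rank, then feature name).
#'
#' @param mdi Named impurity scores, see [mdi_importance()].
#' @param perm Named permutation scores, see [permutation_importance()].
#' @return Tibble with columns `feature`, `mdi_score`, `perm_score`,
#'   `mdi_rank`, `perm_rank`, `consensus_rank`, sorted by consensus rank.
#' @export
importance_table <- function(mdi, perm) {
  stopifnot(setequal(names(mdi), names(perm)))
  perm <- perm[names(mdi)]
  tab <- tibble::tibble(
    feature = names(mdi),
    mdi_score = unname(mdi),
    perm_score = unname(perm),
    mdi_rank = rank(-unname(mdi), ties.method = "min"),
    perm_rank = rank(-unname(perm), ties.method = "min")
  )
  tab$mean_rank <- (tab$mdi_rank + tab$perm_rank) / 2
  ord <- order(tab$mean_rank, tab$mdi_rank, tab$feature)
  tab <- tab[ord, ]
  tab$consensus_rank <- seq_len(nrow(tab))
  tab$mean_rank <- NULL
  tab
}

#' Select the top-k features of an importance table
#'
#' @param importances Tibble from [importance_table()], or a named numeric
#'   vector (single-measure selection).
#' @param k Number of features to keep (default 10); `min(k, p)` returned.
#' @param measure For a table: `"consensus"` (default), `"mdi"`, or
#'   `"permutation"`.
#' @return Character vector of selected feature names, best first.
#' @export
select_top_features <- function(importances, k = 10,
                                measure = c("consensus", "mdi", "permutation")) {
  stopifnot(k >= 1)
  if (is.numeric(importances) && !is.null(names(importances))) {
    ord <- order(-importances, names(importances))
    return(names(importances)[ord][seq_len(min(k, length(importances)))])
  }
  measure <- match.arg(measure)
  tab <- switch(measure,
    consensus = importances[order(importances$consensus_rank), ],
    mdi = importances[order(importances$mdi_rank, importances$feature), ],
    permutation = importances[order(importances$perm_rank,
                                    importances$mdi_rank,
                                    importances$feature), ]
  )
  tab$feature[seq_len(min(k, nrow(tab)))]
}

#' Refit an arm model on a reduced feature set
#'
#' @param data A `pwv_arm_dataset`.
#' @param features Feature names to retain; must be a subset of the data's
#'   features and nonempty.
#' @param hyperparams,seed As in [fit_arm_model()].
#' @return Object of class `pwv_arm_bundle`: the reduced-feature ensemble,
#'   its `selected_features`, and training metadata.
#' @export
refit_reduced <- function(data, features,
                          hyperparams = default_hyperparams(), seed = 1) {
  stopifnot(inherits(data, "pwv_arm_dataset"))
  if (length(features) == 0) {
    stop("Empty feature list for arm ", data$drug, ".", call. = FALSE)
  }
  missing_cols <- setdiff(features, data$feature_names)
  if (length(missing_cols) > 0) {
    stop("Unknown feature(s) for arm ", data$drug, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reduced <- structure(
    list(drug = data$drug,
         x = data$x[, features, drop = FALSE],
         y = data$y,
         patient_ids = data$patient_ids,
         feature_names = features),
    class = "pwv_arm_dataset"
  )
  model <- fit_arm_model(reduced, hyperparams = hyperparams, seed = seed)
  structure(
    list(drug = data$drug, model = model, selected_features = features,
         n = length(data$y), hyperparams = hyperparams, seed = seed),
    class = "pwv_arm_bundle"
  )
}

#' @export
predict.pwv_arm_bundle <- function(object, newdata, ...) {
  predict(object$model, newdata)
}

#' Fit, select, and refit all arm models
#'
#' Runs the full per-arm chain on every arm dataset: fit the full-feature
#' ensemble, compute impurity and permutation importances, select the top-k
#' features by consensus rank, and refit on the reduced feature set.
#'
#' @param arm_data A `pwv_arm_data` object (or its `arms` list).
#' @param hyperparams See [default_hyperparams()].
#' @param k_features Features retained per arm (default 10).
#' @param n_repeats Shuffles for the permutation importance.
#' @param measure Importance measure used for selection, see
#'   [select_top_features()].
#' @param seed Master seed; per-arm seeds are derived deterministically.
#' @return Object of class `pwv_bundles`: named list `bundles` over arms,
#'   plus `importance` (named list of importance tables) and the settings.
#' @export
fit_arm_bundles <- function(arm_data,
                            hyperparams = default_hyperparams(),
                            k_features = 10, n_repeats = 10,
                            measure = "consensus", seed = 1) {
  arms <- if (inherits(arm_data, "pwv_arm_data")) arm_data$arms else arm_data
  bundles <- list()
  importance <- list()
  for (i in seq_along(arms)) {
    arm <- arms[[i]]
    arm_seed <- seed + 1000L * i
    full <- fit_arm_model(arm, hyperparams = hyperparams, seed = arm_seed)
    mdi <- mdi_importance(full)
    perm <- permutation_importance(full, arm$x, arm$y,
                                   n_repeats = n_repeats,
                                   seed = arm_seed + 1L)
    tab <- importance_table(mdi, perm)
    sel <- select_top_features(tab, k = k_features, measure = measure)
    bundles[[arm$drug]] <- refit_reduced(arm, sel, hyperparams = hyperparams,
                                         seed = arm_seed + 2L)
    importance[[arm$drug]] <- tab
  }
  structure(
    list(bundles = bundles, importance = importance,
         k_features = k_features, hyperparams = hyperparams,
         measure = measure, seed = seed),
    class = "pwv_bundles"
  )
}

#' Counterfactual predictions for every arm
#'
#' Queries each arm's reduced-feature ensemble on the same patients,
#' producing the n x 6 matrix of predicted standardized PWV changes that the
#' recommender maximizes over. Columns follow the canonical
#' [drug_classes()] order.
#'
#' @param bundles A `pwv_bundles` object or named list of `pwv_arm_bundle`.
#' @param newdata Feature table containing every bundle's selected features.
#' @return Numeric matrix (patients x arms) of predicted standardized PWV
#'   reductions; arms without a fitted bundle are `NA`.
#' @export
predict_all_arms <- function(bundles, newdata) {
  if (inherits(bundles, "pwv_bundles")) bundles <- bundles$bundles
  classes <- drug_classes()
  out <- matrix(NA_real_, nrow(newdata), length(classes),
                dimnames = list(NULL, classes))
  for (d in names(bundles)) {
    out[, d] <- predict(bundles[[d]], newdata)
  }
  if (any(!is.finite(out[, names(bundles), drop = FALSE]))) {
    stop("Non-finite counterfactual prediction produced.", call. = FALSE)
  }
  out
}

#' @export
print.pwv_bundles <- function(x, ...) {
  cat("<pwv_bundles>", length(x$bundles), "arm models,",
      x$k_features, "features each (", x$measure, "selection )\n")
  for (b in x$bundles) {
    cat(sprintf("  %-8s n = %-4d features: %s\n", b$drug, b$n,
                paste(utils::head(b$selected_features, 4), collapse = ", ")))
  }
  invisible(x)
}
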