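# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-arm importance tables of fitted bundles
#'
#' @param x A `pwv_bundles` object.
#' @param ... Unused.
#' @return Tibble with one row per (drug, feature): both importance scores,
#'   their ranks, the consensus rank, and whether the feature was selected
#'   into the reduced model.
#' @export
tidy.pwv_bundles <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$importance, function(tab, arm_name) {
    sel <- x$bundles[[arm_name]]$selected_features
    tab |>
      dplyr::mutate(drug = arm_name, selected = .data$feature %in% sel) |>
      dplyr::relocate("drug")
  }))
}

#' One-row-per-arm summary of fitted bundles
#'
#' @param x A `pwv_bundles` object.
#' @param ... Unused.
#' @return Tibble with `drug`, training size `n`, number of selected
#'   features, and the out-of-bag R^2 and MSE of the reduced forest.
#' @export
glance.pwv_bundles <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$bundles, function(b) {
    fit <- b$model$fit
    tibble::tibble(
      drug = b$drug, n = b$n,
      n_features = length(b$selected_features),
      oob_r2 = if (is.null(fit)) NA_real_ else fit$r.squared,
      oob_mse = if (is.null(fit)) NA_real_ else fit$prediction.error
    )
  }))
}

#' Tidy the node table of a surrogate tree
#'
#' @param x A `pwv_surrogate` object.
#' @param ... Unused.
#' @return The node tibble (one row per node).
#' @export
tidy.pwv_surrogate <- function(x, ...) x$nodes

#' One-row summary of a surrogate tree
#'
#' @param x A `pwv_surrogate` object.
#' @param ... Unused.
#' @return Tibble with node/leaf counts, realized depth, and settings.
#' @export
glance.pwv_surrogate <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_leaves = sum(x$nodes$is_leaf),
    depth = max(x$nodes$depth),
    max_depth = x$max_depth,
    gini_stop = x$gini_stop
  )
}

#' Tidy a validation report
#'
#' @param x A `pwv_validation_report`.
#' @param ... Unused.
#' @return Tibble with `scheme`, `drug`, `r2`, `mse`, `n_test`.
#' @export
tidy.pwv_validation_report <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), scheme = attr(x, "scheme")) |>
    dplyr::relocate("scheme")
}

#' One-row summary of a full pipeline run
#'
#' @param x A `pwv_pipeline` object.
#' @param ... Unused.
#' @return Tibble with the scheme, cohort size, mean per-arm validation
#'   R^2 / MSE, overall match rate, and surrogate fidelity.
#' @export
glance.pwv_pipeline <- function(x, ...) {
  tibble::tibble(
    scheme = x$config$scheme,
    n_patients = nrow(x$recommendations),
    mean_r2 = mean(x$validation$r2, na.rm = TRUE),
    mean_mse = mean(x$validation$mse, na.rm = TRUE),
    match_rate = x$match$overall,
    surrogate_fidelity = x$fidelity[["in_sample"]]
  )
}
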