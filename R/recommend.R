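# Argmax treatment recommendation over the six counterfactual predictions,
# with match-rate and distribution summaries.

#' Recommend the drug with the largest predicted PWV reduction
#'
#' For each patient, takes the argmax over the six predicted standardized
#' PWV changes. Ties are broken towards the canonical [drug_classes()]
#' order (first maximal column). With `require_benefit = TRUE`, patients
#' whose best predicted change is not positive get `NA` instead of a
#' recommendation.
#'
#' @param predictions n x 6 matrix from [predict_all_arms()] (canonical
#'   column order).
#' @param actual_drugs Optional character vector of the drugs the patients
#'   actually took; enables the `match` flag.
#' @param patient_ids Optional patient identifiers.
#' @param require_benefit Require a predicted reduction > 0 to recommend.
#' @return Tibble of class `pwv_recommendations`: one row per patient with
#'   `pred_<drug>` columns, `recommended_drug`, `predicted_best_reduction`,
#'   and (when known) `actual_drug` and `match`.
#' @export
recommend <- function(predictions, actual_drugs = NULL, patient_ids = NULL,
                      require_benefit = FALSE) {
  classes <- drug_classes()
  predictions <- as.matrix(predictions)[, classes, drop = FALSE]
  bad <- which(!is.finite(predictions), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("Non-finite prediction for patient row(s): ",
         paste(unique(bad[, 1]), collapse = ", "), call. = FALSE)
  }
  best_col <- max.col(predictions, ties.method = "first")
  best_val <- predictions[cbind(seq_len(nrow(predictions)), best_col)]
  recommended <- classes[best_col]
  if (require_benefit) recommended[best_val <= 0] <- NA_character_

  out <- tibble::as_tibble(predictions, .name_repair = "minimal")
  names(out) <- paste0("pred_", classes)
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = patient_ids %||%
                     sprintf("row%05d", seq_len(nrow(predictions)))),
    out,
    tibble::tibble(recommended_drug = recommended,
                   predicted_best_reduction = best_val)
  )
  if (!is.null(actual_drugs)) {
    out$actual_drug <- actual_drugs
    out$match <- !is.na(recommended) & recommended == actual_drugs
  }
  structure(out, class = c("pwv_recommendations", class(out)))
}

#' Per-drug and overall match rates
#'
#' The match rate of drug `d` is the fraction of patients actually on `d`
#' for whom the system also recommends `d`. Arms absent from the actual
#' prescriptions are reported with `NA`.
#'
#' @param recs A `pwv_recommendations` tibble carrying `actual_drug`.
#' @return List with `per_drug` (tibble: `drug`, `n`, `n_match`, `rate`)
#'   and `overall` (single fraction).
#' @export
match_rate <- function(recs) {
  if (!"actual_drug" %in% names(recs)) {
    stop("Recommendations carry no actual drugs.", call. = FALSE)
  }
  per_drug <- tibble::tibble(drug = drug_classes()) |>
    dplyr::left_join(
      recs |>
        dplyr::group_by(drug = .data$actual_drug) |>
        dplyr::summarise(n = dplyr::n(), n_match = sum(.data$match)),
      by = "drug"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  n_match = dplyr::coalesce(.data$n_match, 0L),
                  rate = ifelse(.data$n > 0, .data$n_match / .data$n,
                                NA_real_))
  list(per_drug = per_drug, overall = mean(recs$match))
}

#' Distribution of recommendations over drugs
#'
#' @param recs A `pwv_recommendations` tibble.
#' @return Tibble with `drug`, `n`, and `share` (shares sum to 1 over
#'   non-missing recommendations).
#' @export
recommendation_distribution <- function(recs) {
  if (nrow(recs) == 0) stop("Empty recommendation set.", call. = FALSE)
  done <- recs[!is.na(recs$recommended_drug), ]
  tibble::tibble(drug = drug_classes()) |>
    dplyr::left_join(dplyr::count(done, drug = .data$recommended_drug),
                     by = "drug") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  share = .data$n / nrow(done))
}
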