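# SMOTE-style synthetic oversampling of the per-arm training datasets.
#
# SMOTE is defined for classification; here the drug class plays the role of
# the class label and the interpolation acts on the joint (features, target)
# vector, so the synthetic target inherits the same convex combination and
# the local feature-outcome relationship is preserved.

#' Plan augmented per-arm training counts
#'
#' Chooses per-arm target counts so that the total training size is about
#' four times the external test size (an 80%/20% train/test balance),
#' distributed over arms proportionally to the current arm sizes. No arm is
#' ever planned below its current size.
#'
#' @param train_counts Named integer vector of current per-arm training
#'   sizes.
#' @param test_n External test-set size; must be positive.
#' @return Named integer vector of per-arm target counts.
#' @export
plan_external_counts <- function(train_counts, test_n) {
  stopifnot(test_n > 0, length(train_counts) > 0)
  total_target <- max(sum(train_counts), round(4 * test_n))
  shares <- train_counts / sum(train_counts)
  planned <- round(shares * total_target)
  pmax(planned, train_counts)
}

#' SMOTE-style augmentation of per-arm datasets
#'
#' Enlarges each arm's dataset to `target_counts[arm]` by interpolating
#' between same-arm points: a synthetic sample is
#' `parent + u * (neighbor - parent)` with `u ~ Uniform[0, 1]`, applied
#' coordinate-wise to the joint (features, target) vector, where the
#' neighbor is one of the parent's `k_neighbors` nearest same-arm points
#' (Euclidean distance on z-scored features). Original rows are preserved
#' unchanged; binary 0/1 features are thresholded back to 0/1 at 0.5.
#'
#' @param arm_data A `pwv_arm_data` object or named list of
#'   `pwv_arm_dataset`.
#' @param k_neighbors Neighborhood size; every augmented arm must have more
#'   points than `k_neighbors`.
#' @param target_counts Named integer vector of desired per-arm sizes;
#'   defaults to current sizes (no-op).
#' @param seed Integer seed; neighbor choices and interpolation draws are
#'   reproducible.
#' @param schema Covariate schema used to identify binary features; pass
#'   `NULL` to skip thresholding.
#' @return List with `arms` (augmented named list of `pwv_arm_dataset`) and
#'   `provenance` (tibble: `drug`, `synthetic_id`, `parent_id`,
#'   `neighbor_id`, `u`). Synthetic patients get ids `<drug>_syn<k>`.
#' @export
smote_augment <- function(arm_data, k_neighbors = 5, target_counts = NULL,
                          seed = 1, schema = feature_schema()) {
  arms <- if (inherits(arm_data, "pwv_arm_data")) arm_data$arms else arm_data
  current <- purrr::map_int(arms, ~ length(.x$y))
  if (is.null(target_counts)) target_counts <- current
  if (any(target_counts[names(arms)] < current)) {
    stop("target_counts below current arm size; augmentation only adds.",
         call. = FALSE)
  }
  binary_cols <- if (is.null(schema)) character(0) else
    schema$name[schema$kind == "binary"]

  provenance <- list()
  out <- arms
  local_seed_eval(seed, {
    for (d in names(arms)) {
      n_new <- target_counts[[d]] - current[[d]]
      if (n_new == 0) next
      arm <- arms[[d]]
      n <- length(arm$y)
      if (n <= k_neighbors) {
        stop("Arm ", d, " has ", n, " points but k_neighbors = ",
             k_neighbors, "; use a smaller k.", call. = FALSE)
      }
      # z-score features for the distance computation only
      xm <- as.matrix(arm$x)
      mu <- colMeans(xm)
      sdv <- apply(xm, 2, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      z <- sweep(sweep(xm, 2, mu), 2, sdv, `/`)
      dmat <- as.matrix(stats::dist(z))
      diag(dmat) <- Inf
      nn <- t(apply(dmat, 1, function(row) order(row)[seq_len(k_neighbors)]))

      joint <- cbind(xm, .target = arm$y)
      seeds_idx <- sample.int(n, n_new, replace = TRUE)
      nbr_pick <- sample.int(k_neighbors, n_new, replace = TRUE)
      u <- stats::runif(n_new)
      nbr_idx <- nn[cbind(seeds_idx, nbr_pick)]
      syn <- joint[seeds_idx, , drop = FALSE] +
        u * (joint[nbr_idx, , drop = FALSE] - joint[seeds_idx, , drop = FALSE])

      syn_x <- tibble::as_tibble(syn[, colnames(xm), drop = FALSE])
      for (b in intersect(binary_cols, names(syn_x))) {
        syn_x[[b]] <- as.numeric(syn_x[[b]] >= 0.5)
      }
      syn_ids <- sprintf("%s_syn%04d", d, seq_len(n_new))

      out[[d]] <- structure(
        list(drug = d,
             x = dplyr::bind_rows(arm$x, syn_x),
             y = c(arm$y, unname(syn[, ".target"])),
             patient_ids = c(arm$patient_ids, syn_ids),
             feature_names = arm$feature_names),
        class = "pwv_arm_dataset"
      )
      provenance[[d]] <- tibble::tibble(
        drug = d,
        synthetic_id = syn_ids,
        parent_id = arm$patient_ids[seeds_idx],
        neighbor_id = arm$patient_ids[nbr_idx],
        u = u
      )
    }
  })
  list(arms = out,
       provenance = if (length(provenance) > 0) {
         dplyr::bind_rows(provenance)
       } else {
         tibble::tibble(drug = character(), synthetic_id = character(),
                        parent_id = character(), neighbor_id = character(),
                        u = numeric())
       })
}
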