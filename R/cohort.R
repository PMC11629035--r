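# Synthetic multicohort generator with known treatment-effect functions.

# Evaluate code under a temporary RNG state so generator calls do not
# disturb the caller's random stream.
local_seed_eval <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Truncated normal draw via inverse-CDF so a single runif stream drives it.
# The location parameter is corrected so the *truncated* mean equals the
# requested mean: one-sided truncation (e.g. a zero floor on a skewed
# biomarker) would otherwise bias the marginal upwards.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- if (abs(trunc_mean(mean) - mean) < 1e-9 * sd) mean else {
    stats::uniroot(function(m) trunc_mean(m) - mean,
                   lower = mean - 6 * sd, upper = mean + 6 * sd,
                   tol = 1e-9 * sd)$root
  }
  p_lo <- stats::pnorm(lo, mu, sd)
  p_hi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mu, sd)
}

#' Brachial-ankle pulse wave velocity from height and transit time
#'
#' Estimates baPWV from standing height and the arm-to-ankle pulse transit
#' time using the regression-calibrated path-length formula
#' \eqn{baPWV = (0.5934 \times height_{cm} + 14.4724) / t_{ba}} (cm/s),
#' returned in m/s.
#'
#' @param height_cm Standing height in cm; must lie in (100, 230).
#' @param tba_s Arm-to-ankle pulse transit time in seconds; must be > 0.
#' @return baPWV in m/s (vectorized).
#' @export
#' @examples
#' compute_bapwv(170, 0.08) # ~14.42 m/s
compute_bapwv <- function(height_cm, tba_s) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 100) || any(height_cm >= 230)) {
    stop("`height_cm` must be finite and in (100, 230).", call. = FALSE)
  }
  if (any(!is.finite(tba_s)) || any(tba_s <= 0)) {
    stop("`tba_s` must be finite and positive.", call. = FALSE)
  }
  ((0.5934 * height_cm + 14.4724) / tba_s) / 100
}

#' Generate a synthetic hypertensive multicohort with known effects
#'
#' Draws `n` patients with the 64 candidate covariates of [feature_schema()]
#' (independent truncated Gaussians / Bernoullis at the schema moments),
#' assigns each to one of six antihypertensive classes, and produces baseline
#' and >= 1-year follow-up carotid-femoral and brachial-ankle PWV where the
#' raw-scale change equals a known drug-specific effect function plus noise:
#' `followup = baseline - g_d(x) - eps`, `eps ~ N(0, noise_sd)` independently
#' per modality. Positive `g_d` therefore means PWV reduction (benefit).
#'
#' Baseline PWV covariate columns (`cfpwv`, `bapwv`) are duplicated into the
#' outcome columns `cfpwv_baseline` / `bapwv_baseline`: the covariate copy is
#' a model feature (and may later be masked by [inject_missingness()]); the
#' outcome copy is never masked. Baseline PWV is drawn truncated to
#' [5, 30] m/s so that follow-up values remain physiological even for large
#' simulated reductions.
#'
#' @param n Number of patients; must allow every arm a realistic chance of
#'   reaching `min_per_arm`.
#' @param schema Covariate schema tibble, see [feature_schema()].
#' @param effect_config Per-arm effect functions, see
#'   [default_effect_config()]. Modifier names must be schema covariates.
#' @param noise_sd SD (m/s) of the additive error on each modality's change.
#' @param assignment_probs Named multinomial probabilities over
#'   [drug_classes()]; renormalized if needed.
#' @param cohort_probs Named probabilities over [cohort_labels()].
#' @param cohort_shift_sd Mean shift, in covariate SDs, applied to all
#'   continuous covariates of EVIDENT-labelled patients. Emulates a
#'   distributional shift of the external-validation cohort; default 0.
#' @param age_tilt Strength of a logistic tilt of assignment towards
#'   combination therapy with age (0 = randomized-like multinomial).
#' @param min_per_arm Minimum arm occupancy the generated cohort must reach.
#' @param seed Integer seed; identical inputs give identical cohorts.
#' @return A list with `cohort` (tibble, one row per patient) and `truth`
#'   (object of class `pwv_truth` holding the effect functions, the n x 6
#'   true-effect matrix in m/s, the oracle policy, and the generator
#'   configuration).
#' @export
#' @examples
#' sim <- generate_cohort(n = 194, seed = 1)
#' dplyr::count(sim$cohort, drug_class)
generate_cohort <- function(n,
                            schema = feature_schema(),
                            effect_config = default_effect_config(),
                            noise_sd = 0.2,
                            assignment_probs = default_assignment_probs(),
                            cohort_probs = default_cohort_probs(),
                            cohort_shift_sd = 0,
                            age_tilt = 0,
                            min_per_arm = 2,
                            seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  classes <- drug_classes()
  unknown <- setdiff(unlist(purrr::map(effect_config, "modifiers")), schema$name)
  if (length(unknown) > 0) {
    stop("effect_config names unknown covariates: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(effect_config), classes)) {
    stop("effect_config must define all six drug classes.", call. = FALSE)
  }
  if (n < 6 * min_per_arm) {
    stop("`n` too small to populate all six arms at min_per_arm = ",
         min_per_arm, ".", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  assignment_probs <- assignment_probs[classes] / sum(assignment_probs[classes])

  local_seed_eval(seed, {
    cohort_id <- sample(cohort_labels(), n, replace = TRUE,
                        prob = cohort_probs[cohort_labels()])

    feats <- purrr::pmap(schema, function(name, kind, units, mean, sd, lo, hi) {
      if (kind == "binary") {
        stats::rbinom(n, 1, mean)
      } else if (name %in% c("cfpwv", "bapwv")) {
        rtruncnorm(n, mean, sd, max(lo, 5), hi)
      } else {
        rtruncnorm(n, mean, sd, lo, hi)
      }
    })
    names(feats) <- schema$name
    features <- tibble::as_tibble(feats)

    if (cohort_shift_sd != 0) {
      shift_cols <- schema$name[schema$kind == "continuous"]
      is_ev <- cohort_id == "EVIDENT"
      for (j in shift_cols) {
        s <- schema$sd[schema$name == j]
        features[[j]][is_ev] <- pmin(
          features[[j]][is_ev] + cohort_shift_sd * s,
          schema$hi[schema$name == j]
        )
      }
    }

    g <- true_effect_matrix(effect_config, features, schema)

    if (age_tilt != 0) {
      z_age <- (features$age - schema$mean[schema$name == "age"]) /
        schema$sd[schema$name == "age"]
      tilt <- c(ACEI = -1, ARB = -0.5, BB = 0, DIU = 0.5,
                DIU_ACEI = 1, DIU_ARB = 1.5) * age_tilt
      w <- exp(outer(z_age, tilt))
      w <- sweep(w, 2, assignment_probs, `*`)
      w <- w / rowSums(w)
      drug <- vapply(seq_len(n), function(i) {
        sample(classes, 1, prob = w[i, ])
      }, character(1))
    } else {
      drug <- sample(classes, n, replace = TRUE, prob = assignment_probs)
    }
    if (any(table(factor(drug, levels = classes)) < min_per_arm)) {
      stop("Generated cohort left an arm below min_per_arm; increase `n`.",
           call. = FALSE)
    }

    g_assigned <- g[cbind(seq_len(n), match(drug, classes))]
    eps_cf <- stats::rnorm(n, 0, noise_sd)
    eps_ba <- stats::rnorm(n, 0, noise_sd)

    patient_id <- sprintf("P%05d", seq_len(n))
    cohort <- dplyr::bind_cols(
      tibble::tibble(patient_id = patient_id,
                     cohort_id = cohort_id,
                     drug_class = drug),
      features,
      tibble::tibble(
        cfpwv_baseline = features$cfpwv,
        bapwv_baseline = features$bapwv,
        cfpwv_followup = features$cfpwv - g_assigned - eps_cf,
        bapwv_followup = features$bapwv - g_assigned - eps_ba,
        followup_years = round(stats::runif(n, 1, 2), 2)
      )
    )

    rownames(g) <- patient_id
    truth <- structure(
      list(
        effect_config = effect_config,
        schema = schema,
        noise_sd = noise_sd,
        assignment_probs = assignment_probs,
        effects = g,
        oracle_policy = tibble::tibble(
          patient_id = patient_id,
          oracle_drug = classes[max.col(g, ties.method = "first")]
        )
      ),
      class = "pwv_truth"
    )
    list(cohort = cohort, truth = truth)
  })
}

#' True per-arm effect matrix for arbitrary covariate values
#'
#' Evaluates the synthetic-truth effect functions `g_d` on a feature table:
#' each arm's effect is its base reduction plus a linear index over z-scored
#' effect modifiers. Used to verify oracle policies and to score
#' counterfactual recovery against the ground truth.
#'
#' @param config A `pwv_truth` object or a raw effect-config list.
#' @param features Tibble/data frame containing the modifier columns.
#' @param schema Covariate schema (ignored when `config` is a `pwv_truth`,
#'   which carries its own).
#' @return Numeric matrix, rows = patients, columns = [drug_classes()],
#'   entries in m/s of true PWV reduction.
#' @export
true_effect_matrix <- function(config, features,
                               schema = feature_schema()) {
  if (inherits(config, "pwv_truth")) {
    schema <- config$schema
    config <- config$effect_config
  }
  classes <- drug_classes()
  g <- matrix(0, nrow(features), length(classes),
              dimnames = list(NULL, classes))
  for (d in classes) {
    cfg <- config[[d]]
    idx <- rep(cfg$base, nrow(features))
    for (k in seq_along(cfg$modifiers)) {
      m <- cfg$modifiers[k]
      mu <- schema$mean[schema$name == m]
      s <- schema$sd[schema$name == m]
      idx <- idx + cfg$coefficients[k] * (features[[m]] - mu) / s
    }
    g[, d] <- idx
  }
  g
}

#' Spread of the true effects
#'
#' Standard deviation of all entries of the true-effect matrix; the
#' simulation studies express noise levels relative to this spread.
#'
#' @param truth A `pwv_truth` object.
#' @return A single number (m/s).
#' @export
effect_spread <- function(truth) stats::sd(as.vector(truth$effects))

#' Inject completely-at-random missingness into the covariates
#'
#' Masks each covariate cell independently with probability `rate`. Outcome
#' columns (`*_baseline`, `*_followup`, `followup_years`), identifiers and
#' the drug class are never masked.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed for the mask.
#' @param schema Covariate schema naming the maskable columns.
#' @return The cohort with `NA`s injected into covariate columns.
#' @export
inject_missingness <- function(cohort, rate, seed = NULL,
                               schema = feature_schema()) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1) {
    stop("`rate` must be a single number in [0, 1).", call. = FALSE)
  }
  if (rate == 0) return(cohort)
  cols <- intersect(schema$name, names(cohort))
  local_seed_eval(seed, {
    for (j in cols) {
      mask <- stats::runif(nrow(cohort)) < rate
      cohort[[j]][mask] <- NA
    }
    cohort
  })
}

#' Write / read a cohort with its truth sidecar
#'
#' `write_cohort()` saves the cohort as plain CSV plus a JSON sidecar holding
#' the generator configuration and oracle policy; `read_cohort()` restores
#' both.
#'
#' @param sim List with `cohort` and `truth` as returned by
#'   [generate_cohort()].
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>_truth.json`.
#' @return `write_cohort()` returns the paths invisibly; `read_cohort()`
#'   returns a list with `cohort` and `truth` (truth is `NULL` when no
#'   sidecar exists).
#' @export
write_cohort <- function(sim, prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, "_truth.json")
  utils::write.csv(sim$cohort, csv, row.names = FALSE)
  truth <- sim$truth
  payload <- list(
    effect_config = truth$effect_config,
    noise_sd = truth$noise_sd,
    assignment_probs = as.list(truth$assignment_probs),
    oracle_policy = truth$oracle_policy,
    effects = as.data.frame(truth$effects),
    schema = truth$schema
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA)
  invisible(c(cohort = csv, truth = js))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, "_truth.json")
  cohort <- tibble::as_tibble(utils::read.csv(csv, stringsAsFactors = FALSE))
  truth <- NULL
  if (file.exists(js)) {
    raw <- jsonlite::read_json(js, simplifyVector = TRUE)
    effects <- as.matrix(raw$effects)
    rownames(effects) <- raw$oracle_policy$patient_id
    truth <- structure(
      list(
        effect_config = purrr::map(raw$effect_config, function(cfg) {
          list(modifiers = cfg$modifiers,
               coefficients = as.numeric(cfg$coefficients),
               base = cfg$base)
        }),
        schema = tibble::as_tibble(raw$schema),
        noise_sd = raw$noise_sd,
        assignment_probs = unlist(raw$assignment_probs),
        effects = effects,
        oracle_policy = tibble::as_tibble(raw$oracle_policy)
      ),
      class = "pwv_truth"
    )
  }
  list(cohort = cohort, truth = truth)
}

#' @export
print.pwv_truth <- function(x, ...) {
  cat("<pwv_truth> synthetic treatment-effect ground truth\n")
  cat("  patients:", nrow(x$effects), " noise_sd:", x$noise_sd, "m/s\n")
  cat("  effect spread:", round(effect_spread(x), 3), "m/s\n")
  invisible(x)
}
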