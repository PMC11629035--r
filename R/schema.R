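#' Canonical antihypertensive drug classes
#'
#' The six drug classes modelled by the package, in canonical order. All
#' matrices and recommendation vectors indexed by drug use this order;
#' argmax ties are broken towards the earlier class.
#'
#' @param include_other If `TRUE`, append the `"OTHER"` pseudo-class used for
#'   drugs outside the six modelled groups (calcium channel blockers,
#'   alpha-blockers, ...). `OTHER` is never modelled and is removed during
#'   eligibility filtering.
#' @return Character vector of drug-class codes.
#' @export
#' @examples
#' drug_classes()
drug_classes <- function(include_other = FALSE) {
  classes <- c("ACEI", "ARB", "BB", "DIU", "DIU_ACEI", "DIU_ARB")
  if (include_other) c(classes, "OTHER") else classes
}

#' Cohort labels of the pooled multicohort design
#'
#' @return Character vector: `"EVA"`, `"LOD"`, `"EVIDENT"`.
#' @export
cohort_labels <- function() c("EVA", "LOD", "EVIDENT")

#' Candidate covariate schema for the hypertensive cohort
#'
#' Describes the 64 candidate covariates used throughout the pipeline:
#' demographics, lifestyle, concomitant medication, anthropometrics,
#' hemodynamic measurements (including baseline carotid-femoral and
#' brachial-ankle pulse wave velocity, which double as model features), and
#' biochemistry. Means and SDs are the marginal moments of a pooled
#' hypertensive primary-care population and drive the synthetic generator;
#' `lo`/`hi` give the physiologically admissible range used for truncation.
#'
#' @return A tibble with one row per covariate and columns `name`, `kind`
#'   (`"continuous"` or `"binary"`), `units`, `mean`, `sd`, `lo`, `hi`.
#'   Binary covariates store the prevalence in `mean` and `sd = NA`.
#' @export
#' @examples
#' sch <- feature_schema()
#' nrow(sch) # 64 candidate covariates
feature_schema <- function() {
  cont <- function(name, units, mean, sd, lo, hi) {
    tibble::tibble(name = name, kind = "continuous", units = units,
                   mean = mean, sd = sd, lo = lo, hi = hi)
  }
  bin <- function(name, prev) {
    tibble::tibble(name = name, kind = "binary", units = "0/1",
                   mean = prev, sd = NA_real_, lo = 0, hi = 1)
  }
  dplyr::bind_rows(
    # demographics
    cont("age", "years", 61.8, 10.0, 30, 95),
    bin("sex_male", 0.505),
    # lifestyle
    bin("smoking_current", 0.134),
    bin("smoking_former", 0.366),
    cont("cigarettes_day", "cigarettes/day", 5.75, 10.8, 0, 60),
    cont("alcohol_g_wk", "g/week", 55.5, 111.2, 0, 800),
    cont("medas", "score units", 7.4, 2.0, 0, 14),
    # concomitant medication
    bin("antidiabetics", 0.278),
    bin("lipid_lowering", 0.474),
    bin("antiaggregants", 0.222),
    bin("anticoagulants", 0.021),
    bin("nsaids", 0.005),
    # anthropometrics
    cont("height_cm", "cm", 162.5, 10.3, 130, 200),
    cont("weight_kg", "kg", 80.5, 15.3, 40, 160),
    cont("waist_cm", "cm", 102.6, 10.4, 60, 160),
    # hemodynamics / vascular
    cont("sbp", "mm Hg", 131.2, 16.4, 85, 220),
    cont("dbp", "mm Hg", 81.0, 11.4, 45, 130),
    cont("heart_rate", "beats/min", 69.7, 11.6, 35, 130),
    cont("abi", "ratio", 1.1, 0.1, 0.5, 1.6),
    cont("cfpwv", "m/s", 9.5, 2.6, 2, 30),
    cont("bapwv", "m/s", 14.2, 2.3, 2, 30),
    cont("cavi", "m/s", 8.3, 1.3, 4, 14),
    cont("aix75", "%", 30.8, 10.8, -10, 70),
    cont("imt", "mm", 0.7, 0.1, 0.3, 1.6),
    bin("imt_plaque", 0.211),
    cont("cornell_index", "mm", 15.1, 5.6, 1, 45),
    cont("lvh_cornell", "ms*mV", 1600.0, 610.6, 200, 4500),
    # hematology
    cont("red_blood_cells", "million/mm3", 4.8, 0.4, 3, 7),
    cont("hemoglobin", "g/dL", 14.5, 1.3, 9, 20),
    cont("hematocrit", "%", 43.3, 3.6, 28, 58),
    cont("mchc", "g/dL", 29.7, 2.2, 22, 38),
    cont("chbcm", "pg", 33.3, 0.9, 26, 40),
    cont("mcv", "fl", 89.2, 5.7, 65, 115),
    cont("anisocytosis", "%", 12.8, 1.2, 9, 20),
    cont("leukocytes", "million/mm3", 6.8, 1.9, 2, 16),
    cont("neutrophils", "million/mm3", 3.8, 1.3, 0.8, 12),
    cont("lymphocytes", "million/mm3", 2.2, 0.7, 0.4, 6),
    cont("monocytes", "million/mm3", 0.5, 0.1, 0.1, 1.5),
    cont("eosinophils", "million/mm3", 0.2, 0.1, 0, 1.2),
    cont("basophils", "million/mm3", 0.1, 0.1, 0, 0.6),
    cont("platelets", "1e9/L", 231.4, 59.5, 60, 500),
    cont("rdw", "%", 12.7, 0.9, 10, 20),
    cont("mpv", "fl", 9.4, 1.8, 5, 15),
    # glucose metabolism
    cont("fpg", "mg/100 mL", 101.7, 27.2, 50, 300),
    cont("hba1c", "%", 5.9, 0.8, 3.8, 13),
    cont("insulin", "mIU/L", 12.4, 7.6, 1, 60),
    # lipids
    cont("total_cholesterol", "mg/dL", 191.3, 32.5, 90, 350),
    cont("cldl", "mg/dL", 95.9, 38.1, 25, 280),
    cont("chdl", "mg/dL", 69.5, 34.3, 20, 250),
    cont("triglycerides", "mg/dL", 131.0, 61.5, 30, 500),
    # renal
    cont("uric_acid", "mg/dL", 5.7, 1.4, 1.5, 12),
    cont("serum_creatinine", "mg/dL", 0.8, 0.1, 0.3, 2),
    cont("creatinine_clearance", "ug/min", 117.0, 66.6, 10, 400),
    cont("microalbuminuria", "mg/day", 19.1, 48.7, 0, 400),
    cont("albumin_creatinine_ratio", "mg/g", 17.3, 39.0, 0, 400),
    cont("egfr", "mL/min/1.73m2", 85.2, 14.1, 25, 140),
    # hepatic
    cont("ast_got", "units/L", 23.6, 12.8, 5, 150),
    cont("alt_sgpt", "units/L", 26.6, 18.5, 5, 200),
    cont("ggt", "units/L", 32.9, 37.4, 4, 400),
    # inflammation / endocrine / vitamins
    cont("fibrinogen", "mg/dL", 344.0, 78.3, 120, 700),
    cont("crp", "mg/dL", 0.3, 0.4, 0, 4),
    cont("tsh", "mU/L", 2.4, 1.3, 0.1, 10),
    cont("t4", "ug/dL", 1.1, 0.1, 0.5, 2),
    cont("vitamin_d", "ug/dL", 23.4, 9.7, 3, 70)
  )
}

#' Default effect-modifier structure of the synthetic truth
#'
#' Each drug class reduces PWV by a baseline amount plus a linear index over
#' a small set of effect-modifying covariates (z-scored against the schema
#' moments). The modifiers mirror the top-ranked predictors observed for
#' each class: weight and glycated hemoglobin for ACEI, baseline cfPWV and
#' LDL cholesterol for ARB, TSH and diastolic pressure for beta-blockers,
#' CAVI and waist circumference for diuretics, augmentation index and uric
#' acid for diuretic+ACEI, basophils and platelet volume for diuretic+ARB.
#'
#' @param coefficients Standardized coefficients (m/s of extra PWV reduction
#'   per covariate SD) applied to each arm's modifiers in rank order.
#' @param base_effect Baseline PWV reduction common to all arms, in m/s.
#' @return A list with one element per drug class, each a list with
#'   `modifiers` (covariate names), `coefficients`, and `base` (m/s).
#' @export
default_effect_config <- function(coefficients = c(0.6, 0.4, 0.2, 0.1),
                                  base_effect = 0.6) {
  mods <- list(
    ACEI     = c("weight_kg", "hba1c", "alt_sgpt", "creatinine_clearance"),
    ARB      = c("cfpwv", "cldl", "ast_got", "chbcm"),
    BB       = c("tsh", "dbp", "cfpwv", "hba1c"),
    DIU      = c("cavi", "waist_cm", "vitamin_d", "chdl"),
    DIU_ACEI = c("aix75", "uric_acid", "abi", "lvh_cornell"),
    DIU_ARB  = c("basophils", "mpv", "mcv", "lvh_cornell")
  )
  purrr::map(mods, function(m) {
    k <- min(length(m), length(coefficients))
    list(modifiers = m[seq_len(k)],
         coefficients = coefficients[seq_len(k)],
         base = base_effect)
  })
}

#' Default drug-assignment probabilities
#'
#' Multinomial assignment probabilities matching the observed arm sizes of a
#' pooled 194-patient hypertensive cohort (44/47/17/14/28/44).
#'
#' @return Named numeric vector over [drug_classes()], summing to 1.
#' @export
default_assignment_probs <- function() {
  counts <- c(ACEI = 44, ARB = 47, BB = 17, DIU = 14, DIU_ACEI = 28, DIU_ARB = 44)
  counts / sum(counts)
}

#' Default cohort-label probabilities
#'
#' Mimics the pooled three-study split (about 29% / 29% / 42%).
#'
#' @return Named numeric vector over [cohort_labels()], summing to 1.
#' @export
default_cohort_probs <- function() {
  c(EVA = 56, LOD = 57, EVIDENT = 81) / 194
}
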