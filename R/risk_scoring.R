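# CHADS2 / HEMORR2HAGES scoring and risk banding ------------------------------

#' CHADS2 stroke-risk score
#'
#' Additive stroke-risk score for atrial fibrillation: congestive heart
#' failure, hypertension, age >= 75 and diabetes score 1 point each; prior
#' stroke or transient ischemic attack scores 2. Range 0-6.
#'
#' @param factors data frame (or one-row list) with logical columns `chf`,
#'   `hypertension`, `age_ge_75`, `diabetes`, `prior_stroke_or_tia`
#' @return integer vector of scores in 0..6
#' @examples
#' compute_chads2(data.frame(chf = FALSE, hypertension = TRUE,
#'                           age_ge_75 = TRUE, diabetes = TRUE,
#'                           prior_stroke_or_tia = FALSE))  # 3
#' @export
compute_chads2 <- function(factors) {
  w <- c(chf = 1L, hypertension = 1L, age_ge_75 = 1L, diabetes = 1L,
         prior_stroke_or_tia = 2L)
  .weighted_score(factors, w)
}

#' HEMORR2HAGES bleeding-risk score
#'
#' Additive bleeding-risk score. The re-bleeding component scores 2 points;
#' every other component scores 1: hepatic or renal disease, alcohol
#' (ethanol) abuse, malignancy, reduced platelet count or function,
#' uncontrolled hypertension, anemia, excessive falls risk, and prior
#' hemorrhagic stroke. Two further published components -- older age
#' (> 75 years) and genetic factors (CYP2C9 variants) -- are supported but
#' disabled by default, matching the nine-item variant collected by the
#' CARAT assessment form; enable them with `extended = TRUE` for the full
#' eleven-item score. Range 0-12.
#'
#' @param factors data frame with the logical bleeding-risk columns
#'   (`hepatic_or_renal`, `alcohol_abuse`, `malignancy`, `reduced_platelets`,
#'   `rebleed_risk`, `uncontrolled_htn`, `anemia`, `falls_risk`,
#'   `prior_hemorrhagic_stroke`, and optionally `age_gt_75`,
#'   `genetic_factor`)
#' @param extended logical; include the older-age and genetic-factor
#'   components (default `FALSE`)
#' @return integer vector of scores
#' @examples
#' compute_hemorrhages(data.frame(hepatic_or_renal = FALSE,
#'   alcohol_abuse = FALSE, malignancy = FALSE, reduced_platelets = FALSE,
#'   rebleed_risk = TRUE, uncontrolled_htn = FALSE, anemia = FALSE,
#'   falls_risk = FALSE, prior_hemorrhagic_stroke = FALSE))  # 2
#' @export
compute_hemorrhages <- function(factors, extended = FALSE) {
  w <- c(hepatic_or_renal = 1L, alcohol_abuse = 1L, malignancy = 1L,
         reduced_platelets = 1L, rebleed_risk = 2L, uncontrolled_htn = 1L,
         anemia = 1L, falls_risk = 1L, prior_hemorrhagic_stroke = 1L)
  if (extended) w <- c(w, age_gt_75 = 1L, genetic_factor = 1L)
  .weighted_score(factors, w)
}

.weighted_score <- function(factors, weights) {
  factors <- as.data.frame(factors)
  missing <- setdiff(names(weights), names(factors))
  if (length(missing))
    stop("missing risk-factor column(s): ", paste(missing, collapse = ", "))
  score <- 0L
  for (f in names(weights)) {
    v <- factors[[f]]
    if (!is.logical(v)) stop("risk factor ", f, " must be logical")
    if (anyNA(v)) stop("risk factor ", f, " contains NA")
    score <- score + weights[[f]] * as.integer(v)
  }
  as.integer(score)
}

#' Risk-category cutpoints
#'
#' Default banding of the scores into low / intermediate / high categories,
#' following the published bandings of the two scores: CHADS2 0 = low,
#' 1 = intermediate, >= 2 = high; HEMORR2HAGES 0-1 = low, 2-3 = intermediate,
#' >= 4 = high. Each cutpoint pair `c(a, b)` means scores < a are low,
#' scores in [a, b) intermediate, scores >= b high. Both pairs are
#' configurable because the banding used inside the original tool is not
#' published.
#'
#' @param stroke,bleed length-2 increasing integer cutpoints
#' @return list with elements `stroke` and `bleed`
#' @export
risk_cutpoints <- function(stroke = c(1L, 2L), bleed = c(2L, 4L)) {
  stopifnot(length(stroke) == 2, length(bleed) == 2,
            stroke[1] < stroke[2], bleed[1] < bleed[2])
  list(stroke = as.integer(stroke), bleed = as.integer(bleed))
}

.categorize <- function(score, cut) {
  ifelse(score < cut[1], "low",
         ifelse(score < cut[2], "intermediate", "high"))
}

#' Categorize a stroke-risk score
#'
#' Monotone step function mapping CHADS2 scores to
#' `c("low", "intermediate", "high")` at the configured cutpoints.
#'
#' @param score integer vector in 0..6
#' @param cutpoints see [risk_cutpoints()]
#' @return character vector of categories
#' @export
categorize_stroke <- function(score, cutpoints = risk_cutpoints()) {
  if (any(score < 0 | score > 6))
    stop("CHADS2 score out of range [0, 6]")
  .categorize(score, cutpoints$stroke)
}

#' Categorize a bleeding-risk score
#'
#' Monotone step function mapping HEMORR2HAGES scores to
#' `c("low", "intermediate", "high")` at the configured cutpoints.
#'
#' @inheritParams categorize_stroke
#' @param score integer vector in 0..12
#' @return character vector of categories
#' @export
categorize_bleed <- function(score, cutpoints = risk_cutpoints()) {
  if (any(score < 0 | score > 12))
    stop("HEMORR2HAGES score out of range [0, 12]")
  .categorize(score, cutpoints$bleed)
}

#' Score a cohort
#'
#' Appends `chads2`, `hemorrhages`, `stroke_category` and `bleed_category`
#' columns to a cohort table.
#'
#' @param cohort `carat_cohort` data frame
#' @param cutpoints see [risk_cutpoints()]
#' @param extended logical, passed to [compute_hemorrhages()]
#' @return the cohort with four scoring columns appended
#' @export
score_cohort <- function(cohort, cutpoints = risk_cutpoints(),
                         extended = FALSE) {
  cohort$chads2 <- compute_chads2(cohort)
  cohort$hemorrhages <- compute_hemorrhages(cohort, extended = extended)
  cohort$stroke_category <- categorize_stroke(cohort$chads2, cutpoints)
  cohort$bleed_category <- categorize_bleed(cohort$hemorrhages, cutpoints)
  cohort
}
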