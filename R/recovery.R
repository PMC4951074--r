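# Calibration study for the stepwise intervention-effect estimator ------------

#' Simulate recovery of a known intervention odds ratio
#'
#' Repeatedly simulates a two-arm cluster-randomized prescribing trial in
#' which the intervention multiplies the odds of anticoagulant use by a
#' known factor, then runs the package's analysis pipeline on each
#' replicate -- univariate screening at p < 0.10 followed by forward
#' stepwise (Wald) logistic regression with cluster-robust intervals -- and
#' records the estimated intervention odds ratio and whether its confidence
#' interval covers the truth. Candidate covariates are the arm indicator
#' plus patient characteristics that are independent of therapy by
#' construction (pure noise), so the study measures both effect recovery
#' and resistance to noise selection.
#'
#' @param n_trials number of simulated trials
#' @param true_or intervention odds ratio on anticoagulant use
#' @param p_control control-arm probability of anticoagulant use
#' @param icc intracluster correlation of the outcome
#' @param n_gps_per_arm,patients_per_gp trial dimensions (defaults give
#'   n = 400 per trial)
#' @param seed integer seed for the whole study
#' @return data frame with one row per trial: `or`, `ci_lower`, `ci_upper`,
#'   `covered`, `n_terms` (`NA` odds ratio when the arm indicator was not
#'   selected)
#' @export
simulate_or_recovery <- function(n_trials = 200, true_or = 3,
                                 p_control = 0.65, icc = 0.03,
                                 n_gps_per_arm = 25L,
                                 patients_per_gp = c(8L, 8L),
                                 seed = 1L) {
  p_int <- stats::plogis(stats::qlogis(p_control) + log(true_or))
  mk_dist <- function(p) c(
    warfarin = p, warfarin_plus_antiplatelet = 0, aspirin_only = 1 - p,
    clopidogrel_only = 0, dabigatran = 0, dabigatran_plus_clopidogrel = 0,
    other = 0, none = 0)
  cfg <- simulation_config(
    n_gps_per_arm = n_gps_per_arm, patients_per_gp = patients_per_gp,
    icc = icc, dropout = 0,
    baseline_therapy_distribution = list(intervention = mk_dist(p_int),
                                         control = mk_dist(p_control)))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_trials)

  res <- lapply(seq_len(n_trials), function(i) {
    co <- generate_cohort(cfg, seed = seeds[i])
    outcome <- therapy_class(co$baseline_therapy) == "anticoagulant"
    cands <- data.frame(
      intervention = co$arm == "intervention",
      age = co$age, male = co$sex == "male",
      chf = co$chf, hypertension = co$hypertension, diabetes = co$diabetes,
      malignancy = co$malignancy, falls_risk = co$falls_risk)
    screened <- suppressWarnings(univariate_screen(outcome, cands, 0.10))
    keep <- screened$covariate[screened$selected]
    fit <- forward_stepwise_wald(outcome, cands[keep], cluster = co$gp_id)
    row <- fit$terms[fit$terms$covariate == "interventionTRUE", ]
    if (nrow(row) == 0)
      return(data.frame(or = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, covered = NA,
                        n_terms = length(fit$selected)))
    data.frame(or = row$odds_ratio, ci_lower = row$ci_lower,
               ci_upper = row$ci_upper,
               covered = row$ci_lower <= true_or & true_or <= row$ci_upper,
               n_terms = length(fit$selected))
  })
  do.call(rbind, res)
}
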