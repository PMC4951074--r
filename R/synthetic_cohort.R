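# Synthetic cohort generator with GP clustering -------------------------------
#
# Emulates the marginal structure of the trial population: community-dwelling
# AFib patients aged 65+ recruited by GP practices randomized to an
# intervention (tool-assisted) or control (usual care) arm, with the
# prevalences of the published baseline tables, a per-arm baseline therapy
# distribution, and within-GP clustering of anticoagulant use at a
# configurable intracluster correlation.

#' Simulation configuration
#'
#' Defaults reproduce the design and published marginals of the trial:
#' 25 GPs per arm each recruiting 5-10 patients, intracluster correlation
#' 0.03 for baseline anticoagulant use, up to 20% dropout, risk-factor and
#' checklist prevalences from the baseline tables, per-arm baseline therapy
#' distributions from the published counts, and GP decision behavior
#' (75.2% acceptance of recommendations; on rejection of a warfarin
#' recommendation, dabigatran is substituted with probability 19/22).
#'
#' @param n_gps_per_arm GPs recruited into each arm (default 25)
#' @param patients_per_gp inclusive integer range of patients per GP
#'   (default `c(5, 10)`)
#' @param icc intracluster correlation of baseline anticoagulant use in
#'   [0, 1) (default 0.03)
#' @param dropout post-generation participant removal probability
#'   (default 0.20)
#' @param factor_prevalences named list of Bernoulli prevalences (see
#'   defaults in the function body); `uncontrolled_htn` is interpreted as a
#'   *marginal* prevalence realised only among hypertensive patients
#' @param baseline_therapy_distribution list with per-arm named probability
#'   vectors over regimens, each summing to 1
#' @param gp_behavior list with `p_accept`,
#'   `p_dabigatran_given_warfarin_rejection`, and `reason_probs` over the
#'   disagreement code book
#' @param age_mean,age_sd mean and SD of the (left-truncated at 65) age
#'   distribution
#' @param seed default seed used by [generate_cohort()] when none is passed
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(n_gps_per_arm = 25L,
                              patients_per_gp = c(5L, 10L),
                              icc = 0.03,
                              dropout = 0.20,
                              factor_prevalences = NULL,
                              baseline_therapy_distribution = NULL,
                              gp_behavior = NULL,
                              age_mean = 78, age_sd = 7,
                              seed = 1L) {
  defaults_prev <- list(
    # stroke risk factors (age >= 75 is derived from drawn age)
    prior_stroke_or_tia = 0.183, chf = 0.254, hypertension = 0.682,
    diabetes = 0.198,
    # bleeding risk factors
    hepatic_or_renal = 0.046, alcohol_abuse = 0.020, malignancy = 0.084,
    reduced_platelets = 0.015, rebleed_risk = 0.010,
    uncontrolled_htn = 0.102, anemia = 0.036, falls_risk = 0.056,
    prior_hemorrhagic_stroke = 0.015, age_gt_75 = 0, genetic_factor = 0,
    # safety checklist (polypharmacy_ge4 is derived from rx_med_count)
    allergy_warfarin_aspirin = 0.020, adverse_reaction = 0.038,
    interacting_medication = 0.003, declined_therapy = 0.013,
    contraindication = 0.028, failed_therapy = 0.025, educated = 0.967,
    noncompliant = 0.056, needs_assistance = 0.410,
    access_difficulty = 0.008, residential_care = 0.010,
    cognitive_impairment = 0.046, vision_impairment = 0.061,
    hearing_impairment = 0.087, language_barrier = 0.010,
    mobility_disorder = 0.043, functional_impairment = 0.160,
    # history
    prior_hospitalization = 0.341, male = 0.545)
  if (!is.null(factor_prevalences))
    defaults_prev[names(factor_prevalences)] <- factor_prevalences

  if (is.null(baseline_therapy_distribution)) {
    # published baseline counts; warfarin combinations split so the 16
    # combination users land 6 in the intervention arm, 10 in control
    baseline_therapy_distribution <- list(
      intervention = c(warfarin = 148, warfarin_plus_antiplatelet = 6,
                       aspirin_only = 17, clopidogrel_only = 3,
                       dabigatran = 30, dabigatran_plus_clopidogrel = 0,
                       other = 0, none = 2) / 206,
      control = c(warfarin = 152, warfarin_plus_antiplatelet = 10,
                  aspirin_only = 6, clopidogrel_only = 0,
                  dabigatran = 15, dabigatran_plus_clopidogrel = 0,
                  other = 0, none = 4) / 187)
  }
  if (is.null(gp_behavior))
    gp_behavior <- list(
      p_accept = 0.752,
      p_dabigatran_given_warfarin_rejection = 19 / 22,
      reason_probs = c(inappropriate = 0.30, cardiologist = 0.25,
                       familiarization_program = 0.20,
                       patient_refusal = 1 / 6, other = 1 / 12))

  cfg <- list(n_gps_per_arm = as.integer(n_gps_per_arm),
              patients_per_gp = as.integer(patients_per_gp),
              icc = icc, dropout = dropout,
              factor_prevalences = defaults_prev,
              baseline_therapy_distribution = baseline_therapy_distribution,
              gp_behavior = gp_behavior,
              age_mean = age_mean, age_sd = age_sd,
              seed = as.integer(seed))
  .check_config(cfg)
  structure(cfg, class = "simulation_config")
}

.check_config <- function(cfg) {
  if (cfg$icc < 0 || cfg$icc >= 1) stop("icc must lie in [0, 1)")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must lie in [0, 1)")
  if (length(cfg$patients_per_gp) != 2 ||
      cfg$patients_per_gp[1] > cfg$patients_per_gp[2] ||
      cfg$patients_per_gp[1] < 1)
    stop("patients_per_gp must be an increasing positive integer range")
  for (p in cfg$factor_prevalences)
    if (p < 0 || p > 1) stop("prevalences must lie in [0, 1]")
  for (arm in c("intervention", "control")) {
    d <- cfg$baseline_therapy_distribution[[arm]]
    if (is.null(d)) stop("baseline therapy distribution missing arm: ", arm)
    if (!setequal(names(d), carat_regimens()))
      stop("therapy distribution for ", arm,
           " must name every regimen in carat_regimens()")
    if (abs(sum(d) - 1) > 1e-6)
      stop("therapy distribution for ", arm, " does not sum to 1")
  }
  if (abs(sum(cfg$gp_behavior$reason_probs) - 1) > 1e-6)
    stop("disagreement reason probabilities must sum to 1")
  invisible(cfg)
}

# Cluster-level success probabilities with exact target ICC: a beta draw
# with mean p and variance icc * p * (1 - p) makes the one-way ANOVA ICC of
# the resulting Bernoulli outcome equal icc by construction.
.cluster_probs <- function(n_clusters, p, icc) {
  if (icc == 0 || p <= 0 || p >= 1) return(rep(p, n_clusters))
  nu <- 1 / icc - 1
  stats::rbeta(n_clusters, p * nu, (1 - p) * nu)
}

.rtrunc_norm <- function(n, mean, sd, lower) {
  lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort under a [simulation_config()]: GP clusters assigned to the
#' two arms, ages from a normal distribution left-truncated at the
#' eligibility threshold of 65 years, medication and comorbidity counts,
#' independent Bernoulli risk factors and checklist items at the configured
#' prevalences (uncontrolled hypertension only among hypertensive patients;
#' `age_ge_75` and `polypharmacy_ge4` derived from their underlying
#' fields), and a baseline therapy drawn per arm with a shared GP-level
#' effect on anticoagulant use calibrated to the configured intracluster
#' correlation. Dropout removes each patient independently at the configured
#' rate. The result passes strict cohort validation.
#'
#' @param config a [simulation_config()]
#' @param seed integer seed; defaults to `config$seed`
#' @return `carat_cohort` data frame
#' @export
generate_cohort <- function(config = simulation_config(), seed = NULL) {
  .check_config(config)
  set.seed(if (is.null(seed)) config$seed else seed)
  prev <- config$factor_prevalences

  n_gps <- 2L * config$n_gps_per_arm
  gp_id <- sprintf("gp%03d", seq_len(n_gps))
  gp_arm <- rep(c("intervention", "control"), each = config$n_gps_per_arm)
  size_range <- seq(config$patients_per_gp[1], config$patients_per_gp[2])
  sizes <- if (length(size_range) == 1) rep(size_range, n_gps) else
    sample(size_range, n_gps, replace = TRUE)
  n <- sum(sizes)
  pat_gp <- rep(seq_len(n_gps), sizes)
  arm <- gp_arm[pat_gp]

  age <- pmin(as.integer(round(
    .rtrunc_norm(n, config$age_mean, config$age_sd, 64.5))), 105L)
  age <- pmax(age, 65L)

  draw <- function(p) stats::runif(n) < p
  cohort <- list(
    patient_id = sprintf("p%05d", seq_len(n)),
    gp_id = gp_id[pat_gp], arm = arm, age = age,
    sex = ifelse(draw(prev$male), "male", "female"),
    chronic_condition_count = pmax(0L, as.integer(round(stats::rnorm(n, 5.8, 2.5)))),
    rx_med_count = pmax(0L, as.integer(round(stats::rnorm(n, 9.2, 4.0)))),
    otc_med_count = pmax(0L, as.integer(round(stats::rnorm(n, 1.5, 1.3)))),
    afib_duration = sample(.afib_duration_levels, n, replace = TRUE,
                           prob = c(0.025, 0.099, 0.150, 0.209, 0.517)),
    afib_type = sample(.afib_type_levels, n, replace = TRUE,
                       prob = c(0.354, 0.570, 0.056, 0.020)),
    prior_hospitalization = draw(prev$prior_hospitalization),
    rhythm = sample(.rhythm_levels, n, replace = TRUE,
                    prob = c(0.115, 0.882, 0.003)))
  cohort$hospitalization_reason <- ifelse(
    cohort$prior_hospitalization,
    sample(c("af_management", "stroke", "tia", "other"), n, replace = TRUE,
           prob = c(0.649, 0.179, 0.090, 0.082)),
    NA_character_)

  for (f in c(.stroke_factor_cols, .bleed_factor_cols, .safety_cols)) {
    if (f %in% c("age_ge_75", "polypharmacy_ge4", "uncontrolled_htn")) next
    p <- prev[[f]]
    cohort[[f]] <- if (is.null(p)) rep(FALSE, n) else draw(p)
  }
  cohort$age_ge_75 <- cohort$age >= 75
  cohort$polypharmacy_ge4 <- cohort$rx_med_count >= 4
  # marginal prevalence realised only among hypertensive patients
  p_cond <- if (prev$hypertension > 0)
    min(1, prev$uncontrolled_htn / prev$hypertension) else 0
  cohort$uncontrolled_htn <- cohort$hypertension & draw(p_cond)

  # baseline therapy: GP-level shared effect on the anticoagulant indicator
  therapy <- character(n)
  for (a in c("intervention", "control")) {
    d <- config$baseline_therapy_distribution[[a]]
    ac_reg <- names(d)[therapy_class(names(d)) == "anticoagulant"]
    p_ac <- sum(d[ac_reg])
    gp_in_arm <- which(gp_arm == a)
    p_gp <- stats::setNames(.cluster_probs(length(gp_in_arm), p_ac, config$icc),
                            gp_id[gp_in_arm])
    idx <- which(arm == a)
    is_ac <- stats::runif(length(idx)) < p_gp[cohort$gp_id[idx]]
    non_ac <- setdiff(names(d), ac_reg)
    th <- character(length(idx))
    if (any(is_ac))
      th[is_ac] <- sample(ac_reg, sum(is_ac), replace = TRUE,
                          prob = d[ac_reg] / sum(d[ac_reg]))
    if (any(!is_ac)) {
      w <- d[non_ac]
      if (sum(w) == 0) w[] <- 1
      th[!is_ac] <- sample(non_ac, sum(!is_ac), replace = TRUE,
                           prob = w / sum(w))
    }
    therapy[idx] <- th
  }
  cohort$baseline_therapy <- therapy
  cohort$inr_subtherapeutic <- therapy == "warfarin" & draw(0.005)

  out <- as.data.frame(cohort, stringsAsFactors = FALSE)[names(cohort_schema())]
  if (config$dropout > 0)
    out <- out[stats::runif(n) >= config$dropout, , drop = FALSE]
  rownames(out) <- NULL
  issues <- validate_cohort(out)
  if (length(issues))
    stop("generated cohort failed validation:\n  ",
         paste(issues, collapse = "\n  "))
  structure(out, class = c("carat_cohort", "data.frame"))
}

#' Simulate GP decisions on tool recommendations
#'
#' Each recommendation is accepted with probability `p_accept`. On rejection
#' of a warfarin recommendation the GP substitutes dabigatran with the
#' configured probability (the dominant observed rejection behavior),
#' otherwise aspirin or no therapy (2:1); rejected aspirin or no-therapy
#' recommendations are replaced by one of the remaining options uniformly.
#' A disagreement reason is sampled from the documented code book for every
#' rejection.
#'
#' @param cohort `carat_cohort` data frame
#' @param recommendations result of [recommend()] for the same patients
#' @param behavior GP behavior list (see [simulation_config()])
#' @param seed optional integer seed
#' @return data frame of agreement records (see [agreement_records()])
#' @export
simulate_gp_decisions <- function(cohort, recommendations,
                                  behavior = simulation_config()$gp_behavior,
                                  seed = NULL) {
  if (nrow(cohort) != nrow(recommendations))
    stop("cohort and recommendations differ in length")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(recommendations)
  rec <- recommendations$therapy
  accept <- stats::runif(n) < behavior$p_accept
  final <- rec
  for (i in which(!accept)) {
    final[i] <- if (rec[i] == "warfarin") {
      if (stats::runif(1) < behavior$p_dabigatran_given_warfarin_rejection)
        "dabigatran"
      else sample(c("aspirin_only", "none"), 1, prob = c(2, 1))
    } else if (rec[i] == "aspirin_only") {
      sample(c("warfarin", "none"), 1)
    } else {
      sample(c("warfarin", "aspirin_only"), 1)
    }
  }
  reason <- rep(NA_character_, n)
  rej <- which(final != rec)
  if (length(rej))
    reason[rej] <- sample(names(behavior$reason_probs), length(rej),
                          replace = TRUE, prob = behavior$reason_probs)
  out <- agreement_records(rec, final, reason)
  cbind(patient_id = cohort$patient_id, out, stringsAsFactors = FALSE)
}

#' One-way ANOVA estimator of the intracluster correlation
#'
#' Moment estimator of the ICC of a (typically binary) outcome from the
#' between- and within-cluster mean squares, using the standard unequal
#' cluster-size correction for the effective cluster size. The estimate can
#' be slightly negative by sampling noise; it is returned untruncated.
#'
#' @param cluster vector of cluster identifiers (e.g. `cohort$gp_id`)
#' @param outcome numeric or logical outcome vector
#' @return list with `icc`, `n_clusters`, `n`
#' @export
estimate_icc <- function(cluster, outcome) {
  cluster <- factor(cluster)
  y <- as.numeric(outcome)
  stopifnot(length(cluster) == length(y))
  keep <- !is.na(y) & !is.na(cluster)
  cluster <- droplevels(cluster[keep]); y <- y[keep]
  k <- nlevels(cluster)
  if (k < 2) stop("need at least 2 clusters")
  ni <- as.integer(table(cluster))
  if (all(ni < 2)) stop("all clusters have a single member; ICC undefined")
  N <- length(y)
  if (stats::var(y) == 0) {
    warning("outcome is constant; ICC degenerate")
    return(list(icc = NaN, n_clusters = k, n = N))
  }
  means <- tapply(y, cluster, mean)
  grand <- mean(y)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((y - means[cluster])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  list(icc = (msb - msw) / (msb + (n0 - 1) * msw), n_clusters = k, n = N)
}
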