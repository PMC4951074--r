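# Printed prescribing tables of the CARAT cluster-randomized trial ------------
#
# The trial published aggregate prescribing counts only (no patient-level
# data). These tables are first-class inputs: the summarizer and the
# change-taxonomy reconstruction below recompute every printed proportion
# from them.

#' Published therapy-distribution counts
#'
#' Patient counts by therapy group for the four published columns: the
#' intervention arm at baseline, the intervention arm after the tool was
#' applied, the tool's own recommendations, and the control arm.
#' Warfarin counts include combinations with an antiplatelet; dabigatran
#' counts include combinations with clopidogrel.
#'
#' @return data frame with columns `therapy`, `intervention_baseline`,
#'   `intervention_post`, `intervention_recommended`, `control`
#' @export
trial_therapy_counts <- function() {
  data.frame(
    therapy = c("warfarin", "aspirin_only", "clopidogrel_only",
                "dabigatran", "none"),
    intervention_baseline   = c(154L, 17L, 3L, 30L, 2L),
    intervention_post       = c(156L, 14L, 0L, 34L, 2L),
    intervention_recommended = c(168L, 38L, 0L, 0L, 0L),
    control                 = c(162L, 6L, 0L, 15L, 4L),
    stringsAsFactors = FALSE)
}

#' Summarise a therapy-distribution table
#'
#' Recomputes the headline prescribing proportions from a count table in the
#' [trial_therapy_counts()] layout, each as a percentage rounded to one
#' decimal place:
#' any antithrombotic at baseline (both arms), any anticoagulant at baseline
#' (both arms), warfarin among baseline antithrombotic users (both arms),
#' anticoagulant use in the intervention arm after application of the tool,
#' and (when `n_changes` is supplied) the proportion of intervention
#' patients for whom a change of therapy was recommended.
#'
#' @param counts count table in the [trial_therapy_counts()] layout
#' @param n_changes optional integer, number of recommended regimen changes
#' @return named numeric vector of percentages
#' @export
therapy_distribution_summary <- function(counts = trial_therapy_counts(),
                                         n_changes = NULL) {
  stopifnot(all(c("therapy", "intervention_baseline", "intervention_post",
                  "control") %in% names(counts)))
  anticoag <- counts$therapy %in% c("warfarin", "dabigatran")
  antithrombotic <- counts$therapy != "none"

  base_all <- counts$intervention_baseline + counts$control
  n_all <- sum(base_all)
  n_intervention <- sum(counts$intervention_baseline)

  out <- c(
    pct_any_antithrombotic = 100 * sum(base_all[antithrombotic]) / n_all,
    pct_anticoagulant      = 100 * sum(base_all[anticoag]) / n_all,
    pct_warfarin_among_treated =
      100 * base_all[counts$therapy == "warfarin"] /
        sum(base_all[antithrombotic]),
    pct_post_anticoagulant_intervention =
      100 * sum(counts$intervention_post[anticoag]) / n_intervention)
  if (!is.null(n_changes))
    out <- c(out, pct_recommended_change = 100 * n_changes / n_intervention)
  round(out, 1)
}

#' Reconstruct the recommended therapy transitions
#'
#' The trial reported 75 recommended regimen changes in aggregate: the
#' change-class counts (12 upgrades, 35 side-steps, 28 downgrades), the
#' tool's recommended totals per regimen, the fact that every
#' dabigatran-user and every clopidogrel-user was recommended a different
#' therapy (the tool never recommends a novel oral anticoagulant and its
#' leaves are warfarin / aspirin / none), and that of the six
#' warfarin-plus-antiplatelet patients recommended a change, five were
#' recommended warfarin only and one aspirin only. These marginals admit a
#' two-parameter family of transition tables; this function returns one
#' member consistent with all of them (all clopidogrel-only users
#' side-stepped to aspirin, 27 of the 30 dabigatran users side-stepped to
#' warfarin and 3 were downgraded to aspirin).
#'
#' @return data frame with columns `baseline`, `target`, `dose_changed`,
#'   one row per recommended change (75 rows)
#' @export
reconstruct_recommended_changes <- function() {
  blocks <- list(
    c("none",                       "warfarin",     2L),
    c("aspirin_only",               "warfarin",    10L),
    c("clopidogrel_only",           "aspirin_only", 3L),
    c("dabigatran",                 "warfarin",    27L),
    c("warfarin_plus_antiplatelet", "warfarin",     5L),
    c("warfarin_plus_antiplatelet", "aspirin_only", 1L),
    c("warfarin",                   "aspirin_only",24L),
    c("dabigatran",                 "aspirin_only", 3L))
  baseline <- unlist(lapply(blocks, function(b) rep(b[1], as.integer(b[3]))))
  target   <- unlist(lapply(blocks, function(b) rep(b[2], as.integer(b[3]))))
  data.frame(baseline = baseline, target = target, dose_changed = FALSE,
             stringsAsFactors = FALSE)
}
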