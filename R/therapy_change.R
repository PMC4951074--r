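# Therapy-transition taxonomy and CARAT-vs-GP agreement ------------------------

.change_levels <- c("no_change", "upgrade", "side_step", "downgrade",
                    "dose_adjust")

.class_rank <- c(none = 0L, antiplatelet = 1L, anticoagulant = 2L)

#' Classify a therapy transition
#'
#' Classifies baseline-to-target therapy transitions with the
#' upgrade / side-step / downgrade taxonomy under the effectiveness ordering
#' none < antiplatelet < anticoagulant:
#' *upgrade* when the therapy class rises (e.g. no therapy to any agent, or
#' aspirin to warfarin), *downgrade* when it falls (any agent to no therapy,
#' or an anticoagulant to aspirin), *side-step* when the class is unchanged
#' but the regimen differs (one anticoagulant to another, or
#' warfarin-plus-antiplatelet to warfarin only), *dose_adjust* when the
#' regimen is identical but the dose (or INR target) changed, and
#' *no_change* otherwise. The five values partition all transitions.
#'
#' @param baseline,target character vectors of regimen codes
#'   (see [carat_regimens()])
#' @param dose_changed logical vector (default `FALSE`)
#' @param other_rank optional integer 0-2 assigning an effectiveness rank to
#'   the `"other"` regimen; transitions involving `"other"` are an error when
#'   it is `NULL` (unrankable)
#' @return character vector with values in
#'   `c("no_change", "upgrade", "side_step", "downgrade", "dose_adjust")`
#' @examples
#' classify_change("none", "warfarin")                       # "upgrade"
#' classify_change("warfarin_plus_antiplatelet", "warfarin") # "side_step"
#' classify_change("dabigatran", "aspirin_only")             # "downgrade"
#' @export
classify_change <- function(baseline, target, dose_changed = FALSE,
                            other_rank = NULL) {
  n <- max(length(baseline), length(target), length(dose_changed))
  baseline <- rep(as.character(baseline), length.out = n)
  target <- rep(as.character(target), length.out = n)
  dose_changed <- rep(as.logical(dose_changed), length.out = n)

  rank <- .class_rank
  if (!is.null(other_rank)) {
    stopifnot(other_rank %in% 0:2)
    rank <- c(rank, other = as.integer(other_rank))
  } else if (any(baseline == "other" | target == "other")) {
    stop("transition involves the unrankable regimen \"other\"; ",
         "supply other_rank to classify it")
  }
  rb <- rank[ifelse(therapy_class(baseline) == "other", "other",
                    therapy_class(baseline))]
  rt <- rank[ifelse(therapy_class(target) == "other", "other",
                    therapy_class(target))]

  ifelse(baseline == target,
         ifelse(dose_changed, "dose_adjust", "no_change"),
         ifelse(rt > rb, "upgrade",
                ifelse(rt < rb, "downgrade", "side_step")))
}

#' Tabulate therapy transitions
#'
#' Counts each change class over a set of transitions and expresses
#' upgrades, side-steps, downgrades and dose adjustments as percentages of
#' the *changed* subset (transitions classified `no_change` are excluded
#' from the denominator), rounded to one decimal place.
#'
#' @param transitions data frame with columns `baseline`, `target` and
#'   optionally `dose_changed`; or a character vector of pre-computed change
#'   classes
#' @param other_rank passed to [classify_change()]
#' @return data frame with columns `change`, `n`, `percent_of_changes`
#'   (`NA` for `no_change`, and `NA` throughout if no transition changed
#'   therapy -- a zero denominator is reported as undefined, not as 0)
#' @export
tabulate_changes <- function(transitions, other_rank = NULL) {
  if (is.data.frame(transitions)) {
    if (nrow(transitions) == 0) stop("no transitions supplied")
    dose <- if ("dose_changed" %in% names(transitions))
      transitions$dose_changed else FALSE
    cls <- classify_change(transitions$baseline, transitions$target,
                           dose, other_rank)
  } else {
    if (length(transitions) == 0) stop("no transitions supplied")
    stopifnot(all(transitions %in% .change_levels))
    cls <- transitions
  }
  n <- as.integer(table(factor(cls, levels = .change_levels)))
  out <- data.frame(change = .change_levels, n = n,
                    stringsAsFactors = FALSE)
  changed <- sum(out$n[out$change != "no_change"])
  out$percent_of_changes <- if (changed == 0) NA_real_ else
    ifelse(out$change == "no_change", NA_real_,
           round(100 * out$n / changed, 1))
  out
}

#' Build agreement records from recommendation and decision vectors
#'
#' Pairs each CARAT-recommended therapy with the prescriber's final therapy
#' and derives the three agreement levels: `agree_overall` (identical
#' regimen), `agree_class` (same therapy class, anticoagulant vs
#' antiplatelet vs none), and `agree_agent` (same primary agent).
#' Agent-level agreement implies class-level agreement.
#'
#' @param carat_therapy,gp_final_therapy character vectors of regimen codes
#' @param disagreement_reason optional character vector of reason codes from
#'   `c("inappropriate", "cardiologist", "familiarization_program",
#'   "patient_refusal", "other")`, `NA` where the pair agrees
#' @return data frame of agreement records
#' @export
agreement_records <- function(carat_therapy, gp_final_therapy,
                              disagreement_reason = NULL) {
  if (length(carat_therapy) != length(gp_final_therapy))
    stop("recommendation and decision vectors differ in length")
  agree_overall <- carat_therapy == gp_final_therapy
  agree_class <- therapy_class(carat_therapy) == therapy_class(gp_final_therapy)
  agree_agent <- therapy_agent(carat_therapy) == therapy_agent(gp_final_therapy)
  if (is.null(disagreement_reason))
    disagreement_reason <- rep(NA_character_, length(carat_therapy))
  disagreement_reason[agree_overall] <- NA_character_
  data.frame(carat_therapy = carat_therapy,
             gp_final_therapy = gp_final_therapy,
             agree_overall = agree_overall,
             agree_class = agree_class,
             agree_agent = agree_agent,
             disagreement_reason = disagreement_reason,
             stringsAsFactors = FALSE)
}

#' Proportion of agreeing recommendation/decision pairs
#'
#' @param pairs data frame of agreement records (see [agreement_records()])
#' @param level `"overall"` (identical regimen, default), `"class"`
#'   (anticoagulant vs antiplatelet vs none) or `"agent"`
#' @return proportion in [0, 1]
#' @export
percent_agreement <- function(pairs, level = c("overall", "class", "agent")) {
  if (nrow(pairs) == 0) stop("no pairs supplied")
  level <- match.arg(level)
  col <- paste0("agree_", level)
  mean(pairs[[col]])
}

#' Fleiss kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for `n` raters assigning `N` subjects to `k`
#' categories, from the subject-by-category count table: observed agreement
#' is the mean over subjects of the proportion of concordant rater pairs,
#' chance agreement is the sum of squared overall category proportions, and
#' kappa = (Po - Pe) / (1 - Pe). Equals 1 under perfect agreement with
#' non-degenerate marginals and 0 in expectation when raters assign
#' categories independently of the subjects.
#'
#' @param counts numeric matrix, one row per subject, one column per
#'   category; every row must sum to the same number of raters (>= 2)
#' @return list with elements `kappa`, `p_observed`, `p_expected`,
#'   `n_subjects`, `n_raters`. When the marginals are degenerate (all
#'   ratings in one category, so chance agreement is 1) `kappa` is `NaN` and
#'   a warning is raised.
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 categories")
  raters <- unique(rowSums(counts))
  if (length(raters) != 1)
    stop("every subject must be rated by the same number of raters")
  n <- raters
  if (n < 2) stop("need at least 2 raters")
  N <- nrow(counts)

  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_obs <- mean(p_i)
  p_j <- colSums(counts) / (N * n)
  p_exp <- sum(p_j^2)

  if (1 - p_exp < .Machine$double.eps) {
    warning("degenerate marginals: chance agreement is 1, kappa undefined")
    kappa <- NaN
  } else kappa <- (p_obs - p_exp) / (1 - p_exp)

  list(kappa = kappa, p_observed = p_obs, p_expected = p_exp,
       n_subjects = N, n_raters = n)
}

#' Tally disagreement reasons
#'
#' Counts the documented reason codes over disagreeing pairs only.
#'
#' @param pairs data frame of agreement records
#' @return named integer vector (empty when there is no disagreement)
#' @export
tally_reasons <- function(pairs) {
  reasons <- pairs$disagreement_reason[!pairs$agree_overall]
  reasons <- reasons[!is.na(reasons)]
  if (length(reasons) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(reasons)
  stats::setNames(as.integer(tab), names(tab))
}

#' Summarise CARAT-vs-prescriber agreement
#'
#' Bundles the agreement analyses: regimen-level and class-level percent
#' agreement, Fleiss kappa over the two "raters" (tool and prescriber) using
#' only the therapy categories actually occurring in the data (zero-margin
#' categories are dropped so chance agreement is well defined), and the
#' disagreement-reason tally.
#'
#' @param pairs data frame of agreement records (see [agreement_records()])
#' @return list with `n`, `percent_agreement` (regimen level),
#'   `percent_agreement_class`, `kappa`, `reason_tally`
#' @export
agreement_summary <- function(pairs) {
  if (nrow(pairs) == 0) stop("no pairs supplied")
  cats <- sort(unique(c(pairs$carat_therapy, pairs$gp_final_therapy)))
  counts <- matrix(0L, nrow(pairs), length(cats),
                   dimnames = list(NULL, cats))
  for (j in seq_along(cats))
    counts[, j] <- (pairs$carat_therapy == cats[j]) +
      (pairs$gp_final_therapy == cats[j])
  kap <- if (length(cats) >= 2) fleiss_kappa(counts)$kappa else NaN
  list(n = nrow(pairs),
       percent_agreement = percent_agreement(pairs, "overall"),
       percent_agreement_class = percent_agreement(pairs, "class"),
       kappa = kap,
       reason_tally = tally_reasons(pairs))
}
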