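# CARAT recommendation engine --------------------------------------------------
#
# The tool output is a therapy recommendation drawn from
# {warfarin, aspirin_only, none, other}, a rationale trail, and the
# medication-safety / medication-management flags raised by the checklist.
# Novel oral anticoagulants are never recommended ("other" is reserved in the
# rule vocabulary but unreachable by the default cascade).

#' Default recommendation rule cascade
#'
#' The ordered, declarative rule set the engine evaluates with first-match
#' semantics. Each rule has an `id`, an optional set of admissible
#' `stroke` / `bleed` categories (absent means "any"), an optional
#' `flags_any` set (the rule fires if any listed safety flag is raised), and
#' the `therapy` of its leaf. The default cascade:
#'
#' 1. `absolute_contraindication`: allergy to both warfarin and aspirin, or a
#'    documented contraindication to antithrombotics, blocks all therapy.
#' 2. `warfarin_unsuitable`: a prior adverse reaction, failed antithrombotic
#'    therapy, or an interacting medication steps down to aspirin.
#' 3. `high_bleed_caution`: elevated stroke risk with high bleeding risk
#'    receives aspirin (anticoagulation withheld on safety grounds).
#' 4. `low_benefit_high_bleed`: low stroke risk with high bleeding risk
#'    receives no therapy.
#' 5. `anticoagulate`: high or intermediate stroke risk with low or
#'    intermediate bleeding risk receives warfarin -- the preferred leaf for
#'    the patients most eligible for prophylaxis.
#' 6. `low_stroke_risk`: remaining low-stroke-risk patients receive aspirin.
#'
#' Management-burden flags (cognitive impairment, nonadherence, needing
#' assistance, prior refusal, ...) never alter the risk-based leaf; they are
#' attached to the output as flags for the prescriber.
#'
#' @return list of rules, class `carat_rules`
#' @seealso [recommend()], [read_rules()], [write_rules()]
#' @export
carat_rules <- function() {
  rules <- list(
    list(id = "absolute_contraindication",
         flags_any = c("allergy_warfarin_aspirin", "contraindication"),
         therapy = "none"),
    list(id = "warfarin_unsuitable",
         flags_any = c("adverse_reaction", "failed_therapy",
                       "interacting_medication"),
         therapy = "aspirin_only"),
    list(id = "high_bleed_caution",
         stroke = c("high", "intermediate"), bleed = "high",
         therapy = "aspirin_only"),
    list(id = "low_benefit_high_bleed",
         stroke = "low", bleed = "high",
         therapy = "none"),
    list(id = "anticoagulate",
         stroke = c("high", "intermediate"),
         bleed = c("low", "intermediate"),
         therapy = "warfarin"),
    list(id = "low_stroke_risk",
         stroke = "low",
         therapy = "aspirin_only")
  )
  structure(rules, class = "carat_rules")
}

.check_rules <- function(rules) {
  ok_therapy <- c("warfarin", "aspirin_only", "none", "other")
  for (r in rules) {
    if (is.null(r$id) || is.null(r$therapy))
      stop("every rule needs an id and a therapy leaf")
    if (!r$therapy %in% ok_therapy)
      stop("rule ", r$id, ": therapy must be one of ",
           paste(ok_therapy, collapse = ", "))
  }
  invisible(rules)
}

#' Read / write a rule cascade as JSON
#'
#' The cascade is serialised as an ordered JSON array so alternative
#' reconstructions of the decision matrix can be supplied without code
#' changes.
#'
#' @param path JSON file path
#' @return `read_rules` returns a `carat_rules` list; `write_rules` returns
#'   `path` invisibly.
#' @export
read_rules <- function(path) {
  rules <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  rules <- lapply(rules, function(r) r[!vapply(r, is.null, TRUE)])
  .check_rules(rules)
  structure(rules, class = "carat_rules")
}

#' @rdname read_rules
#' @param rules `carat_rules` list
#' @export
write_rules <- function(rules, path) {
  .check_rules(rules)
  jsonlite::write_json(lapply(unclass(rules), function(r) r),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assess a patient's risks
#'
#' Composes the scoring operations into the assessment block of the tool:
#' CHADS2, HEMORR2HAGES, and their risk categories.
#'
#' @param cohort `carat_cohort` data frame (one or more patients)
#' @param cutpoints see [risk_cutpoints()]
#' @return data frame with columns `patient_id`, `chads2`, `hemorrhages`,
#'   `stroke_category`, `bleed_category`
#' @export
assess <- function(cohort, cutpoints = risk_cutpoints()) {
  scored <- score_cohort(cohort, cutpoints)
  data.frame(patient_id = scored$patient_id, chads2 = scored$chads2,
             hemorrhages = scored$hemorrhages,
             stroke_category = scored$stroke_category,
             bleed_category = scored$bleed_category,
             stringsAsFactors = FALSE)
}

#' Medication-safety and management flags
#'
#' One flag code per checklist item that is `TRUE`, in the fixed checklist
#' order (the code book is the checklist column names). The `educated` item
#' is inverted: the flag `not_educated` is raised when a patient has *not*
#' been educated about their therapy.
#'
#' @param cohort `carat_cohort` data frame
#' @return list of character vectors, one per patient
#' @export
flag_safety <- function(cohort) {
  lapply(seq_len(nrow(cohort)), function(i) {
    codes <- character()
    for (col in .safety_cols) {
      v <- isTRUE(cohort[[col]][i])
      if (col == "educated") {
        if (!v) codes <- c(codes, "not_educated")
      } else if (v) codes <- c(codes, col)
    }
    codes
  })
}

#' Generate CARAT therapy recommendations
#'
#' Runs the deterministic rule cascade over a scored cohort. The output for
#' each patient is the recommended therapy, the rationale (risk categories
#' and the fired rule), all raised safety flags, whether the recommendation
#' differs from baseline therapy at the regimen level, and whether a
#' same-agent dose adjustment is advised instead (baseline warfarin whose
#' INR control is recorded as subtherapeutic).
#'
#' @param cohort `carat_cohort` data frame
#' @param assessment optional result of [assess()]; computed when `NULL`
#' @param rules rule cascade, default [carat_rules()]
#' @param verbose logical; log each fired rule to stderr
#' @return data frame with columns `patient_id`, `therapy`, `rule_id`,
#'   `rationale`, `flags` (semicolon-joined), `change_required`,
#'   `dose_adjust`
#' @export
recommend <- function(cohort, assessment = NULL, rules = carat_rules(),
                      verbose = FALSE) {
  .check_rules(rules)
  if (is.null(assessment)) assessment <- assess(cohort)
  if (!identical(as.character(assessment$patient_id),
                 as.character(cohort$patient_id)))
    stop("assessment is not aligned with the cohort (patient_id mismatch)")

  flags <- flag_safety(cohort)
  n <- nrow(cohort)
  therapy <- character(n); rule_id <- character(n)

  for (i in seq_len(n)) {
    st <- assessment$stroke_category[i]
    bl <- assessment$bleed_category[i]
    fired <- NULL
    for (r in rules) {
      if (!is.null(r$stroke) && !(st %in% r$stroke)) next
      if (!is.null(r$bleed) && !(bl %in% r$bleed)) next
      if (!is.null(r$flags_any) && !any(r$flags_any %in% flags[[i]])) next
      fired <- r
      break
    }
    if (is.null(fired))
      stop("rule cascade is not total: no rule fired for stroke=", st,
           ", bleed=", bl)
    therapy[i] <- fired$therapy
    rule_id[i] <- fired$id
    if (verbose)
      message(sprintf("recommend: %s stroke=%s bleed=%s -> rule %s -> %s",
                      cohort$patient_id[i], st, bl, fired$id, fired$therapy))
  }

  baseline <- cohort$baseline_therapy
  same_regimen <- therapy == baseline
  inr_low <- !is.na(cohort$inr_subtherapeutic) & cohort$inr_subtherapeutic
  dose_adjust <- same_regimen & baseline == "warfarin" & inr_low
  change_required <- !same_regimen

  data.frame(
    patient_id = cohort$patient_id,
    therapy = therapy,
    rule_id = rule_id,
    rationale = paste0("stroke_", assessment$stroke_category, ";",
                       "bleed_", assessment$bleed_category, ";",
                       "rule_", rule_id),
    flags = vapply(flags, paste, "", collapse = ";"),
    change_required = change_required,
    dose_adjust = dose_adjust,
    stringsAsFactors = FALSE)
}
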