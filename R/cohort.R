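# Domain vocabulary -----------------------------------------------------------

#' Therapy regimens and derived groupings
#'
#' The antithrombotic regimens recognised by the package, the coarse therapy
#' class each belongs to, and the primary agent each contains. Warfarin- and
#' dabigatran-based regimens (with or without an accompanying antiplatelet)
#' are anticoagulant therapy; aspirin-only and clopidogrel-only are
#' antiplatelet therapy.
#'
#' @return `carat_regimens()` returns the character vector of valid regimen
#'   codes. `therapy_class(x)` maps regimen codes to
#'   `c("anticoagulant", "antiplatelet", "none", "other")`. `therapy_agent(x)`
#'   maps regimen codes to the primary agent
#'   (`warfarin`, `dabigatran`, `aspirin`, `clopidogrel`, `none`, `other`).
#' @examples
#' therapy_class("warfarin_plus_antiplatelet")  # "anticoagulant"
#' therapy_agent("dabigatran_plus_clopidogrel") # "dabigatran"
#' @export
carat_regimens <- function() {
  c("warfarin", "warfarin_plus_antiplatelet", "aspirin_only",
    "clopidogrel_only", "dabigatran", "dabigatran_plus_clopidogrel",
    "other", "none")
}

.class_map <- c(
  warfarin                    = "anticoagulant",
  warfarin_plus_antiplatelet  = "anticoagulant",
  dabigatran                  = "anticoagulant",
  dabigatran_plus_clopidogrel = "anticoagulant",
  aspirin_only                = "antiplatelet",
  clopidogrel_only            = "antiplatelet",
  none                        = "none",
  other                       = "other"
)

.agent_map <- c(
  warfarin                    = "warfarin",
  warfarin_plus_antiplatelet  = "warfarin",
  dabigatran                  = "dabigatran",
  dabigatran_plus_clopidogrel = "dabigatran",
  aspirin_only                = "aspirin",
  clopidogrel_only            = "clopidogrel",
  none                        = "none",
  other                       = "other"
)

#' @rdname carat_regimens
#' @param x character vector of regimen codes
#' @export
therapy_class <- function(x) {
  bad <- setdiff(unique(x), names(.class_map))
  if (length(bad))
    stop("unknown therapy regimen(s): ", paste(bad, collapse = ", "))
  unname(.class_map[x])
}

#' @rdname carat_regimens
#' @export
therapy_agent <- function(x) {
  bad <- setdiff(unique(x), names(.agent_map))
  if (length(bad))
    stop("unknown therapy regimen(s): ", paste(bad, collapse = ", "))
  unname(.agent_map[x])
}

# Column schema ----------------------------------------------------------------

.afib_duration_levels <- c("lt3mo", "lt12mo", "lt2y", "lt5y", "ge5y")
.afib_type_levels     <- c("paroxysmal", "persistent", "new_onset", "unknown")
.rhythm_levels        <- c("sinus", "controlled_af", "uncontrolled_af")
.arm_levels           <- c("intervention", "control")
.sex_levels           <- c("male", "female")

.stroke_factor_cols <- c("chf", "hypertension", "age_ge_75", "diabetes",
                         "prior_stroke_or_tia")

.bleed_factor_cols <- c("hepatic_or_renal", "alcohol_abuse", "malignancy",
                        "reduced_platelets", "rebleed_risk", "uncontrolled_htn",
                        "anemia", "falls_risk", "prior_hemorrhagic_stroke",
                        "age_gt_75", "genetic_factor")

.safety_cols <- c("allergy_warfarin_aspirin", "adverse_reaction",
                  "interacting_medication", "declined_therapy",
                  "contraindication", "failed_therapy", "educated",
                  "polypharmacy_ge4", "noncompliant", "needs_assistance",
                  "access_difficulty", "residential_care",
                  "cognitive_impairment", "vision_impairment",
                  "hearing_impairment", "language_barrier", "mobility_disorder",
                  "functional_impairment")

.cohort_schema_version <- "carat cohort schema v1"

#' Cohort column schema
#'
#' Column names (in file order) of the delimited cohort format. Booleans are
#' serialised as 0/1 and missing values as empty fields; the first line of a
#' cohort file is the comment `# carat cohort schema v1`.
#'
#' @return named character vector mapping column name to declared type
#'   (`"character"`, `"integer"`, `"logical"`, or an enum name).
#' @export
cohort_schema <- function() {
  c(
    patient_id = "character", gp_id = "character", arm = "arm",
    age = "integer", sex = "sex",
    chronic_condition_count = "integer", rx_med_count = "integer",
    otc_med_count = "integer",
    afib_duration = "afib_duration", afib_type = "afib_type",
    prior_hospitalization = "logical", hospitalization_reason = "character",
    rhythm = "rhythm",
    stats::setNames(rep("logical", length(.stroke_factor_cols)), .stroke_factor_cols),
    stats::setNames(rep("logical", length(.bleed_factor_cols)), .bleed_factor_cols),
    stats::setNames(rep("logical", length(.safety_cols)), .safety_cols),
    baseline_therapy = "regimen", inr_subtherapeutic = "logical"
  )
}

.enum_levels <- function(type) {
  switch(type,
    arm = .arm_levels, sex = .sex_levels,
    afib_duration = .afib_duration_levels, afib_type = .afib_type_levels,
    rhythm = .rhythm_levels, regimen = carat_regimens(),
    stop("not an enum type: ", type))
}

# Validation -------------------------------------------------------------------

#' Validate a patient cohort
#'
#' Checks every structural invariant of the cohort table: column presence and
#' types, enum membership, eligibility (age >= 65), non-negative medication
#' and comorbidity counts, the derived consistency of `age_ge_75` with `age`,
#' and of `polypharmacy_ge4` with `rx_med_count` (when both are present).
#'
#' @param cohort data frame in the [cohort_schema()] layout
#' @return character vector of violation messages, empty when the cohort is
#'   valid. Each message names the offending `patient_id` where applicable.
#' @export
validate_cohort <- function(cohort) {
  schema <- cohort_schema()
  missing_cols <- setdiff(names(schema), names(cohort))
  if (length(missing_cols))
    return(paste0("missing required column(s): ",
                  paste(missing_cols, collapse = ", ")))

  issues <- character()
  pid <- as.character(cohort$patient_id)
  bad_row <- function(mask, what) {
    if (any(mask, na.rm = TRUE))
      paste0(what, " (patient_id: ",
             paste(pid[which(mask)], collapse = ", "), ")")
    else character()
  }

  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("character", "integer", "logical")) next
    vals <- cohort[[col]]
    ok <- is.na(vals) | vals %in% .enum_levels(type)
    issues <- c(issues, bad_row(!ok, paste0("invalid ", col, " value")))
  }

  issues <- c(issues,
    bad_row(cohort$age < 65, "age below eligibility threshold of 65"),
    bad_row(cohort$chronic_condition_count < 0, "negative chronic_condition_count"),
    bad_row(cohort$rx_med_count < 0, "negative rx_med_count"),
    bad_row(cohort$otc_med_count < 0, "negative otc_med_count"),
    bad_row(!is.na(cohort$age) & !is.na(cohort$age_ge_75) &
              (cohort$age_ge_75 != (cohort$age >= 75)),
            "age_ge_75 flag inconsistent with age"),
    bad_row(!is.na(cohort$rx_med_count) & !is.na(cohort$polypharmacy_ge4) &
              (cohort$polypharmacy_ge4 != (cohort$rx_med_count >= 4)),
            "polypharmacy_ge4 flag inconsistent with rx_med_count"),
    bad_row(is.na(cohort$arm), "missing arm"),
    bad_row(is.na(cohort$baseline_therapy), "missing baseline_therapy"))

  if (anyDuplicated(pid))
    issues <- c(issues, paste0("duplicated patient_id: ",
                               paste(unique(pid[duplicated(pid)]), collapse = ", ")))
  issues
}

.row_issues <- function(cohort) {
  # per-row validity mask used by lenient reading
  n <- nrow(cohort)
  bad <- logical(n)
  schema <- cohort_schema()
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("character", "integer", "logical")) next
    bad <- bad | !(is.na(cohort[[col]]) | cohort[[col]] %in% .enum_levels(type))
  }
  bad <- bad |
    (!is.na(cohort$age) & cohort$age < 65) |
    (!is.na(cohort$chronic_condition_count) & cohort$chronic_condition_count < 0) |
    (!is.na(cohort$rx_med_count) & cohort$rx_med_count < 0) |
    (!is.na(cohort$otc_med_count) & cohort$otc_med_count < 0) |
    (!is.na(cohort$age) & !is.na(cohort$age_ge_75) &
       cohort$age_ge_75 != (cohort$age >= 75)) |
    (!is.na(cohort$rx_med_count) & !is.na(cohort$polypharmacy_ge4) &
       cohort$polypharmacy_ge4 != (cohort$rx_med_count >= 4)) |
    is.na(cohort$arm) | is.na(cohort$baseline_therapy)
  bad
}

# I/O --------------------------------------------------------------------------

#' Read a patient cohort from delimited text
#'
#' Reads a comma-separated cohort file (UTF-8, header row, leading
#' `# carat cohort schema v1` comment line). Booleans are read from 0/1 and
#' empty fields become `NA`.
#'
#' @param path path to the cohort file
#' @param strict logical; if `TRUE` (default) any invariant violation aborts
#'   with an error naming the offending patient. If `FALSE`, invalid rows are
#'   dropped with a message and the number of skipped rows is attached as
#'   attribute `"n_skipped"`.
#' @return data frame of class `carat_cohort` with attribute `n_skipped`
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  schema <- cohort_schema()
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols))
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[names(schema)]
  parse_logical <- function(v) {
    # canonical form is 0/1; TRUE/FALSE text is tolerated on input
    out <- suppressWarnings(as.logical(v))
    num <- v %in% c("0", "1")
    out[num] <- v[num] == "1"
    out
  }
  for (col in names(schema)) {
    raw[[col]] <- switch(schema[[col]],
      integer = as.integer(raw[[col]]),
      logical = parse_logical(raw[[col]]),
      raw[[col]])
  }
  if (strict) {
    issues <- validate_cohort(raw)
    if (length(issues))
      stop("cohort validation failed:\n  ", paste(issues, collapse = "\n  "))
    out <- raw
    skipped <- 0L
  } else {
    bad <- .row_issues(raw)
    skipped <- sum(bad)
    if (skipped > 0)
      message("read_cohort: skipped ", skipped, " invalid row(s)")
    out <- raw[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, n_skipped = skipped,
            class = c("carat_cohort", "data.frame"))
}

#' Write a patient cohort to delimited text
#'
#' Serialises a validated cohort in the [cohort_schema()] column order, with
#' booleans as 0/1 and missing values as empty fields, preceded by the schema
#' version comment line. `read_cohort(write_cohort(x))` reproduces `x`
#' field for field.
#'
#' @param cohort validated cohort data frame
#' @param path output file path
#' @return invisibly, the number of data rows written
#' @export
write_cohort <- function(cohort, path) {
  schema <- cohort_schema()
  issues <- validate_cohort(cohort)
  if (length(issues))
    stop("refusing to write invalid cohort:\n  ",
         paste(issues, collapse = "\n  "))
  out <- as.data.frame(cohort)[names(schema)]
  for (col in names(schema))
    if (schema[[col]] == "logical") out[[col]] <- as.integer(out[[col]])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", .cohort_schema_version), con)
  utils::write.table(out, con, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
  invisible(nrow(out))
}

#' Construct a cohort data frame from field vectors
#'
#' Low-level constructor: recycles scalar defaults across `n` patients and
#' fills derived flags (`age_ge_75`, `polypharmacy_ge4`) from `age` and
#' `rx_med_count` unless given explicitly. Used by the synthetic generator and
#' by tests; validates on exit.
#'
#' @param ... named field vectors matching [cohort_schema()] columns
#' @param validate logical, run [validate_cohort()] (default `TRUE`)
#' @return `carat_cohort` data frame
#' @export
new_cohort <- function(..., validate = TRUE) {
  fields <- list(...)
  schema <- cohort_schema()
  unknown <- setdiff(names(fields), names(schema))
  if (length(unknown))
    stop("unknown cohort field(s): ", paste(unknown, collapse = ", "))
  n <- max(vapply(fields, length, 1L))

  defaults <- list(
    gp_id = "gp1", arm = "intervention", sex = "male",
    chronic_condition_count = 0L, rx_med_count = 0L, otc_med_count = 0L,
    afib_duration = "ge5y", afib_type = "persistent",
    prior_hospitalization = FALSE, hospitalization_reason = NA_character_,
    rhythm = "controlled_af", baseline_therapy = "warfarin",
    inr_subtherapeutic = FALSE)
  for (col in c(.stroke_factor_cols, .bleed_factor_cols, .safety_cols))
    defaults[[col]] <- FALSE

  out <- list()
  for (col in names(schema)) {
    v <- fields[[col]]
    if (is.null(v)) v <- defaults[[col]]
    if (is.null(v) && col == "patient_id") v <- sprintf("p%03d", seq_len(n))
    if (is.null(v) && col == "age") v <- 70L
    out[[col]] <- rep(v, length.out = n)
  }
  if (is.null(fields$age_ge_75))        out$age_ge_75 <- out$age >= 75
  if (is.null(fields$polypharmacy_ge4)) out$polypharmacy_ge4 <- out$rx_med_count >= 4
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (validate) {
    issues <- validate_cohort(out)
    if (length(issues))
      stop("invalid cohort:\n  ", paste(issues, collapse = "\n  "))
  }
  structure(out, class = c("carat_cohort", "data.frame"))
}

#' @export
print.carat_cohort <- function(x, ...) {
  cat("<carat_cohort> ", nrow(x), " patients, ",
      length(unique(x$gp_id)), " GP cluster(s); arms: ",
      paste(sprintf("%s=%d", names(table(x$arm)), table(x$arm)),
            collapse = ", "), "\n", sep = "")
  NextMethod()
}
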