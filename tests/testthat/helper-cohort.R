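# Shared fixture builders (all fixtures are constructed in code).

# Minimal valid patients with overridable fields.
make_cohort <- function(n = 3, age = 70L, ...) {
  new_cohort(patient_id = sprintf("p%03d", seq_len(n)), age = age, ...)
}

# Drop class/attribute decoration for content comparison.
as_plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "n_skipped") <- NULL
  x
}

# Serialise a (possibly invalid) cohort data frame in the package file
# format, bypassing write_cohort's validation, to exercise the reader.
write_cohort_raw <- function(df, path) {
  schema <- cohort_schema()
  df <- as.data.frame(df)[names(schema)]
  for (col in names(schema))
    if (schema[[col]] == "logical") df[[col]] <- as.integer(df[[col]])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# carat cohort schema v1", con)
  utils::write.table(df, con, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
}

# Small cohort config used across simulator tests.
small_config <- function(...) {
  simulation_config(n_gps_per_arm = 5L, patients_per_gp = c(4L, 6L),
                    dropout = 0, ...)
}

# Per-arm therapy distribution with a given anticoagulant (warfarin) mass,
# used to isolate the clustering machinery.
balanced_therapy_dist <- function(p = 0.5) {
  d <- c(warfarin = p, warfarin_plus_antiplatelet = 0, aspirin_only = 1 - p,
         clopidogrel_only = 0, dabigatran = 0, dabigatran_plus_clopidogrel = 0,
         other = 0, none = 0)
  list(intervention = d, control = d)
}
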