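test_that("generation is reproducible and the pipeline is seed-deterministic", {
  cfg <- small_config()
  c1 <- generate_cohort(cfg, seed = 21)
  c2 <- generate_cohort(cfg, seed = 21)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_cohort(cfg, seed = 22)))
  # end-to-end: cohort -> recommendations -> decisions
  r1 <- recommend(c1)
  d1 <- simulate_gp_decisions(c1, r1, cfg$gp_behavior, seed = 99)
  d2 <- simulate_gp_decisions(c2, recommend(c2), cfg$gp_behavior, seed = 99)
  expect_identical(d1, d2)
})

test_that("generated cohorts satisfy strict validation and derived flags", {
  co <- generate_cohort(simulation_config(), seed = 23)
  expect_length(validate_cohort(co), 0)
  expect_true(all(co$age >= 65))
  expect_equal(co$age_ge_75, co$age >= 75)
  expect_equal(co$polypharmacy_ge4, co$rx_med_count >= 4)
  expect_true(all(co$uncontrolled_htn <= co$hypertension))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(as_plain(read_cohort(path)), as_plain(co))
})

test_that("configured prevalences are recovered at large n", {
  cfg <- simulation_config(n_gps_per_arm = 50L, patients_per_gp = c(100L, 100L),
                           dropout = 0)
  co <- generate_cohort(cfg, seed = 24)
  n <- nrow(co)
  expect_equal(n, 10000L)
  for (f in c("hypertension", "chf", "diabetes", "prior_stroke_or_tia",
              "malignancy", "needs_assistance", "educated")) {
    p <- cfg$factor_prevalences[[f]]
    ci <- qbinom(c(0.005, 0.995), n, p) / n
    expect_gte(mean(co[[f]]), ci[1])
    expect_lte(mean(co[[f]]), ci[2])
  }
  # age distribution near the published mean/SD, truncated at 65
  expect_equal(mean(co$age), 78.4, tolerance = 0.015)
  expect_gte(min(co$age), 65)
  # age >= 75 share matches its truncated-normal probability (with integer
  # rounding, P(age >= 74.5 | age >= 64.5) = 0.711)
  expect_equal(mean(co$age_ge_75), 0.711, tolerance = 0.025)
})

test_that("baseline therapy distribution matches the configured per-arm probabilities", {
  cfg <- simulation_config(n_gps_per_arm = 50L, patients_per_gp = c(60L, 60L),
                           dropout = 0)
  co <- generate_cohort(cfg, seed = 25)
  for (a in c("intervention", "control")) {
    d <- cfg$baseline_therapy_distribution[[a]]
    obs <- table(factor(co$baseline_therapy[co$arm == a],
                        levels = names(d))) / sum(co$arm == a)
    expect_lt(max(abs(as.numeric(obs) - as.numeric(d))), 0.04)
  }
})

test_that("dropout thins the cohort at the configured rate", {
  cfg <- simulation_config(n_gps_per_arm = 50L, patients_per_gp = c(40L, 40L),
                           dropout = 0.20)
  co <- generate_cohort(cfg, seed = 26)
  expect_equal(nrow(co) / 4000, 0.80, tolerance = 0.03)
})

test_that("icc = 0 leaves only binomial between-GP variation", {
  cfg <- simulation_config(icc = 0, dropout = 0, patients_per_gp = c(8L, 8L),
    baseline_therapy_distribution = balanced_therapy_dist())
  est <- vapply(1:40, function(s) {
    co <- generate_cohort(cfg, seed = 100 + s)
    estimate_icc(co$gp_id,
                 therapy_class(co$baseline_therapy) == "anticoagulant")$icc
  }, 0)
  expect_lt(abs(mean(est)), 0.02)
})

test_that("larger configured icc yields distinguishably larger estimates", {
  est_at <- function(target, seeds) {
    cfg <- simulation_config(icc = target, dropout = 0,
                             patients_per_gp = c(8L, 8L),
                             baseline_therapy_distribution = balanced_therapy_dist())
    vapply(seeds, function(s) {
      co <- generate_cohort(cfg, seed = s)
      estimate_icc(co$gp_id,
                   therapy_class(co$baseline_therapy) == "anticoagulant")$icc
    }, 0)
  }
  low <- est_at(0.03, 200 + 1:40)
  high <- est_at(0.30, 300 + 1:40)
  expect_gt(mean(high), mean(low) + 0.15)
})

test_that("estimate_icc signals its degenerate inputs", {
  expect_error(estimate_icc(c("a", "a", "b"), c(1, 0, NA)[c(1, 2)]),
               "length")
  expect_error(estimate_icc(rep("a", 5), rbinom(5, 1, 0.5)), "2 clusters")
  expect_error(estimate_icc(c("a", "b", "c"), c(1, 0, 1)), "single member")
  expect_warning(r <- estimate_icc(rep(c("a", "b"), each = 4), rep(1, 8)),
                 "constant")
  expect_true(is.nan(r$icc))
})

test_that("GP decision behavior honours its boundary parameters", {
  cfg <- small_config()
  co <- generate_cohort(cfg, seed = 27)
  rec <- recommend(co)
  # full acceptance: perfect agreement and kappa 1 (when both categories occur)
  beh1 <- cfg$gp_behavior; beh1$p_accept <- 1
  dec1 <- simulate_gp_decisions(co, rec, beh1, seed = 1)
  expect_equal(percent_agreement(dec1), 1.0)
  if (length(unique(rec$therapy)) >= 2)
    expect_equal(agreement_summary(dec1)$kappa, 1)
  # certain dabigatran substitution on rejected warfarin recommendations
  beh2 <- cfg$gp_behavior
  beh2$p_accept <- 0
  beh2$p_dabigatran_given_warfarin_rejection <- 1
  dec2 <- simulate_gp_decisions(co, rec, beh2, seed = 2)
  warf <- rec$therapy == "warfarin"
  expect_true(all(dec2$gp_final_therapy[warf] == "dabigatran"))
  expect_true(all(dec2$gp_final_therapy != rec$therapy))
  expect_true(all(!is.na(dec2$disagreement_reason[!dec2$agree_overall])))
  expect_error(simulate_gp_decisions(co[1:3, ], rec), "length")
})

test_that("acceptance probability is recovered in a large decision sample", {
  cfg <- simulation_config(n_gps_per_arm = 25L, patients_per_gp = c(40L, 40L),
                           dropout = 0)
  co <- generate_cohort(cfg, seed = 28)
  rec <- recommend(co)
  beh <- cfg$gp_behavior; beh$p_accept <- 0.75
  dec <- simulate_gp_decisions(co, rec, beh, seed = 3)
  n <- nrow(dec)
  ci <- qbinom(c(0.005, 0.995), n, 0.75) / n
  agree <- percent_agreement(dec)
  expect_gte(agree, ci[1]); expect_lte(agree, ci[2])
})
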