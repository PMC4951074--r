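rankable <- setdiff(carat_regimens(), "other")

test_that("classify_change reproduces the documented transition examples", {
  expect_equal(classify_change("none", "warfarin"), "upgrade")
  expect_equal(classify_change("aspirin_only", "warfarin"), "upgrade")
  expect_equal(classify_change("warfarin_plus_antiplatelet", "warfarin"),
               "side_step")
  expect_equal(classify_change("dabigatran", "warfarin"), "side_step")
  expect_equal(classify_change("dabigatran", "aspirin_only"), "downgrade")
  expect_equal(classify_change("warfarin", "none"), "downgrade")
  expect_equal(classify_change("warfarin", "warfarin"), "no_change")
  expect_equal(classify_change("warfarin", "warfarin", dose_changed = TRUE),
               "dose_adjust")
})

test_that("the five classes partition all rankable transitions", {
  grid <- expand.grid(baseline = rankable, target = rankable,
                      stringsAsFactors = FALSE)
  cls <- classify_change(grid$baseline, grid$target)
  expect_true(all(cls %in% c("no_change", "upgrade", "side_step", "downgrade")))
  # anti-symmetry: reversing an upgrade gives a downgrade and vice versa
  rev_cls <- classify_change(grid$target, grid$baseline)
  expect_equal(rev_cls[cls == "upgrade"],
               rep("downgrade", sum(cls == "upgrade")))
  expect_equal(rev_cls[cls == "downgrade"],
               rep("upgrade", sum(cls == "downgrade")))
  expect_equal(rev_cls[cls == "side_step"],
               rep("side_step", sum(cls == "side_step")))
})

test_that("'other' is unrankable unless a rank is configured", {
  expect_error(classify_change("other", "warfarin"), "unrankable|other_rank")
  expect_equal(classify_change("other", "warfarin", other_rank = 1), "upgrade")
  expect_equal(classify_change("other", "none", other_rank = 1), "downgrade")
})

test_that("tabulate_changes uses the changed subset as denominator", {
  tab <- tabulate_changes(c(rep("upgrade", 1)))
  expect_equal(tab$percent_of_changes[tab$change == "upgrade"], 100.0)

  # all-no-change input: denominator undefined, reported as NA not 0
  tab0 <- tabulate_changes(rep("no_change", 75))
  expect_equal(tab0$n[tab0$change == "no_change"], 75L)
  expect_true(all(is.na(tab0$percent_of_changes)))

  expect_error(tabulate_changes(character(0)), "no transitions")
  # counts always conserve the input total
  set.seed(8)
  trans <- data.frame(baseline = sample(rankable, 200, replace = TRUE),
                      target = sample(rankable, 200, replace = TRUE))
  expect_equal(sum(tabulate_changes(trans)$n), 200L)
})

test_that("percent agreement counts identical-regimen pairs", {
  pairs <- agreement_records(rep("warfarin", 4),
                             c("warfarin", "warfarin", "warfarin", "dabigatran"))
  expect_equal(percent_agreement(pairs), 0.75)
  expect_equal(percent_agreement(pairs, "class"), 1.0)  # both anticoagulant
  all_agree <- agreement_records(c("warfarin", "aspirin_only"),
                                 c("warfarin", "aspirin_only"))
  expect_equal(percent_agreement(all_agree), 1.0)
  expect_error(percent_agreement(all_agree[0, ]), "no pairs")
  # 155 of 206 reproduces the trial-scale arithmetic
  pa <- percent_agreement(agreement_records(
    rep("warfarin", 206), rep(c("warfarin", "dabigatran"), c(155, 51))))
  expect_equal(round(pa, 3), 0.752)
})

test_that("agreement levels nest: agent implies class", {
  grid <- expand.grid(a = carat_regimens(), b = carat_regimens(),
                      stringsAsFactors = FALSE)
  rec <- agreement_records(grid$a, grid$b)
  expect_true(all(!rec$agree_agent | rec$agree_class))
  expect_equal(rec$agree_overall, grid$a == grid$b)
})

test_that("Fleiss kappa matches a hand-computed toy table and its edge cases", {
  # 4 subjects, 2 raters, 3 agreements; marginals 5/8 vs 3/8.
  # Po = 3/4; Pe = (5/8)^2 + (3/8)^2 = 34/64; kappa = (48-34)/(64-34) = 7/15.
  toy <- rbind(c(2, 0), c(0, 2), c(2, 0), c(1, 1))
  k <- fleiss_kappa(toy)
  expect_equal(k$p_observed, 3 / 4)
  expect_equal(k$p_expected, 34 / 64)
  expect_equal(k$kappa, 7 / 15, tolerance = 1e-12)

  # perfect agreement with both categories used
  perfect <- rbind(matrix(c(2, 0), 5, 2, byrow = TRUE),
                   matrix(c(0, 2), 5, 2, byrow = TRUE))
  expect_equal(fleiss_kappa(perfect)$kappa, 1)

  # degenerate marginals are signalled, not silently returned
  expect_warning(k1 <- fleiss_kappa(matrix(c(2, 0, 2, 0), 2, 2, byrow = TRUE)),
                 "degenerate")
  expect_true(is.nan(k1$kappa))

  expect_error(fleiss_kappa(rbind(c(2, 0), c(1, 0))), "same number of raters")
})

test_that("reason tallies cover disagreeing pairs only and conserve counts", {
  pairs <- agreement_records(
    rep("warfarin", 6),
    c("warfarin", "dabigatran", "dabigatran", "aspirin_only", "warfarin", "none"),
    disagreement_reason = c(NA, "familiarization_program", "cardiologist",
                            "patient_refusal", NA, "patient_refusal"))
  tal <- tally_reasons(pairs)
  expect_equal(sum(tal), 4L)
  expect_equal(tal[["patient_refusal"]], 2L)
  expect_length(tally_reasons(pairs[pairs$agree_overall, ]), 0)
})

test_that("agreement_summary bundles the analyses coherently", {
  pairs <- agreement_records(rep(c("warfarin", "aspirin_only"), c(30, 10)),
                             c(rep("warfarin", 25), rep("dabigatran", 5),
                               rep("aspirin_only", 8), rep("none", 2)))
  s <- agreement_summary(pairs)
  expect_equal(s$n, 40)
  expect_equal(s$percent_agreement, 33 / 40)
  expect_true(s$percent_agreement_class >= s$percent_agreement)
  expect_true(s$kappa >= -1 && s$kappa <= 1)
})
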