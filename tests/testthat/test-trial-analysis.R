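test_that("identical arms give p = 1 on a binary variable", {
  co <- data.frame(arm = rep(c("intervention", "control"), each = 40),
                   flag = rep(c(TRUE, FALSE), 40))
  r <- compare_arms(co, "flag")
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_equal(r$test, "chi_square")
  expect_error(compare_arms(co, "missing_var"), "no such variable")
  co$const <- TRUE
  expect_error(compare_arms(co, "const"), "constant")
})

test_that("sparse 2x2 tables fall back to the exact test; 9/197 vs 0/187", {
  co <- data.frame(
    arm = rep(c("intervention", "control"), c(206, 187)),
    changed = rep(c(TRUE, FALSE, FALSE), c(9, 197, 187)))
  r <- compare_arms(co, "changed")
  expect_equal(r$test, "fisher_exact")
  # independent check against the established implementation
  ref <- stats::fisher.test(table(co$arm, co$changed))$p.value
  expect_equal(r$p_value, ref, tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)
})

test_that("vectorized exact p agrees with stats::fisher.test on random tables", {
  set.seed(9)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("summary-statistic t reproduces the printed chronic-conditions contrast", {
  # means 6.1 (SD 2.7, n 206) vs 5.4 (SD 2.3, n 187)
  r <- t_from_summary(6.1, 2.7, 206, 5.4, 2.3, 187)
  expect_equal(r$statistic, 2.774, tolerance = 5e-4)
  expect_lt(r$p_value, 0.01)
  # pooled form is close but distinct
  rp <- t_from_summary(6.1, 2.7, 206, 5.4, 2.3, 187, pooled = TRUE)
  expect_equal(rp$statistic, 2.753, tolerance = 5e-4)
  # agrees with t.test on raw data generated to match the summaries
  set.seed(10)
  x <- rnorm(206); x <- (x - mean(x)) / sd(x) * 2.7 + 6.1
  y <- rnorm(187); y <- (y - mean(y)) / sd(y) * 2.3 + 5.4
  tt <- t.test(x, y)
  rr <- t_from_summary(mean(x), sd(x), 206, mean(y), sd(y), 187)
  expect_equal(rr$statistic, unname(tt$statistic), tolerance = 1e-10)
})

test_that("univariate screen has type-I error near alpha and high power", {
  set.seed(11)
  # null: independent covariate excluded in about 90% of replicates
  excl <- replicate(150, {
    y <- rbinom(300, 1, 0.5)
    x <- rnorm(300)
    !univariate_screen(y, data.frame(x = x), alpha = 0.10)$selected
  })
  expect_gt(mean(excl), 0.84)
  expect_lt(mean(excl), 0.96)
  # power: true OR 3 at n = 1000 is essentially always retained
  incl <- replicate(50, {
    x <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(log(3) * x))
    univariate_screen(y, data.frame(x = x), alpha = 0.10)$selected
  })
  expect_true(all(incl))
  # constant covariates are excluded with a warning
  expect_warning(
    s <- univariate_screen(rbinom(50, 1, 0.5),
                           data.frame(k = rep(1, 50))), "constant")
  expect_false(s$selected)
})

test_that("stepwise selection recovers a single true predictor among noise", {
  set.seed(12)
  n <- 2000
  x_true <- rnorm(n)
  noise <- as.data.frame(matrix(rnorm(n * 10), n,
                                dimnames = list(NULL, sprintf("n%02d", 1:10))))
  y <- rbinom(n, 1, plogis(-0.5 + log(3) * x_true))
  cands <- cbind(data.frame(x_true = x_true), noise)
  fit <- forward_stepwise_wald(y, cands)
  expect_true("x_true" %in% fit$selected)
  or <- fit$terms$odds_ratio[fit$terms$covariate == "x_true"]
  expect_gt(or, 2); expect_lt(or, 4.5)
  expect_true(all(fit$terms$ci_lower <= fit$terms$odds_ratio &
                    fit$terms$odds_ratio <= fit$terms$ci_upper))
  expect_gt(fit$classification_rate, 0.5)
})

test_that("stepwise stays empty or near-empty under the null", {
  set.seed(13)
  sizes <- replicate(20, {
    y <- rbinom(300, 1, 0.5)
    cands <- as.data.frame(matrix(rnorm(300 * 8), 300,
                                  dimnames = list(NULL, sprintf("n%d", 1:8))))
    length(forward_stepwise_wald(y, cands)$selected)
  })
  expect_gt(mean(sizes == 0), 0.5)
  expect_lt(mean(sizes), 1)
})

test_that("selection order is invariant to candidate column order", {
  set.seed(14)
  n <- 800
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x1 - 0.6 * x2))
  cands <- data.frame(x1 = x1, x2 = x2, z = rnorm(n))
  f1 <- forward_stepwise_wald(y, cands)
  f2 <- forward_stepwise_wald(y, cands[c("z", "x2", "x1")])
  expect_equal(sort(f1$selected), sort(f2$selected))
  expect_equal(f1$terms[order(f1$terms$covariate), ],
               f2$terms[order(f2$terms$covariate), ],
               ignore_attr = TRUE)
})

test_that("pseudo R-squared follows its closed forms and ordering", {
  # toy log-likelihoods: Cox-Snell = 1 - exp(-0.5)
  r <- pseudo_r2(ll0 = -10, ll1 = -5, n = 20)
  expect_equal(unname(r["cox_snell"]), 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(unname(r["nagelkerke"]),
               (1 - exp(-0.5)) / (1 - exp(-1)), tolerance = 1e-12)
  # null vs itself is (0, 0)
  expect_equal(unname(pseudo_r2(ll0 = -7, ll1 = -7, n = 10)), c(0, 0))
  expect_error(pseudo_r2(ll0 = -5, ll1 = -6, n = 10), "invalid fit")
  # Nagelkerke >= Cox-Snell on every valid fit
  set.seed(15)
  for (i in 1:20) {
    y <- rbinom(150, 1, plogis(rnorm(1) + 0.5 * rnorm(150)))
    if (length(unique(y)) < 2) next
    x <- rnorm(150)
    fit <- glm(y ~ x, family = binomial)
    r <- pseudo_r2(fit)
    expect_gte(r[["nagelkerke"]], r[["cox_snell"]] - 1e-12)
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("separation is reported rather than producing silent estimates", {
  y <- rep(c(TRUE, FALSE), each = 25)
  cands <- data.frame(mirror = y)
  expect_warning(univariate_screen(y, cands), "separation")
  fit <- forward_stepwise_wald(y, cands)
  expect_length(fit$selected, 0)   # separated candidate skipped, logged
})
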