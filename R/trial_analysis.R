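# Arm comparisons, univariate screening, forward stepwise Wald logistic
# regression, pseudo R-squared -------------------------------------------------

#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' Exact conditional test on a 2x2 table: with margins fixed, the first cell
#' follows a hypergeometric distribution; the two-sided p-value is the total
#' probability of all tables whose point probability does not exceed that of
#' the observed table (with the conventional 1e-7 relative guard against
#' ties lost to floating point). Vectorised over tables.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome:
#'   table is `rbind(c(a, b), c(c, d))`
#' @return numeric vector of p-values
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep(a, length.out = n); b <- rep(b, length.out = n)
  c <- rep(c, length.out = n); d <- rep(d, length.out = n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("negative cell count")
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 total
    k <- a[i] + c[i]          # column 1 total
    tot <- m + c[i] + d[i]
    lo <- max(0L, k - (tot - m)); hi <- min(k, m)
    if (lo == hi) return(1)
    support <- lo:hi
    p <- stats::dhyper(support, m, tot - m, k)
    p_obs <- p[support == a[i]]
    sum(p[p <= p_obs * (1 + 1e-7)])
  }, 0)
}

#' Welch / pooled t statistic from summary statistics
#'
#' Two-sample t statistic computed from group means, standard deviations and
#' sizes, as printed in a baseline-characteristics table.
#'
#' @param m1,s1,n1,m2,s2,n2 group means, SDs, sizes
#' @param pooled logical; pooled-variance (equal-variance) form instead of
#'   the default unequal-variance Welch form
#' @return list with `statistic`, `df`, `p_value`
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2, pooled = FALSE) {
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  list(statistic = stat, df = df,
       p_value = 2 * stats::pt(-abs(stat), df))
}

#' Compare a variable between trial arms
#'
#' Arm comparison with automatic test choice, recorded in the result:
#' categorical (logical, character or factor) variables use the Pearson
#' chi-square test without continuity correction, falling back to the Fisher
#' exact test on 2x2 tables when any expected cell count is below 5;
#' numeric variables use the unequal-variance t test by default (pooled via
#' `equal_var = TRUE`); `rank = TRUE` switches numeric comparisons to the
#' Mann-Whitney (2 arms) or Kruskal-Wallis (more groups) rank test.
#'
#' @param cohort `carat_cohort` data frame (or any data frame with an `arm`
#'   column)
#' @param variable column name to compare
#' @param rank logical, use a rank test for numeric variables
#' @param equal_var logical, pooled-variance t test
#' @return object of class `arm_comparison`: list with `variable`, `test`,
#'   `statistic`, `p_value`
#' @export
compare_arms <- function(cohort, variable, rank = FALSE, equal_var = FALSE) {
  if (!variable %in% names(cohort)) stop("no such variable: ", variable)
  x <- cohort[[variable]]
  arm <- factor(cohort$arm)
  keep <- !is.na(x) & !is.na(arm)
  x <- x[keep]; arm <- droplevels(arm[keep])
  if (length(unique(x)) < 2)
    stop("variable ", variable, " is constant; arm comparison is degenerate")

  if (is.numeric(x) && !rank) {
    if (nlevels(arm) == 2) {
      ht <- stats::t.test(x ~ arm, var.equal = equal_var)
      res <- list(test = "t_or_anova", statistic = unname(ht$statistic),
                  p_value = ht$p.value)
    } else {
      ht <- stats::anova(stats::aov(x ~ arm))
      res <- list(test = "t_or_anova", statistic = ht$`F value`[1],
                  p_value = ht$`Pr(>F)`[1])
    }
  } else if (is.numeric(x)) {
    if (nlevels(arm) == 2) {
      ht <- stats::wilcox.test(x ~ arm, exact = FALSE)
      res <- list(test = "mann_whitney", statistic = unname(ht$statistic),
                  p_value = ht$p.value)
    } else {
      ht <- stats::kruskal.test(x ~ arm)
      res <- list(test = "kruskal_wallis", statistic = unname(ht$statistic),
                  p_value = ht$p.value)
    }
  } else {
    tab <- table(arm, x)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(dim(tab) == 2) && any(expected < 5)) {
      p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
      res <- list(test = "fisher_exact", statistic = NA_real_, p_value = p)
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      res <- list(test = "chi_square", statistic = unname(ht$statistic),
                  p_value = ht$p.value)
    }
  }
  structure(c(list(variable = variable), res), class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %s, p = %.4g\n", x$variable, x$test,
              ifelse(is.na(x$statistic), "-", format(x$statistic, digits = 4)),
              x$p_value))
  invisible(x)
}

# Logistic modelling -----------------------------------------------------------

.fit_logistic <- function(outcome, data, terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- stats::as.formula(paste(".outcome ~", rhs))
  data$.outcome <- outcome
  suppressWarnings(stats::glm(f, family = stats::binomial(), data = data))
}

.is_separated <- function(fit) {
  any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) || !fit$converged
}

.term_rows <- function(fit, v, coef_names) {
  # coefficient rows belonging to model term v (robust to shared prefixes)
  asg <- attr(stats::model.matrix(fit), "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  idx <- which(asg != 0 & labs[pmax(asg, 1L)] == v)
  intersect(colnames(stats::model.matrix(fit))[idx], coef_names)
}

#' Univariate screening of candidate predictors
#'
#' Fits one single-predictor logistic regression per candidate and retains
#' those whose predictor is associated with the outcome at `p < alpha`
#' (default 0.10, the conventional screening threshold ahead of a
#' multivariate model). For a multi-coefficient (factor) candidate the
#' smallest coefficient p-value is used. Constant covariates are dropped
#' with a warning; covariates showing quasi-complete separation are flagged
#' but retained.
#'
#' @param outcome logical or 0/1 vector
#' @param covariates data frame of candidate predictors
#' @param alpha screening threshold (default 0.10)
#' @return data frame with one row per candidate: `covariate`, `p_value`,
#'   `selected`, `separated`
#' @export
univariate_screen <- function(outcome, covariates, alpha = 0.10) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop("outcome is constant")
  res <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("covariate ", v, " is constant; excluded from screening")
      return(data.frame(covariate = v, p_value = NA_real_, selected = FALSE,
                        separated = FALSE, stringsAsFactors = FALSE))
    }
    fit <- .fit_logistic(outcome, covariates[v], v)
    sep <- .is_separated(fit)
    if (sep)
      warning("covariate ", v, " shows (quasi-)separation; retained with flag")
    cf <- summary(fit)$coefficients
    p <- min(cf[-1, "Pr(>|z|)"])
    data.frame(covariate = v, p_value = p, selected = p < alpha,
               separated = sep, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cox-Snell and Nagelkerke pseudo R-squared
#'
#' Cox-Snell = 1 - exp(2 (LL0 - LL1) / n); Nagelkerke rescales it by its
#' attainable maximum 1 - exp(2 LL0 / n), so Nagelkerke >= Cox-Snell on
#' every valid fit.
#'
#' @param fit a fitted `glm` (binomial), or `NULL` when supplying
#'   log-likelihoods directly
#' @param ll0,ll1,n null-model log-likelihood, model log-likelihood and
#'   sample size (extracted from `fit` when given)
#' @return named numeric vector `c(cox_snell, nagelkerke)`
#' @export
pseudo_r2 <- function(fit = NULL, ll0 = NULL, ll1 = NULL, n = NULL) {
  if (!is.null(fit)) {
    ll1 <- as.numeric(stats::logLik(fit))
    # intercept-only binomial log-likelihood in closed form
    y <- fit$y
    p0 <- mean(y)
    ll0 <- if (p0 %in% c(0, 1)) 0 else
      sum(y * log(p0) + (1 - y) * log(1 - p0))
    n <- stats::nobs(fit)
  }
  if (ll1 < ll0 - 1e-8) stop("model log-likelihood below null: invalid fit")
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  max_cs <- 1 - exp(2 * ll0 / n)
  nk <- if (max_cs > 0) cs / max_cs else 0
  c(cox_snell = cs, nagelkerke = nk)
}

#' Forward stepwise (Wald) logistic regression
#'
#' Starts from the intercept-only model, repeatedly adds the candidate with
#' the smallest Wald p-value below `entry_p` (ties broken by covariate name
#' order), and after each entry re-tests every included term by its Wald
#' statistic, removing terms whose p-value exceeds `removal_p`. Revisiting a
#' previously seen model terminates the loop, which guarantees termination.
#' Candidates whose augmented fit fails to converge (separation) are skipped
#' with a message.
#'
#' @param outcome logical or 0/1 vector
#' @param candidates data frame of screened candidate predictors
#' @param entry_p Wald p-value required to enter (default 0.05)
#' @param removal_p Wald p-value above which an included term is removed
#'   (default 0.10)
#' @param cluster optional cluster id vector (e.g. GP id); when supplied,
#'   odds-ratio confidence intervals and reported p-values use a
#'   cluster-robust (CR0 with G/(G-1) adjustment) covariance and t quantiles
#'   on G - 1 degrees of freedom; selection itself always uses the
#'   model-based Wald statistics
#' @param conf_level confidence level for odds-ratio intervals
#' @return object of class `carat_logistic`: list with `terms` (data frame
#'   of covariate, odds_ratio, ci_lower, ci_upper, p_value),
#'   `classification_rate` at the 0.5 cutoff, `r2_cox_snell`,
#'   `r2_nagelkerke`, `cluster_adjusted`, `selected`, `fit`
#' @export
forward_stepwise_wald <- function(outcome, candidates, entry_p = 0.05,
                                  removal_p = 0.10, cluster = NULL,
                                  conf_level = 0.95) {
  outcome <- as.logical(outcome)
  vars <- sort(names(candidates))
  included <- character(0)
  seen <- character(0)
  state_key <- function(s) paste(sort(s), collapse = "+")

  repeat {
    seen <- c(seen, state_key(included))
    # entry step: best Wald p among candidates not yet included
    pool <- setdiff(vars, included)
    entry <- NULL
    best_p <- entry_p
    for (v in pool) {
      fit_v <- .fit_logistic(outcome, candidates, c(included, v))
      if (.is_separated(fit_v)) next
      cf <- summary(fit_v)$coefficients
      rows <- .term_rows(fit_v, v, rownames(cf))
      if (!length(rows)) next
      p_v <- min(cf[rows, "Pr(>|z|)"])
      if (p_v < best_p - 1e-12 ||
          (abs(p_v - best_p) <= 1e-12 && !is.null(entry) && v < entry)) {
        best_p <- p_v
        entry <- v
      }
    }
    if (is.null(entry)) break
    included <- c(included, entry)

    # removal step: Wald re-test of included terms
    repeat {
      fit <- .fit_logistic(outcome, candidates, included)
      cf <- summary(fit)$coefficients
      worst <- NULL; worst_p <- removal_p
      for (v in included) {
        rows <- .term_rows(fit, v, rownames(cf))
        p_v <- min(cf[rows, "Pr(>|z|)"])
        if (p_v > worst_p) { worst_p <- p_v; worst <- v }
      }
      if (is.null(worst)) break
      included <- setdiff(included, worst)
      if (!length(included)) break
    }
    if (state_key(included) %in% seen) break
  }

  fit <- .fit_logistic(outcome, candidates, included)
  cf <- summary(fit)$coefficients
  est <- stats::coef(fit)

  cluster_adjusted <- !is.null(cluster)
  if (cluster_adjusted) {
    used <- as.integer(rownames(fit$model))
    vc <- sandwich::vcovCL(fit, cluster = cluster[used],
                           type = "HC0", cadjust = TRUE)
    se <- sqrt(diag(vc))
    g <- length(unique(cluster))
    q <- stats::qt(1 - (1 - conf_level) / 2, df = g - 1)
    pvals <- 2 * stats::pt(-abs(est / se), df = g - 1)
  } else {
    se <- cf[, "Std. Error"]
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    pvals <- cf[, "Pr(>|z|)"]
  }

  keep <- setdiff(rownames(cf), "(Intercept)")
  terms <- data.frame(
    covariate = keep,
    odds_ratio = exp(est[keep]),
    ci_lower = exp(est[keep] - q * se[keep]),
    ci_upper = exp(est[keep] + q * se[keep]),
    p_value = pvals[keep],
    row.names = NULL, stringsAsFactors = FALSE)

  pred <- stats::predict(fit, type = "response") >= 0.5
  r2 <- pseudo_r2(fit)

  structure(list(
    terms = terms,
    selected = included,
    classification_rate = mean(pred == outcome),
    r2_cox_snell = unname(r2["cox_snell"]),
    r2_nagelkerke = unname(r2["nagelkerke"]),
    cluster_adjusted = cluster_adjusted,
    entry_p = entry_p, removal_p = removal_p,
    fit = fit), class = "carat_logistic")
}

#' @export
print.carat_logistic <- function(x, ...) {
  cat("Forward stepwise (Wald) logistic regression\n")
  cat("  terms entered:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  if (nrow(x$terms)) {
    tt <- x$terms
    cat(sprintf("  %-28s OR %5.2f (%.2f-%.2f), p = %.3g\n",
                tt$covariate, tt$odds_ratio, tt$ci_lower, tt$ci_upper,
                tt$p_value), sep = "")
  }
  cat(sprintf("  correctly classified %.1f%% of cases\n",
              100 * x$classification_rate))
  cat(sprintf("  Cox & Snell R2 = %.3f; Nagelkerke R2 = %.3f%s\n",
              x$r2_cox_snell, x$r2_nagelkerke,
              if (x$cluster_adjusted) " (cluster-robust intervals)" else ""))
  invisible(x)
}
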