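effects_input <- function(x) {
  if (inherits(x, "meta_pool")) x <- x$effects
  if (!is.data.frame(x) || !all(c("log_or", "se") %in% names(x))) {
    abort("Expected a meta_pool object or a tibble with `log_or` and `se` columns.")
  }
  if (!"study_id" %in% names(x)) x$study_id <- paste("study", seq_len(nrow(x)))
  x
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `log_or/se` on the
#' precision `1/se`. Under a symmetric funnel the intercept is zero; a
#' non-zero intercept indicates small-study (publication) bias. The
#' intercept is tested two-sided against a t distribution with k-2
#' degrees of freedom.
#'
#' @param effects A `meta_pool` object or a tibble with `log_or` and `se`
#'   columns (k >= 3 studies).
#' @param ci_level Confidence level for the intercept interval.
#' @return A one-row tibble: `k`, `intercept`, `se_intercept`, `t`, `df`,
#'   `p`, `ci_low`, `ci_high`, `slope`.
#' @examples
#' load_fixture("table1") |> filter_hwe() |> pool_auto("allelic") |> egger_test()
#' @export
egger_test <- function(effects, ci_level = 0.95) {
  eff <- effects_input(effects)
  k <- nrow(eff)
  if (k < 3) abort("Egger's test needs at least 3 studies.")
  y_std <- eff$log_or / eff$se
  prec <- 1 / eff$se
  fit <- lm(y_std ~ prec)
  # a perfect fit is handled explicitly below; summary.lm's warning is noise
  ct <- suppressWarnings(summary(fit))$coefficients
  b0 <- ct["(Intercept)", "Estimate"]
  se0 <- ct["(Intercept)", "Std. Error"]
  if (!is.finite(se0) || se0 < 1e-12) {
    # degenerate fit (e.g. all effects identical with identical se)
    return(tibble(k = k, intercept = b0, se_intercept = NA_real_,
                  t = NA_real_, df = k - 2L, p = 1,
                  ci_low = NA_real_, ci_high = NA_real_,
                  slope = unname(coef(fit)["prec"])))
  }
  tstat <- b0 / se0
  tq <- qt(1 - (1 - ci_level) / 2, df = k - 2)
  tibble(k = k, intercept = b0, se_intercept = se0, t = tstat, df = k - 2L,
         p = 2 * pt(abs(tstat), df = k - 2, lower.tail = FALSE),
         ci_low = b0 - tq * se0, ci_high = b0 + tq * se0,
         slope = unname(coef(fit)["prec"]))
}

# Kendall score between two vectors: concordant minus discordant pairs,
# plus the tie-corrected variance of the score.
kendall_score <- function(x, y) {
  k <- length(x)
  score <- 0L
  for (i in seq_len(k - 1)) {
    dx <- sign(x[(i + 1):k] - x[i])
    dy <- sign(y[(i + 1):k] - y[i])
    score <- score + sum(dx * dy)
  }
  tie_term <- function(v) {
    t <- table(v)
    t <- t[t > 1]
    sum(t * (t - 1) * (2 * t + 5))
  }
  var_score <- (k * (k - 1) * (2 * k + 5) - tie_term(x) - tie_term(y)) / 18
  list(score = score, var = var_score)
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Kendall rank correlation between standardized deviates and sampling
#' variances. Each study's deviate is `(log_or - fixed-effect mean) /
#' sqrt(se^2 - 1/sum(w))` with inverse-variance weights `w = 1/se^2`; the
#' Kendall score between deviates and variances is tested with the
#' normal approximation (tie-corrected variance, continuity correction of
#' 1 on the absolute score).
#'
#' @param effects A `meta_pool` object or a tibble with `log_or` and `se`
#'   (k >= 2 studies).
#' @return A one-row tibble: `k`, `score` (Kendall score), `z`, `p`.
#' @examples
#' load_fixture("table1") |> filter_hwe() |> pool_auto("allelic") |> begg_test()
#' @export
begg_test <- function(effects) {
  eff <- effects_input(effects)
  k <- nrow(eff)
  if (k < 2) abort("Begg's test needs at least 2 studies.")
  w <- 1 / eff$se^2
  ybar <- sum(w * eff$log_or) / sum(w)
  v_dev <- eff$se^2 - 1 / sum(w)
  if (any(v_dev <= 0)) {
    warn("Deviate variance(s) at or below zero floored at a small epsilon.")
    v_dev <- pmax(v_dev, 1e-12)
  }
  u <- (eff$log_or - ybar) / sqrt(v_dev)
  ks <- kendall_score(u, eff$se^2)
  z <- if (ks$var > 0) max(abs(ks$score) - 1, 0) / sqrt(ks$var) else 0
  tibble(k = k, score = as.integer(ks$score), z = z,
         p = 2 * pnorm(z, lower.tail = FALSE))
}

#' Study-level data for a funnel plot
#'
#' @param effects A `meta_pool` object or a tibble with `log_or` and `se`.
#' @return A tibble with one row per study: `study_id`, `log_or`, `or`,
#'   `se`, `precision`.
#' @export
funnel_data <- function(effects) {
  if (is.data.frame(effects) && nrow(effects) == 0) {
    return(tibble(study_id = character(), log_or = double(), or = double(),
                  se = double(), precision = double()))
  }
  eff <- effects_input(effects)
  tibble(study_id = eff$study_id, log_or = eff$log_or, or = exp(eff$log_or),
         se = eff$se, precision = 1 / eff$se)
}

#' Funnel plot of per-study effects
#'
#' @param effects A `meta_pool` object or tibble with `log_or` and `se`.
#' @return A ggplot: log odds ratio against standard error (inverted
#'   axis), with the pooled estimate (fixed-effect mean) as a reference
#'   line.
#' @export
plot_funnel <- function(effects) {
  fd <- funnel_data(effects)
  w <- 1 / fd$se^2
  center <- sum(w * fd$log_or) / sum(w)
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$log_or, y = .data$se)) +
    ggplot2::geom_vline(xintercept = center, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log odds ratio", y = "standard error") +
    ggplot2::theme_minimal()
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the pooled analysis of [pool_auto()] once per study with that
#' study omitted. The analysis is flagged stable when every omitted-study
#' confidence interval excludes 1 on the same side as the full analysis.
#'
#' @inheritParams pool_auto
#' @return A tibble with one row per omitted study (`omitted`, `k`,
#'   `method`, `or`, `ci_low`, `ci_high`, `z`, `p`, `p_het`) carrying the
#'   full-analysis summary as attribute `"full"` and the stability flag as
#'   attribute `"stable"`.
#' @examples
#' loo <- load_fixture("table1") |> filter_hwe() |> leave_one_out("allelic")
#' attr(loo, "stable")
#' @export
leave_one_out <- function(studies, model = names(genetic_models()),
                          het_threshold = 0.1, ci_level = 0.95,
                          increment = 0.5) {
  assert_studies(studies)
  model <- match.arg(model)
  if (nrow(studies) < 3) abort("Leave-one-out needs at least 3 studies.")
  full <- pool_auto(studies, model, het_threshold = het_threshold,
                    ci_level = ci_level, increment = increment)
  rows <- purrr::map(seq_len(nrow(studies)), function(i) {
    fit <- pool_auto(studies[-i, , drop = FALSE], model,
                     het_threshold = het_threshold, ci_level = ci_level,
                     increment = increment)
    g <- glance(fit)
    tibble(omitted = studies$study_id[i], k = g$k, method = g$method,
           or = g$or, ci_low = g$ci_low, ci_high = g$ci_high,
           z = g$z, p = g$p, p_het = g$p_het)
  })
  out <- bind_rows(rows)
  stable <- if (full$ci_low > 1) {
    all(out$ci_low > 1)
  } else if (full$ci_high < 1) {
    all(out$ci_high < 1)
  } else {
    NA
  }
  attr(out, "full") <- glance(full)
  attr(out, "stable") <- stable
  out
}
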