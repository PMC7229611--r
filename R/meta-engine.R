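# Plain-vector kernels --------------------------------------------------
# These do the arithmetic; the exported functions wrap them in tibbles.

or_woolf <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    abort("Zero cell(s) present; apply_continuity() before estimating effects.")
  }
  list(log_or = log(a * d / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

q_stats <- function(log_or, se) {
  w <- 1 / se^2
  ybar <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - ybar)^2)
  df <- length(log_or) - 1L
  denom <- sum(w) - sum(w^2) / sum(w)
  list(q = q, df = df,
       p_het = pchisq(q, df, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0,
       tau2 = if (denom > 0) max(0, (q - df) / denom) else 0)
}

mh_kernel <- function(a, b, c, d) {
  n <- a + b + c + d
  r_i <- a * d / n
  s_i <- b * c / n
  r_sum <- sum(r_i)
  s_sum <- sum(s_i)
  if (r_sum == 0 || s_sum == 0) {
    abort("Degenerate Mantel-Haenszel table set: a numerator or denominator sum is zero.")
  }
  p_i <- (a + d) / n
  q_i <- (b + c) / n
  # Robins-Breslow-Greenland variance of the log MH odds ratio
  var <- sum(p_i * r_i) / (2 * r_sum^2) +
    sum(p_i * s_i + q_i * r_i) / (2 * r_sum * s_sum) +
    sum(q_i * s_i) / (2 * s_sum^2)
  list(log_or = log(r_sum / s_sum), se = sqrt(var), weight = s_i / s_sum)
}

iv_kernel <- function(log_or, se, tau2 = 0) {
  w <- 1 / (se^2 + tau2)
  list(log_or = sum(w * log_or) / sum(w), se = 1 / sqrt(sum(w)),
       weight = w / sum(w))
}

new_meta_pool <- function(method, kernel, het, effects, model, ci_level,
                          n_case = NA_real_, n_ctrl = NA_real_) {
  zq <- qnorm(1 - (1 - ci_level) / 2)
  z <- abs(kernel$log_or) / kernel$se
  structure(list(
    method = method,
    model = model,
    k = nrow(effects),
    n_case = n_case,
    n_ctrl = n_ctrl,
    log_or = kernel$log_or,
    se = kernel$se,
    or = exp(kernel$log_or),
    ci_low = exp(kernel$log_or - zq * kernel$se),
    ci_high = exp(kernel$log_or + zq * kernel$se),
    z = z,
    p = 2 * pnorm(z, lower.tail = FALSE),
    het = het,
    ci_level = ci_level,
    effects = effects
  ), class = "meta_pool")
}

prepare_effects <- function(tables, ci_level) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  if (!"study_id" %in% names(tables)) {
    tables$study_id <- paste("study", seq_len(nrow(tables)))
  }
  study_effects(tables, ci_level = ci_level)
}

# Exported surface -------------------------------------------------------

#' Per-study odds ratios with Woolf standard errors
#'
#' Adds the log odds ratio `log(ad/bc)`, its Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, the odds ratio and its normal-theory
#' confidence limits to a tibble of 2x2 tables. Cells must already be
#' free of zeros (see [apply_continuity()]).
#'
#' @param tables A tibble with columns `a`, `b`, `c`, `d` (and usually
#'   `study_id`), as from [contrast_tables()].
#' @param ci_level Confidence level for the per-study limits.
#' @return `tables` with columns `log_or`, `se`, `or`, `ci_low`,
#'   `ci_high` appended.
#' @examples
#' load_fixture("table1") |> contrast_tables("hom") |> study_effects()
#' @export
study_effects <- function(tables, ci_level = 0.95) {
  est <- or_woolf(tables$a, tables$b, tables$c, tables$d)
  zq <- qnorm(1 - (1 - ci_level) / 2)
  mutate(tables,
         log_or = est$log_or, se = est$se, or = exp(est$log_or),
         ci_low = exp(est$log_or - zq * est$se),
         ci_high = exp(est$log_or + zq * est$se))
}

#' Cochran's Q heterogeneity test and DerSimonian-Laird tau-squared
#'
#' Computes Q as the inverse-variance weighted sum of squared deviations
#' of the per-study log odds ratios from their fixed-effect mean, its
#' chi-square P value on k-1 degrees of freedom, the `I^2` inconsistency
#' percentage, and the DerSimonian-Laird moment estimate of the
#' between-study variance `tau^2 = max(0, (Q - df) / (sum(w) -
#' sum(w^2)/sum(w)))`.
#'
#' @param log_or Per-study log odds ratios (length k >= 2).
#' @param se Their standard errors.
#' @return A one-row tibble with columns `q`, `df`, `p_het`, `i2`, `tau2`.
#' @export
cochran_q <- function(log_or, se) {
  if (length(log_or) < 2) abort("Heterogeneity assessment needs at least 2 studies.")
  if (length(se) != length(log_or)) abort("`log_or` and `se` lengths differ.")
  as_tibble(q_stats(log_or, se))
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Pools 2x2 tables with the Mantel-Haenszel estimator
#' `sum(a d / n) / sum(b c / n)`, with the Robins-Breslow-Greenland
#' variance for its confidence interval and Z test. Heterogeneity is
#' assessed on the Woolf log odds ratios (so zero-cell tables must be
#' continuity-corrected first, the default in [contrast_tables()]).
#'
#' @param tables A tibble of 2x2 tables (columns `a`, `b`, `c`, `d`).
#' @param ci_level Confidence level.
#' @param model Optional genetic-model code stored on the result.
#' @return A `meta_pool` object; see [tidy.meta_pool()] and
#'   [glance.meta_pool()].
#' @examples
#' rt <- dplyr::filter(load_fixture("table1"), method == "RT-PCR")
#' pool_mh(contrast_tables(rt, "hom"))   # OR 9.83 (5.18-18.65)
#' @export
pool_mh <- function(tables, ci_level = 0.95, model = NA_character_) {
  eff <- prepare_effects(tables, ci_level)
  if (nrow(eff) < 1) abort("At least one table is required.")
  kern <- mh_kernel(eff$a, eff$b, eff$c, eff$d)
  het <- if (nrow(eff) >= 2) q_stats(eff$log_or, eff$se) else
    list(q = 0, df = 0L, p_het = NA_real_, i2 = 0, tau2 = 0)
  eff$weight_pct <- 100 * kern$weight
  new_meta_pool("MH_fixed", kern, het, eff, model, ci_level)
}

#' Inverse-variance fixed-effect pooled odds ratio
#'
#' Fixed-effect pooling with weights `1/se^2` on the Woolf log odds
#' ratios. Numerically this is [pool_dl()] with `tau^2` forced to zero;
#' it is exposed because on many published tables the Mantel-Haenszel and
#' inverse-variance fixed estimates agree to rounding and software
#' differs in which it reports.
#'
#' @inheritParams pool_mh
#' @return A `meta_pool` object.
#' @export
pool_iv <- function(tables, ci_level = 0.95, model = NA_character_) {
  eff <- prepare_effects(tables, ci_level)
  if (nrow(eff) < 1) abort("At least one table is required.")
  kern <- iv_kernel(eff$log_or, eff$se, tau2 = 0)
  het <- if (nrow(eff) >= 2) q_stats(eff$log_or, eff$se) else
    list(q = 0, df = 0L, p_het = NA_real_, i2 = 0, tau2 = 0)
  eff$weight_pct <- 100 * kern$weight
  new_meta_pool("IV_fixed", kern, het, eff, model, ci_level)
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Pools Woolf log odds ratios with random-effects weights
#' `1/(se^2 + tau^2)`, where `tau^2` is the DerSimonian-Laird moment
#' estimate from [cochran_q()]. When `Q <= df` the estimate collapses to
#' inverse-variance fixed pooling.
#'
#' @inheritParams pool_mh
#' @return A `meta_pool` object.
#' @examples
#' load_fixture("table1") |>
#'   filter_hwe() |>
#'   contrast_tables("allelic") |>
#'   pool_dl()     # OR 2.56 (2.34-2.80)
#' @export
pool_dl <- function(tables, ci_level = 0.95, model = NA_character_) {
  eff <- prepare_effects(tables, ci_level)
  if (nrow(eff) < 2) abort("Random-effects pooling needs at least 2 studies.")
  het <- q_stats(eff$log_or, eff$se)
  kern <- iv_kernel(eff$log_or, eff$se, tau2 = het$tau2)
  eff$weight_pct <- 100 * kern$weight
  new_meta_pool("DL_random", kern, het, eff, model, ci_level)
}

#' Pool a study set under a genetic model with automatic model dispatch
#'
#' The full per-model pipeline: build the 2x2 contrast tables for `model`,
#' continuity-correct zero cells, compute Woolf effects and Cochran's Q,
#' then pool with the Mantel-Haenszel fixed-effect model when the
#' heterogeneity P value exceeds `het_threshold` (default 0.1) and with
#' DerSimonian-Laird random effects otherwise.
#'
#' @param studies A study table (see [studies]); apply [filter_hwe()]
#'   first if Hardy-Weinberg screening is wanted.
#' @param model Genetic-model code (see [genetic_models()]).
#' @param het_threshold Heterogeneity P cutoff for the fixed/random choice.
#' @param ci_level Confidence level.
#' @param increment Continuity-correction increment for zero-cell tables.
#' @return A `meta_pool` object carrying the per-study effects, the
#'   heterogeneity assessment and the pooled estimate.
#' @examples
#' load_fixture("table1") |> filter_hwe() |> pool_auto("allelic")
#' @export
pool_auto <- function(studies, model = names(genetic_models()),
                      het_threshold = 0.1, ci_level = 0.95, increment = 0.5) {
  assert_studies(studies)
  model <- match.arg(model)
  if (!is.numeric(het_threshold) || het_threshold <= 0 || het_threshold > 1) {
    abort("`het_threshold` must be in (0, 1].")
  }
  if (nrow(studies) < 2) abort("Pooling needs at least 2 studies.")
  tables <- contrast_tables(studies, model, correct = TRUE, increment = increment)
  eff <- study_effects(tables, ci_level = ci_level)
  het <- q_stats(eff$log_or, eff$se)
  out <- if (het$p_het > het_threshold) {
    pool_mh(eff, ci_level = ci_level, model = model)
  } else {
    pool_dl(eff, ci_level = ci_level, model = model)
  }
  out$n_case <- sum(studies$case_AA + studies$case_AG + studies$case_GG)
  out$n_ctrl <- sum(studies$ctrl_AA + studies$ctrl_AG + studies$ctrl_GG)
  out
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf("Meta-analysis of %d studies%s\n", x$k,
              if (!is.na(x$model)) sprintf(" (%s model: %s)", x$model,
                                           genetic_models()[[x$model]]) else ""))
  cat(sprintf("  method: %s\n", x$method))
  cat(sprintf("  OR = %.3f, %d%% CI %.3f-%.3f, Z = %.2f, P = %.3g\n",
              x$or, round(100 * x$ci_level), x$ci_low, x$ci_high, x$z, x$p))
  cat(sprintf("  heterogeneity: Q = %.2f (df %d), P = %.3g, I2 = %.1f%%, tau2 = %.4f\n",
              x$het$q, x$het$df, x$het$p_het, x$het$i2, x$het$tau2))
  invisible(x)
}

#' Per-study components of a pooled result
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A tibble with one row per study: the 2x2 cells, log odds
#'   ratio, standard error, odds ratio with confidence limits, and the
#'   percentage weight the pooling method assigned.
#' @method tidy meta_pool
#' @export
tidy.meta_pool <- function(x, ...) {
  as_tibble(x$effects)
}

#' One-row summary of a pooled result
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `model`, `k`, `n_case`, `n_ctrl`,
#'   `or`, `ci_low`, `ci_high`, `z`, `p`, `q`, `df`, `p_het`, `i2`, `tau2`.
#' @method glance meta_pool
#' @export
glance.meta_pool <- function(x, ...) {
  tibble(method = x$method, model = x$model, k = x$k,
         n_case = x$n_case, n_ctrl = x$n_ctrl,
         or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
         z = x$z, p = x$p,
         q = x$het$q, df = x$het$df, p_het = x$het$p_het,
         i2 = x$het$i2, tau2 = x$het$tau2)
}
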