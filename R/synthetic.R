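#' Configuration for the synthetic study generator
#'
#' Describes a population of case-control genotype-count studies with
#' known truth: control genotypes in Hardy-Weinberg equilibrium at risk
#' allele frequency `f_control`, case genotypes under a multiplicative
#' per-allele odds ratio `psi`, optional between-study heterogeneity
#' `tau` on the log odds-ratio scale, and optional Hardy-Weinberg
#' distortion of designated control arms. A single integer `seed`
#' determines the whole study set; each study draws from a substream
#' derived from `(seed, index)`, so growing `k` leaves earlier studies
#' unchanged.
#'
#' @param k Number of studies (>= 1).
#' @param f_control Risk-allele (A) frequency in controls, in (0, 1).
#' @param psi True per-allele odds ratio (> 0).
#' @param tau Between-study standard deviation of `log(psi)` (>= 0).
#' @param n_cases,n_controls Per-study arm sizes: either a single count or
#'   a range `c(min, max)` sampled log-uniformly (the default ranges mimic
#'   the heavy size spread of published AMD study tables).
#' @param hwe_violation Disequilibrium (inbreeding-type) coefficient in
#'   `[0, 1)` applied to the control arms of the studies in `violate`.
#' @param violate Integer indices of studies whose controls are distorted.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(k, f_control = 0.35, psi = 2.5, tau = 0,
                             n_cases = c(46, 1335), n_controls = c(13, 1073),
                             hwe_violation = 0, violate = integer(0),
                             seed = 1) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k)) {
    abort("`k` must be a positive integer.")
  }
  if (f_control <= 0 || f_control >= 1) abort("`f_control` must be in (0, 1).")
  if (psi <= 0) abort("`psi` must be positive.")
  if (tau < 0) abort("`tau` must be non-negative.")
  for (nm in c("n_cases", "n_controls")) {
    v <- get(nm)
    if (!length(v) %in% 1:2 || any(v < 10)) {
      abort(sprintf("`%s` must be a size or range with all entries >= 10.", nm))
    }
  }
  if (hwe_violation < 0 || hwe_violation >= 1) {
    abort("`hwe_violation` must be in [0, 1).")
  }
  structure(list(k = as.integer(k), f_control = f_control, psi = psi,
                 tau = tau, n_cases = n_cases, n_controls = n_controls,
                 hwe_violation = hwe_violation, violate = as.integer(violate),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Genotype probabilities under the multiplicative per-allele odds model
#'
#' Controls follow Hardy-Weinberg proportions `(f^2, 2f(1-f), (1-f)^2)`
#' over (AA, AG, GG). Case probabilities are the control probabilities
#' tilted by genotype odds `(psi^2, psi, 1)` and renormalized, i.e. each
#' A allele multiplies the disease odds by `psi`, making the allelic
#' contrast the natural estimand.
#'
#' @param f Risk-allele frequency in controls, in (0, 1).
#' @param psi Per-allele odds ratio (> 0).
#' @return A list with numeric length-3 components `control` and `case`,
#'   named AA/AG/GG, each summing to 1.
#' @examples
#' genotype_probs(0.35, 2.5)
#' @export
genotype_probs <- function(f, psi) {
  if (f <= 0 || f >= 1) abort("`f` must be strictly inside (0, 1).")
  if (psi <= 0) abort("`psi` must be positive.")
  control <- c(AA = f^2, AG = 2 * f * (1 - f), GG = (1 - f)^2)
  case <- control * c(psi^2, psi, 1)
  list(control = control, case = case / sum(case))
}

study_substream <- function(seed, index) {
  # deterministic per-study substream, kept inside 32-bit integer range
  (as.double(seed) * 48271 + index * 16807) %% 2147483647
}

draw_size <- function(range) {
  if (length(range) == 1) return(as.integer(range))
  as.integer(round(exp(runif(1, log(range[1]), log(range[2])))))
}

#' Simulate one case-control study
#'
#' Draws study `index` of the configuration: realized `log(psi_i) ~
#' Normal(log(psi), tau^2)`, control genotype counts from a multinomial
#' at the (optionally distorted) Hardy-Weinberg control probabilities,
#' and case counts from the multiplicative-odds case probabilities at
#' `psi_i`. Fully determined by `(config$seed, index)`.
#'
#' @param config A [synthetic_config()].
#' @param index Study index in `1:config$k`.
#' @return A list with `study` (one study-table row) and `truth` (one
#'   row: `index`, `log_psi`, genotype probabilities used).
#' @export
simulate_study <- function(config, index) {
  stopifnot(inherits(config, "synthetic_config"))
  if (index < 1 || index > config$k) abort("`index` out of range.")
  set.seed(study_substream(config$seed, index))
  log_psi <- rnorm(1, log(config$psi), config$tau)
  probs <- genotype_probs(config$f_control, exp(log_psi))
  ctrl_p <- probs$control
  if (index %in% config$violate && config$hwe_violation > 0) {
    f <- config$f_control
    rho <- config$hwe_violation
    ctrl_p <- c(AA = f^2 + rho * f * (1 - f),
                AG = 2 * f * (1 - f) * (1 - rho),
                GG = (1 - f)^2 + rho * f * (1 - f))
  }
  n_case <- draw_size(config$n_cases)
  n_ctrl <- draw_size(config$n_controls)
  case_counts <- as.integer(rmultinom(1, n_case, probs$case))
  ctrl_counts <- as.integer(rmultinom(1, n_ctrl, ctrl_p))
  ethnicity <- sample(c("Asian", "Caucasian"), 1)
  soc <- sample(c("HB", "PB"), 1)
  method <- sample(c("Sequencing", "TaqMan", "PCR-RFLP"), 1)
  study <- tibble(
    author = sprintf("Synth%03d", index), year = 2020L, country = "simulated",
    ethnicity = ethnicity, amd_type = "AMD", soc = soc, method = method,
    case_AA = case_counts[1], case_AG = case_counts[2], case_GG = case_counts[3],
    ctrl_AA = ctrl_counts[1], ctrl_AG = ctrl_counts[2], ctrl_GG = ctrl_counts[3],
    hwe_p_printed = NA_character_)
  truth <- tibble(index = index, log_psi = log_psi,
                  ctrl_AA = ctrl_p[["AA"]], ctrl_AG = ctrl_p[["AG"]],
                  ctrl_GG = ctrl_p[["GG"]],
                  case_AA = probs$case[["AA"]], case_AG = probs$case[["AG"]],
                  case_GG = probs$case[["GG"]])
  list(study = study, truth = truth)
}

#' Simulate a full synthetic meta-analysis
#'
#' @param config A [synthetic_config()].
#' @return A list with `studies` (a study table of `k` rows, accepted by
#'   every pipeline function) and `truth` (per-study realized log odds
#'   ratios and genotype probabilities).
#' @examples
#' sim <- simulate_meta(synthetic_config(k = 5, seed = 42))
#' sim$studies
#' @export
simulate_meta <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  draws <- purrr::map(seq_len(config$k), function(i) simulate_study(config, i))
  studies <- bind_rows(purrr::map(draws, "study"))
  studies <- dplyr::bind_cols(tibble(study_id = make_study_ids(studies)), studies)
  list(studies = studies, truth = bind_rows(purrr::map(draws, "truth")))
}

#' Power of the two-sided two-proportion test
#'
#' Normal-approximation power for detecting a difference between two
#' proportions (e.g. pooled risk-allele frequencies of cases and
#' controls) at significance level `alpha`, using unpooled variances.
#' Equals `alpha` when the proportions coincide and tends to 1 with
#' growing samples.
#'
#' @param p1,p2 The two proportions, in (0, 1).
#' @param n1,n2 The two sample sizes (allele counts when comparing allele
#'   frequencies).
#' @param alpha Two-sided significance level.
#' @return The power, in `[alpha, 1]`.
#' @examples
#' power_two_proportions(0.542, 0.365, 2 * 8101, 2 * 7215)
#' @export
power_two_proportions <- function(p1, p2, n1, n2, alpha = 0.05) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) {
    abort("Proportions must be strictly inside (0, 1).")
  }
  if (any(c(n1, n2) < 2)) abort("Sample sizes must be at least 2.")
  z_a <- qnorm(1 - alpha / 2)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  delta <- abs(p1 - p2) / se
  pnorm(delta - z_a) + pnorm(-delta - z_a)
}
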