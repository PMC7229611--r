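#' The five genetic-model contrasts
#'
#' Codes and human-readable labels for the five ways a 2x3 genotype table
#' (AA/AG/GG by case/control) is collapsed into a 2x2 exposed/unexposed
#' table, with A the risk allele: allelic (A vs G, counted on alleles),
#' heterozygote (AG vs GG), dominant (AA+AG vs GG), homozygote (AA vs GG)
#' and recessive (AA vs AG+GG).
#'
#' @return A named character vector; names are the model codes accepted by
#'   `model` arguments throughout the package.
#' @export
genetic_models <- function() {
  c(allelic = "A vs G",
    het = "AG vs GG",
    dom = "AA+AG vs GG",
    hom = "AA vs GG",
    rec = "AA vs AG+GG")
}

#' Hardy-Weinberg equilibrium test for biallelic genotype counts
#'
#' Pearson's chi-square goodness-of-fit test of the observed AA/AG/GG
#' counts against the proportions `p^2, 2pq, q^2` implied by the sample
#' allele frequency `p = (2 AA + AG) / 2n`, on 1 degree of freedom (three
#' classes, one estimated parameter). An exact test (full enumeration of
#' heterozygote counts conditional on the allele counts) is available via
#' `method = "exact"`. Monomorphic samples admit no test and return
#' `chisq = 0`, `p = 1` with `monomorphic = TRUE` and a warning.
#'
#' All three count arguments are vectorized.
#'
#' @param n_AA,n_AG,n_GG Genotype counts (non-negative, total > 0).
#' @param method `"chisq"` (default, the test used to screen control arms)
#'   or `"exact"`.
#' @return A tibble with columns `chisq` (NA for the exact test), `df`,
#'   `p` and `monomorphic`.
#' @examples
#' hwe_test(104, 224, 140)     # p ~ 0.423
#' hwe_test(25, 50, 25)        # exact HWE proportions: chisq 0, p 1
#' @export
hwe_test <- function(n_AA, n_AG, n_GG, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- n_AA + n_AG + n_GG
  if (any(n <= 0)) abort("Genotype counts must have a positive total.")
  if (any(c(n_AA, n_AG, n_GG) < 0)) abort("Genotype counts must be non-negative.")
  p_a <- (2 * n_AA + n_AG) / (2 * n)
  mono <- p_a == 0 | p_a == 1
  if (any(mono)) warn("Monomorphic sample(s): no HWE test possible; returning p = 1.")
  if (method == "chisq") {
    exp_aa <- n * p_a^2
    exp_ag <- n * 2 * p_a * (1 - p_a)
    exp_gg <- n * (1 - p_a)^2
    chisq <- ifelse(mono, 0,
                    (n_AA - exp_aa)^2 / pmax(exp_aa, .Machine$double.eps) +
                    (n_AG - exp_ag)^2 / pmax(exp_ag, .Machine$double.eps) +
                    (n_GG - exp_gg)^2 / pmax(exp_gg, .Machine$double.eps))
    p <- ifelse(mono, 1, pchisq(chisq, df = 1, lower.tail = FALSE))
    tibble(chisq = chisq, df = 1L, p = p, monomorphic = mono)
  } else {
    p <- vapply(seq_along(n), function(i) {
      if (mono[i]) return(1)
      hwe_exact_p(n_AA[i], n_AG[i], n_GG[i])
    }, numeric(1))
    tibble(chisq = NA_real_, df = NA_integer_, p = p, monomorphic = mono)
  }
}

# Exact HWE test: probability of each heterozygote count conditional on the
# observed allele counts, summing probabilities <= that of the observed
# configuration (two-sided by probability ordering).
hwe_exact_p <- function(n_AA, n_AG, n_GG) {
  n <- n_AA + n_AG + n_GG
  n_a <- 2 * n_AA + n_AG
  rare <- min(n_a, 2 * n - n_a)
  het <- seq(rare %% 2, rare, by = 2)
  logp <- lgamma(n + 1) - lgamma((n_a - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((2 * n - n_a - het) / 2 + 1) + het * log(2) +
    lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  min(1, sum(prob[prob <= prob[het == n_AG] * (1 + 1e-12)]))
}

#' Allele counts from genotype counts
#'
#' For a biallelic marker, `n_A = 2 AA + AG` and `n_G = 2 GG + AG`;
#' together they total twice the person count. Vectorized.
#'
#' @inheritParams hwe_test
#' @return A tibble with columns `n_A` and `n_G`.
#' @examples
#' allele_counts(104, 224, 140)   # 432 A and 504 G alleles
#' @export
allele_counts <- function(n_AA, n_AG, n_GG) {
  tibble(n_A = 2 * n_AA + n_AG, n_G = 2 * n_GG + n_AG)
}

#' Aggregate risk-allele frequency across studies
#'
#' Frequency of the A allele in one arm across a set of studies, either
#' pooling allele counts over studies (`weighting = "pooled"`, each person
#' counted once) or averaging per-study frequencies with equal study
#' weights (`weighting = "mean"`). The published summary frequencies fall
#' between the two, so both are exposed.
#'
#' @param studies A study table (see [studies]).
#' @param arm `"cases"` or `"controls"`.
#' @param weighting `"pooled"` or `"mean"`.
#' @return A single frequency in `[0, 1]`.
#' @examples
#' t1 <- load_fixture("table1")
#' aggregate_allele_frequency(t1, "cases")
#' aggregate_allele_frequency(t1, "controls")
#' @export
aggregate_allele_frequency <- function(studies, arm = c("cases", "controls"),
                                       weighting = c("pooled", "mean")) {
  assert_studies(studies)
  arm <- match.arg(arm)
  weighting <- match.arg(weighting)
  if (nrow(studies) == 0) abort("`studies` is empty.")
  pre <- if (arm == "cases") "case" else "ctrl"
  aa <- studies[[paste0(pre, "_AA")]]
  ag <- studies[[paste0(pre, "_AG")]]
  gg <- studies[[paste0(pre, "_GG")]]
  if (weighting == "pooled") {
    sum(2 * aa + ag) / sum(2 * (aa + ag + gg))
  } else {
    mean((2 * aa + ag) / (2 * (aa + ag + gg)))
  }
}

#' Build per-study 2x2 contrast tables under a genetic model
#'
#' Collapses each study's 2x3 genotype table into the 2x2 exposed/unexposed
#' table of the requested genetic model (see [genetic_models()]). Cells are
#' `a` (case, exposed), `b` (case, unexposed), `c` (control, exposed),
#' `d` (control, unexposed). The allelic model counts alleles (two per
#' person); the heterozygote and homozygote models drop the unused genotype
#' class. With `correct = TRUE` (default) tables containing a zero cell
#' receive the Haldane-Anscombe correction via [apply_continuity()].
#'
#' @param studies A study table.
#' @param model One of `"allelic"`, `"het"`, `"dom"`, `"hom"`, `"rec"`.
#' @param correct Apply the continuity correction to zero-cell tables?
#' @param increment Correction increment (default 0.5).
#' @return A tibble with columns `study_id`, `model`, `unit` (`"allele"`
#'   or `"person"`), `a`, `b`, `c`, `d`, `continuity`.
#' @examples
#' contrast_tables(load_fixture("table1"), "hom")
#' @export
contrast_tables <- function(studies, model = names(genetic_models()),
                            correct = TRUE, increment = 0.5) {
  assert_studies(studies)
  model <- match.arg(model)
  s <- studies
  cells <- switch(model,
    allelic = list(a = 2 * s$case_AA + s$case_AG, b = 2 * s$case_GG + s$case_AG,
                   c = 2 * s$ctrl_AA + s$ctrl_AG, d = 2 * s$ctrl_GG + s$ctrl_AG),
    het = list(a = s$case_AG, b = s$case_GG, c = s$ctrl_AG, d = s$ctrl_GG),
    dom = list(a = s$case_AA + s$case_AG, b = s$case_GG,
               c = s$ctrl_AA + s$ctrl_AG, d = s$ctrl_GG),
    hom = list(a = s$case_AA, b = s$case_GG, c = s$ctrl_AA, d = s$ctrl_GG),
    rec = list(a = s$case_AA, b = s$case_AG + s$case_GG,
               c = s$ctrl_AA, d = s$ctrl_AG + s$ctrl_GG))
  unit <- if (model == "allelic") "allele" else "person"
  out <- tibble(study_id = s$study_id, model = model, unit = unit,
                a = as.numeric(cells$a), b = as.numeric(cells$b),
                c = as.numeric(cells$c), d = as.numeric(cells$d),
                continuity = FALSE)
  if (correct) out <- apply_continuity(out, increment = increment) else out
}

#' Continuity-correct zero-cell 2x2 tables
#'
#' Adds `increment` to all four cells of every table that contains at
#' least one zero cell (Haldane-Anscombe correction), so the odds ratio
#' and its Woolf variance are defined. Tables without a zero cell are
#' returned unchanged.
#'
#' @param tables A tibble of 2x2 tables as produced by
#'   [contrast_tables()] (columns `a`, `b`, `c`, `d`, `continuity`).
#' @param increment Amount added to each cell of a zero-cell table.
#' @return `tables` with corrected cells and `continuity` set accordingly.
#' @export
apply_continuity <- function(tables, increment = 0.5) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  if (!"continuity" %in% names(tables)) tables$continuity <- FALSE
  zero <- tables$a == 0 | tables$b == 0 | tables$c == 0 | tables$d == 0
  for (col in c("a", "b", "c", "d")) {
    tables[[col]] <- tables[[col]] + increment * zero
  }
  tables$continuity <- tables$continuity | zero
  tables
}
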