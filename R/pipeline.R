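#' Normalize genotyping-method labels into analysis strata
#'
#' Maps free-text genotyping method labels onto the strata used by the
#' published subgroup analysis: `Sequencing`, `TaqMan`, `PCR-RFLP`,
#' `RT-PCR`, `MassARRAY MALDI-TOF`, and `Others` for everything else
#' (array platforms, SNaPshot, multiplex PCR, mass spectrometry variants
#' not matching the named five).
#'
#' @param method Character vector of method labels.
#' @return Character vector of stratum labels.
#' @export
normalize_method <- function(method) {
  known <- c("Sequencing", "TaqMan", "PCR-RFLP", "RT-PCR", "MassARRAY MALDI-TOF")
  ifelse(method %in% known, method, "Others")
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of [run_analysis()].
#'
#' @param hwe_alpha Hardy-Weinberg screening level for control arms.
#' @param hwe_source `"printed"` or `"recomputed"`; see [filter_hwe()].
#' @param het_threshold Heterogeneity P cutoff: Mantel-Haenszel fixed
#'   effect when the Q-test P exceeds it, DerSimonian-Laird otherwise.
#' @param ci_level Confidence level for all intervals.
#' @param continuity_increment Added to all four cells of zero-cell tables.
#' @param subgroup_keys Subgroups to stratify on, from `ethnicity`, `soc`,
#'   `amd_type`, `method`.
#' @param models Genetic models to run (codes of [genetic_models()]).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(hwe_alpha = 0.05,
                            hwe_source = c("printed", "recomputed"),
                            het_threshold = 0.1,
                            ci_level = 0.95,
                            continuity_increment = 0.5,
                            subgroup_keys = c("ethnicity", "soc", "amd_type", "method"),
                            models = names(genetic_models())) {
  hwe_source <- match.arg(hwe_source)
  stopifnot(hwe_alpha > 0, hwe_alpha < 1, het_threshold > 0, het_threshold < 1,
            ci_level > 0, ci_level < 1, continuity_increment > 0)
  bad <- setdiff(subgroup_keys, c("ethnicity", "soc", "amd_type", "method"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown subgroup key(s): %s.", paste(bad, collapse = ", ")))
  }
  models <- match.arg(models, names(genetic_models()), several.ok = TRUE)
  structure(list(hwe_alpha = hwe_alpha, hwe_source = hwe_source,
                 het_threshold = het_threshold, ci_level = ci_level,
                 continuity_increment = continuity_increment,
                 subgroup_keys = subgroup_keys, models = models),
            class = "analysis_config")
}

pool_row <- function(studies, model, config, subset, stratum) {
  base <- tibble(subset = subset, stratum = stratum, model = model,
                 k = nrow(studies),
                 n_case = sum(studies$case_AA + studies$case_AG + studies$case_GG),
                 n_ctrl = sum(studies$ctrl_AA + studies$ctrl_AG + studies$ctrl_GG))
  if (nrow(studies) < 2) {
    return(mutate(base, pooled = FALSE, method = NA_character_,
                  or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  z = NA_real_, p = NA_real_, q = NA_real_,
                  p_het = NA_real_, i2 = NA_real_, tau2 = NA_real_))
  }
  fit <- pool_auto(studies, model, het_threshold = config$het_threshold,
                   ci_level = config$ci_level,
                   increment = config$continuity_increment)
  mutate(base, pooled = TRUE, method = fit$method, or = fit$or,
         ci_low = fit$ci_low, ci_high = fit$ci_high, z = fit$z, p = fit$p,
         q = fit$het$q, p_het = fit$het$p_het, i2 = fit$het$i2,
         tau2 = fit$het$tau2)
}

#' Run the complete meta-analysis
#'
#' Reproduces the full analysis layout of the published study: a `Total`
#' row over all studies (including Hardy-Weinberg-violating ones, as the
#' published totals do), an `HWE` row over the HWE-screened set, subgroup
#' rows (ethnicity, source of control and genotyping-method strata of the
#' HWE set; wet/dry strata of the HWE-screened wet/dry table), each
#' crossed with the requested genetic models, plus per-model
#' publication-bias tests and leave-one-out sensitivity analyses on the
#' HWE set.
#'
#' @param studies Whole-disease study table (e.g. `load_fixture("table1")`).
#' @param wetdry Optional wet/dry study table (e.g.
#'   `load_fixture("table2")`) feeding the `amd_type` strata.
#' @param config An [analysis_config()].
#' @return An object of class `amd_report`: a list with `rows` (pooled
#'   results tibble), `bias` (Egger/Begg per model, for both the HWE and
#'   the unfiltered set), `sensitivity` (leave-one-out rows per model),
#'   `sets` (the study subsets analysed) and `provenance`.
#' @examples
#' \donttest{
#' report <- run_analysis(load_fixture("table1"), load_fixture("table2"))
#' dplyr::filter(report$rows, model == "allelic")
#' }
#' @export
run_analysis <- function(studies, wetdry = NULL, config = analysis_config()) {
  assert_studies(studies)
  stopifnot(inherits(config, "analysis_config"))
  hwe <- filter_hwe(studies, alpha = config$hwe_alpha, source = config$hwe_source)
  sets <- list(Total = studies, HWE = hwe)
  if ("ethnicity" %in% config$subgroup_keys) {
    for (e in intersect(.ethnicity_levels, unique(hwe$ethnicity))) {
      sets[[e]] <- hwe[hwe$ethnicity == e, ]
    }
  }
  if ("soc" %in% config$subgroup_keys) {
    for (s in intersect(.soc_levels, unique(hwe$soc))) {
      sets[[s]] <- hwe[hwe$soc == s, ]
    }
  }
  if ("method" %in% config$subgroup_keys) {
    strata <- normalize_method(hwe$method)
    for (m in unique(strata)) sets[[m]] <- hwe[strata == m, ]
  }
  if (!is.null(wetdry) && "amd_type" %in% config$subgroup_keys) {
    assert_studies(wetdry)
    wd <- filter_hwe(wetdry, alpha = config$hwe_alpha, source = config$hwe_source)
    for (ty in intersect(c("wet", "dry"), unique(wd$amd_type))) {
      sets[[ty]] <- wd[wd$amd_type == ty, ]
    }
  }
  stratum_of <- function(label) {
    if (label %in% c("Total", "HWE")) return(tolower(label))
    if (label %in% .ethnicity_levels) return("ethnicity")
    if (label %in% .soc_levels) return("soc")
    if (label %in% c("wet", "dry")) return("amd_type")
    "method"
  }
  rows <- bind_rows(purrr::imap(sets, function(set, label) {
    bind_rows(purrr::map(config$models, function(m) {
      pool_row(set, m, config, subset = label, stratum = stratum_of(label))
    }))
  }))
  bias <- bind_rows(purrr::map(c("HWE", "Total"), function(label) {
    set <- sets[[label]]
    bind_rows(purrr::map(config$models, function(m) {
      if (nrow(set) < 3) return(NULL)
      fit <- pool_auto(set, m, het_threshold = config$het_threshold,
                       ci_level = config$ci_level,
                       increment = config$continuity_increment)
      eg <- egger_test(fit, ci_level = config$ci_level)
      bg <- begg_test(fit)
      tibble(subset = label, model = m, k = eg$k,
             egger_intercept = eg$intercept, egger_se = eg$se_intercept,
             egger_t = eg$t, egger_p = eg$p,
             egger_ci_low = eg$ci_low, egger_ci_high = eg$ci_high,
             begg_score = bg$score, begg_z = bg$z, begg_p = bg$p)
    }))
  }))
  sensitivity <- bind_rows(purrr::map(config$models, function(m) {
    if (nrow(hwe) < 3) return(NULL)
    loo <- leave_one_out(hwe, m, het_threshold = config$het_threshold,
                         ci_level = config$ci_level,
                         increment = config$continuity_increment)
    mutate(loo, model = m, stable = attr(loo, "stable"), .before = 1)
  }))
  structure(list(rows = rows, bias = bias, sensitivity = sensitivity,
                 sets = sets,
                 provenance = list(
                   config = config,
                   fixtures = c(studies = attr(studies, "fixture"),
                                wetdry = if (!is.null(wetdry)) attr(wetdry, "fixture")),
                   n_studies = nrow(studies),
                   n_wetdry = if (is.null(wetdry)) 0L else nrow(wetdry))),
            class = "amd_report")
}

#' @export
print.amd_report <- function(x, ...) {
  cat(sprintf("AMD meta-analysis report: %d pooled rows over %d subsets x %d models\n",
              nrow(x$rows), length(x$sets),
              length(unique(x$rows$model))))
  print(x$rows, n = 20)
  invisible(x)
}

#' Forest-plot data for one subset and model
#'
#' Per-study odds ratios, confidence limits and normalized weights for
#' the requested subset of a report, followed by the pooled summary row
#' (`study_id = "Pooled"`). Weights sum to 100 within the subset; study
#' order follows the input table.
#'
#' @param report An `amd_report` from [run_analysis()].
#' @param subset Subset label present in the report (e.g. `"HWE"`,
#'   `"Asian"`, `"wet"`).
#' @param model Genetic-model code.
#' @return A tibble with columns `study_id`, `or`, `ci_low`, `ci_high`,
#'   `weight_pct`, `pooled`.
#' @export
forest_data <- function(report, subset, model = names(genetic_models())) {
  stopifnot(inherits(report, "amd_report"))
  model <- match.arg(model)
  if (!subset %in% names(report$sets)) {
    abort(sprintf("Unknown subset '%s'; available: %s.", subset,
                  paste(names(report$sets), collapse = ", ")))
  }
  config <- report$provenance$config
  fit <- pool_auto(report$sets[[subset]], model,
                   het_threshold = config$het_threshold,
                   ci_level = config$ci_level,
                   increment = config$continuity_increment)
  eff <- tidy(fit)
  bind_rows(
    tibble(study_id = eff$study_id, or = eff$or, ci_low = eff$ci_low,
           ci_high = eff$ci_high, weight_pct = eff$weight_pct, pooled = FALSE),
    tibble(study_id = "Pooled", or = fit$or, ci_low = fit$ci_low,
           ci_high = fit$ci_high, weight_pct = 100, pooled = TRUE))
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

fmt_p <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 3))
}

#' Render a report deterministically
#'
#' Serializes the pooled-results table of a report. Output is a pure
#' function of the report: fixed column order, odds ratios and
#' confidence limits to 3 decimals, P values to 3 significant digits, so
#' repeated renderings are byte-identical.
#'
#' @param report An `amd_report`.
#' @param format `"tsv"`, `"json"` or `"text"`.
#' @return A single character string.
#' @export
render_report <- function(report, format = c("tsv", "json", "text")) {
  stopifnot(inherits(report, "amd_report"))
  format <- match.arg(format)
  rows <- report$rows
  fmt <- mutate(rows,
                or = fmt_num(.data$or), ci_low = fmt_num(.data$ci_low),
                ci_high = fmt_num(.data$ci_high), z = fmt_num(.data$z, 2),
                p = fmt_p(.data$p), q = fmt_num(.data$q, 2),
                p_het = fmt_p(.data$p_het), i2 = fmt_num(.data$i2, 1),
                tau2 = fmt_num(.data$tau2, 4))
  if (format == "tsv") {
    header <- paste(names(fmt), collapse = "\t")
    body <- apply(fmt, 1, function(r) paste(as.character(r), collapse = "\t"))
    paste0(paste(c(header, body), collapse = "\n"), "\n")
  } else if (format == "json") {
    as.character(jsonlite::toJSON(fmt, dataframe = "rows", pretty = TRUE))
  } else {
    lines <- c("Meta-analysis of HTRA1 rs11200638 and AMD risk", "")
    for (s in unique(fmt$subset)) {
      sub <- fmt[fmt$subset == s, ]
      lines <- c(lines, sprintf("%s (k=%d, %d cases / %d controls)",
                                s, sub$k[1], sub$n_case[1], sub$n_ctrl[1]))
      for (i in seq_len(nrow(sub))) {
        lines <- c(lines, sprintf(
          "  %-8s %-9s OR %s (%s-%s)  P=%s  P_het=%s",
          sub$model[i],
          ifelse(is.na(sub$method[i]), "not pooled", sub$method[i]),
          sub$or[i], sub$ci_low[i], sub$ci_high[i], sub$p[i], sub$p_het[i]))
      }
      lines <- c(lines, "")
    }
    paste0(paste(lines, collapse = "\n"), "\n")
  }
}
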