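#' Forest plot of a pooled result
#'
#' Per-study odds ratios with confidence limits on a log scale, point
#' size proportional to pooling weight, and the pooled estimate as the
#' bottom row with a dashed reference line at OR = 1.
#'
#' @param object A `meta_pool` object.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' \donttest{
#' load_fixture("table1") |> filter_hwe() |> pool_auto("allelic") |> autoplot()
#' }
#' @method autoplot meta_pool
#' @export
autoplot.meta_pool <- function(object, ...) {
  eff <- tidy(object)
  dat <- bind_rows(
    tibble(study_id = eff$study_id, or = eff$or, ci_low = eff$ci_low,
           ci_high = eff$ci_high, weight_pct = eff$weight_pct, pooled = FALSE),
    tibble(study_id = "Pooled", or = object$or, ci_low = object$ci_low,
           ci_high = object$ci_high, weight_pct = 100, pooled = TRUE))
  dat$study_id <- factor(dat$study_id, levels = rev(dat$study_id))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$study_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_pct,
                                     shape = .data$pooled)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  title = if (!is.na(object$model))
                    sprintf("%s (%s), %s", object$model,
                            genetic_models()[[object$model]], object$method)
                  else object$method) +
    ggplot2::theme_minimal()
}
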