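#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted association model
#'
#' Returns the per-exposure-level summary (the shape of a journal results
#' table): reference level first with `estimate = NA`, then one row per
#' level with the estimate (beta for linear models, odds ratio for ordinal
#' and multinomial models), Wald 95% CI and p-value.
#'
#' @param x A `dda_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dda_fit
#' @export
tidy.dda_fit <- function(x, ...) {
  dplyr::mutate(x$summary, outcome = x$outcome, model = x$adjust,
                family = x$family, .before = 1)
}

#' One-row model summary
#'
#' @param x A `dda_fit`.
#' @param ... Unused.
#' @return Tibble with family, outcome, exposure, adjustment, n, p-trend
#'   and log-likelihood.
#' @method glance dda_fit
#' @export
glance.dda_fit <- function(x, ...) {
  tibble::tibble(family = x$family, outcome = x$outcome,
                 exposure = x$exposure, adjust = x$adjust, n = x$n,
                 p_trend = x$p_trend,
                 logLik = as.numeric(logLik(x$fit)))
}

#' @method tidy dda_subgroups
#' @export
tidy.dda_subgroups <- function(x, ...) {
  dplyr::mutate(x$strata, outcome = x$outcome, subgroup = x$subgroup,
                interaction_p = x$lrt$p.value, .before = 1)
}

#' @method glance dda_subgroups
#' @export
glance.dda_subgroups <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, exposure = x$exposure,
                 subgroup = x$subgroup, family = x$family,
                 statistic = x$lrt$statistic, df = x$lrt$df,
                 p.value = x$lrt$p.value)
}

#' Forest plot of subgroup estimates
#'
#' Squares at the top-vs-reference estimate with horizontal 95% CI lines,
#' one row per stratum, annotated with the interaction p-value. The null
#' line sits at 0 for linear fits and 1 for odds ratios.
#'
#' @param x A `dda_subgroups` object or a list of them (e.g.
#'   `run_full_pipeline()$subgroup_fits`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_forest <- function(x, ...) {
  objs <- if (inherits(x, "dda_subgroups")) list(x) else x
  df <- purrr::map(objs, tidy) |> dplyr::bind_rows()
  df$label <- paste(df$subgroup, df$stratum, sep = ": ")
  null_at <- if (objs[[1]]$family == "linear") 0 else 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = null_at, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point(shape = 15, size = 2.5) +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(x = "Top vs reference estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_forest
#' @param object A `dda_subgroups` object.
#' @method autoplot dda_subgroups
#' @export
autoplot.dda_subgroups <- function(object, ...) plot_forest(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
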