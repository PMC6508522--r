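#' MA-style plot of the replicate-free differential-expression results
#'
#' Normalized mean expression against the raw log2 fold (YK/SH), with
#' FDR-called genes highlighted.
#'
#' @param de Output of [de_test()].
#' @return A ggplot object.
#' @export
plot_de <- function(de) {
  d <- de |>
    mutate(base_mean = (.data$base_mean_sh + .data$base_mean_yk) / 2) |>
    filter(is.finite(.data$log2_fold_raw), .data$base_mean > 0)
  ggplot(d, aes(x = .data$base_mean, y = .data$log2_fold_raw,
                colour = .data$de_call)) +
    geom_point(alpha = 0.5, size = 0.8) +
    scale_x_log10() +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                        name = "DE call") +
    labs(x = "mean normalized count", y = expression(log[2]~"fold (YK/SH)")) +
    theme_minimal()
}

#' Transgression ratio plot of the heterosis calls
#'
#' Per-metabolite transgression ratios (F1 / high parent for upward calls,
#' low parent / F1 for downward calls), signed by direction.
#'
#' @param calls Output of [heterosis_calls()].
#' @return A ggplot object.
#' @export
plot_heterosis <- function(calls) {
  d <- calls |>
    filter(!is.na(.data$transgressive),
           .data$transgressive %in% c("high", "low")) |>
    mutate(signed_ratio = ifelse(.data$transgressive == "high",
                                 .data$ratio, -.data$ratio),
           metabolite = stats::reorder(.data$metabolite, .data$signed_ratio))
  ggplot(d, aes(x = .data$metabolite, y = .data$signed_ratio,
                fill = .data$transgressive)) +
    geom_col() +
    coord_flip() +
    scale_fill_manual(values = c(high = "steelblue", low = "darkorange")) +
    labs(x = NULL, y = "transgression ratio (sign = direction)") +
    theme_minimal()
}

#' Dilution-series plot for a fitted primer efficiency
#'
#' @param object A `primer_efficiency` (see [fit_efficiency()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot primer_efficiency
#' @export
autoplot.primer_efficiency <- function(object, ...) {
  ggplot(object$points, aes(x = .data$logc, y = .data$ct)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "steelblue") +
    labs(x = expression(log[10]~"relative concentration"), y = "CT",
         subtitle = sprintf("slope %.3f, E = %.1f%%", object$slope,
                            100 * object$efficiency)) +
    theme_minimal()
}
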