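#' Fit primer efficiency from a dilution series
#'
#' Ordinary least squares of CT on log10(relative concentration); technical
#' replicates are averaged per dilution point before the regression.
#' Efficiency is `10^(-1/slope) - 1`; a primer passes when the slope is
#' negative and the efficiency lies in the inclusive band \[0.80, 1.10\].
#'
#' @param series Tibble with columns `concentration` (strictly positive
#'   relative template amounts) and `ct` (threshold cycles); one row per
#'   well.
#' @return An object of class `primer_efficiency`: slope, intercept,
#'   efficiency, r_squared, pass, n_points, and the fitted points.
#' @export
fit_efficiency <- function(series) {
  if (!all(c("concentration", "ct") %in% names(series)))
    abort("fit_efficiency: series needs columns concentration, ct")
  series <- series[stats::complete.cases(series[, c("concentration", "ct")]), ]
  if (any(series$concentration <= 0))
    abort("fit_efficiency: concentrations must be > 0")
  pts <- series |>
    group_by(logc = log10(.data$concentration)) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  if (nrow(pts) < 3) abort("fit_efficiency: need >= 3 distinct dilution points")
  if (var(pts$logc) == 0) abort("fit_efficiency: zero variance in concentration")
  fit <- lm(ct ~ logc, data = pts)
  slope <- unname(coef(fit)[2])
  eff <- 10^(-1 / slope) - 1
  out <- list(
    slope = slope, intercept = unname(coef(fit)[1]),
    efficiency = eff,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    pass = slope < 0 & eff >= 0.80 - 1e-9 & eff <= 1.10 + 1e-9,
    n_points = nrow(pts),
    points = pts
  )
  class(out) <- "primer_efficiency"
  out
}

#' @export
print.primer_efficiency <- function(x, ...) {
  cat(sprintf("<primer_efficiency> slope %.4f  E = %.3f (%s)  R^2 = %.4f\n",
              x$slope, x$efficiency, if (x$pass) "pass" else "fail",
              x$r_squared))
  invisible(x)
}

#' @method tidy primer_efficiency
#' @export
tidy.primer_efficiency <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @method glance primer_efficiency
#' @export
glance.primer_efficiency <- function(x, ...) {
  tibble(slope = x$slope, efficiency = x$efficiency,
         r_squared = x$r_squared, pass = x$pass, n_points = x$n_points)
}

#' Efficiency-corrected relative expression (delta-CT)
#'
#' `(1 + E)^-(ct_target - ct_reference)`: the expression of the target gene
#' relative to the reference gene, corrected for the primer efficiency E.
#' Missing CTs (no amplification) propagate as NA.
#'
#' @param ct_target,ct_reference Threshold cycles (vectorized).
#' @param efficiency Primer efficiency E (> -1), as a fraction.
#' @return Numeric relative expression, always > 0 where defined.
#' @export
relative_expression <- function(ct_target, ct_reference, efficiency) {
  if (any(efficiency <= -1)) abort("relative_expression: efficiency must be > -1")
  (1 + efficiency)^(-(ct_target - ct_reference))
}

#' Fit efficiencies for every primer of a dilution table
#'
#' @param dilutions Tibble with columns primer, concentration, ct.
#' @return Tibble: one [glance()] row per primer.
#' @export
fit_efficiencies <- function(dilutions) {
  dilutions |>
    group_by(primer = .data$primer) |>
    group_modify(~ glance(fit_efficiency(.x))) |>
    ungroup()
}

qpcr_direction <- function(fold, absent_in) {
  dplyr::case_when(
    !is.na(absent_in) & absent_in == "SH" ~ 1,
    !is.na(absent_in) & absent_in == "YK" ~ -1,
    !is.na(fold) & fold > 0 ~ 1,
    !is.na(fold) & fold < 0 ~ -1,
    TRUE ~ 0
  )
}

#' Concordance of qRT-PCR and RNA-seq fold directions
#'
#' A gene agrees when the two platforms report the same direction of change
#' (sign of the fold), counting "absent/not detected in X" as the matching
#' direction (lower in X).  Genes whose qPCR result is non-significant
#' disagree; untested genes are excluded.
#'
#' @param data Tibble with columns `rnaseq_fold` (log2 or signed linear
#'   fold; sign is all that matters), `rnaseq_absent` (NA, "SH" or "YK"),
#'   `qpcr_fold`, `qpcr_absent`, and logical `qpcr_ns` (significance not
#'   reached) and `qpcr_tested`.
#' @return The tested rows with an `agree` logical column and attributes
#'   `n_tested` / `n_agree`.
#' @export
qpcr_rnaseq_concordance <- function(data) {
  tested <- filter(data, .data$qpcr_tested)
  res <- tested |>
    mutate(
      dir_rnaseq = qpcr_direction(.data$rnaseq_fold, .data$rnaseq_absent),
      dir_qpcr = qpcr_direction(.data$qpcr_fold, .data$qpcr_absent),
      agree = !.data$qpcr_ns & .data$dir_rnaseq != 0 &
        .data$dir_rnaseq == .data$dir_qpcr
    )
  attr(res, "n_tested") <- nrow(res)
  attr(res, "n_agree") <- sum(res$agree)
  res
}
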