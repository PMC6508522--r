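#' Mid-parent and transgressive heterosis calls for F1 metabolite profiles
#'
#' For every metabolite measured in SH, YK and their F1 within one
#' experiment:
#'
#' * the mid-parent test: a one-sample t of the F1 replicates against the
#'   constant mid-parent mean `(mean_SH + mean_YK)/2`, using the variance
#'   estimated from the F1 hybrids (df = n_F1 - 1), with a below/above flag;
#' * the transgressive test: a two-sample two-tailed t of F1 against the
#'   extreme parent; the label `high` / `low` is assigned only when the F1
#'   mean lies beyond that parent and p <= `alpha`, with the ratio
#'   F1 / high parent (upward) or low parent / F1 (downward);
#' * a heterosis mode classification (`class_call`): transgressive when the
#'   label is set; otherwise dominant when the F1 differs (p <= `alpha`)
#'   from exactly one parent, additive when it differs from both (it sits
#'   between them) or neither (falling back on the mid-parent test for
#'   parentally equivalent metabolites).
#'
#' Metabolites undetected (all-zero) in one parent are reported with
#' `parent_detected = "one"` and no transgressive label or class call.
#'
#' @param records Long metabolite tibble (metabolite, experiment, genotype,
#'   replicate, value) with genotypes "SH", "YK", "F1".
#' @param experiment Experiment containing the F1 (default 2).
#' @param alpha Significance threshold for labels (default 0.05).
#' @param var_equal Pooled-variance two-sample t tests (default) or Welch.
#' @return Tibble, one row per metabolite: means, mid_parent,
#'   below_mid_parent, p_mid_parent, p_vs_sh, p_vs_yk, transgressive
#'   ("none"/"high"/"low"/NA), p_transgressive, ratio, parent_detected,
#'   class_call; metabolite `class` is carried through when present.
#' @export
heterosis_calls <- function(records, experiment = 2L, alpha = 0.05,
                            var_equal = TRUE) {
  check_metabolite_records(records)
  d <- records[records$experiment == experiment, ]
  grp <- split(seq_len(nrow(d)), d$metabolite)
  rows <- lapply(names(grp), function(met) {
    ix <- grp[[met]]
    sh <- d$value[ix][d$genotype[ix] == "SH"]
    yk <- d$value[ix][d$genotype[ix] == "YK"]
    f1 <- d$value[ix][d$genotype[ix] == "F1"]
    if (!length(sh) || !length(yk) || length(f1) < 2) return(NULL)
    mean_sh <- mean(sh); mean_yk <- mean(yk); mean_f1 <- mean(f1)
    mid <- (mean_sh + mean_yk) / 2
    parent_detected <- if (all(sh == 0) || all(yk == 0)) "one" else "both"

    p_mid <- t1_pvalue(f1, mid)
    p_sh <- t2_pvalue(f1, sh, var_equal)
    p_yk <- t2_pvalue(f1, yk, var_equal)

    hi <- max(mean_sh, mean_yk); lo <- min(mean_sh, mean_yk)
    hi_vals <- if (mean_sh >= mean_yk) sh else yk
    lo_vals <- if (mean_sh < mean_yk) sh else yk
    trans <- "none"; p_trans <- NA_real_; ratio <- NA_real_
    if (mean_f1 > hi) {
      p_trans <- t2_pvalue(f1, hi_vals, var_equal)
      if (!is.na(p_trans) && p_trans <= alpha) {
        trans <- "high"; ratio <- mean_f1 / hi
      }
    } else if (mean_f1 < lo) {
      p_trans <- t2_pvalue(f1, lo_vals, var_equal)
      if (!is.na(p_trans) && p_trans <= alpha) {
        trans <- "low"; ratio <- lo / mean_f1
      }
    }

    class_call <- if (trans != "none") {
      "transgressive"
    } else {
      n_sig <- sum(c(p_sh, p_yk) <= alpha, na.rm = TRUE)
      if (n_sig == 2) "additive"
      else if (n_sig == 1) "dominant"
      else if (!is.na(p_mid) && p_mid <= alpha) "dominant"
      else "additive"
    }
    if (parent_detected == "one") {
      trans <- NA_character_; class_call <- NA_character_; ratio <- NA_real_
    }

    tibble(metabolite = met, mean_sh = mean_sh, mean_yk = mean_yk,
           f1_mean = mean_f1, mid_parent = mid,
           below_mid_parent = mean_f1 < mid,
           p_mid_parent = p_mid, p_vs_sh = p_sh, p_vs_yk = p_yk,
           transgressive = trans, p_transgressive = p_trans, ratio = ratio,
           parent_detected = parent_detected, class_call = class_call)
  })
  out <- bind_rows(rows)
  if ("class" %in% names(records) && nrow(out)) {
    cls <- distinct(records[, c("metabolite", "class")])
    out <- left_join(out, cls, by = "metabolite") |>
      relocate("class", .after = "metabolite")
  }
  out
}

#' Exact binomial test of transgression direction
#'
#' Two-sided exact binomial test (against 0.5) of negative versus positive
#' transgressive calls among metabolites detected in both parents.
#'
#' @param calls Output of [heterosis_calls()].
#' @return One-row tibble: n_low, n_high, p_value.
#' @export
direction_binomial <- function(calls) {
  tc <- calls[!is.na(calls$transgressive) &
                calls$transgressive %in% c("high", "low") &
                calls$parent_detected == "both", ]
  n_low <- sum(tc$transgressive == "low")
  n_high <- sum(tc$transgressive == "high")
  if (n_low + n_high == 0)
    abort("direction_binomial: no transgressive calls")
  tibble(n_low = n_low, n_high = n_high,
         p_value = binom.test(n_low, n_low + n_high, 0.5)$p.value)
}

#' Contingency test: parental difference versus heterosis
#'
#' 2x2 chi-squared association test (no continuity correction by default)
#' between "the parents differ in concentration" (t test p <= `alpha` in the
#' F1 experiment) and "the metabolite shows heterosis".  Heterosis is either
#' a transgressive label (default) or a significant deviation of the F1 from
#' the mid-parent value (`heterosis = "mid_parent"`).
#'
#' @param calls Output of [heterosis_calls()].
#' @param parent_tests Per-metabolite parental t tests for the F1
#'   experiment, e.g. `metab_ttest(records, experiments = 2)`.
#' @param alpha Significance threshold for both verdicts.
#' @param heterosis Which heterosis verdict enters the table.
#' @param correct Apply the Yates continuity correction.
#' @return Object of class `heterosis_contingency`: `table` (2x2 counts),
#'   `chi2_stat`, `p_value`, `test_used`, `heterosis`.
#' @export
heterosis_contingency <- function(calls, parent_tests, alpha = 0.05,
                                  heterosis = c("transgressive", "mid_parent"),
                                  correct = FALSE) {
  heterosis <- match.arg(heterosis)
  d <- calls |>
    inner_join(select(parent_tests, "metabolite", parent_p = "p_value"),
               by = "metabolite") |>
    filter(!is.na(.data$parent_p), .data$parent_detected == "both")
  het <- if (heterosis == "transgressive") {
    d$transgressive %in% c("high", "low")
  } else {
    !is.na(d$p_mid_parent) & d$p_mid_parent <= alpha
  }
  diffp <- d$parent_p <= alpha
  tab <- table(parental_difference = factor(diffp, c(TRUE, FALSE)),
               heterosis = factor(het, c(TRUE, FALSE)))
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  out <- list(table = tab, chi2_stat = unname(ct$statistic),
              p_value = ct$p.value,
              test_used = if (correct) "chi-squared (Yates)" else "chi-squared",
              heterosis = heterosis)
  class(out) <- "heterosis_contingency"
  out
}

#' @export
print.heterosis_contingency <- function(x, ...) {
  cat(sprintf("<heterosis_contingency> %s on %s heterosis: X^2 = %.3f, p = %.4g\n",
              x$test_used, x$heterosis, x$chi2_stat, x$p_value))
  print(x$table)
  invisible(x)
}

#' @method tidy heterosis_contingency
#' @export
tidy.heterosis_contingency <- function(x, ...) {
  tibble(heterosis = x$heterosis, chi2_stat = x$chi2_stat,
         p_value = x$p_value, test_used = x$test_used,
         n = sum(x$table))
}

#' Fraction of metabolites with F1 mean below the mid-parent value
#'
#' Reports, overall and per metabolite class, the fraction of measured
#' metabolites whose F1 mean falls below the mid-parent prediction, together
#' with the fraction deviating significantly below it (mid-parent t test
#' p <= `alpha`) since either reading is of interest.
#'
#' @param calls Output of [heterosis_calls()].
#' @param alpha Threshold for the significant-deviation count.
#' @return Tibble with an "all" row and one row per class (when classes are
#'   present): group, n, n_below, frac_below, n_below_sig, frac_below_sig.
#' @export
mid_parent_fraction <- function(calls, alpha = 0.05) {
  summarize_one <- function(d, label) {
    tibble(group = label, n = nrow(d),
           n_below = sum(d$below_mid_parent),
           frac_below = mean(d$below_mid_parent),
           n_below_sig = sum(d$below_mid_parent & !is.na(d$p_mid_parent) &
                               d$p_mid_parent <= alpha),
           frac_below_sig = mean(d$below_mid_parent & !is.na(d$p_mid_parent) &
                                   d$p_mid_parent <= alpha))
  }
  out <- summarize_one(calls, "all")
  if ("class" %in% names(calls)) {
    per <- calls |>
      group_by(.data$class) |>
      group_map(~ summarize_one(.x, .y$class)) |>
      bind_rows()
    out <- bind_rows(out, per)
  }
  out
}
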