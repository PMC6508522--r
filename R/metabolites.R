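check_metabolite_records <- function(records) {
  need <- c("metabolite", "experiment", "genotype", "replicate", "value")
  if (!all(need %in% names(records)))
    abort(paste("metabolite records need columns",
                paste(need, collapse = ", ")))
  if (any(records$value < 0, na.rm = TRUE))
    abort("metabolite records: values must be >= 0")
  key <- paste(records$metabolite, records$experiment, records$genotype,
               records$replicate)
  if (anyDuplicated(key))
    abort("metabolite records: (metabolite, experiment, genotype, replicate) must be unique")
  invisible(records)
}

#' Significance stars at the .05 / .01 / .001 thresholds
#'
#' @param p Numeric p-values.
#' @return Character vector: "***", "**", "*", "n.s." (NA preserved).
#' @export
p_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- as.character(cut(p[ok], c(-Inf, 0.001, 0.01, 0.05, Inf),
                              labels = c("***", "**", "*", "n.s.")))
  out
}

# two-sample t p-value with degenerate-variance handling: equal constant
# groups give p = 1 (t = 0); unequal constant groups are untestable (NA)
t2_pvalue <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (var(x) + var(y) == 0) return(if (mean(x) == mean(y)) 1 else NA_real_)
  t.test(x, y, var.equal = var_equal)$p.value
}

# one-sample t against a constant, same degenerate handling
t1_pvalue <- function(x, mu) {
  if (length(x) < 2) return(NA_real_)
  if (sd(x) == 0) return(if (mean(x) == mu) 1 else NA_real_)
  t.test(x, mu = mu)$p.value
}

#' Per-experiment parental t tests
#'
#' Two-sample two-tailed t test of SH against YK for every metabolite in
#' each requested experiment (pooled variance by default, Welch optional).
#' Metabolites absent (all-zero) in one genotype are still tested whenever
#' the variances permit; groups with no variance at all are flagged
#' untestable.
#'
#' @param records Long metabolite tibble (metabolite, experiment, genotype,
#'   replicate, value), genotypes "SH"/"YK" (others ignored).
#' @param experiments Experiments to test (default both).
#' @param var_equal Pooled-variance t test (default) or Welch.
#' @return Tibble: metabolite, experiment, n_sh, n_yk, mean_sh, mean_yk,
#'   p_value, testable, stars.
#' @export
metab_ttest <- function(records, experiments = c(1L, 2L), var_equal = TRUE) {
  check_metabolite_records(records)
  d <- records[records$experiment %in% experiments &
                 records$genotype %in% c("SH", "YK"), ]
  grp <- split(seq_len(nrow(d)), paste(d$metabolite, d$experiment, sep = "\r"))
  rows <- lapply(grp, function(ix) {
    x <- d$value[ix][d$genotype[ix] == "SH"]
    y <- d$value[ix][d$genotype[ix] == "YK"]
    p <- t2_pvalue(x, y, var_equal)
    tibble(metabolite = d$metabolite[ix][1],
           experiment = d$experiment[ix][1],
           n_sh = length(x), n_yk = length(y),
           mean_sh = mean(x), mean_yk = mean(y),
           p_value = p, testable = !is.na(p))
  })
  bind_rows(rows) |>
    mutate(stars = p_stars(.data$p_value)) |>
    arrange(.data$metabolite, .data$experiment)
}

#' Tukey studentized-range comparisons among SH, YK and F1
#'
#' One-way ANOVA per metabolite followed by Tukey's honest significant
#' difference test over all genotype pairs, familywise-adjusted via the
#' studentized range distribution.  When the within-group variance is exactly
#' zero, identical group means give adjusted p = 1 and distinct means give
#' p = 0.
#'
#' @param records Long metabolite tibble.
#' @param experiment Experiment holding all three genotypes (default 2).
#' @return Tibble: metabolite, comparison, diff, p_adj.
#' @export
tukey_hsd <- function(records, experiment = 2L) {
  check_metabolite_records(records)
  d <- records[records$experiment == experiment, ]
  grp <- split(seq_len(nrow(d)), d$metabolite)
  rows <- lapply(names(grp), function(met) {
    ix <- grp[[met]]
    g <- factor(d$genotype[ix])
    if (nlevels(g) < 3 || any(table(g) < 2)) return(NULL)
    v <- d$value[ix]
    fit <- aov(v ~ g)
    rss <- sum(stats::residuals(fit)^2)
    tk <- TukeyHSD(fit)$g
    p <- tk[, "p adj"]
    if (rss < 1e-12 * max(1, sum(v^2)))
      p <- ifelse(abs(tk[, "diff"]) < 1e-12, 1, 0)
    tibble(metabolite = met, comparison = rownames(tk),
           diff = unname(tk[, "diff"]), p_adj = unname(p))
  })
  bind_rows(rows)
}

#' Two-factor combined-experiment ANOVA
#'
#' Fixed-effects analysis of variance over the two experiments with
#' experiment and genotype as the two main factors and no interaction term
#' (additive model, the default).  `nested = TRUE` instead nests genotype
#' within experiment (`value ~ experiment + experiment:genotype`).  Only
#' genotypes measured in both experiments (SH, YK) enter.
#'
#' @param records Long metabolite tibble.
#' @param nested Use the genotype-within-experiment parameterization.
#' @return Tibble: metabolite, p_genotype, p_experiment, stars (genotype).
#' @export
nested_anova <- function(records, nested = FALSE) {
  check_metabolite_records(records)
  d <- records[records$genotype %in% c("SH", "YK"), ]
  grp <- split(seq_len(nrow(d)), d$metabolite)
  rows <- lapply(names(grp), function(met) {
    ix <- grp[[met]]
    ex <- factor(d$experiment[ix])
    g <- factor(d$genotype[ix])
    if (nlevels(ex) < 2 || nlevels(g) < 2) return(NULL)
    if (any(table(ex, g) < 1)) return(NULL)
    v <- d$value[ix]
    tab <- if (nested) anova(lm(v ~ ex + ex:g)) else anova(lm(v ~ ex + g))
    gr <- if (nested) "ex:g" else "g"
    tibble(metabolite = met,
           p_genotype = tab[gr, "Pr(>F)"],
           p_experiment = tab["ex", "Pr(>F)"])
  })
  bind_rows(rows) |> mutate(stars = p_stars(.data$p_genotype))
}

#' Combined per-metabolite test table
#'
#' Joins the per-experiment parental t tests with the combined two-factor
#' ANOVA into one wide table: per-experiment SH and YK means, per-experiment
#' p-values and the combined-analysis genotype p, each with significance
#' stars.
#'
#' @param records Long metabolite tibble.
#' @param var_equal Pooled-variance t tests (default) or Welch.
#' @return Tibble: metabolite, class (when present), mean_sh_e1, mean_yk_e1,
#'   mean_sh_e2, mean_yk_e2, p_e1, p_e2, p_nested, stars_e1, stars_e2,
#'   stars_nested.
#' @export
metab_table <- function(records, var_equal = TRUE) {
  tt <- metab_ttest(records, var_equal = var_equal)
  wide <- tt |>
    select("metabolite", "experiment", "mean_sh", "mean_yk", "p_value") |>
    tidyr::pivot_wider(names_from = "experiment",
                       values_from = c("mean_sh", "mean_yk", "p_value"),
                       names_glue = "{.value}_e{experiment}")
  nest <- nested_anova(records) |>
    select("metabolite", p_nested = "p_genotype")
  out <- wide |>
    left_join(nest, by = "metabolite") |>
    mutate(stars_e1 = p_stars(.data$p_value_e1),
           stars_e2 = p_stars(.data$p_value_e2),
           stars_nested = p_stars(.data$p_nested)) |>
    rename(p_e1 = "p_value_e1", p_e2 = "p_value_e2")
  if ("class" %in% names(records)) {
    cls <- distinct(records[, c("metabolite", "class")])
    out <- left_join(out, cls, by = "metabolite") |>
      relocate("class", .after = "metabolite")
  }
  out
}

#' Starch-degradation proxy: SH/YK ratio of pooled maltose + glucose
#'
#' Sums the per-experiment mean relative concentrations of maltose and
#' glucose (the primary starch-degradation products) over both experiments
#' for each parent and reports the SH/YK ratio, with the 1-decimal display
#' value.
#'
#' @param records Long metabolite tibble containing maltose and glucose for
#'   SH and YK in both experiments (metabolite names matched
#'   case-insensitively).
#' @return One-row tibble: sh_total, yk_total, ratio, display.
#' @export
starch_proxy <- function(records) {
  check_metabolite_records(records)
  d <- records[tolower(records$metabolite) %in% c("maltose", "glucose") &
                 records$genotype %in% c("SH", "YK"), ]
  have <- unique(tolower(d$metabolite))
  if (!all(c("maltose", "glucose") %in% have))
    abort("starch_proxy: records must contain maltose and glucose")
  m <- d |>
    group_by(metabolite = tolower(.data$metabolite), .data$experiment,
             .data$genotype) |>
    summarise(mean = mean(.data$value), .groups = "drop")
  if (length(unique(m$experiment)) < 2)
    abort("starch_proxy: both experiments are required")
  sh <- sum(m$mean[m$genotype == "SH"])
  yk <- sum(m$mean[m$genotype == "YK"])
  tibble(sh_total = sh, yk_total = yk, ratio = sh / yk,
         display = round_half_away(sh / yk, 1))
}
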