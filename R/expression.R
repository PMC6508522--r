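check_count_table <- function(counts) {
  need <- c("gene_id", "count_sh", "count_yk")
  if (!all(need %in% names(counts)))
    abort("count table needs columns gene_id, count_sh, count_yk")
  if (anyDuplicated(counts$gene_id))
    abort("count table: gene_id values must be unique")
  k <- cbind(counts$count_sh, counts$count_yk)
  if (any(k < 0) || any(k != round(k)))
    abort("count table: counts must be non-negative integers")
  invisible(counts)
}

#' Median-of-ratios size factors
#'
#' Per-column normalization scalars: each column's median ratio to the
#' geometric-mean pseudo-reference gene, computed over genes with positive
#' counts in every column.
#'
#' @param counts Count tibble (gene_id, count_sh, count_yk).
#' @return Named numeric vector `c(sh = ..., yk = ...)`.
#' @export
size_factors <- function(counts) {
  check_count_table(counts)
  k <- cbind(sh = counts$count_sh, yk = counts$count_yk)
  loggeo <- rowMeans(log(k))
  ok <- is.finite(loggeo)
  if (!any(ok))
    abort("size_factors: no gene has positive counts in every column")
  apply(k, 2, function(col) median(col[ok] / exp(loggeo[ok])))
}

# ---- replicate-free negative-binomial machinery ----------------------------

# blind per-gene dispersion: both columns treated as replicates of one
# condition; method-of-moments on the common scale
blind_dispersions <- function(k, sf) {
  norm <- sweep(k, 2, sf, "/")
  q <- rowMeans(norm)
  w <- apply(norm, 1, var)
  xim <- mean(1 / sf)
  disp <- (w - xim * q) / q^2
  list(mean = q, disp = disp)
}

# parametric mean-dispersion trend a0 + a1/mu via gamma-family iterative fit;
# NULL on divergence
fit_trend_parametric <- function(means, disps) {
  ok <- is.finite(disps) & disps > 1e-8 & means > 0
  if (sum(ok) < 10) return(NULL)
  m <- means[ok]; d <- disps[ok]
  coefs <- c(0.1, 1)
  for (iter in 1:15) {
    resid <- d / (coefs[1] + coefs[2] / m)
    good <- resid > 1e-4 & resid < 15
    if (sum(good) < 10) return(NULL)
    fit <- tryCatch(
      suppressWarnings(glm(d[good] ~ I(1 / m[good]),
                           family = Gamma(link = "identity"), start = coefs)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    old <- coefs
    coefs <- unname(coefficients(fit))
    if (any(!is.finite(coefs)) || coefs[1] <= 0 || coefs[2] < 0) return(NULL)
    if (sum(log(pmax(coefs, 1e-12) / pmax(old, 1e-12))^2) < 1e-6) break
  }
  function(mu) coefs[1] + coefs[2] / mu
}

# local (loess on log scale) fallback trend
fit_trend_local <- function(means, disps) {
  ok <- is.finite(disps) & disps > 1e-8 & means > 0
  if (sum(ok) < 10) {
    med <- if (any(ok)) median(disps[ok]) else 1e-8
    return(function(mu) rep(med, length(mu)))
  }
  df <- data.frame(log_mean = log(means[ok]), log_disp = log(disps[ok]))
  lo <- loess(log_disp ~ log_mean, data = df, span = 0.5,
              control = loess.control(surface = "direct"))
  rng <- range(df$log_mean)
  function(mu) {
    x <- pmin(pmax(log(mu), rng[1]), rng[2])
    exp(predict(lo, data.frame(log_mean = x)))
  }
}

fit_dispersion_trend <- function(means, disps, fit_type = c("parametric", "local")) {
  fit_type <- match.arg(fit_type)
  f <- if (fit_type == "parametric") fit_trend_parametric(means, disps) else NULL
  f %||% fit_trend_local(means, disps)
}

# exact conditional two-sided NB test: probability, under equal-mean NB laws,
# of splits of the observed column sum no more probable than the observed one
nb_exact_test <- function(k1, k2, mu1, mu2, size) {
  K <- k1 + k2
  if (K == 0) return(NA_real_)
  a <- 0:K
  lp <- dnbinom(a, mu = mu1, size = size, log = TRUE) +
    dnbinom(K - a, mu = mu2, size = size, log = TRUE)
  mx <- max(lp)
  denom <- mx + log(sum(exp(lp - mx)))
  sel <- lp <= lp[k1 + 1] + 1e-7
  num <- mx + log(sum(exp(lp[sel] - mx)))
  min(1, exp(num - denom))
}

#' Replicate-free differential expression between two accessions
#'
#' Tests each gene of a two-column count table for differential expression
#' without biological replicates.  Counts are normalized by median-of-ratios
#' size factors; per-gene dispersions are estimated blind (the two columns
#' treated as replicates of one condition) and replaced by a fitted
#' mean-dispersion trend, parametric `a0 + a1/mu` by gamma-family iterative
#' fit with a local-regression fallback when the fit diverges
#' (fit-only sharing, dispersion floor 1e-8).  The per-gene p-value is the
#' exact conditional negative-binomial test: the probability, under
#' equal-mean NB laws with the fitted dispersion and the size factors, of
#' splits of the observed count sum as or less probable than the observed
#' split.  P-values are BH-adjusted and genes are called at `padj <= fdr`.
#'
#' @param counts Count tibble (gene_id, count_sh, count_yk).
#' @param fdr False-discovery-rate threshold for `de_call` (default 0.2).
#' @param fit_type `"parametric"` (default, with local fallback) or
#'   `"local"` for the dispersion trend.
#' @return Tibble with per-gene size-factor-normalized means, raw and
#'   normalized log2 folds (YK/SH; NA when a count is zero), the display
#'   fold label, dispersion, pvalue, padj, de_call and pav_call.
#' @export
de_test <- function(counts, fdr = 0.2, fit_type = c("parametric", "local")) {
  check_count_table(counts)
  fit_type <- match.arg(fit_type)
  k <- cbind(counts$count_sh, counts$count_yk)
  if (all(k == 0)) abort("de_test: all counts are zero")
  sf <- size_factors(counts)

  bd <- blind_dispersions(k, sf)
  trend <- fit_dispersion_trend(bd$mean, bd$disp, fit_type)
  disp <- pmax(trend(pmax(bd$mean, 1e-8)), 1e-8)

  q <- bd$mean
  mu1 <- q * sf[1]
  mu2 <- q * sf[2]
  pvalue <- vapply(seq_len(nrow(k)), function(g) {
    nb_exact_test(k[g, 1], k[g, 2], mu1[g], mu2[g], 1 / disp[g])
  }, numeric(1))
  padj <- p.adjust(pvalue, method = "BH")

  norm <- sweep(k, 2, sf, "/")
  tibble(
    gene_id = counts$gene_id,
    count_sh = k[, 1], count_yk = k[, 2],
    base_mean_sh = norm[, 1], base_mean_yk = norm[, 2],
    size_factor_sh = sf[1], size_factor_yk = sf[2],
    log2_fold_raw = ifelse(k[, 1] > 0 & k[, 2] > 0, log2(k[, 2] / k[, 1]), NA_real_),
    log2_fold_norm = ifelse(k[, 1] > 0 & k[, 2] > 0,
                            log2(norm[, 2] / norm[, 1]), NA_real_),
    fold_display = fold_display(k[, 1], k[, 2]),
    dispersion = disp,
    pvalue = pvalue, padj = padj,
    de_call = !is.na(padj) & padj <= fdr,
    pav_call = pav_call(k[, 1], k[, 2])
  )
}

#' Raw-count log2 fold change (YK/SH)
#'
#' @param sh_count,yk_count Non-negative counts (vectorized).
#' @return Numeric log2(yk/sh); NA when either count is zero.
#' @seealso [fold_display()] for the reporting convention with absence labels.
#' @export
fold_change <- function(sh_count, yk_count) {
  if (any(sh_count < 0 | yk_count < 0)) abort("fold_change: counts must be >= 0")
  ifelse(sh_count > 0 & yk_count > 0, log2(yk_count / sh_count), NA_real_)
}

#' Display fold difference with absence labels
#'
#' Formats log2(YK/SH) at one decimal (half away from zero); genes with zero
#' reads in one accession are labelled "Absent in SH" / "Absent in YK", and
#' genes with no reads at all give NA.
#'
#' @inheritParams fold_change
#' @return Character vector.
#' @export
fold_display <- function(sh_count, yk_count) {
  lf <- fold_change(sh_count, yk_count)
  out <- sprintf("%.1f", round_half_away(lf, 1))
  out[sh_count == 0 & yk_count > 0] <- "Absent in SH"
  out[yk_count == 0 & sh_count > 0] <- "Absent in YK"
  out[sh_count == 0 & yk_count == 0] <- NA_character_
  out
}

pav_call <- function(sh, yk) {
  dplyr::case_when(
    sh > 0 & yk > 0 ~ "both",
    sh > 0 & yk == 0 ~ "sh_only",
    sh == 0 & yk > 0 ~ "yk_only",
    TRUE ~ "neither"
  )
}

#' Presence-absence classification of a count table
#'
#' A gene is a presence-absence variant when reads are detected in exactly
#' one accession.
#'
#' @param counts Count tibble (gene_id, count_sh, count_yk).
#' @return Tibble (gene_id, count_sh, count_yk, pav_call) with a
#'   `pav_fraction` attribute: single-accession genes / detected genes.
#' @seealso [pav_summary()]
#' @export
pav_classify <- function(counts) {
  check_count_table(counts)
  res <- tibble(gene_id = counts$gene_id,
                count_sh = counts$count_sh, count_yk = counts$count_yk,
                pav_call = pav_call(counts$count_sh, counts$count_yk))
  s <- pav_summary(counts)
  attr(res, "pav_fraction") <- s$pav_fraction
  res
}

#' Presence-absence summary fractions
#'
#' @param counts Count tibble (gene_id, count_sh, count_yk).
#' @return One-row tibble: n_detected, n_sh_only, n_yk_only, pav_fraction.
#' @export
pav_summary <- function(counts) {
  check_count_table(counts)
  calls <- pav_call(counts$count_sh, counts$count_yk)
  detected <- sum(calls != "neither")
  tibble(n_detected = detected,
         n_sh_only = sum(calls == "sh_only"),
         n_yk_only = sum(calls == "yk_only"),
         pav_fraction = if (detected) sum(calls %in% c("sh_only", "yk_only")) / detected
                        else NA_real_)
}
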