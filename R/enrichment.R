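#' Wilcoxon signed-rank test of fold changes against zero
#'
#' Two-sided one-sample signed-rank test.  Zeros are dropped before ranking
#' and ties receive midranks.  For n <= `exact_max` the null distribution of
#' W is computed exactly by convolving the sign-flip generating function
#' (valid under ties, where the tabulated distribution is not); above that,
#' a normal approximation with continuity correction and the exact
#' permutation variance of the midranks is used.  The two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x Numeric values (e.g. log2 fold changes), tested against 0.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List: statistic (W, sum of positive ranks), n (nonzero values),
#'   p_value, method.
#' @export
signed_rank_test <- function(x, exact_max = 25) {
  x <- x[is.finite(x) & x != 0]
  n <- length(x)
  if (n == 0) return(list(statistic = NA_real_, n = 0L, p_value = NA_real_,
                          method = "empty"))
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))          # doubled ranks are integers
    total <- sum(r2)
    f <- numeric(total + 1); f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
      f <- g
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_lo <- sum(probs[1:(w2 + 1)])
    p_hi <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    p_lo <- pnorm((w - mu + 0.5) / sigma)
    p_hi <- pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "normal approximation"
  }
  list(statistic = w, n = n, p_value = p, method = method)
}

#' Category-level test for coordinated direction of fold changes
#'
#' For every category with at least `min_size` members, tests whether the
#' members' log2 fold changes diverge from an even up/down split around
#' zero.  The default is the one-sample Wilcoxon signed-rank test of member
#' folds against 0 ([signed_rank_test()]); `mode = "rank_sum"` instead runs
#' a Wilcoxon rank-sum test of members against all non-members.  P-values
#' are reported uncorrected (the calling convention of the emulated pathway
#' analysis); a supplementary BH column is included but drives no calls.
#'
#' @param folds Tibble with columns `item_id` and `log2_fold` (non-finite
#'   folds, e.g. absence-labelled items, are excluded).
#' @param map Tibble with columns `item_id` and `category`; items may carry
#'   several categories.
#' @param min_size Minimum category size (default 3).
#' @param mode `"signed_rank"` (default) or `"rank_sum"`.
#' @param exact_max Passed to [signed_rank_test()].
#' @return Tibble: category, n_items, statistic, p_uncorrected, median_fold,
#'   p_bh.
#' @export
enrich_categories <- function(folds, map, min_size = 3,
                              mode = c("signed_rank", "rank_sum"),
                              exact_max = 25) {
  mode <- match.arg(mode)
  if (!all(c("item_id", "log2_fold") %in% names(folds)))
    abort("enrich_categories: folds needs columns item_id, log2_fold")
  if (!all(c("item_id", "category") %in% names(map)) || nrow(map) == 0)
    abort("enrich_categories: map needs rows with columns item_id, category")
  if (any(is.na(map$category) | map$category == ""))
    abort("enrich_categories: empty category labels")
  folds <- filter(folds, is.finite(.data$log2_fold))
  joined <- inner_join(map, folds, by = "item_id")
  rows <- joined |>
    group_by(.data$category) |>
    group_map(function(d, key) {
      if (nrow(d) < min_size) return(NULL)
      if (mode == "signed_rank") {
        t <- signed_rank_test(d$log2_fold, exact_max)
        stat <- t$statistic; p <- t$p_value
      } else {
        others <- folds$log2_fold[!folds$item_id %in% d$item_id]
        if (!length(others)) return(NULL)
        wt <- suppressWarnings(wilcox.test(d$log2_fold, others))
        stat <- unname(wt$statistic); p <- wt$p.value
      }
      tibble(category = key$category, n_items = nrow(d), statistic = stat,
             p_uncorrected = p, median_fold = median(d$log2_fold))
    }) |>
    bind_rows()
  if (nrow(rows)) rows$p_bh <- p.adjust(rows$p_uncorrected, method = "BH")
  rows
}
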