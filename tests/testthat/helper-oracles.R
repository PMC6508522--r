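# Independent oracle implementations used to cross-check the package.
# Each is a literal transcription of the textbook definition, kept free of
# the code paths it checks.

# Benjamini-Hochberg step-up, literally: padj at rank i is the minimum over
# j >= i of n * p_(j) / j, capped at 1
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(n * ps[i:n] / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# median-of-ratios size factors, literally
size_factors_oracle <- function(k) {
  geo <- exp(rowMeans(log(k)))
  pos <- apply(k, 1, function(r) all(r > 0))
  vapply(seq_len(ncol(k)),
         function(j) median(k[pos, j] / geo[pos]), numeric(1))
}

# exhaustive all-windows cluster flagging: every window start is examined
cluster_oracle <- function(pos, window = 100L, max_snps = 4L) {
  flag <- logical(length(pos))
  if (!length(pos)) return(flag)
  for (s in (min(pos) - window + 1L):max(pos)) {
    inw <- pos >= s & pos <= s + window - 1L
    if (sum(inw) > max_snps) flag[inw] <- TRUE
  }
  flag
}

# two-sided signed-rank p by enumeration of all 2^n sign assignments
signed_rank_brute <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(grid, 1, function(s) sum(r[s]))
  p_lo <- mean(ws <= w + 1e-9)
  p_hi <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# chi-squared statistic by the hand formula sum (O - E)^2 / E
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# two-sided exact binomial p against 0.5: sum of outcome probabilities no
# larger than the observed one
binom_oracle <- function(x, n) {
  probs <- choose(n, 0:n) * 0.5^n
  sum(probs[probs <= probs[x + 1] + 1e-12])
}

# additive two-factor ANOVA via explicit design matrices and QR least
# squares (no lm/anova); type-I order: experiment then genotype
anova2_oracle <- function(value, ex, g) {
  ex <- factor(ex); g <- factor(g)
  X0 <- matrix(1, length(value))
  X1 <- cbind(X0, stats::model.matrix(~ex)[, -1, drop = FALSE])
  X2 <- cbind(X1, stats::model.matrix(~g)[, -1, drop = FALSE])
  rss <- function(X) {
    b <- qr.solve(crossprod(X), crossprod(X, value))
    sum((value - X %*% b)^2)
  }
  r0 <- rss(X0); r1 <- rss(X1); r2 <- rss(X2)
  df_ex <- nlevels(ex) - 1L
  df_g <- nlevels(g) - 1L
  df_res <- length(value) - 1L - df_ex - df_g
  f_ex <- ((r0 - r1) / df_ex) / (r2 / df_res)
  f_g <- ((r1 - r2) / df_g) / (r2 / df_res)
  list(p_experiment = stats::pf(f_ex, df_ex, df_res, lower.tail = FALSE),
       p_genotype = stats::pf(f_g, df_g, df_res, lower.tail = FALSE))
}

# Tukey HSD adjusted p from group means and the pooled MSE, via the
# studentized range distribution (balanced groups)
tukey_oracle <- function(values, groups) {
  groups <- factor(groups)
  m <- tapply(values, groups, mean)
  nn <- tapply(values, groups, length)
  stopifnot(length(unique(nn)) == 1)
  df <- length(values) - nlevels(groups)
  mse <- sum((values - m[groups])^2) / df
  pairs <- utils::combn(levels(groups), 2)
  p <- apply(pairs, 2, function(pr) {
    q <- abs(m[pr[1]] - m[pr[2]]) / sqrt(mse / nn[1])
    stats::ptukey(q, nlevels(groups), df, lower.tail = FALSE)
  })
  stats::setNames(p, apply(pairs, 2, paste, collapse = "-"))
}
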