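test_that("parental t tests match closed forms and handle degeneracy", {
  # identical non-constant vectors: t = 0, p = 1
  r <- metab_records(sh2 = c(10, 12, 14), yk2 = c(10, 12, 14))
  expect_equal(metab_ttest(r, experiments = 2)$p_value, 1)

  # one constant group, pooled variance: closed-form t
  r2 <- metab_records(sh1 = c(10, 10, 10, 10), yk1 = c(20, 20, 20, 21))
  out <- metab_ttest(r2, experiments = 1)
  sp2 <- (3 * 0 + 3 * var(c(20, 20, 20, 21))) / 6
  tstat <- (20.25 - 10) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(out$p_value, 2 * pt(-abs(tstat), 6), tolerance = 1e-12)
  expect_lt(out$p_value, 0.001)
  expect_equal(out$stars, "***")

  # both groups constant: equal means give 1, unequal are untestable
  expect_equal(metab_ttest(metab_records(sh2 = c(5, 5), yk2 = c(5, 5)),
                           experiments = 2)$p_value, 1)
  flat <- metab_ttest(metab_records(sh2 = c(0, 0, 0), yk2 = c(4, 4, 4)),
                      experiments = 2)
  expect_true(is.na(flat$p_value))
  expect_false(flat$testable)

  # Welch flavour reachable
  r3 <- metab_records(sh2 = c(10, 11, 12), yk2 = c(30, 45, 60))
  pooled <- metab_ttest(r3, experiments = 2)$p_value
  welch <- metab_ttest(r3, experiments = 2, var_equal = FALSE)$p_value
  expect_false(isTRUE(all.equal(pooled, welch)))
})

test_that("swapping the parent labels preserves every p-value", {
  sim <- simulate_metabolome(sim_config(seed = 51, n_metabolites = 15))
  swapped <- sim$records
  swapped$genotype <- ifelse(sim$records$genotype == "SH", "YK",
                             ifelse(sim$records$genotype == "YK", "SH", "F1"))
  a <- metab_ttest(sim$records)
  b <- metab_ttest(swapped)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$mean_sh, b$mean_yk)
  nb <- nested_anova(swapped)
  na_ <- nested_anova(sim$records)
  expect_equal(na_$p_genotype, nb$p_genotype, tolerance = 1e-12)
})

test_that("Tukey comparisons follow the studentized range distribution", {
  # all three genotypes identical: every adjusted p is 1
  rec <- dplyr::bind_rows(
    metab_records(sh2 = c(7, 7, 7), yk2 = c(7, 7, 7)),
    tibble::tibble(metabolite = "m1", class = "other", experiment = 2L,
                   genotype = "F1", replicate = 1:3, value = c(7, 7, 7)))
  expect_equal(tukey_hsd(rec)$p_adj, rep(1, 3))

  # one genotype ten pooled-SDs away: its two comparisons fire, not the third
  set.seed(52)
  base <- rnorm(3, 10, 0.5)
  rec2 <- dplyr::bind_rows(
    metab_records(sh2 = base, yk2 = rnorm(3, 10, 0.5)),
    tibble::tibble(metabolite = "m1", class = "other", experiment = 2L,
                   genotype = "F1", replicate = 1:3, value = rnorm(3, 15, 0.5)))
  out <- tukey_hsd(rec2)
  sig <- out$p_adj < 0.05
  expect_equal(sum(sig[grepl("F1", out$comparison)]), 2)
  expect_false(sig[out$comparison == "YK-SH"])

  # adjusted p equals the ptukey oracle, and the k=3, df=6 critical value
  # sits at the textbook 4.34
  expect_equal(qtukey(0.95, 3, 6), 4.34, tolerance = 0.005)
  set.seed(53)
  for (i in 1:10) {
    vals <- rnorm(9, 10, 1)
    rec3 <- dplyr::bind_rows(
      metab_records(sh2 = vals[1:3], yk2 = vals[4:6]),
      tibble::tibble(metabolite = "m1", class = "other", experiment = 2L,
                     genotype = "F1", replicate = 1:3, value = vals[7:9]))
    out3 <- tukey_hsd(rec3)
    genotype <- rep(c("SH", "YK", "F1"), each = 3)
    oracle <- tukey_oracle(vals, genotype)
    for (cmp in out3$comparison) {
      key <- paste(sort(strsplit(cmp, "-")[[1]]), collapse = "-")
      ok <- names(oracle)[vapply(names(oracle), function(nm)
        identical(paste(sort(strsplit(nm, "-")[[1]]), collapse = "-"), key),
        logical(1))]
      expect_equal(out3$p_adj[out3$comparison == cmp], unname(oracle[ok]),
                   tolerance = 1e-10)
    }
  }
})

test_that("the combined two-factor ANOVA matches a matrix-algebra oracle", {
  set.seed(54)
  for (i in 1:30) {
    rec <- metab_records(sh1 = rnorm(4, 10), yk1 = rnorm(4, 11),
                         sh2 = rnorm(3, 14), yk2 = rnorm(3, 15))
    out <- nested_anova(rec)
    value <- rec$value
    orc <- anova2_oracle(value, rec$experiment, rec$genotype)
    expect_equal(out$p_genotype, orc$p_genotype, tolerance = 1e-10)
    expect_equal(out$p_experiment, orc$p_experiment, tolerance = 1e-10)
  }
  # pure genotype shift far above noise
  rec <- metab_records(sh1 = rnorm(4, 10, 0.1), yk1 = rnorm(4, 30, 0.1),
                       sh2 = rnorm(3, 10, 0.1), yk2 = rnorm(3, 30, 0.1))
  expect_lt(nested_anova(rec)$p_genotype, 0.001)
  # nested parameterization is available and differs in general
  nst <- nested_anova(rec, nested = TRUE)
  expect_true(is.finite(nst$p_genotype))
})

test_that("mid-parent test uses the F1 variance against a constant", {
  rec <- metab_records(sh2 = c(10, 10, 10), yk2 = c(20, 20, 20),
                       f1 = c(12.0, 12.1, 11.9))
  out <- heterosis_calls(rec)
  expect_true(out$below_mid_parent)
  tstat <- (12 - 15) / (sd(c(12.0, 12.1, 11.9)) / sqrt(3))
  expect_equal(out$p_mid_parent, 2 * pt(-abs(tstat), 2), tolerance = 1e-12)
  expect_lt(out$p_mid_parent, 0.001)

  # F1 exactly at the mid-parent: t = 0, p = 1
  at_mid <- metab_records(sh2 = c(10, 10, 10), yk2 = c(20, 20, 20),
                          f1 = c(15, 15, 15))
  expect_equal(heterosis_calls(at_mid)$p_mid_parent, 1)
})

test_that("transgressive labels need both excursion and significance", {
  between <- metab_records(sh2 = c(10, 11, 9), yk2 = c(20, 21, 19),
                           f1 = c(15, 15.5, 14.5))
  expect_equal(heterosis_calls(between)$transgressive, "none")

  low <- metab_records(sh2 = c(10, 11, 9), yk2 = c(20, 21, 19),
                       f1 = c(2, 2.1, 1.9))
  out <- heterosis_calls(low)
  expect_equal(out$transgressive, "low")
  expect_equal(out$ratio, 10 / 2, tolerance = 1e-12)
  expect_gt(out$ratio, 1)
  expect_equal(out$class_call, "transgressive")

  # an excursion without significance stays unlabelled
  noisy <- metab_records(sh2 = c(10, 14, 6), yk2 = c(20, 24, 16),
                         f1 = c(9, 13, 5))
  expect_equal(heterosis_calls(noisy)$transgressive, "none")

  # single-parent metabolites are reported separately
  single <- metab_records(sh2 = c(0, 0, 0), yk2 = c(20, 21, 19),
                          f1 = c(30, 31, 29))
  out_s <- heterosis_calls(single)
  expect_equal(out_s$parent_detected, "one")
  expect_true(is.na(out_s$transgressive))
})

test_that("planted transgressive-down metabolites are recovered", {
  cfg <- sim_config(seed = 55, n_metabolites = 120,
                    heterosis_mix = c(additive = 0, dominant = 0,
                                      transgressive_up = 0,
                                      transgressive_down = 1),
                    transgressive_margin = 0.5, cv_metab = 0.1,
                    single_parent_fraction = 0)
  sim <- simulate_metabolome(cfg)
  calls <- heterosis_calls(sim$records)
  expect_gte(mean(calls$transgressive == "low"), 0.9)
})

test_that("direction binomial equals exact closed forms", {
  even <- contingency_fixture(6, 6, 6, 6)$calls
  even$transgressive <- rep(c("low", "high"), 12)
  expect_equal(direction_binomial(even)$p_value, 1)

  allneg <- contingency_fixture(12, 0, 12, 0)$calls
  expect_equal(direction_binomial(allneg)$n_low, 24)
  expect_equal(direction_binomial(allneg)$p_value, 2 * 0.5^24,
               tolerance = 1e-12)

  skewed <- contingency_fixture(10, 0, 10, 4)$calls
  skewed$transgressive <- rep(c("low", "high"), c(20, 4))
  db <- direction_binomial(skewed)
  expect_equal(db$p_value, binom_oracle(20, 24), tolerance = 1e-12)
  expect_equal(round(db$p_value, 5), 0.00154)
})

test_that("the contingency chi-squared equals the hand formula", {
  indep <- contingency_fixture(10, 10, 10, 10)
  ct <- heterosis_contingency(indep$calls, indep$parent_tests)
  expect_equal(ct$chi2_stat, 0)
  expect_equal(ct$p_value, 1)

  diag <- contingency_fixture(20, 0, 0, 20)
  ct2 <- heterosis_contingency(diag$calls, diag$parent_tests)
  expect_equal(ct2$chi2_stat, 40)
  expect_lt(ct2$p_value, 1e-9)

  set.seed(56)
  for (i in 1:50) {
    n <- sample(2:30, 4, replace = TRUE)
    fx <- contingency_fixture(n[1], n[2], n[3], n[4])
    ct3 <- heterosis_contingency(fx$calls, fx$parent_tests)
    expect_equal(ct3$chi2_stat, chisq_oracle(ct3$table), tolerance = 1e-10)
  }
  # the mid-parent flavour of heterosis is also available
  fx <- contingency_fixture(8, 9, 10, 11)
  fx$calls$p_mid_parent <- runif(nrow(fx$calls))
  expect_s3_class(heterosis_contingency(fx$calls, fx$parent_tests,
                                        heterosis = "mid_parent"),
                  "heterosis_contingency")
  td <- tidy(heterosis_contingency(fx$calls, fx$parent_tests))
  expect_equal(td$n, 38)
})

test_that("starch proxy reproduces the published parent means ratio", {
  tab3 <- read_metabolites(system.file("extdata", "table3_starch_means.csv",
                                       package = "nightcontrast"))
  out <- starch_proxy(tab3)
  expect_equal(out$display, 1.7)
  expect_equal(out$ratio, 60592.1 / 36328.2, tolerance = 1e-10)

  # identical parents give 1; doubling YK halves the ratio
  eq <- tab3
  eq$value[eq$genotype == "YK"] <-
    eq$value[eq$genotype == "SH"]
  expect_equal(starch_proxy(eq)$ratio, 1)
  dbl <- tab3
  dbl$value[dbl$genotype == "YK"] <- 2 * dbl$value[dbl$genotype == "YK"]
  expect_equal(starch_proxy(dbl)$ratio, out$ratio / 2, tolerance = 1e-12)
  expect_error(starch_proxy(metab_records(sh2 = 1:3, yk2 = 1:3)),
               "maltose")
})

test_that("mid-parent fractions count both readings", {
  above <- dplyr::bind_rows(lapply(1:6, function(i)
    metab_records(sh2 = c(10, 10, 10), yk2 = c(20, 20, 20),
                  f1 = c(25, 26, 24), metabolite = paste0("m", i))))
  calls <- heterosis_calls(above)
  mpf <- mid_parent_fraction(calls)
  expect_equal(mpf$frac_below[mpf$group == "all"], 0)

  sim <- simulate_metabolome(sim_config(seed = 57))
  calls2 <- heterosis_calls(sim$records)
  mpf2 <- mid_parent_fraction(calls2)
  expect_true(all(c("all", unique(calls2$class)) %in% mpf2$group))
  expect_gte(mpf2$frac_below[1], mpf2$frac_below_sig[1])
})
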