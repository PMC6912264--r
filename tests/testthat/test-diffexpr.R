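short_ct <- contrast_specs()$short

groups4 <- function(A, B, C, D) {
  stats::setNames(list(A, B, C, D),
                  c("si-hVDAC1_short", "si-NT_short", "si-hVDAC1_long", "si-NT_long"))
}

test_that("residual df follows the post-exclusion 3/3/2/2 design", {
  vg <- groups4(c(10, 11, 12), c(10, 11, 12), c(20, 21), c(20, 21))
  res <- anova_contrast(vg, short_ct)
  expect_equal(res$residual_df, 6)   # 10 observations - 4 groups
  expect_equal(res$delta_log2, 0)
  expect_equal(res$p_value, 1)       # null contrast: t = 0
})

test_that("contrast p matches an independent pooled-MSE computation", {
  cases <- list(
    groups4(c(10, 11, 12), c(13, 14, 15), c(20, 21), c(20, 23)),
    groups4(c(24.1, 25.3, 23.8), c(25.9, 26.2, 27.1), c(22.4, 23.0), c(25.5, 24.8)),
    groups4(c(10, 12), c(11, 15, 13), c(20, 21, 19), c(18, 22))
  )
  for (vg in cases) {
    got <- anova_contrast(vg, short_ct)
    oracle <- oracle_contrast_p(vg, short_ct$A, short_ct$B)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
    expect_equal(got$delta_log2, oracle$estimate, tolerance = 1e-10)
  }
})

test_that("with two populated groups the contrast is the pooled two-sample t", {
  vg <- groups4(c(10.2, 11.5, 12.1), c(13.4, 12.9, 15.0), numeric(0), c(19))
  got <- anova_contrast(vg, short_ct)
  tt <- t.test(vg[[1]], vg[[2]], var.equal = TRUE)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(got$residual_df, 4)
})

test_that("contrast preconditions produce undefined results, not errors", {
  # contrast group with < 2 observations
  vg <- groups4(c(10), c(11, 12, 13), c(20, 21), c(20, 21))
  res <- anova_contrast(vg, short_ct)
  expect_true(is.na(res$p_value))
  expect_equal(res$n_A, 1)
  # zero MSE with nonzero difference: boundary p = 0
  vg0 <- groups4(c(5, 5), c(7, 7), c(9, 9), c(9, 9))
  expect_message(res0 <- anova_contrast(vg0, short_ct), "boundary")
  expect_equal(res0$p_value, 0)
})

test_that("signed fold change follows the -1/x convention", {
  expect_equal(fold_change(0), 1)
  expect_equal(fold_change(1), 2)
  expect_equal(fold_change(-1), -2)
  expect_true(is.na(fold_change(NA)))
  set.seed(8)
  deltas <- runif(100, -6, 6)
  fc <- fold_change(deltas)
  expect_equal(abs(fc), 2^abs(deltas))
  expect_equal(sign(fc[deltas != 0]), sign(deltas[deltas != 0]))
  expect_true(all(abs(fc) >= 1))
})

test_that("analyze_dataset agrees with the scalar contrast on ragged data", {
  sim <- tiny_sim(seed = 17, n = 40, censor_midpoint = 23)
  logm <- log2_transform(sim$intensity)
  ds1 <- build_missing_dataset(logm)
  res <- analyze_dataset(ds1, sim$samples)
  grp <- paste(sim$samples$treatment, sim$samples$duration, sep = "_")
  for (acc in sample(rownames(logm), 12)) {
    vg <- split(logm[acc, ], grp)
    for (ct in contrast_specs()) {
      want <- anova_contrast(vg, ct)
      row <- res[res$accession == acc & res$contrast == ct$id, ]
      expect_equal(row$p, want$p_value, tolerance = 1e-12)
      expect_equal(row$delta_log2, want$delta_log2, tolerance = 1e-12)
      expect_equal(row$df, want$residual_df)
    }
  }
})

test_that("imputed datasets yield complete result tables; dataset 1 may not", {
  sim <- tiny_sim(seed = 19, n = 100, censor_midpoint = 24)
  logm <- log2_transform(sim$intensity)
  coll <- build_dataset_collection(logm, imputation_params())
  res_imp <- analyze_dataset(coll$datasets[[2]], sim$samples)
  expect_equal(nrow(res_imp), 2 * nrow(logm))
  expect_false(anyNA(res_imp$p))

  # a protein entirely missing in group A(short) is undefined for that contrast
  logm2 <- logm
  acc <- rownames(logm)[which(rowSums(is.na(logm)) == 0)[1]]  # fully observed
  a_cols <- sim$samples$sample_id[sim$samples$treatment == "si-hVDAC1" &
                                    sim$samples$duration == "short"]
  logm2[acc, a_cols] <- NA
  res1 <- analyze_dataset(build_missing_dataset(logm2), sim$samples)
  row <- res1[res1$accession == acc & res1$contrast == "short", ]
  expect_true(is.na(row$p))
  other <- res1[res1$accession == acc & res1$contrast == "long", ]
  expect_false(is.na(other$p))
})

test_that("null p-values are uniform and the type-I rate is calibrated", {
  sim <- simulate_experiment(sim_config(
    n_human_proteins = 2000, n_mouse_proteins = 0, de_fraction = 0,
    censor_midpoint = -Inf, outlier_sample_shift = 0,
    protein_level_sd = 0, baseline_log2_sd = 2, seed = 23))
  res <- analyze_dataset(build_missing_dataset(log2_transform(sim$intensity)),
                         sim$samples)
  p <- res$p[res$contrast == "short"]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(p)))  # 1% critical value

  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)))
})

test_that("rejection rate is monotone in the planted effect size", {
  rate_for <- function(effect) {
    sim <- simulate_experiment(sim_config(
      n_human_proteins = 300, n_mouse_proteins = 0, de_fraction = 1,
      effect_log2_range = c(effect, effect), censor_midpoint = -Inf,
      outlier_sample_shift = 0, baseline_log2_sd = 0.5, seed = 29))
    res <- analyze_dataset(build_missing_dataset(log2_transform(sim$intensity)),
                           sim$samples)
    short <- res[res$contrast == "short", ]
    affected <- sim$truth$accession[sim$truth$de_short]  # carries the effect
    mean(short$p[short$accession %in% affected] < 0.05)
  }
  rates <- vapply(c(0, 0.5, 1, 2), rate_for, 0)
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.15)
  expect_gt(rates[4], 0.9)
})
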