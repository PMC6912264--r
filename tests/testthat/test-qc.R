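test_that("log2 transform maps zeros to missing and is otherwise invertible", {
  m <- matrix(c(8, 0, 1, 2^10.5, 0, 4), 2, 3,
              dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  lg <- log2_transform(m)
  expect_equal(lg["p1", "s1"], 3)
  expect_true(is.na(lg["p2", "s1"]))
  expect_identical(is.na(lg), m == 0)           # missing pattern == zero pattern
  expect_equal(2^lg[m > 0], m[m > 0])
  expect_error(log2_transform(matrix(-1)), "negative")
})

test_that("QC PCA matches an independent eigendecomposition", {
  sim <- tiny_sim(seed = 21, n = 120, censor_midpoint = -Inf,
                  outlier_sample_shift = 0)
  logm <- log2_transform(sim$intensity)
  rep <- qc_summaries(logm, sim$samples, k = 3)

  # oracle: eigendecomposition of the covariance of the row-centered matrix
  xc <- t(logm - rowMeans(logm))           # samples x proteins, centered
  eig <- eigen(stats::cov(xc))
  scores_oracle <- xc %*% eig$vectors[, 1:3]
  for (j in 1:3) {
    expect_equal(unname(abs(rep$scores[, j])), unname(abs(scores_oracle[, j])),
                 tolerance = 1e-8)
  }

  expect_equal(nrow(rep$summaries), 12)
  expect_equal(rep$summaries$n_observed, unname(colSums(!is.na(logm))))
})

test_that("duplicated samples get identical summaries and zero PC distance", {
  set.seed(5)
  x <- matrix(rnorm(300, 25, 2), 50, 6)
  x[, 4] <- x[, 3]  # literal duplicate column
  dimnames(x) <- list(sprintf("p%02d", 1:50),
                      c("si-NT_short_r1", "si-NT_short_r2", "si-hVDAC1_short_r1",
                        "si-hVDAC1_short_r2", "si-NT_long_r1", "si-hVDAC1_long_r1"))
  sheet <- data.frame(
    sample_id = colnames(x),
    treatment = rep(c("si-NT", "si-hVDAC1", "si-NT", "si-hVDAC1"), c(2, 2, 1, 1)),
    duration = rep(c("short", "long"), c(4, 2)),
    replicate = c(1, 2, 1, 2, 1, 1), included = TRUE,
    stringsAsFactors = FALSE
  )
  rep <- qc_summaries(log2_transform(2^x), sheet, k = 2)
  expect_equal(rep$scores[3, ], rep$scores[4, ], ignore_attr = TRUE)
  expect_equal(rep$summaries[3, -1], rep$summaries[4, -1], ignore_attr = TRUE)
})

test_that("k is reduced with a warning when complete rows are scarce", {
  sim <- tiny_sim(seed = 1, n = 4)
  x <- matrix(rnorm(48, 25, 1), 4, 12,
              dimnames = list(paste0("p", 1:4), sim$samples$sample_id))
  x[3:4, 1] <- NA  # leaves two complete rows
  expect_warning(rep <- qc_summaries(x, sim$samples, k = 4), "reducing k")
  expect_lte(rep$k, 1)
})

test_that("planted outlier replicates are flagged; homogeneous runs are not", {
  planted <- vapply(1:10, function(s) {
    sim <- simulate_experiment(sim_config(n_human_proteins = 250,
                                          n_mouse_proteins = 0, seed = s))
    fl <- flag_outlier_samples(qc_summaries(log2_transform(sim$intensity),
                                            sim$samples), sim$samples)
    want <- sim$samples$sample_id[sim$samples$duration == "long" &
                                    sim$samples$replicate == 1]
    setequal(as.character(fl), want)
  }, logical(1))
  expect_gte(sum(planted), 9)

  homogeneous <- vapply(1:20, function(s) {
    sim <- simulate_experiment(sim_config(n_human_proteins = 250,
                                          n_mouse_proteins = 0,
                                          outlier_sample_shift = 0,
                                          seed = 700 + s))
    fl <- flag_outlier_samples(qc_summaries(log2_transform(sim$intensity),
                                            sim$samples), sim$samples)
    length(fl) == 0
  }, logical(1))
  expect_gte(sum(homogeneous), 19)
})

test_that("flagging respects k_mad = Inf and small groups", {
  sim <- tiny_sim(seed = 33, n = 100)
  rep <- qc_summaries(log2_transform(sim$intensity), sim$samples)
  expect_length(flag_outlier_samples(rep, sim$samples, k_mad = Inf), 0)

  # groups of size 2 cannot be flagged
  sheet <- sim$samples
  sheet$included[sheet$duration == "long" & sheet$replicate == 3] <- FALSE
  logm <- log2_transform(sim$intensity)[, sheet$sample_id[sheet$included]]
  rep2 <- qc_summaries(logm, sheet)
  expect_message(fl <- flag_outlier_samples(rep2, sheet), "no flag possible")
  long_ids <- sheet$sample_id[sheet$duration == "long"]
  expect_false(any(fl %in% long_ids))
})

test_that("confirmed exclusions reproduce the duplicate/triplicate design", {
  sim <- tiny_sim(seed = 41, n = 100)
  logm <- log2_transform(sim$intensity)
  out_ids <- sim$samples$sample_id[sim$samples$duration == "long" &
                                     sim$samples$replicate == 1]
  res <- apply_exclusions(logm, sim$samples, out_ids)
  grp <- table(paste(res$sheet$treatment, res$sheet$duration, sep = "_")[
    res$sheet$included])
  expect_equal(as.integer(grp[c("si-NT_short", "si-hVDAC1_short")]), c(3L, 3L))
  expect_equal(as.integer(grp[c("si-NT_long", "si-hVDAC1_long")]), c(2L, 2L))
  expect_equal(ncol(res$logm), 10)

  # identity, contract violations
  none <- apply_exclusions(logm, sim$samples, character())
  expect_identical(none$logm, logm)
  expect_error(apply_exclusions(logm, sim$samples, "nope"), "unknown sample")
  too_many <- sim$samples$sample_id[sim$samples$duration == "long" &
                                      sim$samples$treatment == "si-NT"][1:2]
  expect_error(apply_exclusions(logm, sim$samples, too_many), "fewer than 2")
})
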