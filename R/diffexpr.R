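# Per-protein one-way ANOVA over the four design groups with two planned
# contrasts (si-hVDAC1 vs. si-NT within each duration), pooled-variance
# t inference, and signed linear fold changes. The per-dataset engine is
# vectorized across proteins; `anova_contrast()` is the scalar reference
# used on individual proteins and in tests.

#' The two planned contrasts
#'
#' Each contrast compares the silencing treatment (si-hVDAC1, group A) with
#' the non-targeting control (si-NT, group B) at one treatment duration.
#'
#' @return Named list with elements `short` and `long`, each a list with the
#'   group ids `A` and `B`.
#' @export
contrast_specs <- function() {
  lapply(stats::setNames(DURATIONS, DURATIONS), function(d) {
    list(id = d, A = group_id("si-hVDAC1", d), B = group_id("si-NT", d))
  })
}

#' One planned contrast within a one-way ANOVA
#'
#' Pools the error variance across all groups contributing at least two
#' observed values (groups with fewer are dropped from the pool entirely) and
#' tests the difference of the two contrast-group means with
#' `t = (mean_A - mean_B) / sqrt(MSE * (1/n_A + 1/n_B))` on
#' `N_obs - g_obs` residual degrees of freedom. The contrast is evaluable
#' only when both contrast groups have >= 2 observed values and the residual
#' df is >= 1; otherwise the result is marked undefined (`NA`), not an error.
#' A zero MSE with a nonzero mean difference yields the boundary p = 0 (with
#' a message); a zero MSE with a zero difference yields p = 1.
#'
#' @param values_by_group Named list of numeric vectors of observed log2
#'   values, one element per design group.
#' @param contrast One element of [contrast_specs()] (list with `A`, `B`).
#' @return List with `p_value`, `delta_log2` (mean A - mean B), `residual_df`,
#'   `n_A`, `n_B`, and `mse`.
#' @export
anova_contrast <- function(values_by_group, contrast) {
  stopifnot(is.list(values_by_group), all(c(contrast$A, contrast$B) %in%
                                            names(values_by_group)))
  obs <- lapply(values_by_group, function(v) v[!is.na(v)])
  n <- lengths(obs)
  contrib <- n >= 2L
  N <- sum(n[contrib])
  G <- sum(contrib)
  df <- N - G
  sse <- sum(vapply(obs[contrib], function(v) sum((v - mean(v))^2), 0))

  n_a <- n[[contrast$A]]
  n_b <- n[[contrast$B]]
  m_a <- if (n_a > 0) mean(obs[[contrast$A]]) else NA_real_
  m_b <- if (n_b > 0) mean(obs[[contrast$B]]) else NA_real_
  delta <- m_a - m_b

  if (n_a < 2L || n_b < 2L || df < 1L) {
    return(list(p_value = NA_real_, delta_log2 = delta, residual_df = df,
                n_A = n_a, n_B = n_b, mse = NA_real_))
  }
  mse <- sse / df
  if (mse == 0) {
    if (!isTRUE(all.equal(delta, 0))) {
      message("zero pooled MSE with nonzero contrast difference: p = 0 boundary")
      p <- 0
    } else {
      p <- 1
    }
  } else {
    t_stat <- delta / sqrt(mse * (1 / n_a + 1 / n_b))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  list(p_value = p, delta_log2 = delta, residual_df = df,
       n_A = n_a, n_B = n_b, mse = mse)
}

#' Signed linear fold change
#'
#' Maps a log2 mean difference to the field's signed linear convention:
#' `2^delta` for increases and `-2^(-delta)` for decreases, so that
#' `|FC| = 2^|delta| >= 1` always and a 2-fold reduction reads -2.
#'
#' @param delta_log2 Numeric vector of log2 differences (NA allowed).
#' @return Signed linear fold changes.
#' @export
fold_change <- function(delta_log2) {
  ifelse(is.na(delta_log2), NA_real_,
         ifelse(delta_log2 >= 0, 2^delta_log2, -(2^(-delta_log2))))
}

# Vectorized per-group moments over a proteins x samples matrix:
# counts, means and within-group sums of squares for each design group.
group_moments <- function(x, sheet) {
  inc <- sheet[sheet$included & sheet$sample_id %in% colnames(x), , drop = FALSE]
  grp <- group_id(inc$treatment, inc$duration)
  groups <- design_groups()
  n <- m <- ss <- matrix(NA_real_, nrow(x), length(groups),
                         dimnames = list(rownames(x), groups))
  for (g in groups) {
    cols <- inc$sample_id[grp == g]
    xg <- x[, cols, drop = FALSE]
    n[, g] <- rowSums(!is.na(xg))
    mg <- rowMeans(xg, na.rm = TRUE)
    mg[n[, g] == 0] <- NA_real_
    m[, g] <- mg
    ss[, g] <- rowSums((xg - mg)^2, na.rm = TRUE)
  }
  list(n = n, mean = m, ss = ss)
}

#' Analyze one dataset
#'
#' Runs the pooled-MSE ANOVA contrast and fold-change computation for every
#' protein and both contrasts on one dataset of the collection. Imputed
#' datasets have no missing values so every result is defined; in dataset 1
#' a (protein, contrast) whose preconditions fail (a contrast group with
#' fewer than 2 observed values, or residual df < 1) is reported with an
#' undefined p-value.
#'
#' @param ds A dataset (see [build_dataset_collection()]).
#' @param sheet Sample sheet (included samples define the groups).
#' @param contrasts Contrast list, default [contrast_specs()].
#' @return Data frame with one row per (protein, contrast): `accession`,
#'   `contrast`, `dataset`, `kind`, `p`, `delta_log2`, `fc`, `n_A`, `n_B`,
#'   `df`.
#' @export
analyze_dataset <- function(ds, sheet, contrasts = contrast_specs()) {
  stopifnot(inherits(ds, "pc_dataset"))
  x <- ds$matrix
  mom <- group_moments(x, sheet)
  contrib <- mom$n >= 2L
  N <- rowSums(mom$n * contrib)
  G <- rowSums(contrib)
  df <- N - G
  sse <- rowSums(mom$ss * contrib)
  mse <- ifelse(df >= 1, sse / df, NA_real_)

  res <- lapply(contrasts, function(ct) {
    n_a <- mom$n[, ct$A]
    n_b <- mom$n[, ct$B]
    delta <- mom$mean[, ct$A] - mom$mean[, ct$B]
    eligible <- n_a >= 2 & n_b >= 2 & df >= 1
    se <- sqrt(mse * (1 / n_a + 1 / n_b))
    p <- ifelse(eligible & se > 0, 2 * stats::pt(-abs(delta / se), df), NA_real_)
    zero_mse <- eligible & !is.na(mse) & mse == 0
    p[zero_mse] <- ifelse(delta[zero_mse] == 0, 1, 0)
    data.frame(accession = rownames(x), contrast = ct$id, dataset = ds$id,
               kind = ds$kind, p = unname(p), delta_log2 = unname(delta),
               fc = unname(fold_change(delta)), n_A = unname(n_a),
               n_B = unname(n_b), df = unname(df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Analyze every dataset of a collection
#'
#' @param collection A [build_dataset_collection()] result.
#' @inheritParams analyze_dataset
#' @return Row-bound [analyze_dataset()] results for all datasets — the full
#'   contrast result table (protein x contrast x dataset).
#' @export
analyze_collection <- function(collection, sheet, contrasts = contrast_specs()) {
  stopifnot(inherits(collection, "dataset_collection"))
  out <- do.call(rbind, lapply(collection$datasets, analyze_dataset,
                               sheet = sheet, contrasts = contrasts))
  rownames(out) <- NULL
  out
}
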