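# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (enumeration, O(n^3) agglomeration, direct formulas)
# and share no code with the package.

# One-sided enrichment p by explicit hypergeometric tail enumeration:
# universe of N genes, K in the term, n drawn (DE), observed overlap a.
oracle_hyper_p <- function(a, n, K, N) {
  hi <- min(n, K)
  sum(vapply(a:hi, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, 0))
}

# Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j) on the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Naive O(n^3) complete-linkage agglomeration on a distance matrix.
# Returns the sorted merge heights.
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- max(d[clusters[[i]], clusters[[j]]])
          if (h < best_h) {
            best_h <- h
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# Pooled-MSE planned contrast computed through aov + emmeans, an
# implementation-independent route to the same statistic.
oracle_contrast_p <- function(values_by_group, a, b) {
  df <- do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NULL)  # mirrors dropping sparse groups
    data.frame(y = v, g = g, stringsAsFactors = FALSE)
  }))
  fit <- stats::aov(y ~ g, data = df)
  em <- emmeans::emmeans(fit, "g")
  lv <- levels(factor(df$g))
  w <- as.numeric(lv == a) - as.numeric(lv == b)
  s <- summary(emmeans::contrast(em, list(ct = w)))
  list(p = s$p.value, estimate = s$estimate)
}

# Small simulated experiment shared by several tests.
tiny_sim <- function(seed = 1, n = 60, ...) {
  simulate_experiment(sim_config(n_human_proteins = n, n_mouse_proteins = 10,
                                 seed = seed, ...))
}

# Build a synthetic contrast-result table for one protein/contrast in which
# exactly `k` of `n_imp` imputed datasets pass the default thresholds, with
# chosen dataset-1 behavior and vote signs.
make_result_rows <- function(accession, contrast = "short", k = 0, n_imp = 5,
                             d1 = c("fail", "pass", "na"), signs = NULL) {
  d1 <- match.arg(d1)
  pass_row <- function(ds, sign = 1) {
    data.frame(accession = accession, contrast = contrast, dataset = ds,
               kind = if (ds == 1) "missing_neglect" else "imputed",
               p = 0.001, delta_log2 = sign * 1, fc = sign * 2,
               n_A = 3, n_B = 3, df = 8, stringsAsFactors = FALSE)
  }
  fail_row <- function(ds, na = FALSE) {
    data.frame(accession = accession, contrast = contrast, dataset = ds,
               kind = if (ds == 1) "missing_neglect" else "imputed",
               p = if (na) NA_real_ else 0.9,
               delta_log2 = if (na) NA_real_ else 0.1,
               fc = if (na) NA_real_ else 1.07,
               n_A = 3, n_B = 3, df = 8, stringsAsFactors = FALSE)
  }
  if (is.null(signs)) signs <- rep(1, k)
  d1_row <- switch(d1, fail = fail_row(1), na = fail_row(1, na = TRUE),
                   pass = pass_row(1))
  imp <- lapply(seq_len(n_imp), function(i) {
    if (i <= k) pass_row(i + 1, signs[i]) else fail_row(i + 1)
  })
  do.call(rbind, c(list(d1_row), imp))
}
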