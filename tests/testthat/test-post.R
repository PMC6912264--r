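test_that("row standardization yields zero-mean unit-sd rows", {
  expect_equal(standardize(matrix(c(1, 2, 3), 1))[1, ], c(-1, 0, 1))

  set.seed(3)
  x <- matrix(rnorm(300, 20, 4), 50, 6,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:6)))
  z <- standardize(x)
  expect_equal(unname(rowMeans(z)), rep(0, 50))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 50))

  x[7, ] <- 5  # constant row
  expect_message(z2 <- standardize(x), "constant")
  expect_equal(unname(z2[7, ]), rep(0, 6))
  expect_equal(attr(z2, "constant_rows"), "p07")
})

test_that("clustering merges duplicates first and anticorrelated rows last", {
  base <- c(1, 2, 3, 4, 2, 5)
  x <- rbind(a = base, b = base + 10,        # r = 1 -> d = 0
             mid = c(1, 3, 2, 4, 5, 2),
             neg = -base)                    # r = -1 with a/b -> d = 2
  out <- cluster_proteins(x)
  first_pair <- rownames(x)[sort(-out$hclust$merge[1, ])]
  expect_equal(out$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(first_pair, c("a", "b"))
  expect_equal(max(out$hclust$height), 2, tolerance = 1e-12)
})

test_that("complete-linkage heights equal a brute-force agglomeration", {
  set.seed(23)
  x <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(letters[1:12], NULL))
  out <- cluster_proteins(x)
  d <- 1 - cor(t(x[order(rownames(x)), ]))
  expect_equal(sort(out$hclust$height),
               oracle_complete_linkage_heights(as.dist(d)),
               tolerance = 1e-10)
})

test_that("zero-variance rows are excluded; row order does not matter", {
  set.seed(31)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("p%02d", 1:10), NULL))
  x[4, ] <- 2
  expect_message(out <- cluster_proteins(x), "zero-variance")
  expect_equal(out$excluded, "p04")
  expect_equal(length(out$leaf_order), 9)

  shuffled <- x[sample(nrow(x)), ]
  expect_message(out2 <- cluster_proteins(shuffled), "zero-variance")
  expect_equal(out2$hclust$height, out$hclust$height)
  expect_equal(out2$leaf_order, out$leaf_order)
})

test_that("volcano flags re-derive from the strict thresholds", {
  res <- rbind(
    make_result_rows("P1", k = 0, d1 = "fail"),
    make_result_rows("P2", k = 0, d1 = "pass")
  )
  res$p[res$accession == "P1" & res$dataset == 1] <- 0.05   # boundary
  res$fc[res$accession == "P1" & res$dataset == 1] <- 2
  v <- volcano_table(res, "short", dataset = 1)
  expect_false(v$pass_p[v$accession == "P1"])               # strict at alpha
  expect_true(v$candidate[v$accession == "P2"])

  set.seed(7)
  rnd <- make_result_rows("P3", k = 5)
  rnd$p <- runif(6); rnd$fc <- fold_change(rnd$delta_log2 <- runif(6, -3, 3))
  for (ds in 2:6) {
    vv <- volcano_table(rnd, "short", dataset = ds)
    r <- rnd[rnd$dataset == ds, ]
    expect_equal(vv$pass_p, r$p < 0.05)
    expect_equal(vv$pass_fc, abs(r$fc) > 1.5)
    expect_equal(vv$candidate, vv$pass_p & vv$pass_fc)
  }
})

test_that("Fisher enrichment equals hypergeometric tail enumeration", {
  universe <- sprintf("G%02d", 1:20)
  db <- structure(list(
    sets = list(T1 = universe[1:6], T2 = universe[5:16], T3 = universe,
                T4 = universe[19:20]),
    info = data.frame(term = c("T1", "T2", "T3", "T4"), description = "x")),
    class = "gene_set_db")
  de <- universe[c(1:4, 7, 11)]
  rows <- fisher_enrichment(de, universe, db)
  for (i in seq_len(nrow(rows))) {
    K <- rows$n_bg_in_term[i]
    expect_equal(rows$p_value[i],
                 oracle_hyper_p(rows$n_de_in_term[i], length(de), K, 20),
                 tolerance = 1e-12)
  }
  # a term equal to the whole background can never be enriched
  expect_equal(rows$p_value[rows$term == "T3"], 1)
  # empty DE set: p = 1 everywhere
  empty <- fisher_enrichment(character(), universe, db)
  expect_true(all(empty$p_value == 1))
  expect_error(fisher_enrichment(c("NOPE", de), universe, db), "NOPE")
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the term reporting filter is strict at both cuts", {
  rows <- data.frame(term = paste0("T", 1:4),
                     n_de_in_term = c(4, 5, 10, 6),
                     q_value = c(0.01, 0.01, 0.05, 0.049),
                     p_value = c(0.001, 0.002, 0.01, 0.02))
  kept <- filter_terms(rows)
  expect_setequal(kept$term, c("T2", "T4"))  # T1: only 4 DE; T3: q not < 0.05

  set.seed(5)
  rnd <- data.frame(term = paste0("R", 1:50),
                    n_de_in_term = sample(0:12, 50, TRUE),
                    q_value = runif(50), p_value = runif(50))
  got <- filter_terms(rnd, q_max = 0.3, min_de_in_term = 6)
  expect_setequal(got$term,
                  rnd$term[rnd$q_value < 0.3 & rnd$n_de_in_term > 6])
})

test_that("planted enriched terms rank above null terms", {
  ranks_ok <- vapply(1:10, function(s) {
    sim <- tiny_sim(seed = s, n = 400, de_fraction = 0.25)
    db <- simulate_gene_sets(sim$truth, n_terms = 30, size_range = c(15, 40),
                             n_enriched_terms = 3, enriched_odds = 12,
                             seed = s + 100)
    human <- sim$truth[sim$truth$organism == "human", ]
    de <- unique(human$gene[human$de_short | human$de_long])
    rows <- fisher_enrichment(de, unique(human$gene), db)
    rows <- rows[order(rows$q_value, rows$p_value), ]
    planted <- db$info$term[db$info$enriched]
    all(planted %in% rows$term[1:6])
  }, logical(1))
  expect_gte(sum(ranks_ok), 9)
})
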