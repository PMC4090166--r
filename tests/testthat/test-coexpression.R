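test_that("pairwise correlations match hand-computed values", {
  mat <- rbind(
    x = c(1, 2, 3, 4),
    y = c(2, 4, 6, 8),
    z = c(8, 6, 4, 2),
    w = c(1, 3, 2, 4)
  )
  colnames(mat) <- paste0("s", 1:4)
  r <- pairwise_correlation(toy_panel(mat))
  expect_equal(unname(diag(r)), rep(1, 4)) # gene vs itself
  expect_equal(r["x", "y"], 1)             # collinear
  expect_equal(r["x", "z"], -1)            # anti-collinear
  expect_equal(r["x", "w"], 0.8)           # product-moment by hand
  expect_true(isSymmetric(unclass(r)))
  expect_true(all(abs(r) <= 1 + 1e-12))
})

test_that("spearman equals pearson applied to within-gene ranks", {
  for (seed in 1:5) {
    panel <- random_panel(10, 15, seed = seed) # continuous => tie-free
    sp <- pairwise_correlation(panel, method = "spearman")
    ranked <- toy_panel(t(apply(panel_matrix(panel), 1L, rank)))
    pe <- pairwise_correlation(ranked, method = "pearson")
    expect_equal(unclass(sp), unclass(pe), tolerance = 1e-12,
      ignore_attr = TRUE
    )
  }
})

test_that("zero-variance genes are dropped with a warning, not scored", {
  mat <- rbind(
    a = c(1, 2, 3, 4),
    flat = c(2, 2, 2, 2),
    b = c(4, 1, 3, 2)
  )
  colnames(mat) <- paste0("s", 1:4)
  expect_warning(r <- pairwise_correlation(toy_panel(mat)), "flat")
  expect_equal(rownames(r), c("a", "b"))
})

test_that("requesting genes absent from the panel errors", {
  panel <- random_panel(5, 6, seed = 2)
  expect_error(
    pairwise_correlation(panel, rows = c(panel_genes(panel)[1], "NOPE")),
    "NOPE"
  )
})

test_that("combination weights are normalized inverse variances", {
  # build matrices with known off-diagonal variances via explicit entries
  m1 <- toy_cor(rbind(
    c(1, 0.1, 0.3), c(0.1, 1, 0.5), c(0.3, 0.5, 1)
  ), source = "i1")
  v1 <- var(c(0.1, 0.3, 0.5))
  m2 <- toy_cor(rbind(
    c(1, 0.0, 0.8), c(0.0, 1, 0.4), c(0.8, 0.4, 1)
  ), source = "i2")
  v2 <- var(c(0.0, 0.8, 0.4))
  w <- combination_weights(list(m1, m2), time_period = "adult")
  expect_equal(w$variance, c(v1, v2))
  expect_equal(w$weight, (1 / c(v1, v2)) / sum(1 / c(v1, v2)))
  expect_equal(sum(w$weight), 1)
  expect_true(all(w$weight >= 0))
  # the lower-variance individual gets the larger weight
  expect_equal(which.max(w$weight), which.min(w$variance))
})

test_that("inverse-variance normalization reproduces hand-derived weights", {
  # two individuals with correlation variances 0.01 and 0.04 -> weights .8/.2
  sd_pair <- sqrt(c(0.01, 0.04))
  base <- c(-1, 0, 1, 0.5, -0.5, 0.25)
  mk <- function(s, id) {
    vals <- base * s / sd(base) # off-diagonals with exact variance s^2
    m <- diag(4)
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    toy_cor(m, source = id)
  }
  w <- combination_weights(list(mk(sd_pair[1], "lo"), mk(sd_pair[2], "hi")))
  expect_equal(w$weight, c(0.8, 0.2))

  # equal variances split the weight evenly
  w_eq <- combination_weights(list(mk(0.1, "a"), mk(0.1, "b")))
  expect_equal(w_eq$weight, c(0.5, 0.5))
})

test_that("weights are equivariant under permuting individuals", {
  mats <- lapply(1:3, function(i) {
    m <- withr::with_seed(i, {
      x <- matrix(rnorm(8 * 20), nrow = 8)
      cor(t(x))
    })
    toy_cor(m, source = paste0("ind", i))
  })
  w12 <- combination_weights(mats)
  w21 <- combination_weights(mats[c(3, 1, 2)])
  expect_equal(
    w21$weight[match(w12$individual_id, w21$individual_id)],
    w12$weight
  )
})

test_that("degenerate weight inputs error", {
  m <- toy_cor(diag(3))
  expect_error(combination_weights(list(m)), "at least 2")
  expect_error(combination_weights(list(m, m)), "degenerate")
})

test_that("weighted combination behaves as a convex combination", {
  m1 <- toy_cor(rbind(c(1, 0.6), c(0.6, 1)), source = "i1")
  m2 <- toy_cor(rbind(c(1, 0.2), c(0.2, 1)), source = "i2")
  w <- tibble::tibble(
    individual_id = c("i1", "i2"), variance = c(1, 1),
    weight = c(0.5, 0.5), time_period = "adult"
  )
  comb <- combine_correlations(list(m1, m2), w)
  expect_equal(comb["g01", "g02"], 0.4) # arithmetic mean at equal weights
  expect_equal(cor_source(comb), "combined:adult")

  # single individual with unit weight is the identity
  solo <- combine_correlations(list(m1))
  expect_equal(unclass(solo), unclass(m1), ignore_attr = TRUE)

  # convexity: combined entries stay within the per-individual envelope
  for (seed in 1:4) {
    mats <- lapply(1:3, function(i) {
      m <- withr::with_seed(seed * 10 + i, cor(t(matrix(rnorm(6 * 12), 6))))
      dimnames(m) <- list(sprintf("g%02d", 1:6), sprintf("g%02d", 1:6))
      toy_cor(m, source = paste0("ind", i))
    })
    ww <- combination_weights(mats)
    cc <- combine_correlations(mats, ww)
    lo <- pmin(unclass(mats[[1]]), unclass(mats[[2]]), unclass(mats[[3]]))
    hi <- pmax(unclass(mats[[1]]), unclass(mats[[2]]), unclass(mats[[3]]))
    expect_true(all(cc >= lo - 1e-12 & cc <= hi + 1e-12))
    expect_true(isSymmetric(unclass(cc)))
    expect_equal(unname(diag(cc)), rep(1, 6))
    expect_true(all(abs(cc) <= 1 + 1e-12))
  }
})

test_that("misaligned matrices refuse to combine", {
  m1 <- toy_cor(diag(2))
  m2 <- toy_cor(matrix(c(1, 0, 0, 1), 2,
    dimnames = list(c("x", "y"), c("x", "y"))
  ))
  expect_error(
    combine_correlations(list(m1, m2), tibble::tibble(
      individual_id = c("toy", "toy2"), variance = 1:2,
      weight = c(.5, .5), time_period = "p"
    )),
    "aligned"
  )
})

test_that("null pair counts follow the choose(n, 2) identity", {
  panel <- random_panel(60, 10, seed = 3)
  ref <- panel_genes(panel)[1:5]
  s <- null_distribution(list(panel), ref, n_genes = 29, seed = 1)
  expect_equal(s$n_null_pairs, 406L)
  expect_equal(s$n_reference_pairs, choose(5, 2))
  expect_error(
    null_distribution(list(panel), ref, n_genes = 60, seed = 1),
    "exceeds"
  )
})

test_that("independent genes give a null median near zero", {
  panel <- random_panel(120, 40, seed = 4)
  ref <- panel_genes(panel)[1:10]
  s <- null_distribution(list(panel), ref, n_genes = 80, seed = 5)
  # under independence the null median r is 0; pairs share gene vectors, so
  # the effective sample size is ~n_genes, giving SE ~ (1/sqrt(39))/sqrt(80)
  expect_lt(abs(s$median_r_null), 3 * (1 / sqrt(39)) / sqrt(80))
  expect_gte(s$median_abs_r_null, 0)
  td <- tidy(s)
  expect_true(all(td$ecdf > 0 & td$ecdf <= 1))
  expect_false(is.unsorted(td$ecdf[td$set == "null"]))
})

test_that("significance cutoff follows the nearest-rank quantile rule", {
  # all pairwise |r| equal to 1: genes are exact linear transforms
  base <- c(1, 4, 2, 8, 5, 7)
  mat <- rbind(a = base, b = 2 * base, c = -base + 3, d = 0.5 * base - 1)
  colnames(mat) <- paste0("s", seq_along(base))
  ts <- significance_cutoff(list(toy_panel(mat)),
    n_sampled_pairs = 100, seed = 1
  )
  expect_equal(ts$cutoff, 1)

  # independence: cutoff approximates the Fisher-z null quantile for n = 30
  panel <- random_panel(250, 30, seed = 6)
  ts2 <- significance_cutoff(list(panel),
    quantile = 0.95,
    n_sampled_pairs = 2e4, seed = 7
  )
  fisher_q <- tanh(stats::qnorm(0.975) / sqrt(30 - 3))
  expect_lt(abs(ts2$cutoff - fisher_q), 0.03)

  # monotone nondecreasing in the quantile
  cuts <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(q) {
    significance_cutoff(list(panel),
      quantile = q, n_sampled_pairs = 5000,
      seed = 8
    )$cutoff
  }, numeric(1))
  expect_false(is.unsorted(cuts))

  expect_error(
    significance_cutoff(list(panel), n_sampled_pairs = 50),
    "unstable"
  )
})

test_that("pair unranking is a bijection onto distinct pairs", {
  n <- 7L
  idx <- coexpnet:::unrank_pairs(seq_len(choose(n, 2)), n)
  expect_true(all(idx[, 1] < idx[, 2]))
  expect_equal(nrow(unique(as.data.frame(idx))), choose(n, 2))
  expect_true(all(idx >= 1 & idx <= n))
})
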