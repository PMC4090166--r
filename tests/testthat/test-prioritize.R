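test_that("connectivity counts and sums significant edges", {
  r <- matrix(0, 4, 3, dimnames = list(
    c("cand1", "cand2", "cand3", "cand4"), c("ref1", "ref2", "ref3")
  ))
  r["cand1", ] <- c(0.50, 0.20, -0.60)
  r["cand2", ] <- c(0.10, -0.30, 0.40)   # all below cutoff
  r["cand3", ] <- c(1, 1, 1)             # saturated
  r["cand4", ] <- c(0.44, 0.44, 0.44)    # exactly at the cutoff: strict >
  m <- structure(r, method = "pearson", source = "toy", class = "cor_matrix")
  tab <- connectivity_scores(m, colnames(r), rownames(r), cutoff = 0.44)
  expect_equal(tab$k_star[tab$gene == "cand1"], 2L)
  expect_equal(tab$k[tab$gene == "cand1"], 1.10)
  expect_equal(tab$k_star[tab$gene == "cand2"], 0L)
  expect_equal(tab$k[tab$gene == "cand2"], 0)
  expect_equal(tab$k_star[tab$gene == "cand3"], 3L)
  expect_equal(tab$k[tab$gene == "cand3"], 3)
  expect_equal(tab$k_star[tab$gene == "cand4"], 0L) # exceed means strictly

  expect_error(
    connectivity_scores(m, colnames(r), c("cand1", "ref1"), 0.44),
    "ref1"
  )
})

test_that("a saturated candidate attains the K = K* = |reference| bound", {
  refs <- sprintf("R%02d", 1:29)
  r <- matrix(1, 1, 29, dimnames = list("cand", refs))
  m <- structure(r, method = "pearson", source = "toy", class = "cor_matrix")
  tab <- connectivity_scores(m, refs, "cand", cutoff = 0.44)
  expect_equal(tab$k_star, 29L)
  expect_equal(tab$k, 29)
})

test_that("connectivity obeys its bounds and is nonincreasing in cutoff", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, {
      x <- matrix(rnorm(10 * 20), 10)
      cor(t(x))
    })
    dimnames(m) <- list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10))
    mm <- toy_cor(m)
    refs <- rownames(m)[1:6]
    cands <- rownames(m)[7:10]
    prev <- NULL
    for (cutoff in c(0.1, 0.3, 0.5, 0.7)) {
      tab <- connectivity_scores(mm, refs, cands, cutoff)
      expect_true(all(tab$k >= cutoff * tab$k_star - 1e-12))
      expect_true(all(tab$k <= tab$k_star + 1e-12))
      expect_true(all(tab$k_star <= length(refs)))
      if (!is.null(prev)) {
        expect_true(all(tab$k_star <= prev$k_star))
        expect_true(all(tab$k <= prev$k + 1e-12))
      }
      prev <- tab
    }
  }
})

test_that("connectivity matches the brute-force oracle", {
  for (seed in 1:4) {
    m <- withr::with_seed(seed, cor(t(matrix(rnorm(9 * 25), 9))))
    dimnames(m) <- list(sprintf("g%02d", 1:9), sprintf("g%02d", 1:9))
    refs <- rownames(m)[1:5]
    cands <- rownames(m)[6:9]
    tab <- connectivity_scores(toy_cor(m), refs, cands, cutoff = 0.25)
    for (g in cands) {
      oracle <- brute_connectivity(m, g, refs, 0.25)
      expect_equal(tab$k_star[tab$gene == g], oracle$k_star)
      expect_equal(tab$k[tab$gene == g], oracle$k)
    }
  }
})

test_that("leave-one-out scores each reference gene against the rest", {
  # complete block: every pairwise |r| above the cutoff
  block <- matrix(0.9, 5, 5)
  diag(block) <- 1
  dimnames(block) <- list(sprintf("r%d", 1:5), sprintf("r%d", 1:5))
  loo <- leave_one_out_connectivity(toy_cor(block), rownames(block), 0.5)
  expect_equal(loo$k_star, rep(4L, 5))
  expect_equal(loo$k, rep(4 * 0.9, 5))

  # one isolated gene: its edges vanish, others lose exactly that edge
  iso <- block
  iso["r5", ] <- iso[, "r5"] <- 0.1
  iso["r5", "r5"] <- 1
  loo_iso <- leave_one_out_connectivity(toy_cor(iso), rownames(iso), 0.5)
  expect_equal(loo_iso$k_star[loo_iso$gene == "r5"], 0L)
  expect_equal(loo_iso$k_star[loo_iso$gene != "r5"], rep(3L, 4))

  expect_error(leave_one_out_connectivity(toy_cor(block), c("r1", "r2"), .5),
    "at least 3"
  )
})

test_that("leave-one-out agrees with brute-force recomputation", {
  m <- withr::with_seed(11, cor(t(matrix(rnorm(6 * 30), 6))))
  dimnames(m) <- list(sprintf("g%02d", 1:6), sprintf("g%02d", 1:6))
  refs <- rownames(m)
  loo <- leave_one_out_connectivity(toy_cor(m), refs, 0.2)
  oracle <- brute_loo(m, refs, 0.2)
  for (i in seq_along(refs)) {
    expect_equal(loo$k_star[loo$gene == refs[i]], oracle[[i]]$k_star)
    expect_equal(loo$k[loo$gene == refs[i]], oracle[[i]]$k)
  }
})

test_that("ranks order by descending K with lexicographic tie-breaks", {
  r <- matrix(c(0.9, 0.9, 0.5, 0.2), 4, 1,
    dimnames = list(c("zeta", "alpha", "mid", "low"), "ref1")
  )
  m <- structure(r, method = "pearson", source = "t", class = "cor_matrix")
  tab <- connectivity_scores(m, "ref1", rownames(r), cutoff = 0.1)
  expect_equal(tab$gene[order(tab$rank)], c("alpha", "zeta", "mid", "low"))
})

efdr_fixture <- function(n_true, seed, n_resamples = 200) {
  b <- planted_benchmark(
    n_true_candidates = n_true, n_decoys = 50, seed = seed
  )
  mats <- lapply(b$panels, pairwise_correlation, rows = b$reference)
  w <- combination_weights(mats)
  ts <- significance_cutoff(b$panels,
    weights = w, n_sampled_pairs = 5000,
    seed = seed + 1
  )
  cand_mats <- lapply(b$panels, pairwise_correlation,
    rows = b$candidates, cols = b$reference
  )
  cc <- combine_correlations(cand_mats, w)
  tab <- connectivity_scores(cc, b$reference, b$candidates$symbols, ts$cutoff)
  curve <- efdr_curve(tab, b$panels, b$reference,
    cutoff = ts$cutoff,
    n_resamples = n_resamples, weights = w, seed = seed + 2
  )
  list(bench = b, weights = w, threshold = ts, table = tab, curve = curve)
}

test_that("the eFDR curve is the resampling ratio, truncated and monotone", {
  fx <- efdr_fixture(n_true = 5, seed = 21)
  df <- tibble::as_tibble(fx$curve)
  ok <- df$n_observed > 0
  expect_equal(df$efdr_raw[ok], df$mean_random[ok] / df$n_observed[ok])
  expect_true(all(is.na(df$efdr_raw[!ok]))) # undefined, reported missing
  expect_true(all(df$efdr[ok] <= 1 + 1e-12))
  expect_false(is.unsorted(rev(df$efdr[ok]))) # nonincreasing in T
})

test_that("the eFDR is near one at low thresholds under the null", {
  fx <- efdr_fixture(n_true = 0, seed = 31)
  df <- tibble::as_tibble(fx$curve)
  low <- df$efdr_raw[df$threshold == 0]
  expect_gt(low, 0.7) # observed candidates exchangeable with resamples
})

test_that("resampling with the same seed is bit-reproducible", {
  fx <- efdr_fixture(n_true = 3, seed = 41)
  again <- efdr_curve(fx$table, fx$bench$panels, fx$bench$reference,
    cutoff = fx$threshold$cutoff, n_resamples = 200,
    weights = fx$weights, seed = 43
  )
  expect_identical(
    tibble::as_tibble(fx$curve), tibble::as_tibble(again)
  )
})

test_that("selection prioritizes exactly the genes above the chosen T", {
  fx <- efdr_fixture(n_true = 8, seed = 51)
  sel <- select_prioritized(fx$table, fx$curve)
  chosen <- attr(sel, "chosen_T")
  expect_false(is.na(chosen))
  expect_equal(sel$prioritized, sel$k > chosen)
  expect_setequal(sel$rank, seq_len(nrow(sel)))

  # a candidate just above the threshold is in; just below or at is out
  eps <- min(sel$k[sel$k > chosen] - chosen) / 2
  expect_true(all(sel$prioritized[sel$k >= chosen + eps]))
  expect_false(any(sel$prioritized[sel$k <= chosen]))
})

test_that("an unattainable target leaves the prioritized set empty", {
  fx <- efdr_fixture(n_true = 0, seed = 61)
  expect_warning(
    sel <- select_prioritized(fx$table, fx$curve, target = 1e-6),
    "nothing prioritized"
  )
  expect_false(any(sel$prioritized))
})
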