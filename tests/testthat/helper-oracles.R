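# Shared fixtures and independent brute-force oracles used across tests.

# A deterministic tiny panel from an explicit matrix.
toy_panel <- function(mat, id = "toy", period = "pooled") {
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  }
  expression_panel(mat, individual_id = id, time_period = period)
}

# Random panel with seeded iid normal entries (independent genes).
random_panel <- function(n_genes, n_samples, seed, id = "rand") {
  m <- withr::with_seed(seed, matrix(rnorm(n_genes * n_samples),
    nrow = n_genes
  ))
  toy_panel(m, id = id)
}

# Wrap a plain symmetric matrix as the cor_matrix the package produces.
toy_cor <- function(m, method = "pearson", source = "toy") {
  if (is.null(rownames(m))) {
    dimnames(m) <- list(
      sprintf("g%02d", seq_len(nrow(m))), sprintf("g%02d", seq_len(ncol(m)))
    )
  }
  structure(m, method = method, source = source, class = "cor_matrix")
}

# Brute-force connectivity for one candidate: explicit loop over reference
# genes, independent of the vectorized implementation.
brute_connectivity <- function(r, candidate, reference, cutoff) {
  k_star <- 0L
  k <- 0
  for (g in reference) {
    v <- abs(r[candidate, g])
    if (v > cutoff) {
      k_star <- k_star + 1L
      k <- k + v
    }
  }
  list(k_star = k_star, k = k)
}

# Brute-force leave-one-out: re-score every reference gene from scratch.
brute_loo <- function(r, reference, cutoff) {
  lapply(reference, function(g) {
    brute_connectivity(r, g, setdiff(reference, g), cutoff)
  })
}

# Exhaustive one-sided Mann-Whitney permutation p-value: enumerate every
# assignment of group labels and compare flagged-group rank sums.
enum_mw_p <- function(x, flagged) {
  n <- length(x)
  n1 <- sum(flagged)
  r <- rank(x)
  obs <- sum(r[flagged])
  splits <- utils::combn(n, n1)
  stats <- apply(splits, 2L, function(idx) sum(r[idx]))
  mean(stats >= obs)
}

# A 2-block block-diagonal correlation matrix.
two_block_cor <- function(n1 = 5, n2 = 4, within = 0.8, between = 0) {
  n <- n1 + n2
  m <- matrix(between, n, n)
  m[seq_len(n1), seq_len(n1)] <- within
  m[n1 + seq_len(n2), n1 + seq_len(n2)] <- within
  diag(m) <- 1
  dimnames(m) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  m
}

# Circular contiguity: are the positions of `members` within `ordering`
# consecutive, allowing wrap-around?
circular_contiguous <- function(ordering, members) {
  pos <- sort(match(members, ordering))
  gaps <- diff(c(pos, pos[1] + length(ordering)))
  sum(gaps > 1L) <= 1L
}
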