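#' Genome-wide null co-expression distribution and ECDF comparison
#'
#' Draws `n_genes` genes uniformly without replacement from the panels' gene
#' universe (excluding the reference set and any further exclusions such as
#' candidate genes, so the null is not contaminated by putative signal),
#' computes all their pairwise combined correlations, and returns the |r|
#' distribution alongside the reference set's |r| distribution for ECDF
#' comparison. With `n_genes = 1000` this yields 499,500 null gene pairs.
#'
#' @param panels List of [expression_panel()] objects over the same gene
#'   universe, one per individual.
#' @param reference Reference [gene_set()] (or character vector) whose
#'   pairwise |r| values form the foreground distribution.
#' @param n_genes Number of null genes to draw (default 1000).
#' @param exclude Further symbols to keep out of the null draw (typically
#'   the candidate list).
#' @param method `"pearson"` or `"spearman"`.
#' @param weights A [combination_weights()] tibble; computed from the
#'   reference-panel matrices when `NULL` and more than one panel is given.
#' @param time_period Label used when weights are derived internally.
#' @param seed Integer seed for the null gene draw.
#' @return An object of class `ecdf_summary`: reference and null sorted |r|
#'   vectors, the signed and absolute null medians, and pair counts.
#' @export
null_distribution <- function(panels, reference, n_genes = 1000,
                              exclude = NULL,
                              method = c("pearson", "spearman"),
                              weights = NULL, time_period = "pooled",
                              seed = 1) {
  method <- match.arg(method)
  reference <- as_symbols(reference)
  universe <- common_genes(panels)
  pool <- setdiff(universe, c(reference, as_symbols(exclude %||% character())))
  if (n_genes > length(pool)) {
    abort(sprintf(
      "n_genes = %d exceeds the eligible gene universe (%d)",
      n_genes, length(pool)
    ))
  }
  null_genes <- withr::with_seed(seed, sample(pool, n_genes))
  ref_mats <- map(panels, pairwise_correlation, rows = reference,
    method = method
  )
  if (is.null(weights) && length(panels) > 1L) {
    weights <- combination_weights(ref_mats, time_period = time_period)
  }
  ref_combined <- combine_correlations(ref_mats, weights)
  null_mats <- map(panels, pairwise_correlation, rows = null_genes,
    method = method
  )
  null_combined <- combine_correlations(null_mats, weights)
  null_r <- null_combined[upper.tri(null_combined)]
  structure(
    list(
      reference_abs_r = sort(abs(ref_combined[upper.tri(ref_combined)])),
      null_abs_r = sort(abs(null_r)),
      median_r_null = median(null_r),
      median_abs_r_null = median(abs(null_r)),
      n_reference_pairs = sum(upper.tri(ref_combined)),
      n_null_genes = n_genes,
      n_null_pairs = length(null_r),
      method = method,
      seed = seed
    ),
    class = "ecdf_summary"
  )
}

common_genes <- function(panels) {
  Reduce(intersect, map(panels, panel_genes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ecdf_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<ecdf_summary> %d reference pairs vs %d null pairs (%d genes)\n",
      "  null median r = %.3f, median |r| = %.3f\n"
    ),
    x$n_reference_pairs, x$n_null_pairs, x$n_null_genes,
    x$median_r_null, x$median_abs_r_null
  ))
  invisible(x)
}

#' @export
tidy.ecdf_summary <- function(x, ...) {
  bind_rows(
    tibble(
      set = "reference", abs_r = x$reference_abs_r,
      ecdf = seq_along(x$reference_abs_r) / length(x$reference_abs_r)
    ),
    tibble(
      set = "null", abs_r = x$null_abs_r,
      ecdf = seq_along(x$null_abs_r) / length(x$null_abs_r)
    )
  )
}

#' @export
glance.ecdf_summary <- function(x, ...) {
  tibble(
    n_reference_pairs = x$n_reference_pairs,
    n_null_genes = x$n_null_genes,
    n_null_pairs = x$n_null_pairs,
    median_r_null = x$median_r_null,
    median_abs_r_null = x$median_abs_r_null
  )
}

#' @export
autoplot.ecdf_summary <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$abs_r, .data$ecdf,
    colour = .data$set
  )) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "|r|", y = "ECDF", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write an ECDF summary as two-column TSV per set
#' @param x An `ecdf_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecdf_summary <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}

#' Top-quantile |r| significance cutoff
#'
#' Estimates the genome-wide distribution of combined |r| from a seeded
#' uniform sample of distinct gene pairs drawn over the whole dataset (all
#' genes, not just reference or candidates) and returns its empirical
#' quantile by the nearest-rank rule. With the default `quantile = 0.95`
#' this is the top-5% |r| cutoff above which an edge is called significant.
#'
#' @inheritParams null_distribution
#' @param quantile Probability in (0, 1); default 0.95.
#' @param n_sampled_pairs Number of distinct gene pairs to sample (at least
#'   100; capped at the total number of pairs, in which case every pair is
#'   used).
#' @param weights A [combination_weights()] tibble; required for more than
#'   one panel.
#' @param seed Integer seed for the pair sample.
#' @return An object of class `threshold_spec` with fields `quantile`,
#'   `cutoff`, `n_sampled_pairs`, `seed`, `method`.
#' @export
significance_cutoff <- function(panels, weights = NULL, quantile = 0.95,
                                n_sampled_pairs = 1e5,
                                method = c("pearson", "spearman"),
                                seed = 1) {
  method <- match.arg(method)
  if (quantile <= 0 || quantile >= 1) abort("quantile must lie in (0, 1)")
  if (n_sampled_pairs < 100) {
    abort("n_sampled_pairs < 100 gives an unstable cutoff estimate")
  }
  if (length(panels) > 1L && is.null(weights)) {
    abort("weights are required to combine more than one panel")
  }
  universe <- common_genes(panels)
  n_u <- length(universe)
  if (n_u < 2L) abort("need at least two genes")
  total <- n_u * (n_u - 1) / 2
  k <- min(n_sampled_pairs, total)
  pick <- withr::with_seed(seed, sample.int(total, k))
  pairs <- unrank_pairs(pick, n_u)
  abs_r <- abs(combined_pair_correlations(panels, weights, universe,
    pairs, method
  ))
  abs_r <- abs_r[!is.na(abs_r)]
  sorted <- sort(abs_r)
  cutoff <- sorted[ceiling(quantile * length(sorted))]
  structure(
    list(
      quantile = quantile, cutoff = unname(cutoff),
      n_sampled_pairs = length(abs_r), seed = seed, method = method
    ),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "<threshold_spec> |r| cutoff %.4f at quantile %.2f (%d sampled pairs)\n",
    x$cutoff, x$quantile, x$n_sampled_pairs
  ))
  invisible(x)
}

# Map linear indices in 1..choose(n, 2) to (i, j) pairs with i < j,
# enumerated row-wise: (1,2), (1,3), ..., (1,n), (2,3), ...
unrank_pairs <- function(k, n) {
  offsets <- cumsum(c(0, n - seq_len(n - 1)))
  i <- findInterval(k - 1, offsets)
  j <- i + (k - offsets[i])
  cbind(i, j)
}

# Weighted-combined correlation for an explicit set of gene pairs, computed
# from per-panel standardized expression rows (avoids forming the full
# genome-wide correlation matrix).
combined_pair_correlations <- function(panels, weights, universe, pairs,
                                       method) {
  w <- if (is.null(weights)) {
    setNames(1, panel_id(panels[[1]]))
  } else {
    setNames(weights$weight, weights$individual_id)
  }
  acc <- numeric(nrow(pairs))
  for (panel in panels) {
    mat <- panel_matrix(panel)[universe, , drop = FALSE]
    if (method == "spearman") mat <- rank_rows(mat)
    z <- mat - rowMeans(mat)
    ss <- sqrt(rowSums(z^2))
    z <- z / ss # zero-variance rows become NaN and propagate to NA pairs
    r <- rowSums(z[pairs[, 1], , drop = FALSE] * z[pairs[, 2], , drop = FALSE])
    acc <- acc + w[[panel_id(panel)]] * r
  }
  acc
}
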