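#' Empirical FDR curve by gene-set resampling
#'
#' Estimates, for each connectivity threshold T, the ratio of the mean
#' number of randomly drawn genes whose connectivity K exceeds T (strictly)
#' to the number of observed candidates exceeding T. Random sets have the
#' same size as the candidate set and are drawn, `n_resamples` times, from
#' the panels' gene universe excluding both the reference and the observed
#' candidate genes, so the resampled null is not contaminated by putative
#' signal. Where no observed candidate exceeds T the ratio is undefined and
#' reported as missing. For reporting, raw ratios are truncated at 1 and
#' the curve is monotonized by a running minimum in ascending T, so the
#' estimated eFDR never increases as the threshold is raised; the chosen
#' threshold is the smallest T whose monotonized eFDR is at or below the
#' target rate.
#'
#' @param observed A [connectivity_scores()] table for the candidate genes.
#' @inheritParams null_distribution
#' @param cutoff The |r| significance cutoff used for `observed`.
#' @param set_size Size of each resampled set; defaults to the number of
#'   observed candidates.
#' @param n_resamples Number of resampled gene sets (default 1000).
#' @param target Target empirical FDR (default 0.25).
#' @param seed Integer seed for the resampling.
#' @return A tibble of class `efdr_curve` with columns `threshold` (every
#'   point where the empirical curve can change: 0 and the observed and
#'   resampled K values), `n_observed`, `mean_random`, `efdr_raw`, `efdr`
#'   (truncated and monotonized), plus attributes `chosen_T`, `target`,
#'   `n_resamples`, `set_size`, `seed`.
#' @export
efdr_curve <- function(observed, panels, reference, cutoff,
                       set_size = nrow(observed), n_resamples = 1000,
                       target = 0.25,
                       method = c("pearson", "spearman"),
                       weights = NULL, exclude = NULL, seed = 1) {
  method <- match.arg(method)
  reference <- as_symbols(reference)
  pool <- setdiff(
    common_genes(panels),
    c(reference, observed$gene, as_symbols(exclude %||% character()))
  )
  if (set_size > length(pool)) {
    abort(sprintf(
      "set_size = %d exceeds the eligible gene universe (%d)",
      set_size, length(pool)
    ))
  }
  # K is a per-gene property of the fixed universe, so compute it once for
  # every eligible gene and resample indices rather than correlations.
  pool_mats <- map(panels, pairwise_correlation, rows = pool,
    cols = reference, method = method
  )
  pool_combined <- combine_correlations(pool_mats, weights)
  pool_k <- connectivity_scores(pool_combined, reference,
    rownames(pool_combined), cutoff
  )
  k_by_gene <- setNames(pool_k$k, pool_k$gene)
  draws <- withr::with_seed(seed, {
    replicate(n_resamples, sample(names(k_by_gene), set_size))
  })
  sampled_k <- sort(as.numeric(k_by_gene[draws]))
  obs_k <- sort(observed$k)
  # evaluate the eFDR step function at every point where it can change:
  # the observed K values (denominator steps) and the resampled K values
  # (numerator steps)
  thresholds <- sort(unique(c(0, obs_k, sampled_k)))
  n_obs <- length(obs_k) - findInterval(thresholds, obs_k)
  mean_rand <- (length(sampled_k) - findInterval(thresholds, sampled_k)) /
    n_resamples
  efdr_raw <- ifelse(n_obs > 0L, mean_rand / n_obs, NA_real_)
  efdr <- monotonize_efdr(pmin(efdr_raw, 1))
  df <- tibble(
    threshold = thresholds, n_observed = n_obs,
    mean_random = mean_rand, efdr_raw = efdr_raw, efdr = efdr
  )
  structure(
    df,
    class = c("efdr_curve", class(tibble())),
    chosen_T = choose_threshold(df, target),
    target = target, n_resamples = n_resamples,
    set_size = set_size, seed = seed
  )
}

# Running minimum in ascending threshold order, over defined values, so the
# reported curve is nonincreasing in T (raising the threshold never raises
# the estimated eFDR).
monotonize_efdr <- function(e) {
  ok <- !is.na(e)
  e[ok] <- cummin(e[ok])
  e
}

choose_threshold <- function(curve, target) {
  hit <- which(!is.na(curve$efdr) & curve$efdr <= target)
  if (!length(hit)) NA_real_ else curve$threshold[min(hit)]
}

#' @export
print.efdr_curve <- function(x, ...) {
  cat(sprintf(
    "<efdr_curve> %d thresholds, %d resamples of size %d; chosen T = %s at target %.2f\n",
    nrow(x), attr(x, "n_resamples"), attr(x, "set_size"),
    format(attr(x, "chosen_T"), digits = 3), attr(x, "target")
  ))
  NextMethod()
}

#' @export
glance.efdr_curve <- function(x, ...) {
  tibble(
    chosen_T = attr(x, "chosen_T"),
    target = attr(x, "target"),
    n_resamples = attr(x, "n_resamples"),
    set_size = attr(x, "set_size"),
    n_thresholds = nrow(x)
  )
}

#' @export
autoplot.efdr_curve <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(
    df[!is.na(df$efdr), ],
    ggplot2::aes(.data$threshold, .data$efdr)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = attr(object, "target"),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(x = "connectivity threshold T", y = "eFDR") +
    ggplot2::theme_minimal()
  if (!is.na(attr(object, "chosen_T"))) {
    p <- p + ggplot2::geom_vline(
      xintercept = attr(object, "chosen_T"), linetype = "dotted"
    )
  }
  p
}

#' Select prioritized candidates at a target eFDR
#'
#' Flags as prioritized every candidate whose continuous connectivity K
#' strictly exceeds the chosen threshold, i.e. the smallest T whose
#' monotonized eFDR is at or below the target. When no threshold attains
#' the target the prioritized set is empty and a warning is issued.
#'
#' @param table A [connectivity_scores()] table.
#' @param curve The matching [efdr_curve()] (same cutoff and panels).
#' @param target Target eFDR (default: the curve's target, 0.25).
#' @return The `connectivity_table` with `prioritized` filled in and ranks
#'   recomputed (K descending, ties by gene symbol).
#' @export
select_prioritized <- function(table, curve, target = NULL) {
  target <- target %||% attr(curve, "target")
  chosen <- choose_threshold(curve, target)
  if (is.na(chosen)) {
    warn(sprintf("no threshold attains eFDR <= %.3g; nothing prioritized",
      target
    ))
    table$prioritized <- FALSE
  } else {
    table$prioritized <- table$k > chosen
  }
  df <- rank_by_k(as_tibble(table))
  out <- new_connectivity_table(df, attr(table, "cutoff"),
    attr(table, "n_reference")
  )
  attr(out, "chosen_T") <- chosen
  attr(out, "efdr_target") <- target
  out
}

#' Write an eFDR curve as TSV
#' @param x An `efdr_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_efdr_curve <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
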