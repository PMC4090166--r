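#' Compare connectivity between annotated and unannotated candidates
#'
#' Tests whether candidates flagged by an external evidence source (e.g.
#' genic intolerance, prior neurological disease association, predicted
#' damaging variants) have higher connectivity scores than unflagged
#' candidates. Uses a one-sided two-sample Mann-Whitney rank-sum test with
#' continuity correction (normal approximation with tie correction) and, in
#' parallel, a label-permutation p-value with the add-one estimator
#' `(1 + #{permuted W >= observed W}) / (1 + n_permutations)`, which can
#' never be exactly zero. Genes with a missing flag (not assessed by the
#' resource) are excluded from the test rather than treated as unflagged.
#'
#' @param data Data frame holding one row per gene, with a numeric score
#'   column and a logical/0-1 flag column (e.g. a [connectivity_scores()]
#'   table joined with an annotation table).
#' @param score Column holding the score to compare (e.g. `k` or `k_star`),
#'   given unquoted.
#' @param flag Column holding the group label, given unquoted; `TRUE`/1 =
#'   flagged, `FALSE`/0 = unflagged, `NA` = not assessed.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return A one-row tibble: `flag`, `score_type`, `n_flagged`,
#'   `n_unflagged`, `statistic` (the Mann-Whitney W of the flagged group),
#'   `p_asymptotic`, `p_permutation`.
#' @export
group_test <- function(data, score, flag, n_permutations = 1000, seed = 1) {
  score_q <- enquo(score)
  flag_q <- enquo(flag)
  x <- dplyr::pull(data, !!score_q)
  g <- dplyr::pull(data, !!flag_q)
  keep <- !is.na(g)
  x <- x[keep]
  g <- as.logical(g[keep])
  n1 <- sum(g)
  n0 <- sum(!g)
  if (n1 == 0L || n0 == 0L) {
    abort("both flagged and unflagged groups must be nonempty")
  }
  wt <- suppressWarnings(wilcox.test(x[g], x[!g],
    alternative = "greater", correct = TRUE, exact = FALSE
  ))
  obs_w <- mw_statistic(x, g)
  perm <- withr::with_seed(seed, {
    replicate(n_permutations, mw_statistic(x, sample(g)))
  })
  tibble(
    flag = as_name(flag_q),
    score_type = as_name(score_q),
    n_flagged = n1,
    n_unflagged = n0,
    statistic = obs_w,
    p_asymptotic = unname(wt$p.value),
    p_permutation = (1 + sum(perm >= obs_w)) / (1 + n_permutations)
  )
}

# Mann-Whitney W for the flagged group: rank sum minus its minimum.
mw_statistic <- function(x, g) {
  r <- rank(x)
  sum(r[g]) - sum(g) * (sum(g) + 1) / 2
}

#' Run group tests across several flags and score types
#'
#' Convenience wrapper applying [group_test()] to every combination of the
#' given flag columns and score columns.
#'
#' @param scores A [connectivity_scores()] table.
#' @param annotation Data frame with a `gene` column and 0/1/NA flag
#'   columns.
#' @param flags Character vector of flag column names; defaults to every
#'   non-`gene` column of `annotation`.
#' @param score_types Character vector of score columns to test (default
#'   `c("k", "k_star")`).
#' @inheritParams group_test
#' @return A tibble with one row per flag-score combination.
#' @export
group_tests <- function(scores, annotation, flags = NULL,
                        score_types = c("k", "k_star"),
                        n_permutations = 1000, seed = 1) {
  flags <- flags %||% setdiff(names(annotation), "gene")
  joined <- dplyr::left_join(as_tibble(scores), as_tibble(annotation),
    by = "gene"
  )
  grid <- expand.grid(
    flag = flags, score_type = score_types,
    stringsAsFactors = FALSE
  )
  bind_rows(purrr::pmap(grid, function(flag, score_type) {
    res <- group_test(joined, !!rlang::sym(score_type), !!rlang::sym(flag),
      n_permutations = n_permutations, seed = seed
    )
    res
  }))
}
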