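new_connectivity_table <- function(df, cutoff, n_reference) {
  structure(
    df,
    class = c("connectivity_table", class(tibble())),
    cutoff = cutoff, n_reference = n_reference
  )
}

#' Connectivity of candidate genes to a reference set
#'
#' An edge between a candidate and a reference gene is significant when the
#' combined correlation exceeds the cutoff in absolute value (strictly).
#' Each candidate receives a discrete score K* (the number of significant
#' edges, at most the reference set size) and a continuous score K (the sum
#' of |r| over those edges), so that `cutoff * K_star <= K <= K_star`.
#' Candidates are ranked by K descending, ties broken by gene symbol.
#'
#' @param combined A combined `cor_matrix` containing all candidate and
#'   reference genes (square, or rectangular candidates-by-reference).
#' @param reference Reference [gene_set()] or character vector.
#' @param candidates Candidate [gene_set()] or character vector; must be
#'   disjoint from the reference set (self-edges would inflate scores).
#' @param cutoff Significance cutoff on |r|, from [significance_cutoff()].
#' @return A tibble of class `connectivity_table` with columns `gene`,
#'   `k_star`, `k`, `rank`, `prioritized` (NA until
#'   [select_prioritized()] is applied).
#' @export
connectivity_scores <- function(combined, reference, candidates, cutoff) {
  reference <- as_symbols(reference)
  candidates <- as_symbols(candidates)
  overlap <- intersect(candidates, reference)
  if (length(overlap)) {
    abort(paste0(
      "candidate gene(s) present in the reference set: ",
      paste(overlap, collapse = ", ")
    ))
  }
  missing_rows <- setdiff(candidates, rownames(combined))
  missing_cols <- setdiff(reference, colnames(combined))
  if (length(missing_rows) || length(missing_cols)) {
    abort(paste0(
      "genes absent from the correlation matrix: ",
      paste(c(missing_rows, missing_cols), collapse = ", ")
    ))
  }
  sub <- abs(unclass(combined)[candidates, reference, drop = FALSE])
  edge <- sub > cutoff
  df <- tibble(
    gene = candidates,
    k_star = as.integer(rowSums(edge)),
    k = unname(rowSums(sub * edge)),
    prioritized = NA
  ) |>
    rank_by_k()
  new_connectivity_table(df, cutoff, length(reference))
}

rank_by_k <- function(df) {
  ord <- order(-df$k, df$gene)
  df$rank <- integer(nrow(df))
  df$rank[ord] <- seq_len(nrow(df))
  df[c("gene", "k_star", "k", "rank", "prioritized")]
}

#' Leave-one-out connectivity of the reference set
#'
#' Scores each reference gene against the remaining reference genes as if
#' it were a candidate, quantifying how strongly the known genes co-express
#' as a network (cross-validation of the guilt-by-association premise).
#'
#' @param combined Square combined `cor_matrix` over the reference genes.
#' @inheritParams connectivity_scores
#' @return A `connectivity_table` with one row per reference gene.
#' @export
leave_one_out_connectivity <- function(combined, reference, cutoff) {
  reference <- as_symbols(reference)
  if (length(reference) < 3L) abort("need at least 3 reference genes")
  rows <- map(reference, function(g) {
    others <- setdiff(reference, g)
    sub <- abs(unclass(combined)[g, others])
    edge <- sub > cutoff
    tibble(
      gene = g, k_star = as.integer(sum(edge)),
      k = sum(sub[edge]), prioritized = NA
    )
  })
  df <- rank_by_k(bind_rows(rows))
  new_connectivity_table(df, cutoff, length(reference) - 1L)
}

#' @export
glance.connectivity_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_reference = attr(x, "n_reference"),
    cutoff = attr(x, "cutoff"),
    n_prioritized = if (all(is.na(x$prioritized))) NA_integer_ else
      sum(x$prioritized, na.rm = TRUE),
    max_k = max(x$k),
    mean_k_star = mean(x$k_star)
  )
}

#' @export
autoplot.connectivity_table <- function(object, ...) {
  df <- as_tibble(object)
  df$status <- dplyr::case_when(
    is.na(df$prioritized) ~ "unscored",
    df$prioritized ~ "prioritized",
    .default = "not prioritized"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$k,
    colour = .data$status
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank", y = "connectivity K", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a connectivity table as TSV
#' @param x A `connectivity_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
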