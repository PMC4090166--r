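new_cor_matrix <- function(r, method, source) {
  structure(r, method = method, source = source, class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf(
    "<cor_matrix> %d x %d, method '%s', source '%s'\n",
    nrow(x), ncol(x), attr(x, "method"), attr(x, "source")
  ))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
    drop = FALSE
  ])
  invisible(x)
}

cor_method <- function(m) attr(m, "method")
cor_source <- function(m) attr(m, "source")

is_square_cor <- function(m) {
  nrow(m) == ncol(m) && identical(rownames(m), colnames(m))
}

rank_rows <- function(m) {
  t(apply(m, 1L, rank, ties.method = "average"))
}

drop_zero_variance <- function(mat, label) {
  sds <- apply(mat, 1L, sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warn(paste0(
      "dropping zero-variance gene(s) with undefined correlations from ",
      label, ": ", paste(rownames(mat)[flat], collapse = ", ")
    ))
    mat <- mat[!flat, , drop = FALSE]
  }
  if (nrow(mat) == 0L) abort("all genes have zero variance")
  mat
}

#' Pairwise correlation matrix for a gene panel
#'
#' Computes the sample correlation of every row-gene with every column-gene
#' across the panel's samples. Spearman's coefficient is obtained as
#' Pearson's coefficient on within-gene ranks (average ranks on ties).
#' Genes whose expression vector has zero variance have no defined
#' correlation; they are dropped with a warning rather than assigned r = 0.
#'
#' @inheritParams panel_genes
#' @param rows,cols Gene sets (or character vectors) selecting the row and
#'   column genes; `rows` defaults to all genes in the panel and `cols`
#'   defaults to `rows`. When `rows` and `cols` coincide the result is
#'   symmetric with a unit diagonal.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `cor_matrix`: a numeric matrix of correlations in \[-1, 1\] with
#'   gene dimnames and attributes `method` and `source` (the individual id).
#' @export
pairwise_correlation <- function(panel, rows = NULL, cols = NULL,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rows <- if (is.null(rows)) panel_genes(panel) else as_symbols(rows)
  cols <- if (is.null(cols)) rows else as_symbols(cols)
  absent <- setdiff(union(rows, cols), panel_genes(panel))
  if (length(absent)) {
    abort(paste0("genes absent from panel: ", paste(absent, collapse = ", ")))
  }
  mat <- panel_matrix(panel)[union(rows, cols), , drop = FALSE]
  if (ncol(mat) < 3L) abort("correlation needs at least 3 samples")
  if (method == "spearman") mat <- rank_rows(mat)
  mat <- drop_zero_variance(mat, panel_id(panel))
  rows <- intersect(rows, rownames(mat))
  cols <- intersect(cols, rownames(mat))
  r <- cor(t(mat[rows, , drop = FALSE]), t(mat[cols, , drop = FALSE]))
  if (identical(rows, cols)) {
    r <- (r + t(r)) / 2
    diag(r) <- 1
  }
  new_cor_matrix(r, method = method, source = panel_id(panel))
}

#' Inverse-variance combination weights across individuals
#'
#' Each individual's weight derives from the sample variance of the
#' off-diagonal entries of that individual's correlation matrix for the same
#' gene panel: `w_i = (1/v_i) / sum_j (1/v_j)`. Individuals with greater
#' correlation variability therefore receive lower weight, and the weights
#' sum to one within a time period.
#'
#' @param per_individual List of square `cor_matrix` objects on the same
#'   gene panel, one per individual (at least two).
#' @param time_period Label for the period the individuals belong to.
#' @return A tibble of class `coexp_weights` with columns `individual_id`,
#'   `variance`, `weight`, `time_period`.
#' @export
combination_weights <- function(per_individual, time_period = "pooled") {
  if (length(per_individual) < 2L) {
    abort("combination weights need at least 2 individuals")
  }
  check_aligned(per_individual)
  v <- map_dbl(per_individual, function(m) {
    if (!is_square_cor(m)) abort("weights need square correlation matrices")
    var(m[upper.tri(m)])
  })
  if (any(!is.finite(v)) || any(v == 0)) {
    abort("degenerate panel: zero or undefined correlation variance")
  }
  w <- (1 / v) / sum(1 / v)
  structure(
    tibble(
      individual_id = map_chr(per_individual, cor_source),
      variance = unname(v),
      weight = unname(w),
      time_period = time_period
    ),
    class = c("coexp_weights", class(tibble()))
  )
}

check_aligned <- function(mats) {
  ref <- dimnames(mats[[1]])
  ok <- vapply(
    mats, function(m) identical(dimnames(m), ref), logical(1)
  )
  if (!all(ok)) abort("correlation matrices are not aligned on the same genes")
  invisible(mats)
}

#' Combine per-individual correlation matrices with weights
#'
#' The combined entry for a gene pair is the weighted sum of the
#' individuals' raw correlation coefficients (no Fisher transformation),
#' `sum_i w_i r_i(a, b)`. With weights summing to one the combination is
#' convex, so entries stay within the per-individual range and in \[-1, 1\].
#'
#' @inheritParams combination_weights
#' @param weights A [combination_weights()] tibble matching the individuals,
#'   or `NULL` for a single matrix (identity).
#' @return A `cor_matrix` with source `"combined:<time_period>"`.
#' @export
combine_correlations <- function(per_individual, weights = NULL) {
  check_aligned(per_individual)
  if (is.null(weights)) {
    if (length(per_individual) != 1L) {
      abort("weights are required to combine more than one individual")
    }
    weights <- tibble(
      individual_id = cor_source(per_individual[[1]]),
      variance = NA_real_, weight = 1, time_period = "pooled"
    )
  }
  ids <- map_chr(per_individual, cor_source)
  if (!setequal(ids, weights$individual_id) || length(ids) != nrow(weights)) {
    abort("weights do not match the supplied individuals")
  }
  w <- weights$weight[match(ids, weights$individual_id)]
  combined <- Reduce(`+`, map2(per_individual, w, function(m, wi) {
    unclass(m) * wi
  }))
  new_cor_matrix(combined,
    method = cor_method(per_individual[[1]]),
    source = paste0("combined:", weights$time_period[1])
  )
}

#' @export
tidy.cor_matrix <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(unclass(x), stringsAsFactors = FALSE))
  names(long) <- c("gene_a", "gene_b", "r")
  if (is_square_cor(x)) {
    idx <- which(upper.tri(x), arr.ind = TRUE)
    long <- tibble(
      gene_a = rownames(x)[idx[, 1]],
      gene_b = colnames(x)[idx[, 2]],
      r = x[idx]
    )
  }
  long
}

#' @export
autoplot.cor_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(unclass(object),
    stringsAsFactors = FALSE
  ))
  names(df) <- c("gene_a", "gene_b", "r")
  df$gene_a <- factor(df$gene_a, levels = rownames(object))
  df$gene_b <- factor(df$gene_b, levels = rev(colnames(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_a, .data$gene_b,
    fill = .data$r
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Write a correlation matrix as TSV
#' @param m A `cor_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cor_matrix <- function(m, path) {
  df <- tibble(gene = rownames(m)) |>
    dplyr::bind_cols(as_tibble(unclass(m), .name_repair = "minimal"))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
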