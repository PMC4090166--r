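#' Construct an expression panel
#'
#' An expression panel holds one individual's genes-by-samples matrix of
#' log-scale expression values as a tibble: a `gene` column of identifiers
#' (gene symbols, or probe ids before probe collapsing) followed by one
#' numeric column per sample. The individual id and time-period label travel
#' as attributes so panels from several individuals can be combined within a
#' time period downstream.
#'
#' @param values A numeric matrix (rows = genes, columns = samples) with
#'   rownames and colnames, or a data frame whose first column holds gene
#'   identifiers.
#' @param individual_id Identifier for the individual (brain, donor, array
#'   batch) the panel came from.
#' @param time_period Label grouping individuals whose correlation matrices
#'   may be combined, e.g. `"developing"`, `"adult"` or `"pooled"`.
#'
#' @return A tibble of class `expression_panel` with a `gene` column and one
#'   numeric column per sample.
#' @export
expression_panel <- function(values, individual_id = "individual",
                             time_period = "pooled") {
  if (is.matrix(values)) {
    if (is.null(rownames(values)) || is.null(colnames(values))) {
      abort("matrix input needs rownames (genes) and colnames (samples)")
    }
    df <- tibble(gene = rownames(values)) |>
      dplyr::bind_cols(as_tibble(values, .name_repair = "minimal"))
  } else {
    df <- as_tibble(values, .name_repair = "minimal")
    names(df)[1] <- "gene"
    df$gene <- trimws(as.character(df$gene))
  }
  validate_panel(df)
  structure(df,
    class = c("expression_panel", class(tibble())),
    individual_id = as.character(individual_id),
    time_period = as.character(time_period)
  )
}

validate_panel <- function(df) {
  if (nrow(df) == 0L) abort("panel has no gene rows")
  samples <- names(df)[-1]
  if (length(samples) < 3L) {
    abort("panel needs at least 3 sample columns to support correlation")
  }
  if (anyDuplicated(samples)) {
    abort(paste0(
      "duplicate sample ids: ",
      paste(unique(samples[duplicated(samples)]), collapse = ", ")
    ))
  }
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup)) {
    abort(paste0("duplicate gene identifiers: ", paste(dup, collapse = ", ")))
  }
  bad <- !vapply(df[-1], is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0(
      "non-numeric sample columns: ", paste(samples[bad], collapse = ", ")
    ))
  }
  if (anyNA(df[-1])) abort("panel contains missing expression values")
  invisible(df)
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf(
    "<expression_panel> individual '%s', period '%s': %d genes x %d samples\n",
    attr(x, "individual_id"), attr(x, "time_period"),
    nrow(x), ncol(x) - 1L
  ))
  NextMethod()
}

#' Gene identifiers of a panel
#' @param panel An [expression_panel()].
#' @return Character vector of gene identifiers in panel order.
#' @export
panel_genes <- function(panel) panel$gene

#' Sample identifiers of a panel
#' @inheritParams panel_genes
#' @return Character vector of sample identifiers.
#' @export
panel_samples <- function(panel) names(panel)[-1]

#' Panel values as a genes-by-samples matrix
#' @inheritParams panel_genes
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
panel_matrix <- function(panel) {
  m <- as.matrix(panel[-1])
  rownames(m) <- panel$gene
  m
}

panel_id <- function(panel) attr(panel, "individual_id")
panel_period <- function(panel) attr(panel, "time_period")

#' Construct a gene set
#'
#' A named list of gene symbols, optionally carrying the symbols that were
#' requested but absent from a particular expression panel (missingness is
#' data, not an error: genes absent from an array are excluded and counted).
#'
#' @param symbols Character vector of gene symbols; whitespace is trimmed and
#'   duplicates removed, preserving first-occurrence order.
#' @param name Label for the set (e.g. `"reference"`, `"candidates"`).
#' @param missing Symbols requested but not present in the relevant panel.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(symbols, name = "genes", missing = character()) {
  symbols <- unique(trimws(as.character(symbols)))
  symbols <- symbols[nzchar(symbols)]
  missing <- unique(trimws(as.character(missing)))
  if (length(intersect(symbols, missing))) {
    abort("a symbol cannot be both matched and missing")
  }
  structure(list(name = name, symbols = symbols, missing = missing),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf(
    "<gene_set '%s'> %d symbols (%d missing)\n",
    x$name, length(x$symbols), length(x$missing)
  ))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

as_symbols <- function(x) {
  if (inherits(x, "gene_set")) x$symbols else unique(trimws(as.character(x)))
}
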