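#' Order genes by principal-component angle
#'
#' Performs an eigendecomposition of the (symmetric) correlation matrix and
#' orders genes by the angle `atan2(PC2 loading, PC1 loading)` mapped to
#' \[0, 2*pi). Correlation matrices of co-expressed gene sets typically show
#' more than one principal component of interest, and sorting by the angle
#' between the first two exposes cluster structure as contiguous blocks when
#' the matrix is re-drawn in that order. The eigenvector sign ambiguity is
#' fixed by forcing each component's largest-magnitude loading positive
#' (first index on ties), and angle ties are broken by gene symbol, so the
#' ordering is deterministic.
#'
#' @param m A square symmetric `cor_matrix`, at least 3 genes.
#' @return A tibble of class `gene_ordering` with columns `gene`, `angle`,
#'   `pc1`, `pc2`, sorted by ascending angle.
#' @export
angular_order <- function(m) {
  if (nrow(m) < 3L) abort("angular ordering needs at least 3 genes")
  if (!is_square_cor(m) || !isSymmetric(unclass(m), tol = 1e-8)) {
    abort("angular ordering needs a symmetric correlation matrix")
  }
  eig <- eigen((unclass(m) + t(unclass(m))) / 2, symmetric = TRUE)
  fix_sign <- function(v) v * sign(v[which.max(abs(v))])
  pc1 <- fix_sign(eig$vectors[, 1])
  pc2 <- fix_sign(eig$vectors[, 2])
  # round the sort key so numerically degenerate angles (exchangeable genes,
  # repeated eigenvalues) tie-break by gene symbol, not floating-point noise
  angle <- round(atan2(pc2, pc1) %% (2 * pi), 9)
  df <- tibble(gene = rownames(m), angle = angle, pc1 = pc1, pc2 = pc2) |>
    arrange(.data$angle, .data$gene)
  structure(df, class = c("gene_ordering", class(tibble())))
}

#' Reorder a correlation matrix by an external gene ordering
#'
#' Applies an ordering derived from one dataset to another dataset's
#' correlation matrix (cross-ordering), used to test whether cluster
#' structure replicates across resources. The ordering may cover a subset
#' of the matrix's genes, in which case the corresponding submatrix is
#' returned.
#'
#' @param m A square `cor_matrix`.
#' @param ordering A [angular_order()] result, or character vector of genes.
#' @return `m` with rows and columns rearranged to the ordering.
#' @export
cross_order <- function(m, ordering) {
  genes <- if (is.data.frame(ordering)) ordering$gene else as.character(ordering)
  absent <- setdiff(genes, rownames(m))
  if (length(absent)) {
    abort(paste0(
      "ordering references genes absent from the matrix: ",
      paste(absent, collapse = ", ")
    ))
  }
  new_cor_matrix(unclass(m)[genes, genes, drop = FALSE],
    method = cor_method(m), source = cor_source(m)
  )
}

#' Thresholded co-expression network
#'
#' Retains every unordered gene pair whose correlation exceeds the cutoff
#' in absolute value (strictly), keeping the signed r so positively and
#' negatively correlated edges stay distinguishable. Nodes are annotated by
#' role (reference / candidate / other) when gene sets are supplied.
#'
#' @param m A square `cor_matrix`.
#' @param cutoff Significance cutoff on |r|, in (0, 1).
#' @param reference,candidates Optional [gene_set()]s (or character
#'   vectors) used to annotate nodes.
#' @return An object of class `coexp_network`: list with `edges` (tibble
#'   `gene_a`, `gene_b`, `r`) and `nodes` (tibble `gene`, `role`).
#' @export
build_network <- function(m, cutoff, reference = NULL, candidates = NULL) {
  if (cutoff <= 0 || cutoff >= 1) abort("cutoff must lie in (0, 1)")
  if (!is_square_cor(m)) abort("network building needs a square matrix")
  idx <- which(upper.tri(m) & abs(unclass(m)) > cutoff, arr.ind = TRUE)
  edges <- tibble(
    gene_a = rownames(m)[idx[, 1]],
    gene_b = colnames(m)[idx[, 2]],
    r = unclass(m)[idx]
  ) |>
    arrange(.data$gene_a, .data$gene_b)
  roles <- rep("other", nrow(m))
  roles[rownames(m) %in% as_symbols(candidates %||% character())] <- "candidate"
  roles[rownames(m) %in% as_symbols(reference %||% character())] <- "reference"
  nodes <- tibble(gene = rownames(m), role = roles)
  structure(list(edges = edges, nodes = nodes, cutoff = cutoff),
    class = "coexp_network"
  )
}

#' @export
print.coexp_network <- function(x, ...) {
  cat(sprintf(
    "<coexp_network> %d nodes, %d edges at |r| > %.3f\n",
    nrow(x$nodes), nrow(x$edges), x$cutoff
  ))
  invisible(x)
}

#' @export
tidy.coexp_network <- function(x, ...) x$edges

#' @export
glance.coexp_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_positive = sum(x$edges$r > 0), n_negative = sum(x$edges$r < 0),
    cutoff = x$cutoff
  )
}

#' Convert a co-expression network to an igraph object
#' @param network A [build_network()] result.
#' @return An undirected igraph graph with edge attribute `r` and vertex
#'   attribute `role`.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges,
    directed = FALSE,
    vertices = network$nodes
  )
}

#' Write a network as edge-list TSV or GraphML
#' @param network A [build_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(network$edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
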