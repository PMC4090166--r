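#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene (or
#' probe) identifiers; remaining cells must be numeric log-scale intensities.
#' Empty files, ragged rows, duplicate sample ids, duplicate gene rows and
#' non-numeric or missing cells are parse errors, reported with the offending
#' line where possible.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; guessed from the extension when `NULL`
#'   (`.csv` gives `","`, anything else tab).
#' @inheritParams expression_panel
#' @return An [expression_panel()].
#' @export
read_expression <- function(path, delim = NULL, individual_id = NULL,
                            time_period = "pooled") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0L) abort(paste0("empty expression file: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]][-1]
  header <- trimws(header)
  if (anyDuplicated(header)) {
    abort(paste0(
      "duplicate sample ids in header: ",
      paste(unique(header[duplicated(header)]), collapse = ", ")
    ))
  }
  raw <- suppressWarnings(readr::read_delim(path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    abort(sprintf(
      "parse error at line %d: expected %s", probs$row[1], probs$expected[1]
    ))
  }
  if (nrow(raw) == 0L) abort(paste0("no data rows in ", path))
  ids <- trimws(raw[[1]])
  vals <- raw[-1]
  num <- lapply(vals, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]))
    if (length(bad)) {
      what <- if (is.na(vals[[j]][bad[1]])) "missing" else
        paste0("non-numeric ('", vals[[j]][bad[1]], "')")
      abort(sprintf(
        "%s value at line %d, sample '%s'",
        what, bad[1] + 1L, names(vals)[j]
      ))
    }
  }
  df <- tibble(gene = ids) |>
    dplyr::bind_cols(as_tibble(num, .name_repair = "minimal"))
  if (is.null(individual_id)) {
    individual_id <- sub("\\.(tsv|csv|txt)$", "", basename(path),
      ignore.case = TRUE
    )
  }
  expression_panel(df, individual_id = individual_id,
    time_period = time_period
  )
}

#' Read a gene list
#'
#' Plain text, one symbol per line; `#` starts a comment, blank lines are
#' skipped, whitespace is trimmed and duplicates dropped.
#'
#' @param path Path to the list file.
#' @param name Label for the resulting set; defaults to the file stem.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set(lines, name = name)
}

#' Read a probe-to-gene map
#'
#' Two- or three-column TSV: `probe_id`, `gene_symbol` and optionally
#' `transcript_length` (base pairs). Probe ids must be unique, each mapping
#' to exactly one gene symbol.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `probe_id`, `gene_symbol` and, when present,
#'   `transcript_length`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  map <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(map)[1:2] <- c("probe_id", "gene_symbol")
  probe_map(map)
}

#' Validate a probe map
#' @param map Data frame with columns `probe_id` and `gene_symbol`.
#' @return The map as a validated tibble.
#' @export
probe_map <- function(map) {
  map <- as_tibble(map)
  if (!all(c("probe_id", "gene_symbol") %in% names(map))) {
    abort("probe map needs columns probe_id and gene_symbol")
  }
  map$probe_id <- trimws(as.character(map$probe_id))
  map$gene_symbol <- trimws(as.character(map$gene_symbol))
  dup <- unique(map$probe_id[duplicated(map$probe_id)])
  if (length(dup)) {
    abort(paste0("probe ids mapped more than once: ", paste(dup, collapse = ", ")))
  }
  map
}

#' Collapse probe-level rows to one row per gene
#'
#' For each gene the retained row is the probe with the highest median
#' expression across the panel's samples; medians are computed within the
#' panel (per individual), and ties are broken by the lexicographically
#' smallest probe id so the choice is reproducible.
#'
#' @param panel Probe-level [expression_panel()]; the `gene` column holds
#'   probe ids.
#' @param map A [probe_map()] covering every probe in the panel.
#' @return A gene-level [expression_panel()], rows ordered by gene symbol.
#' @export
collapse_probes <- function(panel, map) {
  map <- probe_map(map)
  unmapped <- setdiff(panel$gene, map$probe_id)
  if (length(unmapped)) {
    abort(paste0("probes missing from map: ", paste(unmapped, collapse = ", ")))
  }
  med <- apply(panel_matrix(panel), 1L, median)
  pick <- tibble(
    probe_id = panel$gene,
    gene_symbol = map$gene_symbol[match(panel$gene, map$probe_id)],
    med = med
  ) |>
    arrange(.data$gene_symbol, desc(.data$med), .data$probe_id) |>
    group_by(.data$gene_symbol) |>
    slice(1L) |>
    ungroup()
  out <- panel[match(pick$probe_id, panel$gene), ]
  out$gene <- pick$gene_symbol
  expression_panel(out,
    individual_id = panel_id(panel), time_period = panel_period(panel)
  )
}

#' Reconcile requested gene symbols with a panel
#'
#' Partitions the requested symbols into those present in the panel's gene
#' universe (input order preserved) and those absent. Matching is
#' case-sensitive after whitespace trimming; absence is recorded, not an
#' error, mirroring genes that are simply not represented on an array.
#'
#' @inheritParams panel_genes
#' @param requested A [gene_set()] or character vector of symbols.
#' @return A [gene_set()] whose `symbols` are the matched genes and whose
#'   `missing` are the absent ones.
#' @export
match_genes <- function(panel, requested) {
  want <- as_symbols(requested)
  name <- if (inherits(requested, "gene_set")) requested$name else "genes"
  present <- want %in% panel_genes(panel)
  gene_set(want[present], name = name, missing = want[!present])
}

#' Write a panel back to TSV
#' @inheritParams panel_genes
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(panel, path) {
  readr::write_tsv(as_tibble(panel), path, progress = FALSE)
  invisible(path)
}
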