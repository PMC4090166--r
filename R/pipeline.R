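#' Default pipeline configuration
#'
#' Returns the run configuration as a named list, with the method's
#' canonical settings: Pearson correlation, top-5% |r| cutoff
#' (`quantile = 0.95`), eFDR target 0.25, 1000 null genes, 1000 eFDR
#' resamples. A user config (YAML file or list) overrides any subset of
#' fields; the resolved configuration is written alongside the outputs so
#' every run is self-describing.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    panels = NULL,          # list of {path, individual_id} or NULL
    probe_map = NULL,       # optional path
    reference = NULL,       # path to reference gene list
    candidates = NULL,      # path to candidate gene list
    annotations = NULL,     # optional path to 0/1/NA flag table
    simulate = NULL,        # optional planted_benchmark() arguments
    output_dir = "coexpnet-run",
    method = "pearson",
    time_period = "pooled",
    quantile = 0.95,
    efdr_target = 0.25,
    n_null_genes = 1000,
    n_resamples = 1000,
    n_sampled_pairs = 1e5,
    seed = 1
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  do.call(default_config, config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the prioritization pipeline end to end
#'
#' Orchestrates every stage from expression input to prioritized gene list:
#' read (or simulate) panels, collapse probes, match gene lists, compute
#' per-individual correlations and combination weights, combine matrices,
#' build the genome-wide null ECDF comparison and the top-quantile |r|
#' cutoff, score candidate connectivity, estimate the eFDR curve and select
#' prioritized candidates, order and export the correlation matrix and the
#' thresholded network, and (when annotations are given) run group
#' comparisons. All randomness flows from the single master seed through
#' fixed per-stage offsets, so a rerun with the same configuration is
#' byte-identical. Every output is a plain TSV (plus GraphML for the
#' network) and the resolved configuration is written as YAML.
#'
#' @param config A YAML file path or named list of overrides of
#'   [default_config()].
#' @param seed Optional master seed overriding the config's.
#' @return The output directory path, invisibly; a named list of result
#'   objects is attached as attribute `"results"`.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    inform(line)
    log_lines <<- c(log_lines, line)
  }

  inputs <- stage("inputs", {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% cfg$seed
      bench <- do.call(planted_benchmark, sim_args)
      say("simulated %d panels of %d genes",
        length(bench$panels), cfg$simulate$n_genes %||% 400
      )
      readr::write_tsv(bench$truth, file.path(out, "truth.tsv"),
        progress = FALSE
      )
      bench
    } else {
      if (is.null(cfg$panels) || is.null(cfg$reference) ||
        is.null(cfg$candidates)) {
        abort("config needs panels, reference and candidates (or simulate)")
      }
      panels <- lapply(cfg$panels, function(p) {
        read_expression(p$path,
          individual_id = p$individual_id,
          time_period = cfg$time_period
        )
      })
      if (!is.null(cfg$probe_map)) {
        map <- read_probe_map(cfg$probe_map)
        panels <- lapply(panels, collapse_probes, map = map)
      }
      list(
        panels = panels,
        reference = read_gene_list(cfg$reference, name = "reference"),
        candidates = read_gene_list(cfg$candidates, name = "candidates")
      )
    }
  })
  panels <- inputs$panels

  matched <- stage("gene matching", {
    ref <- match_genes(panels[[1]], inputs$reference)
    cand <- match_genes(panels[[1]], inputs$candidates)
    say(
      "%d of %d reference genes matched; %d of %d candidates matched (%d absent)",
      length(ref), length(ref) + length(ref$missing),
      length(cand), length(cand) + length(cand$missing),
      length(cand$missing)
    )
    if (length(ref$missing)) {
      say("absent reference genes: %s", paste(ref$missing, collapse = ", "))
    }
    if (length(cand$missing)) {
      say("absent candidate genes: %s", paste(cand$missing, collapse = ", "))
    }
    list(reference = ref, candidates = cand)
  })
  reference <- matched$reference
  candidates <- matched$candidates

  corr <- stage("correlation and weights", {
    ref_mats <- map(panels, pairwise_correlation,
      rows = reference, method = cfg$method
    )
    w <- NULL
    if (length(panels) > 1L) {
      w <- combination_weights(ref_mats, time_period = cfg$time_period)
      readr::write_tsv(as_tibble(w), file.path(out, "weights.tsv"),
        progress = FALSE
      )
      say(
        "combination weights: %s",
        paste(sprintf("%s=%.3f", w$individual_id, w$weight), collapse = ", ")
      )
    }
    combined <- combine_correlations(ref_mats, w)
    write_cor_matrix(combined, file.path(out, "reference_correlations.tsv"))
    list(weights = w, combined = combined)
  })
  weights <- corr$weights
  ref_combined <- corr$combined

  ecdf_sum <- stage("null distribution", {
    n_null <- min(
      cfg$n_null_genes,
      length(setdiff(
        common_genes(panels),
        c(reference$symbols, candidates$symbols)
      ))
    )
    s <- null_distribution(panels, reference,
      n_genes = n_null, exclude = candidates,
      method = cfg$method, weights = weights,
      time_period = cfg$time_period, seed = cfg$seed + 1L
    )
    write_ecdf_summary(s, file.path(out, "ecdf_summary.tsv"))
    say(
      "null over %d genes (%d pairs): median r = %.3f, median |r| = %.3f",
      s$n_null_genes, s$n_null_pairs, s$median_r_null, s$median_abs_r_null
    )
    s
  })

  threshold <- stage("significance cutoff", {
    ts <- significance_cutoff(panels,
      weights = weights, quantile = cfg$quantile,
      n_sampled_pairs = cfg$n_sampled_pairs,
      method = cfg$method, seed = cfg$seed + 2L
    )
    readr::write_tsv(
      tibble(
        quantile = ts$quantile, cutoff = ts$cutoff,
        n_sampled_pairs = ts$n_sampled_pairs
      ),
      file.path(out, "cutoff.tsv"),
      progress = FALSE
    )
    say("|r| cutoff at quantile %.2f: %.4f", ts$quantile, ts$cutoff)
    ts
  })

  scores <- stage("connectivity", {
    cand_mats <- map(panels, pairwise_correlation,
      rows = candidates, cols = reference, method = cfg$method
    )
    cand_combined <- combine_correlations(cand_mats, weights)
    tab <- connectivity_scores(cand_combined, reference,
      rownames(cand_combined), threshold$cutoff
    )
    loo <- leave_one_out_connectivity(ref_combined, reference,
      threshold$cutoff
    )
    write_connectivity(loo, file.path(out, "reference_loo_connectivity.tsv"))
    tab
  })

  prioritized <- stage("eFDR and selection", {
    curve <- efdr_curve(scores, panels, reference,
      cutoff = threshold$cutoff, n_resamples = cfg$n_resamples,
      target = cfg$efdr_target, method = cfg$method,
      weights = weights, seed = cfg$seed + 3L
    )
    write_efdr_curve(curve, file.path(out, "efdr_curve.tsv"))
    tab <- select_prioritized(scores, curve)
    write_connectivity(tab, file.path(out, "connectivity.tsv"))
    hits <- tab$gene[tab$prioritized]
    writeLines(sort(hits), file.path(out, "prioritized_genes.txt"))
    say(
      "chosen T = %s; %d of %d candidates prioritized at eFDR <= %.2f",
      format(attr(tab, "chosen_T"), digits = 3), length(hits),
      nrow(tab), cfg$efdr_target
    )
    list(table = tab, curve = curve)
  })

  network <- stage("network export", {
    ordering <- angular_order(ref_combined)
    ordered <- cross_order(ref_combined, ordering)
    write_cor_matrix(ordered, file.path(out, "reference_ordered.tsv"))
    net <- build_network(ref_combined, threshold$cutoff,
      reference = reference, candidates = candidates
    )
    write_edge_list(net, file.path(out, "edges.tsv"))
    write_graphml(net, file.path(out, "network.graphml"))
    say("network: %d edges among %d genes", nrow(net$edges), nrow(net$nodes))
    list(ordering = ordering, network = net)
  })

  comparisons <- NULL
  if (!is.null(cfg$annotations)) {
    comparisons <- stage("group comparisons", {
      ann <- readr::read_tsv(cfg$annotations,
        col_types = readr::cols(), progress = FALSE
      )
      res <- group_tests(prioritized$table, ann, seed = cfg$seed + 4L)
      readr::write_tsv(res, file.path(out, "group_tests.tsv"),
        progress = FALSE
      )
      res
    })
  }

  yaml::write_yaml(cfg, file.path(out, "config_resolved.yaml"))
  writeLines(log_lines, log_path)
  results <- list(
    panels = panels, reference = reference, candidates = candidates,
    weights = weights, reference_correlations = ref_combined,
    ecdf = ecdf_sum, threshold = threshold,
    connectivity = prioritized$table, efdr = prioritized$curve,
    ordering = network$ordering, network = network$network,
    comparisons = comparisons
  )
  out <- structure(out, results = results)
  invisible(out)
}
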