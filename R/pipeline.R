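#' Run the full edge-FC analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain a dataset (synthetic via
#' [generate_edge_dataset()] or loaded from a long-format TSV), validate it,
#' fit and classify all edge trajectories, run the angular-distance
#' permutational MANOVA per requested edge subset, classify wake-to-NREM
#' transitions, and assemble a consolidated report. Every stochastic stage
#' receives a child seed derived from the single root seed, so identical
#' configurations produce identical reports.
#'
#' @param config A list with elements:
#'   * `simulation`: arguments for [sim_config()] (used when `dataset` is
#'     absent), or
#'   * `dataset`: path to an edge-FC TSV (with partition sidecar or
#'     `partition` path);
#'   * `partition`: optional partition JSON path;
#'   * `n_iter`, `seed`, `alpha`: permutation settings (defaults 1000, 17,
#'     0.05);
#'   * `subsets`: edge subsets for the angular analysis (default all three);
#'   * `selection`: trajectory selection rule (default `"nested"`);
#'   * `out_dir`: optional output directory for TSV/JSON stage outputs.
#' @return The report (list), invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config = list()) {
  n_iter <- config$n_iter %||% 1000
  seed <- config$seed %||% 17
  alpha <- config$alpha %||% 0.05
  subsets <- config$subsets %||% c("all", "higher_order", "dmn_fp")
  selection <- config$selection %||% "nested"
  bad <- setdiff(subsets, c("all", "higher_order", "dmn_fp"))
  if (length(bad)) {
    stop("unknown edge subset mode(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(config$dataset)) {
    partition <- if (!is.null(config$partition)) read_partition(config$partition)
    dataset <- read_edge_dataset(config$dataset, partition)
    sim <- NULL
  } else {
    sim_args <- config$simulation %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(seed, 11)
    sim <- do.call(sim_config, sim_args)
    dataset <- generate_edge_dataset(sim)
  }
  diags <- validate_edge_dataset(dataset)
  if (length(diags)) {
    stop("dataset failed validation: ", paste(diags, collapse = "; "))
  }
  part <- dataset$partition
  universe <- list(
    n_nodes = nrow(part),
    n_edges = nrow(dataset$edge_index),
    n_higher_order_edges = length(subset_edges(part, "higher_order",
                                               dataset$edge_index)),
    n_dmn_fp_edges = length(subset_edges(part, "dmn_fp", dataset$edge_index))
  )
  poly_cfg <- perm_config(n_iter, derive_seed(seed, 101), alpha)
  traj <- fit_edge_trajectories(dataset, poly_cfg, selection = selection)
  angular <- lapply(seq_along(subsets), function(k) {
    acfg <- perm_config(n_iter, derive_seed(seed, 200 + k), alpha)
    angular_analysis(dataset, subsets[k], acfg)
  })
  names(angular) <- subsets
  trans_cfg <- perm_config(n_iter, derive_seed(seed, 301), alpha)
  transitions <- if (all(c("wake", "NREM2") %in% names(dataset$stages)) ||
                     all(c("wake", "SWS") %in% names(dataset$stages))) {
    calls <- classify_all_transitions(dataset, trans_cfg)
    list(calls = calls, summary = summarize_transitions(calls, part))
  }
  report <- list(
    package_version = as.character(utils::packageVersion("sleepfc")),
    config = list(n_iter = n_iter, seed = seed, alpha = alpha,
                  subsets = subsets, selection = selection,
                  simulated = is.null(config$dataset)),
    edge_universe = universe,
    trajectory = list(
      class_counts = as.list(traj$class_counts),
      chi_square = traj$chi_square,
      n_survive_correction = traj$n_survive_correction
    ),
    angular = lapply(angular, function(a) {
      list(pseudo_F = a$global$pseudo_F, p = a$global$p,
           pairwise = a$pairwise)
    }),
    transitions = if (!is.null(transitions)) {
      s <- transitions$summary
      list(counts = as.data.frame(s$counts),
           corrected_counts = as.data.frame(s$corrected_counts),
           binomial_all = s$binomial$all)
    }
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$out_dir, ...)
    if (is.null(config$dataset)) {
      write_edge_dataset(dataset, out("dataset.tsv"), sim)
    }
    utils::write.table(traj$edges, out("polyfit.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (s in names(angular)) {
      utils::write.table(angular[[s]]$pairwise,
                         out(paste0("angular_", s, "_pairwise.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(transitions)) {
      utils::write.table(transitions$calls, out("transitions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", force = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# In-memory dataset diagnostics shared by validate_dataset and run_pipeline.
validate_edge_dataset <- function(dataset) {
  diags <- character(0)
  n_nodes <- nrow(dataset$partition)
  expected <- choose(n_nodes, 2)
  n_edges <- nrow(dataset$edge_index)
  if (n_edges != expected) {
    diags <- c(diags, sprintf(
      "edge count %d does not match C(%d, 2) = %d", n_edges, n_nodes, expected))
  }
  for (s in names(dataset$stages)) {
    m <- dataset$stages[[s]]
    if (!all(is.finite(m))) {
      diags <- c(diags, sprintf("non-finite FC values in stage %s", s))
    }
    if (ncol(m) != n_edges) {
      diags <- c(diags, sprintf(
        "stage %s has %d edge columns, expected %d", s, ncol(m), n_edges))
    }
  }
  bad_stage <- setdiff(names(dataset$stages), sleep_stages())
  if (length(bad_stage)) {
    diags <- c(diags, paste("unknown stage label(s):",
                            paste(bad_stage, collapse = ", ")))
  }
  diags
}

#' Validate an edge-FC dataset file
#'
#' Checks the TSV/JSON contracts: readable file, complete partition sidecar,
#' edge-count consistency with the partition, finite FC values, and known
#' stage labels.
#'
#' @param path Path to an edge-FC TSV written by [write_edge_dataset()].
#' @param partition Optional [node_partition()] (else read from the sidecar).
#' @return Character vector of diagnostics; empty when the file is valid.
#' @export
validate_dataset <- function(path, partition = NULL) {
  if (!file.exists(path)) stop("cannot read dataset file: ", path)
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  diags <- character(0)
  need <- c("stage", "subject_id", "edge_id", "fc_z")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(partition)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      return(paste("no partition sidecar found at", sidecar))
    }
    obj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nodes <- obj$partition$nodes
    part_diag <- tryCatch({
      partition <- node_partition(nodes$name, nodes$class, nodes$dmn_fp)
      character(0)
    }, error = function(e) paste("partition coverage violation:",
                                 conditionMessage(e)))
    if (length(part_diag)) return(part_diag)
  }
  idx <- edge_index(partition)
  n_found <- length(unique(rows$edge_id))
  if (n_found != nrow(idx)) {
    diags <- c(diags, sprintf(
      "edge count violation: found %d distinct edges, partition implies %d",
      n_found, nrow(idx)))
  }
  unknown <- setdiff(unique(rows$edge_id), idx$edge_id)
  if (length(unknown)) {
    diags <- c(diags, paste("unknown edge id(s):",
                            paste(utils::head(unknown, 3), collapse = ", ")))
  }
  if (!all(is.finite(rows$fc_z))) {
    diags <- c(diags, "non-finite FC values")
  }
  bad_stage <- setdiff(unique(rows$stage), sleep_stages())
  if (length(bad_stage)) {
    diags <- c(diags, paste("unknown stage label(s):",
                            paste(bad_stage, collapse = ", ")))
  }
  diags
}
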