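#' Edge trajectory archetype
#'
#' An archetype specifies the population stage means (Fisher-z units) of one
#' FC edge at the four stage codes 1--4, the trajectory shape they realise,
#' and the between-subject noise standard deviation.
#'
#' Shape invariants are checked at construction: `flat` archetypes have four
#' equal means; `quadratic_convex` / `quadratic_concave` archetypes must have
#' a positive / negative leading coefficient when a quadratic is fit to the
#' four means, and second differences of a consistent sign; `linear`
#' archetypes need a non-zero slope; `cubic` archetypes a non-zero third
#' difference.
#'
#' @param shape One of `"flat"`, `"linear"`, `"quadratic_convex"`,
#'   `"quadratic_concave"`, `"cubic"`.
#' @param stage_means Numeric length-4 vector of stage means at codes 1--4.
#' @param noise_sd Positive noise standard deviation (Fisher-z units).
#' @return An `edge_archetype` list.
#' @export
edge_archetype <- function(shape = c("flat", "linear", "quadratic_convex",
                                     "quadratic_concave", "cubic"),
                           stage_means, noise_sd = 0.2) {
  shape <- match.arg(shape)
  stage_means <- as.numeric(stage_means)
  if (length(stage_means) != 4 || anyNA(stage_means)) {
    stop("'stage_means' must be 4 finite values (stage codes 1-4)")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd <= 0) {
    stop("'noise_sd' must be a single positive number")
  }
  d2 <- diff(diff(stage_means))
  if (shape == "flat" && any(stage_means != stage_means[1])) {
    stop("flat archetype requires equal stage means")
  }
  if (shape == "linear" && isTRUE(all.equal(stats::sd(stage_means), 0))) {
    stop("linear archetype requires a non-zero slope")
  }
  if (shape %in% c("quadratic_convex", "quadratic_concave")) {
    lead <- stats::lm.fit(outer(1:4, 0:2, `^`), stage_means)$coefficients[3]
    want <- if (shape == "quadratic_convex") 1 else -1
    if (sign(lead) != want || any(sign(d2) == -want)) {
      stop("stage means inconsistent with ", shape, " curvature")
    }
  }
  if (shape == "cubic" && abs(diff(d2)) < 1e-12) {
    stop("cubic archetype requires a non-zero third difference")
  }
  structure(list(shape = shape, stage_means = stage_means, noise_sd = noise_sd),
            class = "edge_archetype")
}

#' Build an archetype from polynomial coefficients
#'
#' Evaluates a polynomial at the stage codes 1--4 so that the stage means lie
#' exactly on the generating curve; the archetype shape then matches the
#' polynomial's order and curvature by construction.
#'
#' @param shape Archetype shape; must be consistent with `coef`.
#' @param coef Numeric coefficients in increasing order (intercept first).
#' @param noise_sd Positive noise standard deviation.
#' @return An [edge_archetype()].
#' @export
archetype_from_poly <- function(shape, coef, noise_sd = 0.2) {
  x <- 1:4
  means <- drop(outer(x, seq_along(coef) - 1, `^`) %*% coef)
  edge_archetype(shape = shape, stage_means = means, noise_sd = noise_sd)
}

#' Default archetype assignment mirroring the reported result profile
#'
#' For demonstration runs the 91 edges of a 14-node set are assigned
#' 49 flat, 5 linear, 18 convex-quadratic, 18 concave-quadratic and 1 cubic
#' archetype. Quadratic means lie exactly on symmetric parabolas (vertex at
#' stage code 2.5) with amplitudes and offsets cycling deterministically, so
#' that a subset dips across zero (the "opposite-direction" pattern) while
#' others merely shrink. All archetypes use the same noise level.
#'
#' @param n_edges Number of edges to cover (default 91).
#' @param noise_sd Common noise standard deviation (default 0.2 Fisher-z).
#' @return A list of [edge_archetype()]s of length `n_edges`.
#' @export
default_archetypes <- function(n_edges = 91, noise_sd = 0.2) {
  counts <- round(n_edges * c(flat = 49, linear = 5, convex = 18,
                              concave = 18, cubic = 1) / 91)
  counts["flat"] <- n_edges - sum(counts[-1])
  flat_levels <- c(0.4, 0.2, 0, -0.2)
  amps <- c(0.25, 0.35, 0.45)
  offsets <- c(-0.35, -0.15, 0.05)
  arch <- list()
  for (i in seq_len(counts["flat"])) {
    m <- flat_levels[(i - 1) %% length(flat_levels) + 1]
    arch[[length(arch) + 1]] <- edge_archetype("flat", rep(m, 4), noise_sd)
  }
  for (i in seq_len(counts["linear"])) {
    slope <- 0.15 * if (i %% 2) 1 else -1
    arch[[length(arch) + 1]] <- archetype_from_poly(
      "linear", c(-2.5 * slope + 0.05, slope), noise_sd)
  }
  for (i in seq_len(counts["convex"])) {
    a <- amps[(i - 1) %% 3 + 1]
    c0 <- offsets[(i - 1) %/% 3 %% 3 + 1]
    # f(x) = a (x - 2.5)^2 + c0 : wake/REM high, NREM dip
    arch[[length(arch) + 1]] <- archetype_from_poly(
      "quadratic_convex", c(a * 6.25 + c0, -5 * a, a), noise_sd)
  }
  for (i in seq_len(counts["concave"])) {
    a <- amps[(i - 1) %% 3 + 1]
    c0 <- -offsets[(i - 1) %/% 3 %% 3 + 1]
    arch[[length(arch) + 1]] <- archetype_from_poly(
      "quadratic_concave", c(-a * 6.25 + c0, 5 * a, -a), noise_sd)
  }
  for (i in seq_len(counts["cubic"])) {
    arch[[length(arch) + 1]] <- edge_archetype(
      "cubic", c(0.2, 0.5, -0.1, 0.2), noise_sd)
  }
  arch[seq_len(n_edges)]
}

#' Simulation configuration
#'
#' Bundles everything the synthetic generator needs: the node set size, the
#' per-stage subject counts (defaults follow the unbalanced design wake 33,
#' NREM2 24, SWS 9, REM 6), the per-edge archetype assignment, the root seed,
#' and optional time-series parameters.
#'
#' @param n_nodes Number of network nodes (default 14, giving 91 edges).
#' @param group_sizes Named integer vector of subjects per stage; all >= 2.
#' @param archetypes List of [edge_archetype()], one per edge in edge-index
#'   order; `NULL` uses [default_archetypes()].
#' @param seed Root RNG seed; per-edge child streams are derived from it.
#' @param timeseries_length Volumes per pseudo time series (default 150).
#' @param ar1 AR(1) coefficient in (-1, 1) for generated node time series.
#' @param latent_loading Loading of an optional shared per-subject latent
#'   factor added to every edge (induces cross-edge dependence; default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_nodes = 14,
                       group_sizes = c(wake = 33, NREM2 = 24, SWS = 9, REM = 6),
                       archetypes = NULL,
                       seed = 1,
                       timeseries_length = 150,
                       ar1 = 0,
                       latent_loading = 0) {
  if (n_nodes < 2) stop("'n_nodes' must be at least 2")
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% sleep_stages())) {
    stop("'group_sizes' must be named with stages among: ",
         paste(sleep_stages(), collapse = ", "))
  }
  if (any(group_sizes < 2)) {
    stop("all group sizes must be >= 2 (per-stage variance must be estimable)")
  }
  n_edges <- choose(n_nodes, 2)
  if (is.null(archetypes)) archetypes <- default_archetypes(n_edges)
  if (abs(ar1) >= 1) stop("'ar1' must lie strictly inside (-1, 1)")
  if (timeseries_length < 1) stop("'timeseries_length' must be positive")
  structure(list(
    n_nodes = as.integer(n_nodes),
    group_sizes = group_sizes[intersect(sleep_stages(), names(group_sizes))],
    archetypes = archetypes,
    seed = as.integer(seed),
    timeseries_length = as.integer(timeseries_length),
    ar1 = ar1,
    latent_loading = latent_loading
  ), class = "sim_config")
}

#' Generate a synthetic edge-FC dataset
#'
#' For each edge and stage, draws `group_sizes[stage]` subject values as the
#' archetype stage mean plus independent Gaussian noise. Each edge uses its
#' own child RNG stream derived from the root seed, so edge-level values are
#' reproducible independent of edge order. An optional shared per-subject
#' latent factor (see [sim_config()]) adds cross-edge dependence.
#'
#' @param config A [sim_config()].
#' @param partition Optional [node_partition()] with `config$n_nodes` nodes;
#'   the default 14-node partition is used when `n_nodes` is 14.
#' @return An `edge_fc_dataset`: list with `partition`, `edge_index`, and
#'   `stages` (per stage, a subjects x edges matrix of Fisher-z values).
#' @export
generate_edge_dataset <- function(config, partition = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(partition)) {
    if (config$n_nodes == 14) {
      partition <- default_partition()
    } else {
      partition <- node_partition(sprintf("N%02d", seq_len(config$n_nodes)),
                                  rep("other", config$n_nodes),
                                  rep(FALSE, config$n_nodes))
    }
  }
  if (nrow(partition) != config$n_nodes) {
    stop("partition has ", nrow(partition), " nodes but config expects ",
         config$n_nodes)
  }
  idx <- edge_index(partition)
  n_edges <- nrow(idx)
  if (length(config$archetypes) < n_edges) {
    missing_edge <- idx$edge_id[length(config$archetypes) + 1]
    stop("no archetype assigned for edge ", missing_edge)
  }
  stages <- names(config$group_sizes)
  mats <- lapply(stages, function(s) {
    m <- matrix(NA_real_, nrow = config$group_sizes[[s]], ncol = n_edges,
                dimnames = list(sprintf("%s_s%02d", s,
                                        seq_len(config$group_sizes[[s]])),
                                idx$edge_id))
    m
  })
  names(mats) <- stages
  for (j in seq_len(n_edges)) {
    a <- config$archetypes[[j]]
    if (!inherits(a, "edge_archetype")) {
      stop("no archetype assigned for edge ", idx$edge_id[j])
    }
    set.seed(derive_seed(config$seed, j))
    for (s in stages) {
      n_s <- config$group_sizes[[s]]
      mu <- a$stage_means[stage_code_of(s)]
      mats[[s]][, j] <- mu + stats::rnorm(n_s, 0, a$noise_sd)
    }
  }
  if (config$latent_loading != 0) {
    set.seed(derive_seed(config$seed, 0))
    for (s in stages) {
      u <- stats::rnorm(config$group_sizes[[s]])
      mats[[s]] <- mats[[s]] + config$latent_loading * u
    }
  }
  structure(list(partition = partition, edge_index = idx, stages = mats),
            class = "edge_fc_dataset")
}

#' @export
print.edge_fc_dataset <- function(x, ...) {
  cat("edge_fc_dataset:", nrow(x$edge_index), "edges over",
      nrow(x$partition), "nodes\n")
  for (s in names(x$stages)) {
    cat("  ", s, ": ", nrow(x$stages[[s]]), " subjects\n", sep = "")
  }
  invisible(x)
}

#' Generate AR(1) node time series with a target cross-correlation
#'
#' Produces, per subject, a time x node matrix of stationary AR(1) series
#' driven by equicorrelated Gaussian innovations. Because every series shares
#' the AR coefficient, the stationary cross-correlation between any two nodes
#' equals the innovation correlation, i.e. `target_correlation` in
#' expectation.
#'
#' @param config A [sim_config()] with `timeseries_length >= 2` and `ar1` in
#'   (-1, 1).
#' @param target_correlation Desired pairwise cross-correlation in (-1, 1);
#'   must exceed `-1/(n_nodes - 1)` for the innovation covariance to be valid.
#' @param n_subjects Number of independent subject series sets.
#' @param n_nodes Number of node series per subject (default `config$n_nodes`).
#' @return List of `n_subjects` time x node matrices.
#' @export
generate_node_timeseries <- function(config, target_correlation,
                                     n_subjects = 1,
                                     n_nodes = config$n_nodes) {
  stopifnot(inherits(config, "sim_config"))
  T_len <- config$timeseries_length
  phi <- config$ar1
  if (T_len < 2) stop("time series length must be >= 2 (correlation undefined)")
  if (abs(phi) >= 1) stop("AR(1) coefficient must lie inside (-1, 1): non-stationary")
  rho <- target_correlation
  if (abs(rho) >= 1) stop("'target_correlation' must lie inside (-1, 1)")
  if (n_nodes > 1 && rho <= -1 / (n_nodes - 1)) {
    stop("'target_correlation' below the equicorrelation bound -1/(n_nodes-1)")
  }
  Sigma <- matrix(rho, n_nodes, n_nodes)
  diag(Sigma) <- 1
  L <- chol(Sigma)
  set.seed(derive_seed(config$seed, 7001))
  lapply(seq_len(n_subjects), function(s) {
    e <- matrix(stats::rnorm(T_len * n_nodes), T_len, n_nodes) %*% L
    x <- apply(e, 2, function(col) {
      init <- col[1] / sqrt(1 - phi^2)
      as.numeric(stats::filter(c(init, col[-1]), phi, method = "recursive"))
    })
    colnames(x) <- sprintf("N%02d", seq_len(n_nodes))
    x
  })
}

#' Write / read an edge-FC dataset as long-format TSV
#'
#' The TSV has columns `stage`, `subject_id`, `edge_id`, `node_a`, `node_b`,
#' `fc_z`; a JSON sidecar (`<path>.json`) stores the node partition (and the
#' generating configuration when supplied).
#'
#' @param dataset An `edge_fc_dataset`.
#' @param path TSV file path.
#' @param config Optional [sim_config()] echoed into the sidecar.
#' @return `read_edge_dataset` returns an `edge_fc_dataset`;
#'   `write_edge_dataset` returns `path` invisibly.
#' @export
write_edge_dataset <- function(dataset, path, config = NULL) {
  stopifnot(inherits(dataset, "edge_fc_dataset"))
  idx <- dataset$edge_index
  rows <- do.call(rbind, lapply(names(dataset$stages), function(s) {
    m <- dataset$stages[[s]]
    data.frame(
      stage = s,
      subject_id = rep(rownames(m), times = ncol(m)),
      edge_id = rep(colnames(m), each = nrow(m)),
      fc_z = as.vector(m),
      stringsAsFactors = FALSE
    )
  }))
  rows$node_a <- idx$node_a[match(rows$edge_id, idx$edge_id)]
  rows$node_b <- idx$node_b[match(rows$edge_id, idx$edge_id)]
  rows <- rows[, c("stage", "subject_id", "edge_id", "node_a", "node_b", "fc_z")]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(partition = list(nodes = data.frame(
    name = dataset$partition$node,
    class = dataset$partition$class,
    dmn_fp = dataset$partition$dmn_fp)))
  if (!is.null(config)) {
    sidecar$config <- list(
      n_nodes = config$n_nodes,
      group_sizes = as.list(config$group_sizes),
      seed = config$seed,
      timeseries_length = config$timeseries_length,
      ar1 = config$ar1,
      latent_loading = config$latent_loading,
      archetype_shapes = vapply(config$archetypes, `[[`, "", "shape")
    )
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_edge_dataset
#' @param partition Optional [node_partition()] overriding the sidecar.
#' @export
read_edge_dataset <- function(path, partition = NULL) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("stage", "subject_id", "edge_id", "fc_z")
  if (!all(need %in% names(rows))) {
    stop("dataset TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(partition)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("no partition supplied and no sidecar found at ", sidecar)
    }
    obj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nodes <- obj$partition$nodes
    partition <- node_partition(nodes$name, nodes$class, nodes$dmn_fp)
  }
  idx <- edge_index(partition)
  extra <- setdiff(unique(rows$edge_id), idx$edge_id)
  if (length(extra)) {
    stop("dataset contains edge ids not derivable from the partition: ",
         paste(utils::head(extra, 3), collapse = ", "))
  }
  stages <- intersect(sleep_stages(), unique(rows$stage))
  mats <- lapply(stages, function(s) {
    sub <- rows[rows$stage == s, ]
    subjects <- unique(sub$subject_id)
    m <- matrix(NA_real_, length(subjects), nrow(idx),
                dimnames = list(subjects, idx$edge_id))
    m[cbind(match(sub$subject_id, subjects), match(sub$edge_id, idx$edge_id))] <-
      sub$fc_z
    m
  })
  names(mats) <- stages
  ds <- structure(list(partition = partition, edge_index = idx, stages = mats),
                  class = "edge_fc_dataset")
  ds
}
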