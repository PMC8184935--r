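#' Regress confound time courses out of node pseudo time series
#'
#' Each node series is replaced by its residual after ordinary least-squares
#' projection onto the confound columns plus an intercept. Used to remove
#' noise-component time courses before edge FC is computed.
#'
#' @param ts Time x node numeric matrix (pseudo time series).
#' @param confounds Time x k numeric matrix of confound series (k >= 1) with
#'   the same number of time points as `ts`.
#' @return Residual time x node matrix with the same dimnames as `ts`.
#' @export
regress_out_confounds <- function(ts, confounds) {
  ts <- as.matrix(ts)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts)) {
    stop("'confounds' must have the same number of time points as 'ts'")
  }
  if (ncol(confounds) < 1) stop("need at least one confound column")
  if (is.null(colnames(confounds))) {
    colnames(confounds) <- sprintf("confound%d", seq_len(ncol(confounds)))
  }
  X <- cbind(`(intercept)` = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("confound matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qx, ts)
  dimnames(res) <- dimnames(ts)
  res
}

# Bartlett effective degrees of freedom for the correlation of two
# autocorrelated series: T / (1 + 2 * sum_k rho_a(k) rho_b(k)), lags
# 1..floor(T/5), floored at 8.
bartlett_df <- function(a, b, T_len, acfs = NULL) {
  K <- floor(T_len / 5)
  if (K < 1) return(max(T_len, 8))
  denom <- 1 + 2 * sum(acfs$a * acfs$b)
  if (!is.finite(denom) || denom <= 0) denom <- 1
  max(T_len / denom, 8)
}

#' Edge functional connectivity from node time series
#'
#' Computes the full (pairwise Pearson) correlation between every unordered
#' node pair and converts it with the Fisher r-to-z transform. With
#' `df_correction = "bartlett"`, an effective sample size
#' `T / (1 + 2 * sum_k rho_a(k) rho_b(k))` (sample autocorrelations at lags
#' 1..floor(T/5), floored at 8) replaces the nominal length when
#' standardising, so that `z_std = atanh(r) * sqrt(df_eff - 3)` has unit
#' variance under the null even for autocorrelated series.
#'
#' @param ts Time x node numeric matrix with at least 8 time points; node
#'   names taken from `colnames`.
#' @param df_correction `"bartlett"` (default) or `"none"` (`df_eff` = T).
#' @return Data frame with one row per edge: `edge_id`, `node_a`, `node_b`,
#'   `r`, `z` (unstandardised `atanh(r)`), `df_eff`, and `z_std`.
#' @export
compute_edge_fc <- function(ts, df_correction = c("bartlett", "none")) {
  df_correction <- match.arg(df_correction)
  ts <- as.matrix(ts)
  T_len <- nrow(ts)
  if (T_len < 8) stop("need at least 8 time points for edge FC")
  if (is.null(colnames(ts))) colnames(ts) <- sprintf("N%02d", seq_len(ncol(ts)))
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant node series (undefined correlation): ",
         paste(colnames(ts)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(ts)
  idx <- edge_index(colnames(ts))
  ia <- match(idx$node_a, colnames(ts))
  ib <- match(idx$node_b, colnames(ts))
  r <- R[cbind(ia, ib)]
  if (any(abs(r) >= 1 - 1e-12)) {
    bad <- idx$edge_id[abs(r) >= 1 - 1e-12][1]
    stop("|r| = 1 for edge ", bad,
         " gives infinite Fisher z; the input is degenerate ",
         "(e.g. duplicated or perfectly dependent node series)")
  }
  if (df_correction == "bartlett") {
    K <- floor(T_len / 5)
    ac <- apply(ts, 2, function(x) {
      drop(stats::acf(x, lag.max = K, plot = FALSE, demean = TRUE)$acf)[-1]
    })
    ac <- matrix(ac, nrow = K)
    df_eff <- vapply(seq_len(nrow(idx)), function(e) {
      bartlett_df(NULL, NULL, T_len,
                  acfs = list(a = ac[, ia[e]], b = ac[, ib[e]]))
    }, numeric(1))
  } else {
    df_eff <- rep(T_len, nrow(idx))
  }
  z <- atanh(r)
  data.frame(idx, r = r, z = z, df_eff = df_eff,
             z_std = z * sqrt(pmax(df_eff - 3, 1)),
             stringsAsFactors = FALSE)
}

#' Truncate two epochs to a common length
#'
#' When two stages are compared directly, the stage with more volumes is
#' truncated to the length of the shorter stage; the initial volumes of each
#' epoch are kept.
#'
#' @param ts_a,ts_b Time x node matrices (or vectors).
#' @return List with elements `a` and `b`, both of length `min(T_a, T_b)`.
#' @export
truncate_epochs <- function(ts_a, ts_b) {
  ts_a <- as.matrix(ts_a)
  ts_b <- as.matrix(ts_b)
  if (nrow(ts_a) == 0 || nrow(ts_b) == 0) stop("epochs must be non-empty")
  T_min <- min(nrow(ts_a), nrow(ts_b))
  list(a = ts_a[seq_len(T_min), , drop = FALSE],
       b = ts_b[seq_len(T_min), , drop = FALSE])
}

#' Assemble an edge-FC dataset from per-subject node time series
#'
#' Convenience glue from the time-series level to the edge level: applies
#' [compute_edge_fc()] to every subject of every stage and stacks the chosen
#' FC value into the per-stage subject x edge matrices used by the trajectory,
#' angular and transition analyses.
#'
#' @param ts_by_stage Named list (stage -> list of time x node matrices, one
#'   per subject). Node columns must match the partition's nodes.
#' @param partition A [node_partition()].
#' @param df_correction Passed to [compute_edge_fc()].
#' @param value Which column to use as the edge FC value: `"z"`
#'   (unstandardised Fisher z, default) or `"z_std"`.
#' @return An `edge_fc_dataset`.
#' @export
edge_dataset_from_timeseries <- function(ts_by_stage, partition,
                                         df_correction = "bartlett",
                                         value = c("z", "z_std")) {
  value <- match.arg(value)
  idx <- edge_index(partition)
  stages <- intersect(sleep_stages(), names(ts_by_stage))
  if (!length(stages)) stop("'ts_by_stage' must be named by stage")
  mats <- lapply(stages, function(s) {
    subj <- ts_by_stage[[s]]
    m <- t(vapply(subj, function(ts) {
      ts <- ts[, partition$node, drop = FALSE]
      compute_edge_fc(ts, df_correction)[[value]]
    }, numeric(nrow(idx))))
    rownames(m) <- sprintf("%s_s%02d", s, seq_along(subj))
    colnames(m) <- idx$edge_id
    m
  })
  names(mats) <- stages
  structure(list(partition = partition, edge_index = idx, stages = mats),
            class = "edge_fc_dataset")
}
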