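# Welch two-sample t; returns 0 when both groups are constant with equal
# means, and a signed Inf sentinel when the pooled variance is zero but the
# means differ.
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  se2 <- stats::var(x) / nx + stats::var(y) / ny
  if (se2 == 0) {
    if (mx == my) return(0)
    return(sign(mx - my) * Inf)
  }
  (mx - my) / sqrt(se2)
}

one_sample_t <- function(v) {
  n <- length(v)
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) {
    if (m == 0) return(0)
    return(sign(m) * Inf)
  }
  m / (s / sqrt(n))
}

# Shared engine: computes a statistic on (groupA, groupB) under relabelings
# of the pooled values that preserve the group sizes. stat_fun takes the two
# permuted groups. Two-sided p on |statistic|.
two_group_perm <- function(x, y, cfg, stat_fun) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  obs <- stat_fun(x, y)
  n_relab <- relabeling_count(c(nx, n - nx))
  exact <- is.finite(n_relab) && n_relab <= cfg$exact_limit
  if (exact) {
    sel <- utils::combn(n, nx)
    stats <- vapply(seq_len(ncol(sel)), function(j) {
      stat_fun(pooled[sel[, j]], pooled[-sel[, j]])
    }, numeric(1))
  } else {
    set.seed(cfg$seed)
    stats <- vapply(seq_len(cfg$n_iter), function(i) {
      o <- sample.int(n)
      stat_fun(pooled[o[seq_len(nx)]], pooled[o[-seq_len(nx)]])
    }, numeric(1))
  }
  p <- perm_pvalue(abs(stats), abs(obs), exact)
  list(t = obs, p = p, exact = exact,
       n_relabelings = if (exact) n_relab else cfg$n_iter)
}

#' Two-sample permutation t-test between wake and NREM FC values
#'
#' Welch-style t-statistic with a two-sided p-value from relabelings of the
#' pooled values into the two stage groups (add-one convention for
#' Monte-Carlo sampling, exact enumeration when feasible).
#'
#' @param wake_values,nrem_values Numeric vectors, at least 2 values each.
#' @param cfg A [perm_config()].
#' @return List with `t`, `p`, `exact`, `n_relabelings`.
#' @export
two_sample_perm_test <- function(wake_values, nrem_values,
                                 cfg = perm_config()) {
  if (length(wake_values) < 2 || length(nrem_values) < 2) {
    stop("need at least 2 values per group")
  }
  two_group_perm(wake_values, nrem_values, cfg, welch_t)
}

#' One-sample permutation test against zero with between-stage relabeling
#'
#' Computes the one-sample t-statistic of the selected stage's FC values
#' against 0. The null distribution is built by relabeling the pooled values
#' of both stages into the two stage groups and recomputing the selected
#' group's one-sample t, with a two-sided add-one p (exact enumeration when
#' feasible). A sign-flip null (`null = "sign_flip"`) is available as an
#' alternative.
#'
#' @param values_a,values_b The two stages' FC values (e.g. wake and NREM2).
#' @param which `"a"` or `"b"`: which stage's t is tested.
#' @param cfg A [perm_config()].
#' @param null `"relabel"` (default) or `"sign_flip"`.
#' @return List with `t`, `p`, `exact`, `n_relabelings`.
#' @export
one_sample_perm_sign <- function(values_a, values_b, which = c("a", "b"),
                                 cfg = perm_config(),
                                 null = c("relabel", "sign_flip")) {
  which <- match.arg(which)
  null <- match.arg(null)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("need at least 2 values per group")
  }
  target <- if (which == "a") values_a else values_b
  if (null == "sign_flip") {
    obs <- one_sample_t(target)
    set.seed(cfg$seed)
    stats <- vapply(seq_len(cfg$n_iter), function(i) {
      one_sample_t(target * sample(c(-1, 1), length(target), replace = TRUE))
    }, numeric(1))
    return(list(t = obs, p = perm_pvalue(abs(stats), abs(obs), FALSE),
                exact = FALSE, n_relabelings = cfg$n_iter))
  }
  stat_fun <- if (which == "a") {
    function(a, b) one_sample_t(a)
  } else {
    function(a, b) one_sample_t(b)
  }
  two_group_perm(values_a, values_b, cfg, stat_fun)
}

#' Classify one edge's wake-to-NREM transition
#'
#' Categories, checked in order: *reversal* when the wake and NREM one-sample
#' tests are both significant with opposite signs; otherwise, when the
#' two-sample test is significant, *increase* when the NREM mean is larger in
#' magnitude with the same sign as wake, and *reduction* when it is smaller
#' in magnitude (sign-crossed but non-reversal cases also count as
#' reductions: movement toward and past zero without significant opposite
#' FC is a magnitude reduction of wake FC); otherwise *none*.
#'
#' @param dataset An `edge_fc_dataset` containing wake and the NREM stage.
#' @param edge_id Edge identifier.
#' @param nrem_stage `"NREM2"` or `"SWS"`.
#' @param cfg A [perm_config()]; the three tests use derived child seeds.
#' @param alpha Significance level for the category rules (defaults to
#'   `cfg$alpha`).
#' @return One-row data frame: edge_id, nrem_stage, category, wake_mean,
#'   nrem_mean, the three t-statistics and permutation p-values.
#' @export
classify_transition <- function(dataset, edge_id, nrem_stage = c("NREM2", "SWS"),
                                cfg = perm_config(), alpha = cfg$alpha) {
  nrem_stage <- match.arg(nrem_stage)
  for (s in c("wake", nrem_stage)) {
    if (!s %in% names(dataset$stages)) stop("dataset lacks stage: ", s)
  }
  if (!edge_id %in% dataset$edge_index$edge_id) stop("unknown edge: ", edge_id)
  w <- dataset$stages[["wake"]][, edge_id]
  v <- dataset$stages[[nrem_stage]][, edge_id]
  base <- derive_seed(cfg$seed, match(edge_id, dataset$edge_index$edge_id) * 8 +
                        (nrem_stage == "SWS") * 4)
  c1 <- cfg; c1$seed <- derive_seed(base, 1)
  c2 <- cfg; c2$seed <- derive_seed(base, 2)
  c3 <- cfg; c3$seed <- derive_seed(base, 3)
  ts <- two_sample_perm_test(w, v, c1)
  ow <- one_sample_perm_sign(w, v, "a", c2)
  ov <- one_sample_perm_sign(w, v, "b", c3)
  category <- transition_category(ts, ow, ov, mean(w), mean(v), alpha)
  data.frame(edge_id = edge_id, nrem_stage = nrem_stage, category = category,
             wake_mean = mean(w), nrem_mean = mean(v),
             two_sample_t = ts$t, two_sample_p = ts$p,
             wake_onesample_t = ow$t, wake_onesample_p = ow$p,
             nrem_onesample_t = ov$t, nrem_onesample_p = ov$p,
             stringsAsFactors = FALSE)
}

# Category rules shared by uncorrected and Holm-corrected classification.
transition_category <- function(ts, ow, ov, wake_mean, nrem_mean, alpha,
                                sig_ts = ts$p < alpha,
                                sig_ow = ow$p < alpha,
                                sig_ov = ov$p < alpha) {
  if (sig_ow && sig_ov && sign(ow$t) * sign(ov$t) == -1) return("reversal")
  if (sig_ts) {
    if (sign(wake_mean) == sign(nrem_mean) &&
        abs(nrem_mean) > abs(wake_mean)) return("increase")
    return("reduction")
  }
  "none"
}

#' Classify every (edge, NREM stage) transition of a dataset
#'
#' Runs [classify_transition()] for every edge against both NREM stages
#' present, then applies Holm-Bonferroni correction within each test family
#' (the two-sample family, and one one-sample family per stage) and reports
#' whether each call survives (same non-`none` category under corrected
#' significance).
#'
#' @param dataset An `edge_fc_dataset` with wake and at least one NREM stage.
#' @param cfg A [perm_config()].
#' @return Data frame of transition calls with `corrected_category` and
#'   `survives_correction` columns.
#' @export
classify_all_transitions <- function(dataset, cfg = perm_config()) {
  nrem <- intersect(c("NREM2", "SWS"), names(dataset$stages))
  if (!"wake" %in% names(dataset$stages) || !length(nrem)) {
    stop("dataset must contain wake and at least one NREM stage")
  }
  calls <- do.call(rbind, lapply(nrem, function(s) {
    do.call(rbind, lapply(dataset$edge_index$edge_id, function(e) {
      classify_transition(dataset, e, s, cfg)
    }))
  }))
  # Holm within families: two-sample (all calls); one-sample wake and
  # one-sample NREM separately per NREM stage.
  sig_ts <- holm_bonferroni(calls$two_sample_p, cfg$alpha)
  sig_ow <- rep(FALSE, nrow(calls))
  sig_ov <- rep(FALSE, nrow(calls))
  for (s in nrem) {
    k <- calls$nrem_stage == s
    sig_ow[k] <- holm_bonferroni(calls$wake_onesample_p[k], cfg$alpha)
    sig_ov[k] <- holm_bonferroni(calls$nrem_onesample_p[k], cfg$alpha)
  }
  calls$corrected_category <- vapply(seq_len(nrow(calls)), function(i) {
    transition_category(
      list(t = calls$two_sample_t[i]), list(t = calls$wake_onesample_t[i]),
      list(t = calls$nrem_onesample_t[i]),
      calls$wake_mean[i], calls$nrem_mean[i], cfg$alpha,
      sig_ts = sig_ts[i], sig_ow = sig_ow[i], sig_ov = sig_ov[i])
  }, character(1))
  calls$survives_correction <- calls$category != "none" &
    calls$corrected_category == calls$category
  calls
}

#' Binomial test of increases/reversals against reductions
#'
#' Exact one-sided binomial test of whether the proportion of significant
#' wake-to-NREM changes that are increases or reversals exceeds one half.
#'
#' @param n_increase,n_reversal,n_reduction Category counts.
#' @return List with `proportion`, `p` (upper-tail exact binomial at
#'   success probability 0.5), `k`, `n`.
#' @export
binomial_increase_reversal_test <- function(n_increase, n_reversal,
                                            n_reduction) {
  k <- n_increase + n_reversal
  n <- k + n_reduction
  if (n < 1) stop("total count must be at least 1")
  p <- stats::binom.test(k, n, p = 0.5, alternative = "greater")$p.value
  list(proportion = k / n, p = p, k = k, n = n)
}

#' Summarise transition calls by edge node type
#'
#' Counts calls per category for all edges and for the node-type splits
#' higher-order--higher-order, higher-order--sensory and sensory--sensory
#' (non-higher-order nodes are grouped with sensory so the three split rows
#' sum to the all-edges row), plus the overlapping DMN/F-P row. The counting
#' unit is the (edge, NREM stage) pair. A binomial increases+reversals vs
#' reductions test is attached per row, and corrected (Holm-surviving)
#' counts are reported separately.
#'
#' @param calls Data frame from [classify_all_transitions()].
#' @param partition The dataset's [node_partition()].
#' @return List with `counts` (rows: all, ho_ho, ho_sensory,
#'   sensory_sensory, dmn_fp), `binomial` (per-row test results), and
#'   `corrected_counts`.
#' @export
summarize_transitions <- function(calls, partition) {
  idx <- edge_index(partition)
  if (!all(calls$edge_id %in% idx$edge_id)) {
    stop("transition calls reference edges absent from the partition")
  }
  ho <- partition$node[partition$class == "higher_order"]
  dmn <- partition$node[partition$dmn_fp]
  a <- idx$node_a[match(calls$edge_id, idx$edge_id)]
  b <- idx$node_b[match(calls$edge_id, idx$edge_id)]
  n_ho <- (a %in% ho) + (b %in% ho)
  groups <- list(
    all = rep(TRUE, nrow(calls)),
    ho_ho = n_ho == 2,
    ho_sensory = n_ho == 1,
    sensory_sensory = n_ho == 0,
    dmn_fp = (a %in% dmn) | (b %in% dmn)
  )
  cats <- c("reduction", "increase", "reversal", "none")
  counts <- t(vapply(groups, function(g) {
    vapply(cats, function(k) sum(calls$category[g] == k), numeric(1))
  }, numeric(length(cats))))
  corrected <- t(vapply(groups, function(g) {
    vapply(cats, function(k) {
      sum(calls$category[g] == k & calls$survives_correction[g])
    }, numeric(1))
  }, numeric(length(cats))))
  binom <- lapply(rownames(counts), function(r) {
    if (sum(counts[r, c("increase", "reversal", "reduction")]) < 1) {
      return(list(proportion = NA_real_, p = NA_real_, k = 0, n = 0))
    }
    binomial_increase_reversal_test(counts[r, "increase"],
                                    counts[r, "reversal"],
                                    counts[r, "reduction"])
  })
  names(binom) <- rownames(counts)
  list(counts = counts, binomial = binom, corrected_counts = corrected)
}
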