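#' Angular distance between two vectors
#'
#' arccos of the cosine similarity, divided by pi: 0 for parallel vectors,
#' 0.5 for orthogonal, 1 for antiparallel. Scale-invariant for positive
#' scalings. The cosine is clamped to [-1, 1] against rounding.
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return Angular distance in [0, 1].
#' @export
angular_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal dimension")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("angular distance undefined for a zero vector")
  cosine <- sum(a * b) / (na * nb)
  acos(min(max(cosine, -1), 1)) / pi
}

# Pairwise angular distances between the rows of V.
angular_distance_matrix <- function(V) {
  norms <- sqrt(rowSums(V^2))
  if (any(norms == 0)) stop("angular distance undefined for a zero vector")
  Vn <- V / norms
  C <- tcrossprod(Vn)
  # clamp against rounding; cosines within 1e-12 of +/-1 are numerically
  # parallel (identical vectors must give exactly zero distance)
  C[C > 1 - 1e-12] <- 1
  C[C < -1 + 1e-12] <- -1
  D <- acos(C) / pi
  diag(D) <- 0
  D
}

#' Assemble per-subject stage vectors for an edge subset
#'
#' Each subject in each stage contributes one vector of edge FC values, with
#' one dimension per edge of the chosen subset (all 91 edges, the 70 touching
#' a higher-order node, or the 46 touching a DMN/F-P node for the default
#' 14-node set).
#'
#' @param dataset An `edge_fc_dataset`.
#' @param subset `"all"`, `"higher_order"` or `"dmn_fp"`.
#' @return A `stage_vector_set`: list with `vectors` (N x d matrix),
#'   `labels` (factor of stage names), `subset_name`, `edge_ids`.
#' @export
stage_vectors <- function(dataset, subset = c("all", "higher_order", "dmn_fp")) {
  subset <- match.arg(subset)
  ids <- subset_edges(dataset$partition, subset, dataset$edge_index)
  stages <- names(dataset$stages)
  V <- do.call(rbind, lapply(stages, function(s) {
    dataset$stages[[s]][, ids, drop = FALSE]
  }))
  labels <- factor(rep(stages, vapply(dataset$stages, nrow, numeric(1))),
                   levels = stages)
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    stop("need at least 2 stages with at least 2 subjects each")
  }
  structure(list(vectors = V, labels = labels, subset_name = subset,
                 edge_ids = ids), class = "stage_vector_set")
}

#' Mean stage vector
#'
#' Coordinate-wise mean of a stage's subject vectors (edge FC values averaged
#' across participants).
#'
#' @param set A [stage_vectors()] set.
#' @param stage Stage name present in the set.
#' @return Numeric vector of dimension equal to the subset edge count.
#' @export
mean_stage_vector <- function(set, stage) {
  if (!stage %in% levels(set$labels)) stop("stage not present: ", stage)
  colMeans(set$vectors[set$labels == stage, , drop = FALSE])
}

# Distance-based sum-of-squares decomposition on squared angular distances:
# SS_T = sum_{i<j} d^2 / N; SS_W = sum_g sum_{i<j in g} d^2 / n_g;
# SS_A = SS_T - SS_W; pseudo-F = (SS_A/(a-1)) / (SS_W/(N-a)).
ss_decompose <- function(D2, labels) {
  N <- length(labels)
  a <- nlevels(droplevels(labels))
  ss_t <- sum(D2) / (2 * N)
  ss_w <- 0
  for (g in levels(droplevels(labels))) {
    idx <- which(labels == g)
    ss_w <- ss_w + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_a <- ss_t - ss_w
  f <- if (ss_w <= 0) {
    if (ss_a <= 1e-15) 0 else Inf
  } else {
    (ss_a / (a - 1)) / (ss_w / (N - a))
  }
  list(ss_t = ss_t, ss_w = ss_w, ss_a = ss_a, pseudo_F = f,
       df_between = a - 1, df_within = N - a)
}

# Pseudo-F values over relabelings of a fixed squared-distance matrix.
permute_pseudo_F <- function(D2, labels, cfg) {
  N <- length(labels)
  sizes <- as.vector(table(labels))
  a <- length(sizes)
  n_relab <- relabeling_count(sizes)
  exact <- is.finite(n_relab) && n_relab <= cfg$exact_limit
  # canonical block-layout indicator: slot 1..n1 -> group 1, etc.; an
  # ordering 'ord' assigns item ord[i] to the group of slot i
  block <- factor(rep(levels(labels), sizes), levels = levels(labels))
  Gs <- stats::model.matrix(~ block - 1)
  inv_sizes <- 1 / sizes
  ss_t <- sum(D2) / (2 * N)
  f_for_order <- function(ord) {
    Gp <- Gs
    Gp[ord, ] <- Gs
    W <- crossprod(Gp, D2 %*% Gp)
    ss_w <- sum(diag(W) * inv_sizes) / 2
    ss_a <- ss_t - ss_w
    if (ss_w <= 0) {
      if (ss_a <= 1e-15) 0 else Inf
    } else {
      (ss_a / (a - 1)) / (ss_w / (N - a))
    }
  }
  if (exact) {
    ords <- enumerate_relabelings(sizes)
    stats <- apply(ords, 1, f_for_order)
  } else {
    set.seed(cfg$seed)
    stats <- vapply(seq_len(cfg$n_iter),
                    function(i) f_for_order(sample.int(N)), numeric(1))
  }
  list(stats = stats, exact = exact,
       n_relabelings = if (exact) n_relab else cfg$n_iter)
}

#' Permutational MANOVA on angular distances
#'
#' Tests whether the per-subject edge-FC vectors differ between stages using
#' the distance-based pseudo-F on squared angular distances:
#' F = (SS_A / (a - 1)) / (SS_W / (N - a)), with SS_T partitioned into
#' between- and within-stage components from all pairwise squared angular
#' distances. Significance comes from relabeling subjects to stages
#' (preserving group sizes), exactly when feasible.
#'
#' @param set A [stage_vectors()] set (or any list with `vectors`, `labels`).
#' @param cfg A [perm_config()].
#' @return List with `pseudo_F`, `p`, `ss_t`, `ss_w`, `ss_a`, `mean_vectors`
#'   (stage x edge matrix), `degenerate` (`TRUE` when SS_W = 0 with
#'   SS_A > 0), `exact`, `n_relabelings`.
#' @export
permanova_angular <- function(set, cfg = perm_config()) {
  V <- set$vectors
  labels <- droplevels(set$labels)
  D2 <- angular_distance_matrix(V)^2
  obs <- ss_decompose(D2, labels)
  perm <- permute_pseudo_F(D2, labels, cfg)
  p <- perm_pvalue(perm$stats, obs$pseudo_F, perm$exact)
  means <- t(vapply(levels(labels), function(s) {
    colMeans(V[labels == s, , drop = FALSE])
  }, numeric(ncol(V))))
  list(pseudo_F = obs$pseudo_F, p = p, ss_t = obs$ss_t, ss_w = obs$ss_w,
       ss_a = obs$ss_a, df_between = obs$df_between,
       df_within = obs$df_within, mean_vectors = means,
       degenerate = obs$ss_w <= 0 && obs$ss_a > 1e-15,
       exact = perm$exact, n_relabelings = perm$n_relabelings)
}

#' Post-hoc pairwise stage comparison
#'
#' The pairwise t-statistic is the square root of the two-group pseudo-F
#' computed on the pair's vectors alone; its p-value comes from relabeling
#' within the pair.
#'
#' @param set A [stage_vectors()] set.
#' @param stage_a,stage_b Stage names present in the set.
#' @param cfg A [perm_config()].
#' @return List with `t`, `pseudo_F`, `p`, `mean_distance` (angular distance
#'   between the two stage mean vectors), `degrees` (its degree equivalent,
#'   distance x 180), `exact`.
#' @export
posthoc_pairwise <- function(set, stage_a, stage_b, cfg = perm_config()) {
  for (s in c(stage_a, stage_b)) {
    if (!s %in% levels(set$labels)) stop("stage not present: ", s)
  }
  keep <- set$labels %in% c(stage_a, stage_b)
  sub <- list(vectors = set$vectors[keep, , drop = FALSE],
              labels = droplevels(set$labels[keep]))
  res <- permanova_angular(sub, cfg)
  md <- angular_distance(mean_stage_vector(set, stage_a),
                         mean_stage_vector(set, stage_b))
  list(t = sqrt(res$pseudo_F), pseudo_F = res$pseudo_F, p = res$p,
       mean_distance = md, degrees = md * 180, exact = res$exact)
}

#' Full angular-distance analysis of one edge subset
#'
#' Runs the global permutational MANOVA and all pairwise post-hoc tests with
#' Bonferroni correction over the stage pairs, reporting the mean-vector
#' angular distances and their degree equivalents.
#'
#' @param dataset An `edge_fc_dataset`.
#' @param subset `"all"`, `"higher_order"` or `"dmn_fp"`.
#' @param cfg A [perm_config()]; pairwise tests get derived child seeds.
#' @return List with `subset`, `global` (see [permanova_angular()]) and
#'   `pairwise` (data frame: stages, distance, degrees, t, p, p_bonferroni,
#'   significant).
#' @export
angular_analysis <- function(dataset, subset = "all", cfg = perm_config()) {
  set <- stage_vectors(dataset, subset)
  global <- permanova_angular(set, cfg)
  stages <- levels(set$labels)
  pairs <- utils::combn(stages, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(k) {
    pcfg <- cfg
    pcfg$seed <- derive_seed(cfg$seed, 500 + k)
    ph <- posthoc_pairwise(set, pairs[1, k], pairs[2, k], pcfg)
    data.frame(stage_a = pairs[1, k], stage_b = pairs[2, k],
               distance = ph$mean_distance, degrees = ph$degrees,
               t = ph$t, p = ph$p, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_bonferroni <- pmin(1, pw$p * n_pairs)
  pw$significant <- pw$p_bonferroni <= cfg$alpha
  list(subset = subset, global = global, pairwise = pw)
}
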