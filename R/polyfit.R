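#' Stage-code the FC values of one edge
#'
#' Pools every subject's FC value for the edge across stages and pairs it
#' with the stage's numeric code (wake 1, NREM2 2, SWS 3, REM 4), keeping
#' (stage, subject) provenance.
#'
#' @param dataset An `edge_fc_dataset`.
#' @param edge_id Edge identifier present in `dataset$edge_index`.
#' @return Data frame with columns `x` (stage code), `y` (Fisher-z FC),
#'   `stage`, `subject_id`, ordered by stage code.
#' @export
stage_code <- function(dataset, edge_id) {
  stopifnot(inherits(dataset, "edge_fc_dataset"))
  if (!edge_id %in% dataset$edge_index$edge_id) {
    stop("unknown edge: ", edge_id)
  }
  rows <- do.call(rbind, lapply(names(dataset$stages), function(s) {
    m <- dataset$stages[[s]]
    data.frame(x = stage_code_of(s), y = m[, edge_id], stage = s,
               subject_id = rownames(m), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  rows <- rows[order(rows$x), , drop = FALSE]
  rownames(rows) <- NULL
  if (length(unique(rows$x)) < 2) {
    stop("stage coding needs data from at least 2 stages")
  }
  rows
}

#' Ordinary least-squares polynomial fit to stage-coded points
#'
#' Fits y on powers of the stage code up to `order` and returns the raw
#' coefficients and the coefficient of determination
#' R^2 = 1 - SS_res / SS_tot. When all y are equal (SS_tot = 0) the fit is
#' flagged degenerate and R^2 is defined as 0.
#'
#' @param points Data frame with columns `x` and `y` (see [stage_code()]).
#' @param order Polynomial order 1, 2 or 3; must be below the number of
#'   distinct x values.
#' @return List with `coefficients` (increasing powers, intercept first),
#'   `r_squared`, and `degenerate`.
#' @export
fit_polynomial <- function(points, order) {
  stopifnot(order %in% 1:3)
  x <- points$x
  y <- points$y
  if (order >= length(unique(x))) {
    stop("polynomial order must be below the number of distinct stage codes")
  }
  X <- outer(x, 0:order, `^`)
  colnames(X) <- paste0("b", 0:order)
  fit <- stats::lm.fit(X, y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    return(list(coefficients = c(mean(y), rep(0, order)), r_squared = 0,
                degenerate = TRUE))
  }
  ssr <- sum(fit$residuals^2)
  list(coefficients = unname(fit$coefficients),
       r_squared = 1 - ssr / sst, degenerate = FALSE)
}

# Core permutation engine shared by permutation_p_r2 and
# fit_edge_trajectories. For orders 1..max_order it returns the observed R^2,
# the overall permutation p (proportion of relabelings whose R^2 at that
# order reaches the observed R^2), and for orders >= 2 a permutation p for
# the incremental F of the order's extra term over the next-lower order.
# Relabelings preserve the per-stage group sizes; exact enumeration is used
# when the number of distinct relabelings fits within cfg$exact_limit.
r2_permutation_engine <- function(x, y, cfg, max_order = 3) {
  n <- length(y)
  orders <- seq_len(max_order)
  X <- outer(x, 0:max_order, `^`)
  qx <- qr(X)
  if (qx$rank < max_order + 1) {
    stop("polynomial order must be below the number of distinct stage codes")
  }
  Q <- qr.Q(qx)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    return(list(r2 = rep(0, max_order), p = rep(1, max_order),
                p_incr = c(NA, rep(1, max_order - 1))[orders],
                exact = TRUE, n_relabelings = 1, degenerate = TRUE))
  }
  stat_from_y <- function(Y) {
    # Y: n x m matrix of (permuted) responses; returns list of m-vectors
    Z <- crossprod(Q, Y)                      # (max_order+1) x m
    reg <- apply(Z[-1, , drop = FALSE]^2, 2, cumsum)  # cumulative SS per order
    reg <- matrix(reg, nrow = max_order)
    r2 <- reg / sst
    fincr <- matrix(NA_real_, max_order, ncol(Y))
    for (o in orders[-1]) {
      df_res <- n - o - 1
      fincr[o, ] <- (reg[o, ] - reg[o - 1, ]) / ((sst - reg[o, ]) / df_res)
    }
    list(r2 = r2, fincr = fincr)
  }
  obs <- stat_from_y(matrix(y, ncol = 1))
  sizes <- as.vector(table(x))
  n_relab <- relabeling_count(sizes)
  exact <- is.finite(n_relab) && n_relab <= cfg$exact_limit
  if (exact) {
    ord <- enumerate_relabelings(sizes)
    # each row assigns y-values to the stage blocks of the sorted x layout
    Y <- apply(ord, 1, function(o) y[o])
  } else {
    set.seed(cfg$seed)
    Y <- vapply(seq_len(cfg$n_iter), function(i) y[sample.int(n)], numeric(n))
  }
  perm <- stat_from_y(Y)
  p <- vapply(orders, function(o) {
    perm_pvalue(perm$r2[o, ], obs$r2[o, 1], exact)
  }, numeric(1))
  p_incr <- rep(NA_real_, max_order)
  for (o in orders[-1]) {
    p_incr[o] <- perm_pvalue(perm$fincr[o, ], obs$fincr[o, 1], exact)
  }
  list(r2 = obs$r2[, 1], p = p, p_incr = p_incr, exact = exact,
       n_relabelings = if (exact) n_relab else cfg$n_iter, degenerate = FALSE)
}

#' Permutation p-value for a polynomial fit's R-squared
#'
#' The null distribution is built by randomly reassigning the edge's FC
#' values to stages while preserving the per-stage group sizes, refitting the
#' polynomial, and recording R^2. The Monte-Carlo p uses the add-one
#' convention (1 + exceedances) / (1 + n_iter); when the number of distinct
#' relabelings is at most `cfg$exact_limit` the full enumeration is used
#' instead and the p-value is exact.
#'
#' @param points Stage-coded points (see [stage_code()]).
#' @param order Polynomial order 1, 2 or 3.
#' @param cfg A [perm_config()].
#' @return List with `p`, `r_squared`, `exact`, `n_relabelings`.
#' @export
permutation_p_r2 <- function(points, order, cfg = perm_config()) {
  stopifnot(order %in% 1:3)
  eng <- r2_permutation_engine(points$x, points$y, cfg, max_order = order)
  list(p = eng$p[order], r_squared = eng$r2[order], exact = eng$exact,
       n_relabelings = eng$n_relabelings)
}

#' Select the best-fitting trajectory class for an edge
#'
#' Applies the three selection rules to the per-order results: (1) if only
#' one order is significant it names the class; (2) if several are, the best
#' is chosen among them; (3) if none is, the edge is flat. How rule (2)
#' resolves the nested-model degeneracy (R^2 never decreases with order)
#' depends on `method`:
#'
#' * `"nested"` (default): an order is *supported* when its overall R^2
#'   permutation p is below alpha and, for orders 2 and 3, the permutation p
#'   of its incremental F over the next-lower order is also below alpha; the
#'   highest supported order wins. This discriminates between orders, which
#'   the raw-R^2 rule cannot (see the methods vignette).
#' * `"max_r2"`: among significant orders, highest raw R^2 (ties go to the
#'   lower order).
#' * `"adjusted_r2"`: among significant orders, highest adjusted R^2.
#'
#' @param order_results List from [r2_permutation_engine] via
#'   [fit_edge_trajectories()], or any list with elements `r2`, `p`,
#'   `p_incr` (length 3) and `n` (number of points).
#' @param cfg A [perm_config()] (supplies alpha).
#' @param method Selection rule variant, see above.
#' @return Character: `"flat"`, `"linear"`, `"quadratic"` or `"cubic"`.
#' @export
select_best_fit <- function(order_results, cfg = perm_config(),
                            method = c("nested", "max_r2", "adjusted_r2")) {
  method <- match.arg(method)
  alpha <- cfg$alpha
  r2 <- order_results$r2
  p <- order_results$p
  classes <- c("linear", "quadratic", "cubic")
  sig <- p < alpha
  if (method == "nested") {
    supported <- sig & c(TRUE, order_results$p_incr[2:3] < alpha)
    if (!any(supported)) return("flat")
    return(classes[max(which(supported))])
  }
  if (!any(sig)) return("flat")
  if (sum(sig) == 1) return(classes[which(sig)])
  score <- if (method == "max_r2") r2 else {
    n <- order_results$n
    1 - (1 - r2) * (n - 1) / (n - (1:3) - 1)
  }
  score[!sig] <- -Inf
  # ties broken toward the lower order (parsimony)
  best <- which(score >= max(score) - 1e-12)[1]
  classes[best]
}

#' Holm-Bonferroni step-down significance flags
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")` returning, for each
#' p-value, whether it survives family-wise correction at level `alpha`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param alpha Family-wise error level.
#' @return Logical vector of the same length (empty input gives empty output).
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(logical(0))
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Classify a quadratic edge's shape and NREM direction
#'
#' A quadratic trajectory is convex when its leading coefficient is positive
#' and concave otherwise. The edge is flagged *opposite-direction* when,
#' relative to the fitted wake value f(1), the curve moves toward reversed
#' polarity within the NREM range (the vertex location clamped to stage
#' codes [2, 3]) and has returned toward the wake value by REM:
#' sign(f(x*) - f(1)) = -sign(f(1)) and |f(4) - f(1)| < |f(x*) - f(1)|.
#' Movement toward zero counts (magnitude reduction), not only an actual
#' sign flip.
#'
#' @param coefficients Length-3 numeric vector (intercept, linear, quadratic)
#'   of the order-2 fit.
#' @param selected_class The edge's selected class; must be `"quadratic"`.
#' @return List with `shape` (`"convex"` / `"concave"`) and
#'   `opposite_direction` (logical).
#' @export
classify_quadratic <- function(coefficients, selected_class = "quadratic") {
  if (!identical(selected_class, "quadratic")) {
    stop("classify_quadratic is defined only for quadratic edges")
  }
  if (length(coefficients) != 3) {
    stop("'coefficients' must be the 3 coefficients of an order-2 fit")
  }
  c0 <- coefficients[1]; c1 <- coefficients[2]; c2 <- coefficients[3]
  if (c2 == 0) stop("leading coefficient is zero; not a quadratic")
  f <- function(x) c0 + c1 * x + c2 * x^2
  vertex <- -c1 / (2 * c2)
  x_star <- min(max(vertex, 2), 3)
  f1 <- f(1)
  opposite <- sign(f1) != 0 &&
    sign(f(x_star) - f1) == -sign(f1) &&
    abs(f(4) - f1) < abs(f(x_star) - f1)
  list(shape = if (c2 > 0) "convex" else "concave",
       opposite_direction = opposite)
}

#' Chi-square goodness of fit for the trajectory-class distribution
#'
#' One-variable chi-square of the observed counts of linear, quadratic and
#' cubic best fits against equal expected counts (2 degrees of freedom).
#'
#' @param counts Numeric length-3 vector of class counts, in the order
#'   linear, quadratic, cubic (names, if present, are honoured).
#' @return List with `statistic`, `df`, `p_value`, `expected`, and
#'   `low_expected` (`TRUE` when any expected count is below 1).
#' @export
chi_square_fit_distribution <- function(counts) {
  if (!is.null(names(counts))) {
    want <- c("linear", "quadratic", "cubic")
    if (all(want %in% names(counts))) counts <- counts[want]
  }
  counts <- as.numeric(counts)
  if (length(counts) != 3 || sum(counts) < 1) {
    stop("'counts' must be 3 class counts with a positive total")
  }
  ct <- suppressWarnings(stats::chisq.test(counts))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = unname(ct$expected),
       low_expected = any(ct$expected < 1))
}

#' Fit and classify trajectories for every edge of a dataset
#'
#' Runs the stage-coded polynomial analysis over all edges: per-order R^2 and
#' permutation p (orders 1-3), class selection, quadratic shape and
#' opposite-direction flags, Holm-Bonferroni family-wise correction, and the
#' chi-square test on the resulting class distribution.
#'
#' @param dataset An `edge_fc_dataset`.
#' @param cfg A [perm_config()]; each edge gets a child seed derived from
#'   `cfg$seed` and the edge's position, so results do not depend on edge
#'   order.
#' @param selection Passed to [select_best_fit()].
#' @param holm_family `"all"` (default; the per-edge selected-fit p-values of
#'   every edge enter the Holm family, with flat edges contributing their
#'   smallest per-order p) or `"significant"` (non-flat edges only).
#' @return List with `edges` (one row per edge), `class_counts`,
#'   `chi_square`, and `n_survive_correction`.
#' @export
fit_edge_trajectories <- function(dataset, cfg = perm_config(),
                                  selection = c("nested", "max_r2",
                                                "adjusted_r2"),
                                  holm_family = c("all", "significant")) {
  selection <- match.arg(selection)
  holm_family <- match.arg(holm_family)
  ids <- dataset$edge_index$edge_id
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    pts <- stage_code(dataset, ids[j])
    ecfg <- cfg
    ecfg$seed <- derive_seed(cfg$seed, j)
    eng <- r2_permutation_engine(pts$x, pts$y, ecfg, max_order = 3)
    eng$n <- nrow(pts)
    cls <- select_best_fit(eng, cfg, method = selection)
    shape <- "n/a"; opposite <- NA
    if (cls == "quadratic") {
      q <- classify_quadratic(fit_polynomial(pts, 2)$coefficients)
      shape <- q$shape
      opposite <- q$opposite_direction
    }
    p_sel <- if (cls == "flat") min(eng$p) else eng$p[match(cls, c("linear", "quadratic", "cubic"))]
    rows[[j]] <- data.frame(
      edge_id = ids[j],
      r2_1 = eng$r2[1], r2_2 = eng$r2[2], r2_3 = eng$r2[3],
      p_1 = eng$p[1], p_2 = eng$p[2], p_3 = eng$p[3],
      p_incr_2 = eng$p_incr[2], p_incr_3 = eng$p_incr[3],
      selected_class = cls, quadratic_shape = shape,
      opposite_direction = opposite, p_selected = p_sel,
      stringsAsFactors = FALSE
    )
  }
  edges <- do.call(rbind, rows)
  in_family <- if (holm_family == "all") rep(TRUE, nrow(edges)) else
    edges$selected_class != "flat"
  surv <- rep(FALSE, nrow(edges))
  surv[in_family] <- holm_bonferroni(edges$p_selected[in_family], cfg$alpha)
  edges$survives_correction <- surv & edges$selected_class != "flat"
  counts <- vapply(c("linear", "quadratic", "cubic"),
                   function(k) sum(edges$selected_class == k), numeric(1))
  chi <- if (sum(counts) >= 1) chi_square_fit_distribution(counts) else NULL
  list(edges = edges, class_counts = counts, chi_square = chi,
       n_survive_correction = sum(edges$survives_correction))
}
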