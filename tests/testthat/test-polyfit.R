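test_that("stage coding pools subjects with the 1-4 codes", {
  ds <- generate_edge_dataset(sim_config(seed = 12))
  pts <- stage_code(ds, ds$edge_index$edge_id[1])
  expect_equal(nrow(pts), 33 + 24 + 9 + 6)
  expect_equal(as.vector(table(pts$x)), c(33, 24, 9, 6))
  expect_error(stage_code(ds, "nope--nope"), "unknown edge")
  # single-stage data cannot be stage-coded
  ds1 <- ds
  ds1$stages <- ds1$stages["wake"]
  expect_error(stage_code(ds1, ds$edge_index$edge_id[1]), "at least 2 stages")
  # the point set does not depend on the stage storage order
  ds2 <- ds
  ds2$stages <- ds2$stages[c("REM", "SWS", "wake", "NREM2")]
  pts2 <- stage_code(ds2, ds$edge_index$edge_id[1])
  expect_equal(pts2[order(pts2$x, pts2$subject_id), c("x", "y")],
               pts[order(pts$x, pts$subject_id), c("x", "y")],
               ignore_attr = TRUE)
})

test_that("polynomial fits recover exact curves and match normal equations", {
  pts <- data.frame(x = rep(1:4, each = 2), y = rep(1:4, each = 2))
  f1 <- fit_polynomial(pts, 1)
  expect_equal(f1$r_squared, 1)
  expect_equal(f1$coefficients, c(0, 1), tolerance = 1e-12)
  pts2 <- data.frame(x = rep(1:4, each = 2), y = (rep(1:4, each = 2) - 2.5)^2)
  f2 <- fit_polynomial(pts2, 2)
  expect_equal(f2$r_squared, 1)
  expect_gt(f2$coefficients[3], 0)
  # 8 hand-listed points, order 1: frozen normal-equations solution
  pts8 <- data.frame(x = c(1, 1, 2, 2, 3, 3, 4, 4),
                     y = c(0.2, 0.4, 0.1, 0.3, -0.2, 0.0, 0.5, 0.6))
  f8 <- fit_polynomial(pts8, 1)
  expect_equal(f8$coefficients, c(0.125, 0.045), tolerance = 1e-10)
  expect_equal(f8$r_squared, 0.0406015038, tolerance = 1e-9)
  # all-equal y: R^2 defined as 0 with the degenerate flag
  fd <- fit_polynomial(data.frame(x = rep(1:2, each = 4), y = rep(1, 8)), 1)
  expect_true(fd$degenerate)
  expect_equal(fd$r_squared, 0)
  expect_error(fit_polynomial(data.frame(x = rep(1:2, 4), y = rnorm(8)), 2),
               "below the number of distinct")
})

test_that("R-squared is monotone in polynomial order", {
  set.seed(31)
  for (i in 1:20) {
    x <- rep(1:4, sample(2:8, 4, replace = TRUE))
    y <- rnorm(length(x))
    r2 <- vapply(1:3, function(o) fit_polynomial(data.frame(x, y), o)$r_squared,
                 numeric(1))
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("permutation p respects the add-one floor and degenerate cases", {
  # strong exact signal: observed R^2 = 1 beats (almost surely) all draws
  pts <- data.frame(x = rep(1:4, each = 6), y = rep(1:4, each = 6))
  r <- permutation_p_r2(pts, 1, perm_config(999, seed = 4, exact_limit = 10))
  expect_false(r$exact)
  expect_equal(r$p, 1 / 1000)
  # all y equal: every permutation ties at R^2 = 0, p = 1
  ptsc <- data.frame(x = rep(1:4, each = 3), y = rep(0.4, 12))
  expect_equal(permutation_p_r2(ptsc, 1, perm_config(500, seed = 1))$p, 1)
})

test_that("Monte-Carlo permutation p matches exact enumeration (3+3)", {
  pts <- data.frame(x = rep(c(1, 2), each = 3),
                    y = c(0.1, 0.5, 0.3, 0.9, 1.2, 1.0))
  ex <- permutation_p_r2(pts, 1, perm_config(10000, seed = 1))
  expect_true(ex$exact)
  expect_equal(ex$n_relabelings, 20)
  mc <- permutation_p_r2(pts, 1, perm_config(10000, seed = 1, exact_limit = 1))
  se <- sqrt(ex$p * (1 - ex$p) / 10000)
  expect_lt(abs(mc$p - ex$p), 3 * se + 2 / 10001)
  # exact p is invariant under affine transforms of y (R^2 is invariant)
  pts2 <- pts; pts2$y <- 2 * pts2$y + 1
  expect_identical(permutation_p_r2(pts2, 1, perm_config(10000, seed = 1))$p,
                   ex$p)
})

test_that("selection rules resolve significance patterns as specified", {
  cfg <- perm_config(1000, seed = 1, alpha = 0.05)
  base <- list(r2 = c(0.1, 0.4, 0.41), p = c(0.5, 0.01, 0.01),
               p_incr = c(NA, 0.001, 0.6), n = 72)
  # only order 2 significant -> quadratic (rule 1)
  only2 <- base; only2$p <- c(0.5, 0.01, 0.5)
  expect_equal(select_best_fit(only2, cfg, "max_r2"), "quadratic")
  # none significant -> flat (rule 3)
  none <- base; none$p <- c(0.5, 0.6, 0.7)
  expect_equal(select_best_fit(none, cfg, "max_r2"), "flat")
  expect_equal(select_best_fit(none, cfg, "nested"), "flat")
  # orders 1 and 2 significant, R2(2) > R2(1) -> quadratic (rule 2)
  both <- base; both$p <- c(0.01, 0.01, 0.5)
  expect_equal(select_best_fit(both, cfg, "max_r2"), "quadratic")
  # raw-R2 rule prefers the cubic whenever it is significant (nesting)
  expect_equal(select_best_fit(base, cfg, "max_r2"), "cubic")
  # nested rule demands a significant increment for the cubic
  expect_equal(select_best_fit(base, cfg, "nested"), "quadratic")
  # exact R2 ties break toward the lower order
  tie <- base; tie$p <- c(0.01, 0.01, 0.01); tie$r2 <- c(0.4, 0.4, 0.4)
  expect_equal(select_best_fit(tie, cfg, "max_r2"), "linear")
  # adjusted R2 penalises the extra cubic term
  adj <- base; adj$p <- c(0.5, 0.01, 0.01); adj$r2 <- c(0.1, 0.4, 0.401)
  expect_equal(select_best_fit(adj, cfg, "adjusted_r2"), "quadratic")
})

test_that("Holm-Bonferroni flags match the step-down procedure", {
  expect_equal(holm_bonferroni(c(0.001, 0.02, 0.04), 0.05),
               c(TRUE, TRUE, TRUE))
  # step-down stops at 0.02 > 0.05/3
  expect_equal(holm_bonferroni(c(0.001, 0.02, 0.04, 0.3), 0.05),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_false(any(holm_bonferroni(rep(1, 5), 0.05)))
  expect_true(holm_bonferroni(0.04, 0.05))
  expect_length(holm_bonferroni(numeric(0)), 0)
})

test_that("quadratic shape and opposite-direction rules", {
  # (x - 2.5)^2 - 0.5: wake positive, dips below zero, recovers by REM
  q1 <- classify_quadratic(c(5.75, -5, 1))
  expect_equal(q1$shape, "convex")
  expect_true(q1$opposite_direction)
  # mirrored concave case
  q2 <- classify_quadratic(c(-6.25, 5, -1))
  expect_equal(q2$shape, "concave")
  expect_true(q2$opposite_direction)
  # (x - 2.5)^2 + 5: the dip never nears zero but still moves toward it
  q3 <- classify_quadratic(c(11.25, -5, 1))
  expect_equal(q3$shape, "convex")
  expect_true(q3$opposite_direction)
  # concave curve moving away from zero is not opposite-direction
  q4 <- classify_quadratic(c(-0.2 * 6.25 + 1, 0.2 * 5, -0.2))
  expect_equal(q4$shape, "concave")
  expect_false(q4$opposite_direction)
  expect_error(classify_quadratic(c(1, 2, 3), "linear"), "quadratic")
  expect_error(classify_quadratic(c(1, 2)), "3 coefficients")
})

test_that("chi-square of the fit-class distribution", {
  r <- chi_square_fit_distribution(c(linear = 5, quadratic = 36, cubic = 1))
  expect_equal(r$statistic, 734 / 14, tolerance = 1e-12)
  expect_lt(r$p_value, 0.001)
  expect_false(r$low_expected)
  u <- chi_square_fit_distribution(c(14, 14, 14))
  expect_equal(u$statistic, 0)
  expect_equal(u$p_value, 1)
  h <- chi_square_fit_distribution(c(10, 10, 22))
  expect_equal(h$statistic, 96 / 14, tolerance = 1e-12)
  low <- chi_square_fit_distribution(c(1, 1, 0))
  expect_true(low$low_expected)
})

test_that("trajectory table is consistent and correction flags are sane", {
  cfg <- sim_config(n_nodes = 5, archetypes = default_archetypes(10),
                    group_sizes = c(wake = 12, NREM2 = 10, SWS = 6, REM = 5),
                    seed = 19)
  ds <- generate_edge_dataset(cfg)
  traj <- fit_edge_trajectories(ds, perm_config(400, seed = 3))
  expect_equal(nrow(traj$edges), 10)
  # selected_class = flat iff no order supported; flat edges never survive
  expect_false(any(traj$edges$survives_correction &
                     traj$edges$selected_class == "flat"))
  # per-edge R2 monotone in order
  expect_true(all(traj$edges$r2_2 >= traj$edges$r2_1 - 1e-12))
  expect_true(all(traj$edges$r2_3 >= traj$edges$r2_2 - 1e-12))
  expect_equal(sum(traj$class_counts),
               sum(traj$edges$selected_class != "flat"))
})
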