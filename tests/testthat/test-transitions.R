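test_that("two-sample permutation test: identical, separated, planted cases", {
  cfg <- perm_config(500, seed = 2)
  r0 <- two_sample_perm_test(c(1, 2, 3), c(1, 2, 3), cfg)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # (0,0,0,0) vs (1,1,1,1): only the two perfect splits are as extreme
  r1 <- two_sample_perm_test(c(0, 0, 0, 0), c(1, 1, 1, 1), cfg)
  expect_true(r1$exact)
  expect_equal(r1$p, 2 / 70, tolerance = 1e-12)
  # planted shift 1.0, sd 0.1, study-sized groups: p at the add-one floor
  for (i in 1:5) {
    set.seed(100 + i)
    w <- rnorm(33, 0, 0.1); v <- rnorm(24, 1, 0.1)
    ri <- two_sample_perm_test(w, v, perm_config(500, seed = i))
    expect_equal(ri$p, 1 / 501)
  }
})

test_that("one-sample permutation test agrees with full enumeration", {
  a <- c(0.4, 0.9, 0.6); b <- c(-0.2, 0.1, -0.4)
  ex <- one_sample_perm_sign(a, b, "a", perm_config(10000, seed = 1))
  expect_true(ex$exact)
  expect_equal(ex$n_relabelings, 20)
  mc <- one_sample_perm_sign(a, b, "a",
                             perm_config(10000, seed = 3, exact_limit = 1))
  se <- sqrt(ex$p * (1 - ex$p) / 10000)
  expect_lt(abs(mc$p - ex$p), 3 * se + 2 / 10001)
  # all-zero target group gives t = 0
  expect_equal(one_sample_perm_sign(c(0, 0, 0), b, "a",
                                    perm_config(200, seed = 1))$t, 0)
  # sign-flip null is available as an alternative
  sf <- one_sample_perm_sign(a, b, "a", perm_config(200, seed = 1),
                             null = "sign_flip")
  expect_false(sf$exact)
  expect_true(sf$p > 0 && sf$p <= 1)
})

test_that("transition categories follow the reversal-first rules", {
  cfg <- perm_config(300, seed = 5)
  ns <- list(wake = 12, NREM2 = 10)
  mk <- function(w, v, seed) one_edge_dataset(list(wake = w, NREM2 = v), ns,
                                              noise_sd = 0.05, seed = seed)
  e <- "X--Y"
  rev <- classify_transition(mk(0.5, -0.4, 1), e, "NREM2", cfg)
  expect_equal(rev$category, "reversal")
  red <- classify_transition(mk(0.5, 0.2, 2), e, "NREM2", cfg)
  expect_equal(red$category, "reduction")
  inc <- classify_transition(mk(0.3, 0.6, 3), e, "NREM2", cfg)
  expect_equal(inc$category, "increase")
  none <- classify_transition(mk(0.3, 0.3, 4), e, "NREM2", cfg)
  expect_equal(none$category, "none")
  # negative-side mirror: -0.5 -> -0.2 is a reduction
  redn <- classify_transition(mk(-0.5, -0.2, 5), e, "NREM2", cfg)
  expect_equal(redn$category, "reduction")
  # global sign flip leaves every category unchanged
  for (m in list(c(0.5, -0.4), c(0.5, 0.2), c(0.3, 0.6))) {
    d1 <- classify_transition(mk(m[1], m[2], 9), e, "NREM2", cfg)
    dsf <- mk(m[1], m[2], 9)
    dsf$stages <- lapply(dsf$stages, function(x) -x)
    d2 <- classify_transition(dsf, e, "NREM2", cfg)
    expect_equal(d2$category, d1$category)
  }
})

test_that("null data yields reversals at far below alpha", {
  # reversal needs two independent significances; under exchangeable null
  # data the rate is ~ alpha^2
  cfg <- perm_config(300, seed = 1)
  n_rev <- 0
  for (i in 1:150) {
    set.seed(7000 + i)
    w <- rnorm(12, 0, 0.3); v <- rnorm(10, 0, 0.3)
    ow <- one_sample_perm_sign(w, v, "a", perm_config(300, seed = 2 * i))
    ov <- one_sample_perm_sign(w, v, "b", perm_config(300, seed = 2 * i + 1))
    if (ow$p < 0.05 && ov$p < 0.05 && sign(ow$t) * sign(ov$t) == -1) {
      n_rev <- n_rev + 1
    }
  }
  expect_lte(n_rev / 150, 0.02)
})

test_that("binomial increases/reversals test matches exact tail sums", {
  r <- binomial_increase_reversal_test(14, 20, 21)
  expect_equal(r$proportion, 34 / 55, tolerance = 1e-12)
  expect_equal(round(r$proportion, 2), 0.62)
  r0 <- binomial_increase_reversal_test(0, 0, 10)
  expect_equal(r0$p, 1)
  r8 <- binomial_increase_reversal_test(5, 3, 2)
  expect_equal(r8$p, 56 / 1024, tolerance = 1e-12)
})

test_that("transition summary books categories into consistent rows", {
  part <- default_partition()
  idx <- edge_index(part)
  # single reversal on a DMN--DMN edge appears in all, ho_ho and dmn_fp rows
  calls <- data.frame(edge_id = "aDMN--pDMN", nrem_stage = "NREM2",
                      category = "reversal", survives_correction = TRUE,
                      stringsAsFactors = FALSE)
  s <- summarize_transitions(calls, part)
  expect_equal(unname(s$counts[c("all", "ho_ho", "dmn_fp"), "reversal"]),
               c(1, 1, 1))
  expect_equal(unname(s$counts["sensory_sensory", "reversal"]), 0)
  # random calls: the three split rows sum to the all-edges row
  set.seed(17)
  calls2 <- data.frame(
    edge_id = sample(idx$edge_id, 60, replace = TRUE),
    nrem_stage = sample(c("NREM2", "SWS"), 60, replace = TRUE),
    category = sample(c("reduction", "increase", "reversal", "none"), 60,
                      replace = TRUE),
    survives_correction = FALSE, stringsAsFactors = FALSE)
  s2 <- summarize_transitions(calls2, part)
  split_sum <- colSums(s2$counts[c("ho_ho", "ho_sensory", "sensory_sensory"), ])
  expect_equal(split_sum, s2$counts["all", ])
  expect_error(summarize_transitions(transform(calls, edge_id = "zz--yy"), part),
               "absent from the partition")
})

test_that("whole-dataset classification applies family-wise correction", {
  part <- node_partition(c("A", "B", "C"), rep("other", 3), rep(FALSE, 3))
  ds <- planted_dataset(
    part,
    means = list(wake = c(0.5, 0.5, 0.3), NREM2 = c(-0.5, 0.2, 0.3),
                 SWS = c(0.5, 0.5, 0.3)),
    n_per_stage = list(wake = 12, NREM2 = 10, SWS = 8),
    noise_sd = 0.05, seed = 4)
  calls <- classify_all_transitions(ds, perm_config(2000, seed = 6))
  expect_equal(nrow(calls), 6)   # 3 edges x 2 NREM stages
  n2 <- calls[calls$nrem_stage == "NREM2", ]
  expect_equal(n2$category, c("reversal", "reduction", "none"))
  # SWS means equal wake means: nothing survives family-wise correction
  # (single uncorrected calls can false-positive at the 0.05 rate)
  sws <- calls[calls$nrem_stage == "SWS", ]
  expect_equal(sws$corrected_category, rep("none", 3))
  # reversal precedence: no call is both reversal and increase/reduction
  expect_true(all(table(calls$edge_id, calls$category) <= 1))
  # strong planted effects survive Holm within their families
  expect_true(n2$survives_correction[1])
})
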