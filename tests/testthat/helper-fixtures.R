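# Shared fixtures: all synthetic, built in code.

# Minimal 2-node dataset with one edge whose per-stage values are set
# directly (plus optional noise), for targeted classification tests.
one_edge_dataset <- function(stage_means, n_per_stage, noise_sd = 0,
                             seed = 1) {
  part <- node_partition(c("X", "Y"), c("other", "other"), c(FALSE, FALSE))
  idx <- edge_index(part)
  set.seed(seed)
  mats <- lapply(names(stage_means), function(s) {
    n <- n_per_stage[[s]]
    m <- matrix(stage_means[[s]] + stats::rnorm(n, 0, noise_sd), n, 1,
                dimnames = list(sprintf("%s_s%02d", s, seq_len(n)),
                                idx$edge_id))
    m
  })
  names(mats) <- names(stage_means)
  structure(list(partition = part, edge_index = idx, stages = mats),
            class = "edge_fc_dataset")
}

# Dataset with per-edge, per-stage mean matrices given explicitly.
# means: named list stage -> numeric vector (one mean per edge).
planted_dataset <- function(partition, means, n_per_stage, noise_sd = 0.05,
                            seed = 1) {
  idx <- edge_index(partition)
  set.seed(seed)
  mats <- lapply(names(means), function(s) {
    n <- n_per_stage[[s]]
    m <- matrix(rep(means[[s]], each = n), n, nrow(idx)) +
      matrix(stats::rnorm(n * nrow(idx), 0, noise_sd), n, nrow(idx))
    dimnames(m) <- list(sprintf("%s_s%02d", s, seq_len(n)), idx$edge_id)
    m
  })
  names(mats) <- names(means)
  structure(list(partition = partition, edge_index = idx, stages = mats),
            class = "edge_fc_dataset")
}

# Random stage-vector set under the null (all vectors from one distribution).
null_vector_set <- function(n_per_stage, dim, seed, mean = 0, sd = 1) {
  set.seed(seed)
  N <- sum(n_per_stage)
  stages <- names(n_per_stage)
  list(vectors = matrix(stats::rnorm(N * dim, mean, sd), N, dim),
       labels = factor(rep(stages, n_per_stage), levels = stages))
}

# Independent brute-force angular distance (plain formula, no package code).
brute_angular <- function(a, b) acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) / pi
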