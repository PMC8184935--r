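#' Permutation-test configuration
#'
#' @param n_iter Monte-Carlo iterations (default 10000, minimum 100).
#' @param seed RNG seed for the permutation stream.
#' @param alpha Family-wise / per-test significance level (default 0.05).
#' @param exact_limit Exact enumeration is used instead of Monte-Carlo
#'   sampling whenever the number of distinct relabelings is at most this
#'   (default 10000).
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_iter = 10000, seed = 1, alpha = 0.05,
                        exact_limit = 10000) {
  if (n_iter < 100) stop("'n_iter' must be at least 100")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 alpha = alpha, exact_limit = as.integer(exact_limit)),
            class = "perm_config")
}

# Number of distinct assignments of N items to groups of the given sizes
# (multinomial coefficient), computed multiplicatively to avoid overflow.
relabeling_count <- function(sizes) {
  n <- sum(sizes)
  cnt <- 1
  for (s in sizes) {
    cnt <- cnt * choose(n, s)
    n <- n - s
  }
  cnt
}

# Enumerate all distinct relabelings as index orderings: each row lists the
# item indices assigned to group 1, then group 2, ... Within-group order is
# fixed (ascending), so rows are in bijection with label partitions.
enumerate_relabelings <- function(sizes) {
  rec <- function(idx, sizes) {
    if (length(sizes) == 1) return(matrix(idx, nrow = 1))
    first <- utils::combn(idx, sizes[1])
    do.call(rbind, lapply(seq_len(ncol(first)), function(j) {
      rest <- rec(setdiff(idx, first[, j]), sizes[-1])
      cbind(matrix(rep(first[, j], each = nrow(rest)), nrow = nrow(rest)), rest)
    }))
  }
  rec(seq_len(sum(sizes)), sizes)
}

# Add-one Monte-Carlo p-value: (1 + exceedances) / (1 + n_iter). Exact
# enumeration uses the plain proportion over all relabelings (the observed
# labeling is one of them, so p > 0).
perm_pvalue <- function(stat_perm, stat_obs, exact) {
  hits <- sum(stat_perm >= stat_obs - 1e-12)
  if (exact) hits / length(stat_perm) else (1 + hits) / (1 + length(stat_perm))
}
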