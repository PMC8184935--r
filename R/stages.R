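#' Canonical sleep-wake stage order
#'
#' Stages are analysed in the fixed order wake, NREM2, SWS, REM and carry the
#' x-axis codes 1--4 used for trajectory fitting.
#'
#' @return Character vector of the four stage names.
#' @export
sleep_stages <- function() c("wake", "NREM2", "SWS", "REM")

#' Numeric stage codes for trajectory fitting
#'
#' Wake is coded 1, NREM2 is 2, SWS is 3 and REM is 4, so that a polynomial in
#' the code tracks the descent into slow-wave sleep and the return toward a
#' wake-like state in REM.
#'
#' @param stage Character vector of stage names.
#' @return Integer codes in 1--4.
#' @export
stage_code_of <- function(stage) {
  codes <- c(wake = 1L, NREM2 = 2L, SWS = 3L, REM = 4L)
  bad <- setdiff(unique(stage), names(codes))
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  unname(codes[stage])
}

# Deterministic child-seed derivation: one root seed plus a stream index give a
# reproducible 31-bit seed, so per-edge / per-stage streams do not depend on
# the order in which they are consumed.
derive_seed <- function(root, index) {
  root <- as.double(root) %% 2147483647
  index <- as.double(index)
  s <- (root * 48271 + index * 10007 + 12345) %% 2147483629
  as.integer(s + 1)
}
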