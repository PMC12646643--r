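#' @importFrom rlang %||% .data
#' @importFrom tibble as_tibble tibble
#' @importFrom generics tidy glance
NULL

# Model probabilities are clipped below at this floor inside log(): observed
# counts can land on states the truncated model assigns ~0 mass; the floor
# keeps -LL finite and the optimisation smooth, and sits far below 1/N for
# any realistic cell number.
PROB_FLOOR <- 1e-12

# log10-spaced sequence
log10_seq <- function(from_log10, to_log10, n) {
  10^seq(from_log10, to_log10, length.out = n)
}

#' @export
generics::tidy

#' @export
generics::glance
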