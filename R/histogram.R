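#' Count histograms of mRNA copy number
#'
#' A count histogram records, for one gene, the number of cells `n` observed
#' at each mRNA copy number `x`; the total cell number is `N = sum(n)`. It is
#' the sufficient statistic for the steady-state likelihood, which depends on
#' the data only through these per-level counts.
#'
#' `count_histogram()` builds one from parallel vectors; `as_count_histogram()`
#' validates a data frame with columns `x` and `n` (in a priori analyses `n`
#' may be fractional: `n = N * P_target(x)` are expected counts).
#'
#' @param x Nonnegative integer copy numbers (duplicates are aggregated).
#' @param n Nonnegative counts of cells at each `x` (default 1 per entry, so
#'   a raw per-cell count vector can be passed directly as `x`).
#' @return A tibble with columns `x` (integer) and `n` (double), sorted by
#'   `x`, zero-count levels dropped.
#' @examples
#' count_histogram(c(0, 0, 1, 3, 3, 3))
#' @export
count_histogram <- function(x, n = NULL) {
  if (is.null(n)) n <- rep(1, length(x))
  as_count_histogram(tibble::tibble(x = x, n = n))
}

#' @rdname count_histogram
#' @param df A data frame with columns `x` and `n`.
#' @param allow_fractional Permit non-integer `n` (expected counts); default
#'   `TRUE`.
#' @export
as_count_histogram <- function(df, allow_fractional = TRUE) {
  if (!is.data.frame(df) || !all(c("x", "n") %in% names(df))) {
    stop("a count histogram needs columns `x` and `n`", call. = FALSE)
  }
  x <- df$x
  n <- as.numeric(df$n)
  if (length(x) == 0L || sum(n) <= 0) {
    stop("empty count histogram", call. = FALSE)
  }
  if (any(x < 0) || any(x != floor(x))) {
    stop("mRNA copy numbers `x` must be nonnegative integers", call. = FALSE)
  }
  if (any(n < 0) || (!allow_fractional && any(n != floor(n)))) {
    stop("cell counts `n` must be nonnegative", call. = FALSE)
  }
  out <- dplyr::summarise(dplyr::group_by(tibble::tibble(x = as.integer(x), n = n), x),
                          n = sum(.data$n), .groups = "drop")
  dplyr::arrange(dplyr::filter(out, .data$n > 0), .data$x)
}

hist_total <- function(hist) sum(hist$n)

# Model probability of each histogram level, floored. `p` is a probability
# vector over 0..M; levels beyond M get the floor.
prob_at <- function(p, x, floor = PROB_FLOOR) {
  p <- as.numeric(p)
  idx <- x + 1L
  out <- rep(floor, length(x))
  inside <- idx <= length(p)
  out[inside] <- pmax(p[idx[inside]], floor)
  out
}

#' Log-likelihood of a count histogram under the telegraph model
#'
#' Computes `LL(theta) = sum_x n_x log P_x(theta)`, where `P_x(theta)` is the
#' capture-transformed steady-state marginal of the telegraph model. Model
#' probabilities are clipped below at `1e-12` before the log so that counts
#' falling outside the truncated support leave the likelihood finite.
#'
#' @param hist A count histogram (see [count_histogram()]).
#' @param theta Telegraph parameters.
#' @param beta Capture rate in (0, 1].
#' @param tol Truncation tail-mass tolerance passed to [steady_state()].
#' @return A single numeric log-likelihood value.
#' @examples
#' h <- sample_histogram(telegraph_params(0.05, 0.1, 10), N = 200, seed = 1)
#' log_likelihood(h, telegraph_params(0.05, 0.1, 10))
#' @export
log_likelihood <- function(hist, theta, beta = 1, tol = 1e-4) {
  hist <- as_count_histogram(hist)
  p <- steady_marginal(theta, beta = beta, tol = tol)
  sum(hist$n * log(prob_at(p, hist$x)))
}
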