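#' Binomial downsampling of a copy-number distribution
#'
#' Models scRNA-seq dropout: each true mRNA molecule is observed independently
#' with probability `beta` (the capture rate, assumed known), so an underlying
#' count `x` yields an observed count `y ~ Binomial(x, beta)`. The observed
#' distribution is the input pushed through the lower-triangular binomial
#' kernel `K[y, x] = C(x, y) beta^y (1 - beta)^(x - y)`.
#'
#' For the telegraph model this transform is exactly equivalent to scaling the
#' synthesis rate, `ksyn -> beta * ksyn`; the numerical kernel is kept as the
#' canonical route because it applies unchanged to models without that
#' property, and the scaling shortcut serves as an independent check.
#'
#' @param p A probability vector over counts `0..M` (a
#'   `"telegraph_marginal"` or plain numeric vector summing to 1).
#' @param beta Capture rate in (0, 1].
#' @return A `"telegraph_marginal"` over the same support; the recorded
#'   `beta` attribute is multiplied by the applied rate, so composed thinnings
#'   track their product.
#' @examples
#' p <- steady_marginal(telegraph_params(0.05, 0.1, 10))
#' q <- downsample_distribution(p, 0.3)
#' sum(q * (seq_along(q) - 1)) / sum(p * (seq_along(p) - 1))  # ~0.3
#' @export
downsample_distribution <- function(p, beta) {
  check_beta(beta)
  prob <- as.numeric(p)
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-8) {
    stop("input must be a normalized probability vector", call. = FALSE)
  }
  if (beta == 1) {
    out <- prob
  } else {
    K <- binomial_kernel(length(prob) - 1L, beta)
    out <- as.numeric(K %*% prob)
    out <- pmax(out, 0)
    out <- out / sum(out)
  }
  prev <- if (inherits(p, "telegraph_marginal")) attr(p, "beta") %||% 1 else 1
  new_marginal(out, theta = attr(p, "theta"), beta = prev * beta,
               tail_mass_error = attr(p, "tail_mass_error"))
}

# Dense binomial thinning kernel K[y+1, x+1] = P(Binom(x, beta) = y).
# dbinom works on log scale internally, so entries stay finite for any x.
binomial_kernel <- function(M, beta) {
  x <- 0:M
  K <- outer(x, x, function(y, n) stats::dbinom(y, size = n, prob = beta))
  K[is.na(K)] <- 0
  K
}

#' Binomially thin observed molecule counts
#'
#' Sampling counterpart of [downsample_distribution()]: draws the observed
#' count for each true count `x` as `Binomial(x, beta)`.
#'
#' @param x Vector of nonnegative integer mRNA counts.
#' @param beta Capture rate in (0, 1].
#' @param seed Optional integer seed for a reproducible draw; when `NULL` the
#'   current RNG stream is used.
#' @return Integer vector of observed counts, same length as `x`.
#' @export
downsample_counts <- function(x, beta, seed = NULL) {
  check_beta(beta)
  if (any(x < 0) || any(x != floor(x))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  draw <- function() stats::rbinom(length(x), size = x, prob = beta)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
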