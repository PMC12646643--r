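# Independent oracles and shared fixtures for the test suite. Everything here
# is deliberately implemented without reusing the package's solver paths.

tv_dist <- function(p, q) {
  L <- max(length(p), length(q))
  p <- c(as.numeric(p), rep(0, L - length(p)))
  q <- c(as.numeric(q), rep(0, L - length(q)))
  0.5 * sum(abs(p - q))
}

# Analytic stationary law of the telegraph model: a Beta(kon, koff) mixture
# of Poisson(ksyn * p) intensities. Evaluated through the confluent
# hypergeometric representation with the Kummer transform applied so the
# series has positive terms only:
#   P(x) = e^-ksyn ksyn^x/x! * B(kon+x, koff)/B(kon, koff)
#          * 1F1(koff; kon+koff+x; ksyn)
beta_poisson_pmf <- function(x, kon, koff, ksyn) {
  vapply(x, function(xx) {
    lpref <- -ksyn + xx * log(ksyn) - lgamma(xx + 1) +
      lgamma(kon + xx) + lgamma(kon + koff) -
      lgamma(kon + koff + xx) - lgamma(kon)
    term <- 1; s <- 1; k <- 0
    repeat {
      k <- k + 1
      term <- term * (koff + k - 1) / (kon + koff + xx + k - 1) * ksyn / k
      s <- s + term
      if (term < 1e-16 * s || k > 20000) break
    }
    exp(lpref) * s
  }, numeric(1))
}

# Brute-force generator: loop over every state and every reaction channel.
enum_rate_matrix <- function(kon, koff, ksyn, M) {
  nx <- M + 1L
  n <- 2L * nx
  idx <- function(g, x) g * nx + x + 1L
  A <- matrix(0, n, n)
  for (g in 0:1) for (x in 0:M) {
    j <- idx(g, x)
    if (g == 0) A[idx(1, x), j] <- A[idx(1, x), j] + kon
    if (g == 1) A[idx(0, x), j] <- A[idx(0, x), j] + koff
    if (g == 1 && x < M) A[idx(1, x + 1), j] <- A[idx(1, x + 1), j] + ksyn
    if (x > 0) A[idx(g, x - 1), j] <- A[idx(g, x - 1), j] + x
  }
  diag(A) <- -colSums(A)
  A
}

# Vectorised Gillespie SSA: n independent trajectories from the stationary
# promoter distribution and x = 0, run to t_end; the event that would land
# past t_end is not applied. Returns exact independent steady-state samples
# for t_end well past the relaxation time.
ssa_sample <- function(theta, n, t_end, seed) {
  set.seed(seed)
  kon <- theta[["kon"]]; koff <- theta[["koff"]]; ksyn <- theta[["ksyn"]]
  g <- stats::rbinom(n, 1, kon / (kon + koff))
  x <- integer(n)
  t <- numeric(n)
  active <- rep(TRUE, n)
  while (any(active)) {
    idx <- which(active)
    gi <- g[idx]; xi <- x[idx]
    r_sw <- ifelse(gi == 1, koff, kon)
    r_syn <- ifelse(gi == 1, ksyn, 0)
    tot <- r_sw + r_syn + xi
    tnew <- t[idx] + stats::rexp(length(idx), tot)
    over <- tnew >= t_end
    active[idx[over]] <- FALSE
    keep <- !over
    j <- idx[keep]
    if (length(j)) {
      t[j] <- tnew[keep]
      u <- stats::runif(length(j)) * tot[keep]
      sw <- u < r_sw[keep]
      syn <- !sw & u < r_sw[keep] + r_syn[keep]
      deg <- !sw & !syn
      g[j[sw]] <- 1L - g[j[sw]]
      x[j[syn]] <- x[j[syn]] + 1L
      x[j[deg]] <- x[j[deg]] - 1L
    }
  }
  x
}

# Chi-square GOF p-value of integer samples against a probability vector,
# pooling bins with expected count < 5 into one tail bin.
chisq_gof_p <- function(samples, p) {
  obs <- tabulate(samples + 1L, nbins = length(p))
  expd <- p * length(samples)
  keep <- expd >= 5
  o <- c(obs[keep], sum(obs[!keep]))
  e <- c(expd[keep], sum(expd[!keep]))
  if (utils::tail(e, 1) < 1e-9) {
    o <- o[-length(o)]; e <- e[-length(e)]
  }
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
}

# Parameter sets spanning the library ranges, used by several suites.
oracle_param_sets <- function() {
  grid <- expand.grid(kon = c(0.01, 0.3, 30),
                      koff = c(0.01, 0.3, 30),
                      ksyn = c(0.6, 10, 150))
  grid[sample.int(nrow(grid), 20), ]
}

# Shared model-library fixtures, built once per session.
.lib_cache <- new.env(parent = emptyenv())
cached_library <- function(n, beta = 1) {
  key <- paste0("n", n, "_b", format(beta))
  if (is.null(.lib_cache[[key]])) {
    .lib_cache[[key]] <- build_model_library(grid_spec(n = n), beta = beta)
  }
  .lib_cache[[key]]
}

# Faster profiling settings for unit tests (coarser profile grid).
fast_control <- function() {
  inference_control(n_profile = 15, n_local = 5)
}
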