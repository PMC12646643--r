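#' Sample a count histogram from the telegraph model
#'
#' Draws `N` independent cells from the capture-transformed steady-state
#' marginal at `theta` (a multinomial draw over the truncated support --
#' exact for steady-state snapshots) and tabulates them as a count
#' histogram. This is the replicate engine behind bootstrap CIs and the
#' synthetic-data fixtures.
#'
#' @param theta Telegraph parameters.
#' @param N Number of cells to draw.
#' @param beta Capture rate in (0, 1].
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param tol Truncation tail-mass tolerance.
#' @return A count histogram tibble (`x`, `n`) with `sum(n) == N`.
#' @examples
#' sample_histogram(telegraph_params(0.05, 0.1, 10), N = 200, seed = 1)
#' @export
sample_histogram <- function(theta, N, beta = 1, seed = NULL, tol = 1e-4) {
  stopifnot(N >= 1)
  p <- as.numeric(steady_marginal(theta, beta = beta, tol = tol))
  draw <- function() as.integer(stats::rmultinom(1, size = N, prob = p))
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  as_count_histogram(tibble::tibble(x = seq_along(p) - 1L, n = counts))
}

#' Bootstrap replicate maximum-likelihood estimates
#'
#' Samples `n_reps` independent `N`-cell histograms from the model at
#' `theta` and fits each by [fit_mle()]. The spread of replicate MLEs is the
#' sampling counterpart of the ground-truth profile likelihood: for an
#' identifiable parameter set the MLEs concentrate inside the ground-truth
#' CI, while for an unidentifiable one they smear over decades.
#'
#' @param theta Ground-truth telegraph parameters.
#' @param library A `"model_library"` (its `beta` defines the experiment).
#' @param N Cells per replicate.
#' @param n_reps Number of replicates.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param control An [inference_control()].
#' @return An object of class `"replicate_set"`: list with `theta_true`,
#'   `N`, `beta`, `seed`, `histograms` (list of count histograms), and
#'   `mles`, a tibble with one row per replicate (`rep`, `kon`, `koff`,
#'   `ksyn`, `minus_ll`, `fallback`).
#' @export
bootstrap_mles <- function(theta, library, N, n_reps, seed = 1,
                           control = inference_control()) {
  stopifnot(n_reps >= 1)
  theta <- as_telegraph_params(theta)
  rep_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1L, n_reps))
  histograms <- vector("list", n_reps)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    h <- sample_histogram(theta, N = N, beta = library$beta,
                          seed = rep_seeds[r], tol = control$tol)
    histograms[[r]] <- h
    fit <- fit_mle(h, library, control)
    rows[[r]] <- tibble::tibble(rep = r,
                                kon = fit$theta[["kon"]],
                                koff = fit$theta[["koff"]],
                                ksyn = fit$theta[["ksyn"]],
                                minus_ll = fit$minus_ll,
                                fallback = fit$fallback)
  }
  structure(list(theta_true = theta, N = N, beta = library$beta, seed = seed,
                 histograms = histograms, mles = dplyr::bind_rows(rows)),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("<replicate_set>", nrow(x$mles), "replicates, N =", x$N,
      " beta =", x$beta, "\n")
  invisible(x)
}

#' Summary statistics of a count distribution
#'
#' Moment and shape statistics of a histogram or probability vector: mean,
#' variance, Fano factor (variance/mean, 1 for Poisson, > 1 for bursty
#' expression), moment skewness, fraction of zeros, and a bimodality
#' indicator (the number of interior local maxima of the probability
#' sequence after smoothing with a centred window of 3).
#'
#' @param x A count histogram (tibble with `x`, `n`), a
#'   `"telegraph_marginal"`, or a bare probability vector over `0..M`.
#' @return A one-row tibble: `mean`, `variance`, `fano`, `skewness`,
#'   `zero_fraction`, `n_modes`. `fano` is `NA` when the mean is zero.
#' @examples
#' summary_statistics(steady_marginal(telegraph_params(0.05, 0.1, 10)))
#' @export
summary_statistics <- function(x) {
  if (is.data.frame(x)) {
    hist <- as_count_histogram(x)
    support <- 0:max(hist$x)
    w <- numeric(length(support))
    w[hist$x + 1L] <- hist$n
    p <- w / sum(w)
  } else {
    p <- as.numeric(x)
    if (length(p) == 0L || any(p < 0)) stop("invalid distribution",
                                            call. = FALSE)
    p <- p / sum(p)
    support <- seq_along(p) - 1L
  }
  mu <- sum(support * p)
  v <- sum((support - mu)^2 * p)
  skew <- if (v > 0) sum((support - mu)^3 * p) / v^1.5 else NA_real_
  fano <- if (mu > 0) v / mu else NA_real_
  sm <- smooth_window3(p)
  n_modes <- 0L
  if (length(sm) >= 3L) {
    interior <- 2:(length(sm) - 1L)
    n_modes <- sum(sm[interior] > sm[interior - 1L] &
                     sm[interior] >= sm[interior + 1L])
  }
  tibble::tibble(mean = mu, variance = v, fano = fano, skewness = skew,
                 zero_fraction = p[1], n_modes = as.integer(n_modes))
}

smooth_window3 <- function(p) {
  n <- length(p)
  if (n < 3L) return(p)
  c(p[1], (p[-c(n - 1L, n)] + p[-c(1L, n)] + p[-c(1L, 2L)]) / 3, p[n])
}
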