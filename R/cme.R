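#' Telegraph-model CME rate matrix
#'
#' Builds the infinitesimal generator `A` of the chemical master equation
#' `dP/dt = A P` for the telegraph model on the truncated state space
#' `{G, G*} x {0, ..., M}` mRNA copies. `A[i, j]` is the rate of the reaction
#' taking the system from state `j` to state `i`; each column sums to zero.
#' States are indexed promoter-major, mRNA-minor: state `(g, x)` with
#' `g = 0` (inactive, G) or `g = 1` (active, G*) sits at row/column
#' `g * (M + 1) + x + 1`. Synthesis out of `x = M` is suppressed (reflecting
#' truncation), so the generator is exactly conservative on the truncated
#' space; the neglected outflux is controlled by the tail-mass criterion in
#' [steady_state()].
#'
#' @param theta Telegraph parameters.
#' @param M Truncation bound: largest mRNA copy number retained (`M >= 1`).
#' @return A sparse `dgCMatrix` of dimension `2 * (M + 1)`.
#' @examples
#' A <- build_rate_matrix(telegraph_params(1, 1, 5), M = 10)
#' max(abs(Matrix::colSums(A)))  # generator property: columns sum to 0
#' @export
build_rate_matrix <- function(theta, M) {
  theta <- as_telegraph_params(theta)
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 1L) {
    stop("M must be a single integer >= 1", call. = FALSE)
  }
  kon <- theta[["kon"]]; koff <- theta[["koff"]]; ksyn <- theta[["ksyn"]]
  nx <- M + 1L
  idx <- function(g, x) g * nx + x + 1L  # promoter-major, mRNA-minor

  x_all <- 0:M
  x_deg <- 1:M
  x_syn <- if (M >= 1L) 0:(M - 1L) else integer(0)

  ii <- c(idx(1L, x_all),            # G -> G* at kon
          idx(0L, x_all),            # G* -> G at koff
          idx(1L, x_syn + 1L),       # synthesis in active state
          idx(0L, x_deg - 1L),       # degradation, inactive promoter
          idx(1L, x_deg - 1L))       # degradation, active promoter
  jj <- c(idx(0L, x_all), idx(1L, x_all), idx(1L, x_syn),
          idx(0L, x_deg), idx(1L, x_deg))
  xx <- c(rep(kon, nx), rep(koff, nx), rep(ksyn, length(x_syn)),
          x_deg, x_deg)              # kd = 1: degradation propensity is x

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2L * nx, 2L * nx))
  Matrix::diag(A) <- -Matrix::colSums(A)
  A
}

# Solve A p = 0 with sum(p) = 1 at a fixed truncation M: the first balance
# equation (redundant, as columns sum to zero) is replaced by the
# normalisation row and the square system is solved by direct factorisation.
# Small systems (the common case: M tracks the Poisson(ksyn) support) go
# through a dense LAPACK solve, which beats the sparse machinery's setup
# cost; large ones use a sparse LU. Returns the joint probability
# 2 x (M+1) matrix plus the stationarity residual against the untouched
# generator.
solve_cme_fixed <- function(theta, M) {
  dense <- (2L * (M + 1L)) <= 400L
  A <- if (dense) dense_rate_matrix(theta, M) else build_rate_matrix(theta, M)
  n <- nrow(A)
  rhs <- c(1, rep(0, n - 1L))
  if (dense) {
    B <- A
    B[1L, ] <- 1
    p <- solve(B, rhs)
    residual <- max(abs(A %*% p))
  } else {
    B <- A
    B[1L, ] <- 1
    p <- as.numeric(Matrix::solve(B, rhs))
    residual <- max(abs(as.numeric(A %*% p)))
  }
  norm_residual <- abs(sum(p) - 1)
  p[p < 0] <- 0
  p <- p / sum(p)
  joint <- matrix(p, nrow = 2L, ncol = M + 1L, byrow = TRUE,
                  dimnames = list(c("inactive", "active"), NULL))
  list(joint = joint, residual = residual, norm_residual = norm_residual)
}

# Dense twin of build_rate_matrix, used by the small-system fast path.
dense_rate_matrix <- function(theta, M) {
  kon <- theta[["kon"]]; koff <- theta[["koff"]]; ksyn <- theta[["ksyn"]]
  nx <- M + 1L
  n <- 2L * nx
  A <- matrix(0, n, n)
  i_off <- 1:nx          # (inactive, x), x = 0..M
  i_on <- nx + 1:nx      # (active, x)
  A[cbind(i_on, i_off)] <- kon
  A[cbind(i_off, i_on)] <- koff
  if (M >= 1L) {
    x <- 1:M
    A[cbind(i_on[x + 1L], i_on[x])] <- ksyn            # synthesis
    A[cbind(i_off[x], i_off[x + 1L])] <- x             # degradation, kd = 1
    A[cbind(i_on[x], i_on[x + 1L])] <-
      A[cbind(i_on[x], i_on[x + 1L])] + x
  }
  diag(A) <- diag(A) - colSums(A)
  A
}

#' Steady-state joint distribution of the telegraph model
#'
#' Solves `A P = 0` on a truncated state space for the stationary joint
#' distribution over (promoter state, mRNA copy number). The truncation bound
#' `M` is chosen automatically: the initial bound is the smaller of a
#' mean-plus-spread heuristic and the upper-tail quantile of a
#' `Poisson(ksyn)` law (which stochastically dominates the telegraph
#' marginal), and `M` is doubled until the estimated neglected tail mass --
#' the probability of the top two mRNA levels -- falls at or below `tol`.
#'
#' @param theta Telegraph parameters.
#' @param tol Tail-mass tolerance (default `1e-4`).
#' @param max_states Hard cap on the truncation bound `M` (default `1e4`).
#' @return An object of class `"telegraph_joint"`: a list with elements
#'   `probabilities` (2 x (M+1) matrix, rows `inactive`/`active`),
#'   `truncation_bound`, `tail_mass_error`, `residual` (stationarity residual
#'   `max |A p|`), `norm_residual` (pre-renormalisation deviation of the
#'   probability sum from 1), and `theta`.
#' @examples
#' ss <- steady_state(telegraph_params(0.05, 0.1, 10))
#' ss$tail_mass_error <= 1e-4
#' @export
steady_state <- function(theta, tol = 1e-4, max_states = 1e4) {
  theta <- as_telegraph_params(theta)
  stopifnot(is.numeric(tol), tol > 0)
  m <- theta[["ksyn"]] * theta[["kon"]] / (theta[["kon"]] + theta[["koff"]])
  b <- theta[["ksyn"]] / theta[["koff"]]
  heuristic <- ceiling(m + 10 * sqrt(m * (1 + b)))
  pois_cap <- stats::qpois(tol / 10, lambda = theta[["ksyn"]],
                           lower.tail = FALSE) + 5L
  M <- max(16L, min(heuristic, pois_cap))

  repeat {
    sol <- solve_cme_fixed(theta, M)
    marg <- colSums(sol$joint)
    # Tail estimate: probability of the top two retained levels, guarded by
    # the analytic Poisson(ksyn) dominance bound on the mass beyond M.
    tail_mass <- max(sum(marg[c(M, M + 1L)]),
                     stats::ppois(M, theta[["ksyn"]], lower.tail = FALSE))
    if (tail_mass <= tol || M >= max_states) break
    M <- min(2L * M, as.integer(max_states))
  }
  if (tail_mass > tol) {
    stop("state-space truncation failed: tail mass ", signif(tail_mass, 3),
         " > tol ", tol, " at M = ", M, call. = FALSE)
  }
  structure(
    list(probabilities = sol$joint, truncation_bound = M,
         tail_mass_error = tail_mass, residual = sol$residual,
         norm_residual = sol$norm_residual, theta = theta),
    class = "telegraph_joint"
  )
}

#' @export
print.telegraph_joint <- function(x, ...) {
  cat("<telegraph_joint> M =", x$truncation_bound,
      " tail mass =", signif(x$tail_mass_error, 3),
      " |Ap|_inf =", signif(x$residual, 3), "\n")
  invisible(x)
}

new_marginal <- function(prob, theta = NULL, beta = 1,
                         tail_mass_error = NA_real_) {
  structure(as.numeric(prob), class = "telegraph_marginal",
            theta = theta, beta = beta, tail_mass_error = tail_mass_error)
}

#' Marginal mRNA copy-number distribution
#'
#' Projects a joint steady-state solution onto the mRNA copy-number axis by
#' summing over the two promoter states (promoter state is not observable in
#' scRNA-seq data).
#'
#' @param joint A `"telegraph_joint"` object from [steady_state()].
#' @return A `"telegraph_marginal"`: a numeric probability vector over
#'   `x = 0, ..., M`, with the generating `theta`, the capture rate `beta`
#'   (1 at this stage), and `tail_mass_error` kept as attributes.
#' @examples
#' p <- marginalize(steady_state(telegraph_params(0.05, 0.1, 10)))
#' sum(p)  # 1
#' @export
marginalize <- function(joint) {
  stopifnot(inherits(joint, "telegraph_joint"))
  new_marginal(colSums(joint$probabilities), theta = joint$theta, beta = 1,
               tail_mass_error = joint$tail_mass_error)
}

#' @export
print.telegraph_marginal <- function(x, ...) {
  cat("<telegraph_marginal> support 0..", length(x) - 1L,
      "  mean = ", signif(distribution_mean(x), 4), "\n", sep = "")
  invisible(x)
}

distribution_mean <- function(p) sum((seq_along(p) - 1) * as.numeric(p))

#' @export
as_tibble.telegraph_marginal <- function(x, ...) {
  tibble::tibble(x = seq_along(x) - 1L, prob = as.numeric(x))
}

#' mRNA distributions conditioned on promoter state
#'
#' Splits a joint steady-state solution into the two mRNA distributions
#' conditioned on the promoter being inactive (G) or active (G*). Mode
#' separation between the two conditionals is the source of bimodality in the
#' telegraph model and a key driver of practical identifiability.
#'
#' @param joint A `"telegraph_joint"` object.
#' @return A list with elements `inactive` and `active` (each a
#'   `"telegraph_marginal"` normalised conditional distribution) and
#'   `occupancy`, the stationary promoter occupancies
#'   `c(inactive = koff, active = kon) / (kon + koff)`. The occupancy-weighted
#'   sum of the conditionals recovers the marginal.
#' @examples
#' cond <- conditional_distributions(steady_state(telegraph_params(0.23, 0.1, 3.5)))
#' which.max(cond$inactive) - 1  # mode given G
#' which.max(cond$active) - 1    # mode given G*
#' @export
conditional_distributions <- function(joint) {
  stopifnot(inherits(joint, "telegraph_joint"))
  w <- rowSums(joint$probabilities)
  if (any(w <= 0)) {
    stop("degenerate conditioning: a promoter state has zero occupancy",
         call. = FALSE)
  }
  list(
    inactive = new_marginal(joint$probabilities["inactive", ] / w[["inactive"]],
                            theta = joint$theta),
    active = new_marginal(joint$probabilities["active", ] / w[["active"]],
                          theta = joint$theta),
    occupancy = c(inactive = unname(w[["inactive"]]),
                  active = unname(w[["active"]]))
  )
}

#' Capture-transformed steady-state marginal
#'
#' Convenience workhorse: solves the CME at `theta`, marginalises over
#' promoter states, and applies binomial downsampling at capture rate `beta`.
#' This is the model distribution entering every likelihood in the package.
#'
#' @inheritParams steady_state
#' @param beta Capture rate in (0, 1]; see [downsample_distribution()].
#' @return A `"telegraph_marginal"`.
#' @export
steady_marginal <- function(theta, beta = 1, tol = 1e-4, max_states = 1e4) {
  p <- marginalize(steady_state(theta, tol = tol, max_states = max_states))
  if (beta < 1) p <- downsample_distribution(p, beta) else check_beta(beta)
  p
}
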