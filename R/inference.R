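#' Inference tuning parameters
#'
#' Collects the numerical knobs of the maximum-likelihood engine. Defaults:
#' 40 log-spaced profile points per parameter across the library range plus
#' 10 extra points within +/-0.5 decades of the MLE; the 95%
#' profile-likelihood threshold `qchisq(0.95, 1) / 2` (~1.921, the "1.92"
#' constant); CME tail tolerance `1e-4`; Nelder-Mead simplex refinement in
#' log10-parameter space with relative function tolerance `1e-8` and at most
#' `maxit` evaluations.
#'
#' @param n_profile Profile grid points spanning the library range.
#' @param n_local Extra profile points near the MLE.
#' @param local_halfwidth Half-width (decades) of the local refinement band.
#' @param threshold Profile-likelihood CI threshold on `-LL`.
#' @param tol Truncation tail-mass tolerance for CME solves.
#' @param maxit Maximum optimizer iterations.
#' @param reltol Optimizer relative convergence tolerance.
#' @param delta Coarse-surface inclusion margin for the optimisation box.
#' @return A list of class `"inference_control"`.
#' @export
inference_control <- function(n_profile = 40, n_local = 10,
                              local_halfwidth = 0.5,
                              threshold = stats::qchisq(0.95, 1) / 2,
                              tol = 1e-4, maxit = 400, reltol = 1e-8,
                              delta = stats::qchisq(0.95, 1) / 2 + 2) {
  structure(list(n_profile = n_profile, n_local = n_local,
                 local_halfwidth = local_halfwidth, threshold = threshold,
                 tol = tol, maxit = maxit, reltol = reltol, delta = delta),
            class = "inference_control")
}

#' APM configuration
#'
#' Scale factors `T` and cutoff for the alternative precision measure. A
#' parameter with confidence interval `(lb, ub)` has `APM = log(ub/lb) /
#' log(T)`; the parameter set is called practically identifiable when the
#' maximum APM over the three parameters is below `cutoff`. Defaults follow
#' the broad timescale ranges of promoter switching in mammalian cells:
#' `T = 3` for `ksyn` and `T = 100` for `kon` and `koff`, cutoff 1.
#'
#' @param T Named vector of per-parameter scale factors (> 1).
#' @param cutoff Identifiability cutoff on the maximum APM (> 0).
#' @return A list of class `"apm_config"`.
#' @export
apm_config <- function(T = c(kon = 100, koff = 100, ksyn = 3), cutoff = 1) {
  stopifnot(all(T > 1), cutoff > 0,
            all(c("kon", "koff", "ksyn") %in% names(T)))
  structure(list(T = T[c("kon", "koff", "ksyn")], cutoff = cutoff),
            class = "apm_config")
}

#' Alternative precision measure
#'
#' `APM = log_T(ub / lb)`: the width of a confidence interval measured in
#' factors of `T`. APM = 0 for a point interval, 1 when the CI spans exactly
#' one factor of `T`, and grows without bound for unidentifiable parameters.
#'
#' @param lb,ub Lower and upper CI bounds on the natural (rate) scale;
#'   `0 < lb <= ub`.
#' @param T Scale factor (> 1).
#' @return The APM value.
#' @examples
#' apm(0.05, 5, T = 100)  # exactly 1
#' @export
apm <- function(lb, ub, T) {
  if (any(lb <= 0)) stop("CI lower bound must be positive", call. = FALSE)
  if (any(ub < lb)) stop("need lb <= ub", call. = FALSE)
  stopifnot(T > 1)
  log(ub / lb) / log(T)
}

# -LL objective over named log10 parameters, with per-call memoisation:
# profile warm starts revisit identical points.
make_objective <- function(hist, beta, tol) {
  hist <- as_count_histogram(hist)
  x <- hist$x; n <- hist$n
  cache <- new.env(parent = emptyenv())
  function(log10_theta) {
    key <- paste(signif(log10_theta, 12), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    theta <- telegraph_params(10^log10_theta[["kon"]],
                              10^log10_theta[["koff"]],
                              10^log10_theta[["ksyn"]])
    p <- steady_marginal(theta, beta = beta, tol = tol)
    val <- -sum(n * log(prob_at(p, x)))
    cache[[key]] <- val
    val
  }
}

# Bounded derivative-free minimisation in log10 space: free coordinates are
# mapped to the box through a logistic transform and refined by Nelder-Mead
# (1 free dim: golden-section via optimize; 0: nothing to do).
optim_bounded <- function(fn, init, lower, upper, maxit = 400,
                          reltol = 1e-8) {
  free <- which(upper - lower > 1e-9)
  fixed <- setdiff(seq_along(init), free)
  par <- pmin(pmax(init, lower), upper)
  if (length(fixed)) par[fixed] <- (lower[fixed] + upper[fixed]) / 2
  if (length(free) == 0L) {
    return(list(par = par, value = fn(par), convergence = 0L))
  }
  span <- upper[free] - lower[free]
  to_box <- function(z) {
    out <- par
    out[free] <- lower[free] + span * stats::plogis(z)
    out
  }
  frac <- pmin(pmax((par[free] - lower[free]) / span, 1e-6), 1 - 1e-6)
  z0 <- stats::qlogis(frac)
  if (length(free) == 1L) {
    opt <- stats::optimize(function(z) fn(to_box(z)),
                           lower = -12, upper = 12, tol = 1e-6)
    z_best <- opt$minimum; v_best <- opt$objective
    if (fn(to_box(z0)) < v_best) { z_best <- z0; v_best <- fn(to_box(z0)) }
    return(list(par = to_box(z_best), value = v_best, convergence = 0L))
  }
  opt <- stats::optim(z0, function(z) fn(to_box(z)), method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  v0 <- fn(to_box(z0))
  if (v0 < opt$value) {
    list(par = to_box(z0), value = v0, convergence = opt$convergence)
  } else {
    list(par = to_box(opt$par), value = opt$value,
         convergence = opt$convergence)
  }
}

# Bounded minimisation with box self-healing: when the optimum lands on a
# box face that is not the grid range edge, the box was too small (the coarse
# surface underestimated the extent of the likelihood valley, as happens on
# reduced grids) -- widen that face by the current box width and rerun,
# warm-started, until the optimum is interior or the range edge is reached.
optim_boxed <- function(fn, init, lower, upper, range_lower, range_upper,
                        maxit = 400, reltol = 1e-8, max_expand = 8L) {
  lower <- pmax(lower, range_lower)
  upper <- pmin(upper, range_upper)
  start <- init
  for (round in seq_len(max_expand)) {
    res <- optim_bounded(fn, start, lower, upper, maxit = maxit,
                         reltol = reltol)
    width <- pmax(upper - lower, 0.5)
    pin_lo <- (res$par - lower < 1e-4) & (lower - range_lower > 1e-9)
    pin_hi <- (upper - res$par < 1e-4) & (range_upper - upper > 1e-9)
    if (!any(pin_lo | pin_hi)) break
    lower[pin_lo] <- pmax(lower[pin_lo] - width[pin_lo], range_lower[pin_lo])
    upper[pin_hi] <- pmin(upper[pin_hi] + width[pin_hi], range_upper[pin_hi])
    start <- res$par
  }
  res$lower <- lower
  res$upper <- upper
  res
}

grid_range_log10 <- function(grid) {
  list(lower = c(kon = grid$kon$log10_range[1],
                 koff = grid$koff$log10_range[1],
                 ksyn = grid$ksyn$log10_range[1]),
       upper = c(kon = grid$kon$log10_range[2],
                 koff = grid$koff$log10_range[2],
                 ksyn = grid$ksyn$log10_range[2]))
}

#' Maximum-likelihood estimate of telegraph parameters
#'
#' Two-stage fit: the coarse `-LL` surface over the model library identifies
#' the best grid point and an optimisation box (see
#' [search_bounds_from_surface()]); a bounded derivative-free simplex
#' refinement in log10-parameter space, seeded at the coarse argmin, then
#' polishes the estimate. If the refinement fails the coarse argmin is
#' returned with a fallback flag.
#'
#' @param hist A count histogram.
#' @param library A `"model_library"` built at the experiment's capture rate.
#' @param control An [inference_control()].
#' @return An object of class `"telegraph_fit"`: list with `theta` (MLE),
#'   `log10_theta`, `minus_ll` (minimised `-LL`), `coarse_minus_ll`,
#'   `bounds`, `boundary` (named logical: MLE pinned at a search bound),
#'   `fallback`, `N`, and `beta`.
#' @examples
#' lib <- build_model_library(grid_spec(n = 6), beta = 1)
#' h <- sample_histogram(telegraph_params(0.05, 0.1, 10), N = 500, seed = 7)
#' fit <- fit_mle(h, lib)
#' tidy(fit)
#' @export
fit_mle <- function(hist, library, control = inference_control()) {
  hist <- as_count_histogram(hist)
  surface <- coarse_surface(hist, library)
  bounds <- search_bounds_from_surface(surface, library$grid,
                                       delta = control$delta)
  obj <- make_objective(hist, beta = library$beta, tol = control$tol)
  coarse_min <- min(surface$minus_ll)
  rng <- grid_range_log10(library$grid)
  res <- tryCatch(
    optim_boxed(obj, bounds$init, bounds$lower, bounds$upper,
                rng$lower, rng$upper,
                maxit = control$maxit, reltol = control$reltol),
    error = function(e) NULL
  )
  fallback <- is.null(res)
  if (fallback) {
    res <- list(par = bounds$init, value = coarse_min, convergence = 1L)
    warning("fine optimization failed; returning coarse-grid MLE",
            call. = FALSE)
  }
  par <- res$par
  names(par) <- c("kon", "koff", "ksyn")
  if (!is.null(res$lower)) {
    bounds$lower <- res$lower
    bounds$upper <- res$upper
  }
  boundary <- (par - rng$lower < 1e-6) | (rng$upper - par < 1e-6)
  structure(
    list(theta = telegraph_params(10^par[["kon"]], 10^par[["koff"]],
                                  10^par[["ksyn"]]),
         log10_theta = par, minus_ll = res$value,
         coarse_minus_ll = coarse_min, bounds = bounds,
         boundary = boundary, fallback = fallback,
         N = hist_total(hist), beta = library$beta,
         objective = obj),
    class = "telegraph_fit"
  )
}

#' @export
print.telegraph_fit <- function(x, ...) {
  cat("<telegraph_fit> -LL =", format(x$minus_ll), "\n")
  print(x$theta)
  if (any(x$boundary)) {
    cat("  boundary:", paste(names(x$boundary)[x$boundary], collapse = ", "),
        "\n")
  }
  invisible(x)
}

# CI from a profile curve by linear interpolation of the first threshold
# crossings outward from the curve minimum; bounds that never cross are set
# to the range edge and flagged. A curve sitting entirely above the
# threshold (possible only when the global minimum was found off this
# curve's grid) yields the conservative full-range interval, flagged.
ci_from_profile <- function(log10_values, pl, minus_ll_min, threshold) {
  level <- minus_ll_min + threshold
  k <- which.min(pl)
  if (pl[k] > level) {
    return(list(lb_log10 = log10_values[1],
                ub_log10 = log10_values[length(log10_values)],
                lb_boundary = TRUE, ub_boundary = TRUE))
  }
  cross_right <- NA_real_; right_boundary <- TRUE
  if (k < length(pl)) {
    for (i in (k + 1):length(pl)) {
      if (pl[i] > level) {
        f <- (level - pl[i - 1]) / (pl[i] - pl[i - 1])
        cross_right <- log10_values[i - 1] +
          f * (log10_values[i] - log10_values[i - 1])
        right_boundary <- FALSE
        break
      }
    }
  }
  cross_left <- NA_real_; left_boundary <- TRUE
  if (k > 1L) {
    for (i in (k - 1):1) {
      if (pl[i] > level) {
        f <- (level - pl[i + 1]) / (pl[i] - pl[i + 1])
        cross_left <- log10_values[i + 1] +
          f * (log10_values[i] - log10_values[i + 1])
        left_boundary <- FALSE
        break
      }
    }
  }
  if (left_boundary) cross_left <- log10_values[1]
  if (right_boundary) cross_right <- log10_values[length(log10_values)]
  list(lb_log10 = cross_left, ub_log10 = cross_right,
       lb_boundary = left_boundary, ub_boundary = right_boundary)
}

profile_grid_values <- function(grid, param, mle_log10, control) {
  r <- grid[[param]]$log10_range
  vals <- seq(r[1], r[2], length.out = control$n_profile)
  local <- seq(mle_log10 - control$local_halfwidth,
               mle_log10 + control$local_halfwidth,
               length.out = control$n_local)
  sort(unique(pmin(pmax(c(vals, local, mle_log10), r[1]), r[2])))
}

#' Profile likelihoods, confidence intervals, and APM
#'
#' For each parameter in turn, `-LL` is minimised over the other two
#' parameters at a log10-spaced grid of fixed values spanning the library
#' range (densified near the MLE), walking outward from the MLE with warm
#' starts. Confidence intervals are the first crossings of
#' `min(-LL) + threshold` (default `qchisq(0.95, 1)/2`, the 1.92 rule),
#' interpolated linearly in log10; a profile that never crosses before the
#' range edge gets the edge as its bound plus a boundary flag -- such CIs are
#' used as-is in the APM, which therefore reports a large but finite value
#' for unidentifiable parameters.
#'
#' @param hist A count histogram (integer counts for a posteriori data,
#'   fractional expected counts for a priori targets).
#' @param library A `"model_library"`.
#' @param config An [apm_config()].
#' @param control An [inference_control()].
#' @param fit Optional precomputed [fit_mle()] result.
#' @return An object of class `"telegraph_profile"`: list with `mle`
#'   (`telegraph_fit`), `minus_ll_min`, `profiles` (tibble: `param`,
#'   `log10_value`, `value`, `minus_ll`), `ci` (tibble: `param`, `lb`, `ub`,
#'   `lb_boundary`, `ub_boundary`, `T`, `apm`), `overall_apm`,
#'   `identifiable`, `threshold`, `N`, `beta`.
#' @examples
#' lib <- build_model_library(grid_spec(n = 6), beta = 1)
#' tgt <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 200)
#' pr <- ground_truth_profile(tgt, lib)
#' glance(pr)
#' @export
profile_likelihood <- function(hist, library, config = apm_config(),
                               control = inference_control(), fit = NULL) {
  hist <- as_count_histogram(hist)
  if (is.null(fit)) fit <- fit_mle(hist, library, control)
  obj <- fit$objective %||% make_objective(hist, library$beta, control$tol)
  params <- c("kon", "koff", "ksyn")
  rng <- grid_range_log10(library$grid)

  compute_curves <- function(fit) {
    profiles <- vector("list", length(params))
    names(profiles) <- params
    for (par in params) {
      others <- setdiff(params, par)
      vals <- profile_grid_values(library$grid, par, fit$log10_theta[[par]],
                                  control)
      pl <- numeric(length(vals))
      coords <- matrix(NA_real_, length(vals), 2,
                       dimnames = list(NULL, others))
      anchor <- which.min(abs(vals - fit$log10_theta[[par]]))
      lower2 <- fit$bounds$lower[others]
      upper2 <- fit$bounds$upper[others]

      run_direction <- function(indices) {
        start <- fit$log10_theta[others]
        lo <- lower2; hi <- upper2
        for (m in indices) {
          v <- vals[m]
          fn2 <- function(q) {
            full <- c(q[1], q[2], v)
            names(full) <- c(others, par)
            obj(full[params])
          }
          res <- optim_boxed(fn2, start, lo, hi,
                             rng$lower[others], rng$upper[others],
                             maxit = control$maxit, reltol = control$reltol)
          pl[m] <<- res$value
          coords[m, ] <<- res$par
          start <- res$par
          lo <- res$lower; hi <- res$upper  # keep expansion for the walk
        }
      }
      run_direction(anchor:length(vals))
      if (anchor > 1L) run_direction((anchor - 1L):1L)
      profiles[[par]] <- tibble::tibble(param = par, log10_value = vals,
                                        value = 10^vals, minus_ll = pl,
                                        .coords = asplit(coords, 1))
    }
    profiles
  }

  # If profiling uncovers a better optimum than the seeded fit (possible
  # when the coarse box trapped the fit in a side basin), refit from the
  # discovered point and profile again.
  for (pass in 1:3) {
    profiles <- compute_curves(fit)
    prof <- dplyr::bind_rows(profiles)
    best <- which.min(prof$minus_ll)
    if (fit$minus_ll - prof$minus_ll[best] <= 1e-3 || pass == 3) break
    start <- c(prof$.coords[[best]],
               stats::setNames(prof$log10_value[best], prof$param[best]))
    start <- start[params]
    res <- optim_boxed(obj, start, rng$lower, rng$upper,
                       rng$lower, rng$upper,
                       maxit = control$maxit, reltol = control$reltol)
    fit$log10_theta <- stats::setNames(res$par, params)
    fit$theta <- telegraph_params(10^res$par[[1]], 10^res$par[[2]],
                                  10^res$par[[3]])
    fit$minus_ll <- min(res$value, prof$minus_ll[best])
    fit$boundary <- (res$par - rng$lower < 1e-6) |
      (rng$upper - res$par < 1e-6)
  }
  prof$.coords <- NULL
  minus_ll_min <- min(fit$minus_ll, min(prof$minus_ll))
  ci <- dplyr::bind_rows(lapply(params, function(par) {
    pp <- profiles[[par]]
    cr <- ci_from_profile(pp$log10_value, pp$minus_ll, minus_ll_min,
                          control$threshold)
    T_par <- config$T[[par]]
    tibble::tibble(param = par,
                   lb = 10^cr$lb_log10, ub = 10^cr$ub_log10,
                   lb_boundary = cr$lb_boundary, ub_boundary = cr$ub_boundary,
                   T = T_par, apm = apm(10^cr$lb_log10, 10^cr$ub_log10, T_par))
  }))
  overall <- max(ci$apm)
  structure(
    list(mle = fit, minus_ll_min = minus_ll_min, profiles = prof, ci = ci,
         overall_apm = overall, identifiable = overall < config$cutoff,
         threshold = control$threshold, N = hist_total(hist),
         beta = library$beta, config = config),
    class = "telegraph_profile"
  )
}

#' @export
print.telegraph_profile <- function(x, ...) {
  cat("<telegraph_profile> N =", x$N, " beta =", x$beta,
      " max APM =", signif(x$overall_apm, 4),
      if (x$identifiable) "(identifiable)" else "(not identifiable)", "\n")
  print(as.data.frame(x$ci[, c("param", "lb", "ub", "apm")]))
  invisible(x)
}

#' Classify practical identifiability from per-parameter APM values
#'
#' The overall APM of a parameter set is the maximum of the three
#' per-parameter APMs (the least identifiable parameter governs); the set is
#' practically identifiable when the overall APM is below the cutoff.
#'
#' @param x A `"telegraph_profile"`, or a numeric vector of per-parameter
#'   APM values.
#' @param config An [apm_config()].
#' @return A one-row tibble with columns `overall_apm` and `identifiable`.
#' @examples
#' classify_identifiability(c(0.2, 0.5, 0.9))
#' @export
classify_identifiability <- function(x, config = apm_config()) {
  apms <- if (inherits(x, "telegraph_profile")) x$ci$apm else as.numeric(x)
  stopifnot(length(apms) >= 1, all(is.finite(apms)))
  overall <- max(apms)
  tibble::tibble(overall_apm = overall,
                 identifiable = overall < config$cutoff)
}
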