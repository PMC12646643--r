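#' A priori identifiability target
#'
#' An a priori analysis asks whether the telegraph model's parameters could
#' be recovered from a hypothetical experiment with `N` cells and capture
#' rate `beta`, using the model itself as the data-generating process -- no
#' sampling involved. The target bundles the ground-truth parameters with
#' their exact capture-transformed marginal `p_tar`.
#'
#' @param theta Ground-truth telegraph parameters.
#' @param N Hypothetical cell number (>= 1).
#' @param beta Capture rate in (0, 1].
#' @param tol Truncation tail-mass tolerance.
#' @return An object of class `"apriori_target"`.
#' @export
apriori_target <- function(theta, N, beta = 1, tol = 1e-4) {
  theta <- as_telegraph_params(theta)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  check_beta(beta)
  structure(list(theta_tar = theta, N = N, beta = beta,
                 p_tar = steady_marginal(theta, beta = beta, tol = tol)),
            class = "apriori_target")
}

#' @export
print.apriori_target <- function(x, ...) {
  cat("<apriori_target> N =", x$N, " beta =", x$beta, "\n")
  print(x$theta_tar)
  invisible(x)
}

# Expected-count histogram of an a priori target: n_x = N * P_tar(x). The
# cross-entropy surrogate H is exactly the -LL of this fractional histogram,
# so the a priori mode reuses the entire likelihood/profiling machinery.
target_histogram <- function(target, N = target$N) {
  p <- as.numeric(target$p_tar)
  tibble::tibble(x = seq_along(p) - 1L, n = N * p)
}

#' Cross-entropy likelihood surrogate
#'
#' `H(theta) = -N * sum_x P_tar(x) log(P_sim(x | theta))`: the expected `-LL`
#' of an `N`-cell experiment whose data follow the target distribution
#' exactly. By Gibbs' inequality `H` is minimised at the true parameters,
#' where it equals `N` times the Shannon entropy of the target; the cell
#' number enters only as a scalar multiple, so the effect of `N` can be
#' studied without recomputation.
#'
#' @param target An [apriori_target()].
#' @param theta Candidate telegraph parameters (simulated at the target's
#'   capture rate).
#' @param tol Truncation tail-mass tolerance.
#' @return The scalar `H` value.
#' @examples
#' tgt <- apriori_target(telegraph_params(0.05, 0.1, 10), N = 200)
#' cross_entropy(tgt, tgt$theta_tar)  # N * entropy of the target
#' @export
cross_entropy <- function(target, theta, tol = 1e-4) {
  stopifnot(inherits(target, "apriori_target"))
  -log_likelihood(target_histogram(target), theta, beta = target$beta,
                  tol = tol)
}

#' Ground-truth profile likelihood
#'
#' Runs the profile-likelihood machinery of [profile_likelihood()] with the
#' cross-entropy surrogate in place of the sampled `-LL`. The result is the
#' "ground-truth" profile: the sampling-free limit equal to the average of
#' profile likelihoods over infinitely many hypothetical `N`-cell replicates.
#' Fully deterministic.
#'
#' @param target An [apriori_target()].
#' @param library A `"model_library"` built at the target's capture rate.
#' @param config An [apm_config()].
#' @param control An [inference_control()].
#' @return A `"telegraph_profile"` (see [profile_likelihood()]).
#' @export
ground_truth_profile <- function(target, library, config = apm_config(),
                                 control = inference_control()) {
  stopifnot(inherits(target, "apriori_target"))
  if (!isTRUE(all.equal(target$beta, library$beta))) {
    stop("library capture rate (", library$beta,
         ") does not match target capture rate (", target$beta, ")",
         call. = FALSE)
  }
  profile_likelihood(target_histogram(target), library, config = config,
                     control = control)
}

# Re-derive CIs/APM from stored profile curves at a different cell number.
# H scales linearly in N while its minimisers do not move, so curves profiled
# at N = N0 are exact at any N after scaling by N / N0; only the threshold
# crossings must be re-found.
rescale_profile <- function(profile, N) {
  stopifnot(inherits(profile, "telegraph_profile"))
  scale <- N / profile$N
  prof <- dplyr::mutate(profile$profiles, minus_ll = .data$minus_ll * scale)
  minus_ll_min <- profile$minus_ll_min * scale
  config <- profile$config
  ci <- dplyr::bind_rows(lapply(split(prof, prof$param), function(pp) {
    pp <- dplyr::arrange(pp, .data$log10_value)
    cr <- ci_from_profile(pp$log10_value, pp$minus_ll, minus_ll_min,
                          profile$threshold)
    T_par <- config$T[[pp$param[1]]]
    tibble::tibble(param = pp$param[1],
                   lb = 10^cr$lb_log10, ub = 10^cr$ub_log10,
                   lb_boundary = cr$lb_boundary, ub_boundary = cr$ub_boundary,
                   T = T_par, apm = apm(10^cr$lb_log10, 10^cr$ub_log10, T_par))
  }))
  ci <- ci[match(c("kon", "koff", "ksyn"), ci$param), ]
  overall <- max(ci$apm)
  out <- profile
  out$profiles <- prof
  out$minus_ll_min <- minus_ll_min
  out$ci <- ci
  out$overall_apm <- overall
  out$identifiable <- overall < config$cutoff
  out$N <- N
  out
}

#' Smallest cell number achieving practical identifiability
#'
#' Evaluates ground-truth profiles for one parameter set along an increasing
#' ladder of hypothetical cell numbers and reports the smallest `N` at which
#' the maximum APM drops below the cutoff. Because the cross-entropy scales
#' linearly in `N` without moving its minimisers, the profiles are computed
#' once (at the smallest ladder entry) and re-thresholded for every other
#' `N` -- no refitting.
#'
#' @param theta Ground-truth telegraph parameters.
#' @param library A `"model_library"` at the experiment's capture rate.
#' @param N_ladder Increasing vector of cell numbers to try.
#' @param config An [apm_config()].
#' @param control An [inference_control()].
#' @return A list with `N_min` (smallest identifiable `N`, or `NA` if none on
#'   the ladder) and `ladder`, a tibble with one row per `N`: per-parameter
#'   APMs, `apm_max`, `identifiable`.
#' @examples
#' lib <- build_model_library(grid_spec(n = 6), beta = 1)
#' cells_for_identifiability(telegraph_params(0.23, 0.1, 3.5), lib,
#'                           N_ladder = c(1e3, 1e4, 1e5))
#' @export
cells_for_identifiability <- function(theta, library,
                                      N_ladder = c(1e3, 1e4, 1e5, 1e6),
                                      config = apm_config(),
                                      control = inference_control()) {
  stopifnot(length(N_ladder) >= 1, !is.unsorted(N_ladder))
  target <- apriori_target(theta, N = N_ladder[1], beta = library$beta,
                           tol = control$tol)
  base <- ground_truth_profile(target, library, config = config,
                               control = control)
  rows <- lapply(N_ladder, function(N) {
    pr <- if (N == base$N) base else rescale_profile(base, N)
    apms <- stats::setNames(pr$ci$apm, pr$ci$param)
    tibble::tibble(N = N, apm_kon = apms[["kon"]], apm_koff = apms[["koff"]],
                   apm_ksyn = apms[["ksyn"]], apm_max = pr$overall_apm,
                   identifiable = pr$identifiable)
  })
  ladder <- dplyr::bind_rows(rows)
  idx <- which(ladder$identifiable)
  list(N_min = if (length(idx)) ladder$N[min(idx)] else NA_real_,
       ladder = ladder)
}

# Coarse profile CIs for one target using only the precomputed library: the
# H value at every grid point is a dot product, and the profile of each
# parameter is the minimum over the other two grid axes. Used by landscape
# scans where per-point fine optimisation would be prohibitive.
coarse_apm <- function(target, library, config = apm_config(),
                       threshold = stats::qchisq(0.95, 1) / 2) {
  surf <- coarse_surface(target_histogram(target), library)
  minus_ll_min <- min(surf$minus_ll)
  params <- c("kon", "koff", "ksyn")
  apms <- vapply(params, function(par) {
    prof <- dplyr::summarise(
      dplyr::group_by(surf, value = .data[[par]]),
      minus_ll = min(.data$minus_ll), .groups = "drop")
    prof <- dplyr::arrange(prof, .data$value)
    cr <- ci_from_profile(log10(prof$value), prof$minus_ll, minus_ll_min,
                          threshold)
    apm(10^cr$lb_log10, 10^cr$ub_log10, config$T[[par]])
  }, numeric(1))
  apms
}

#' A priori identifiability landscape scan
#'
#' Maps practical identifiability across parameter space: every point of
#' `targets` is treated as a ground truth, its exact capture-transformed
#' marginal is formed, and APMs are derived from coarse profile likelihoods
#' read directly off the model library grid (the minimum of `H` over the two
#' non-profiled axes). This grid-level profile is the scalable screen used
#' for full-landscape figures; individual points of interest can be followed
#' up with [ground_truth_profile()] for refined CIs.
#'
#' @param targets A [grid_spec()] enumerating the ground-truth points, or a
#'   data frame with columns `kon`, `koff`, `ksyn`.
#' @param library A `"model_library"` (its `beta` defines the experiment).
#' @param N Hypothetical cell number.
#' @param config An [apm_config()].
#' @param threshold Profile CI threshold on `H`.
#' @param tol Truncation tolerance for target marginals.
#' @return A tibble with one row per target: `kon`, `koff`, `ksyn`,
#'   per-parameter APMs, `apm_max`, `identifiable`, and `ok` (FALSE where the
#'   point failed and was skipped).
#' @export
scan_landscape <- function(targets, library, N, config = apm_config(),
                           threshold = stats::qchisq(0.95, 1) / 2,
                           tol = 1e-4) {
  pts <- if (inherits(targets, "grid_spec")) grid_points(targets)
         else tibble::as_tibble(targets)
  stopifnot(all(c("kon", "koff", "ksyn") %in% names(pts)))
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    theta <- telegraph_params(pts$kon[i], pts$koff[i], pts$ksyn[i])
    res <- tryCatch({
      tgt <- apriori_target(theta, N = N, beta = library$beta, tol = tol)
      apms <- coarse_apm(tgt, library, config = config,
                         threshold = threshold)
      tibble::tibble(kon = pts$kon[i], koff = pts$koff[i],
                     ksyn = pts$ksyn[i],
                     apm_kon = apms[["kon"]], apm_koff = apms[["koff"]],
                     apm_ksyn = apms[["ksyn"]], apm_max = max(apms),
                     identifiable = max(apms) < config$cutoff, ok = TRUE)
    }, error = function(e) {
      tibble::tibble(kon = pts$kon[i], koff = pts$koff[i],
                     ksyn = pts$ksyn[i],
                     apm_kon = NA_real_, apm_koff = NA_real_,
                     apm_ksyn = NA_real_, apm_max = NA_real_,
                     identifiable = NA, ok = FALSE)
    })
    res
  })
  dplyr::bind_rows(rows)
}
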