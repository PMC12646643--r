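#' Tidy a telegraph fit
#'
#' @param x A `"telegraph_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `log10_estimate`, `at_boundary`.
#' @export
tidy.telegraph_fit <- function(x, ...) {
  tibble::tibble(term = names(x$log10_theta),
                 estimate = as.numeric(x$theta),
                 log10_estimate = as.numeric(x$log10_theta),
                 at_boundary = as.logical(x$boundary))
}

#' @rdname tidy.telegraph_fit
#' @export
glance.telegraph_fit <- function(x, ...) {
  tibble::tibble(minus_ll = x$minus_ll, coarse_minus_ll = x$coarse_minus_ll,
                 N = x$N, beta = x$beta, fallback = x$fallback)
}

#' Tidy a profile-likelihood result
#'
#' @param x A `"telegraph_profile"`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with the MLE, CI bounds, boundary
#'   flags, `T`, and APM. `glance()`: one row with the global fit summary.
#' @export
tidy.telegraph_profile <- function(x, ...) {
  est <- stats::setNames(as.numeric(x$mle$theta), names(x$mle$log10_theta))
  dplyr::mutate(dplyr::rename(x$ci, term = "param"),
                estimate = est[.data$term], .after = "term")
}

#' @rdname tidy.telegraph_profile
#' @export
glance.telegraph_profile <- function(x, ...) {
  tibble::tibble(minus_ll_min = x$minus_ll_min, overall_apm = x$overall_apm,
                 identifiable = x$identifiable, threshold = x$threshold,
                 N = x$N, beta = x$beta)
}

#' Tidy a bootstrap replicate set
#'
#' @param x A `"replicate_set"`.
#' @param ... Unused.
#' @return A long tibble: `rep`, `term`, `estimate`, `true`.
#' @export
tidy.replicate_set <- function(x, ...) {
  truth <- c(kon = x$theta_true[["kon"]], koff = x$theta_true[["koff"]],
             ksyn = x$theta_true[["ksyn"]])
  long <- tidyr::pivot_longer(x$mles, c("kon", "koff", "ksyn"),
                              names_to = "term", values_to = "estimate")
  dplyr::mutate(long[, c("rep", "term", "estimate")],
                true = truth[.data$term])
}

#' Plot profile likelihoods
#'
#' One panel per parameter: the profiled objective (relative to its minimum)
#' against the parameter on a log10 axis, the CI threshold as a horizontal
#' line, CI bounds as vertical lines, and the MLE as a point.
#'
#' @param object A `"telegraph_profile"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.telegraph_profile <- function(object, ...) {
  prof <- dplyr::mutate(object$profiles,
                        rel = .data$minus_ll - object$minus_ll_min)
  ci <- tidyr::pivot_longer(object$ci[, c("param", "lb", "ub")],
                            c("lb", "ub"), values_to = "bound")
  mle <- tibble::tibble(param = names(object$mle$log10_theta),
                        value = as.numeric(object$mle$theta))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$value, y = .data$rel)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                        colour = "darkgreen") +
    ggplot2::geom_vline(data = ci, ggplot2::aes(xintercept = .data$bound),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_point(data = mle, ggplot2::aes(x = .data$value, y = 0),
                        colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 4 * object$threshold)) +
    ggplot2::facet_wrap(~param, scales = "free_x") +
    ggplot2::labs(x = "parameter value (units of kd)",
                  y = "profile objective - minimum")
}

#' Plot an identifiability landscape slice
#'
#' Tile plot of the maximum APM over (kon, koff) for each ksyn slice of a
#' landscape scan; identifiable points (APM below the cutoff) appear dark.
#'
#' @param landscape Output of [scan_landscape()].
#' @param cutoff Identifiability cutoff drawn in the fill scale.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, cutoff = 1) {
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$kon, y = .data$koff,
                               fill = pmin(.data$apm_max, 5))) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "max APM", direction = -1) +
    ggplot2::facet_wrap(~signif(ksyn, 2)) +
    ggplot2::labs(x = "kon (units of kd)", y = "koff (units of kd)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
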