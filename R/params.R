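#' Telegraph-model kinetic parameters
#'
#' Constructs and validates the three-parameter vector of the telegraph
#' (two-state promoter) model: the promoter switches between an inactive state
#' G and an active state G* at rates `kon` (activation) and `koff`
#' (deactivation); mRNA is synthesised at rate `ksyn` only while the promoter
#' is active and degraded at rate `kd`. All rates are expressed in units of
#' the degradation rate, i.e. `kd = 1` defines the time unit, so the model has
#' exactly three free parameters.
#'
#' @param kon Promoter activation rate (units of `kd`). Strictly positive.
#' @param koff Promoter deactivation rate (units of `kd`). Strictly positive.
#' @param ksyn mRNA synthesis rate in the active state (units of `kd`).
#'   Strictly positive.
#'
#' @return A named numeric vector of class `"telegraph_params"` with elements
#'   `kon`, `koff`, `ksyn`.
#'
#' @examples
#' theta <- telegraph_params(kon = 0.05, koff = 0.1, ksyn = 10)
#' burst_summaries(theta)
#' @export
telegraph_params <- function(kon, koff, ksyn) {
  theta <- c(kon = as.numeric(kon), koff = as.numeric(koff),
             ksyn = as.numeric(ksyn))
  validate_params(theta)
  structure(theta, class = "telegraph_params")
}

#' Coerce to telegraph parameters
#'
#' @param x A `telegraph_params` object, a numeric vector of length 3
#'   (order `kon`, `koff`, `ksyn`, or fully named), or a list/one-row data
#'   frame with those names.
#' @return A `telegraph_params` object.
#' @export
as_telegraph_params <- function(x) {
  if (inherits(x, "telegraph_params")) {
    validate_params(x)
    return(x)
  }
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[, c("kon", "koff", "ksyn")])
  }
  if (is.list(x)) x <- unlist(x)
  if (!is.numeric(x) || length(x) != 3L) {
    stop("expected three numeric rates (kon, koff, ksyn)", call. = FALSE)
  }
  if (!is.null(names(x)) && all(c("kon", "koff", "ksyn") %in% names(x))) {
    x <- x[c("kon", "koff", "ksyn")]
  } else {
    names(x) <- c("kon", "koff", "ksyn")
  }
  telegraph_params(x[["kon"]], x[["koff"]], x[["ksyn"]])
}

validate_params <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("telegraph rates must be strictly positive and finite; got (",
         paste(signif(unname(theta), 4), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(theta)
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat("<telegraph_params>  kon =", format(x[["kon"]]),
      " koff =", format(x[["koff"]]),
      " ksyn =", format(x[["ksyn"]]), " (units of kd)\n")
  invisible(x)
}

#' Closed-form bursting summaries
#'
#' Standard kinetic summaries of the telegraph model: transcript burst size
#' `ksyn / koff`, burst frequency `kon * koff / (kon + koff)`, and the
#' steady-state mean expression `ksyn * kon / (kon + koff)` (the mean-field
#' value; the mean alone leaves the three rates structurally unidentifiable).
#'
#' @param theta Telegraph parameters (see [telegraph_params()]).
#' @return A one-row tibble with columns `burst_size`, `burst_frequency`,
#'   `mean_expression`.
#' @examples
#' burst_summaries(telegraph_params(0.05, 0.1, 10))
#' @export
burst_summaries <- function(theta) {
  theta <- as_telegraph_params(theta)
  kon <- theta[["kon"]]; koff <- theta[["koff"]]; ksyn <- theta[["ksyn"]]
  tibble::tibble(
    burst_size = ksyn / koff,
    burst_frequency = kon * koff / (kon + koff),
    mean_expression = ksyn * kon / (kon + koff)
  )
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta > 1) {
    stop("capture rate beta must be a single number in (0, 1]", call. = FALSE)
  }
  beta
}
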