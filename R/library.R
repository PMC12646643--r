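#' Log-spaced parameter grid specification
#'
#' Defines the 3D log10-spaced grid over (kon, koff, ksyn) used for the model
#' library, coarse likelihood surfaces, and landscape scans. The production
#' default is 60 points per axis over kon, koff in `[1e-3, 1e3]` and ksyn in
#' `[10^-0.3, 10^2.3]`, spanning typical measured mammalian bursting-kinetics
#' ranges; reduced grids (e.g. `n = 12`) preserve the geometry for fast
#' exploratory work.
#'
#' @param n Points per axis (scalar, or named vector with entries `kon`,
#'   `koff`, `ksyn`). Must be >= 2.
#' @param kon,koff,ksyn Length-2 numeric `log10` ranges `c(lo, hi)`.
#' @return An object of class `"grid_spec"`.
#' @examples
#' grid_spec(n = 12)
#' @export
grid_spec <- function(n = 60,
                      kon = c(-3, 3),
                      koff = c(-3, 3),
                      ksyn = c(-0.3, 2.3)) {
  if (length(n) == 1L) n <- c(kon = n, koff = n, ksyn = n)
  n <- stats::setNames(as.integer(n[c("kon", "koff", "ksyn")]),
                       c("kon", "koff", "ksyn"))
  ranges <- list(kon = kon, koff = koff, ksyn = ksyn)
  for (par in names(ranges)) {
    r <- ranges[[par]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] >= r[2]) {
      stop("log10 range for ", par, " must be finite and ordered",
           call. = FALSE)
    }
    if (is.na(n[[par]]) || n[[par]] < 2L) {
      stop("grid needs >= 2 points per axis", call. = FALSE)
    }
  }
  structure(list(kon = list(log10_range = kon, n = n[["kon"]]),
                 koff = list(log10_range = koff, n = n[["koff"]]),
                 ksyn = list(log10_range = ksyn, n = n[["ksyn"]])),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  for (par in names(x)) {
    r <- x[[par]]$log10_range
    cat(sprintf("%-5s: %d points, 10^%g .. 10^%g\n", par, x[[par]]$n,
                r[1], r[2]))
  }
  invisible(x)
}

grid_axis <- function(grid, param) {
  r <- grid[[param]]$log10_range
  log10_seq(r[1], r[2], grid[[param]]$n)
}

#' Enumerate the grid points of a grid specification
#'
#' @param grid A [grid_spec()].
#' @return A tibble with columns `index`, `kon`, `koff`, `ksyn`; `index` is
#'   the flat position in kon-major order (kon slowest, ksyn fastest).
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  pts <- tidyr::expand_grid(kon = grid_axis(grid, "kon"),
                            koff = grid_axis(grid, "koff"),
                            ksyn = grid_axis(grid, "ksyn"))
  dplyr::mutate(pts, index = dplyr::row_number(), .before = 1)
}

#' Build a CME model library over a parameter grid
#'
#' Solves the CME at every grid point and stores the capture-transformed
#' steady-state marginals. The library is the coarse reference for maximum
#' likelihood fitting: evaluated against one target histogram it yields the
#' full coarse likelihood surface in a single pass, which seeds and bounds
#' the subsequent fine optimisation. The build is deterministic; a point
#' whose truncation fails is flagged and the build continues.
#'
#' @param grid A [grid_spec()].
#' @param beta Capture rate baked into the library distributions.
#' @param tol Truncation tail-mass tolerance.
#' @param progress Print a progress note every `progress` points (0 = quiet).
#' @return An object of class `"model_library"`: list with `grid`, `beta`,
#'   `tol`, `points` (tibble: `index`, `kon`, `koff`, `ksyn`, `ok`), and
#'   `distributions` (list of probability vectors aligned with `points`).
#' @examples
#' lib <- build_model_library(grid_spec(n = 3), beta = 1)
#' length(lib$distributions)  # 27
#' @export
build_model_library <- function(grid, beta = 1, tol = 1e-4, progress = 0) {
  check_beta(beta)
  pts <- grid_points(grid)
  dists <- vector("list", nrow(pts))
  ok <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    theta <- telegraph_params(pts$kon[i], pts$koff[i], pts$ksyn[i])
    res <- tryCatch(steady_marginal(theta, beta = beta, tol = tol),
                    error = function(e) e)
    if (inherits(res, "error")) {
      ok[i] <- FALSE
      dists[[i]] <- numeric(0)
    } else {
      ok[i] <- TRUE
      dists[[i]] <- as.numeric(res)
    }
    if (progress > 0 && i %% progress == 0) {
      message("model library: ", i, "/", nrow(pts), " points")
    }
  }
  structure(list(grid = grid, beta = beta, tol = tol,
                 points = dplyr::mutate(pts, ok = ok),
                 distributions = dists),
            class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  cat("<model_library> ", nrow(x$points), " grid points, beta = ", x$beta,
      ", tol = ", x$tol, "\n", sep = "")
  invisible(x)
}

#' Serialize / load a model library
#'
#' The library is written as a single plain-text JSON container: grid axes,
#' capture rate, tolerance, and the ragged probability vectors stored as one
#' flat array with offsets. Probabilities are written at full precision, so a
#' round trip reproduces them exactly.
#'
#' @param library A `"model_library"`.
#' @param path Output (input) file path.
#' @return `write_model_library()` returns `path` invisibly;
#'   `read_model_library()` returns the `"model_library"`.
#' @export
write_model_library <- function(library, path) {
  stopifnot(inherits(library, "model_library"))
  lens <- lengths(library$distributions)
  payload <- list(
    format = "burstid-model-library",
    version = 1L,
    beta = library$beta,
    tol = library$tol,
    grid = lapply(library$grid, function(ax)
      list(log10_range = ax$log10_range, n = ax$n)),
    ok = library$points$ok,
    lengths = unname(lens),
    # %.17g guarantees a lossless double round trip through decimal text
    probabilities = paste(
      sprintf("%.17g", unlist(library$distributions, use.names = FALSE)),
      collapse = " ")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_library
#' @export
read_model_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "burstid-model-library")) {
    stop("not a model library file: ", path, call. = FALSE)
  }
  grid <- grid_spec(
    n = c(kon = obj$grid$kon$n, koff = obj$grid$koff$n, ksyn = obj$grid$ksyn$n),
    kon = obj$grid$kon$log10_range,
    koff = obj$grid$koff$log10_range,
    ksyn = obj$grid$ksyn$log10_range
  )
  probs <- if (length(obj$probabilities) && nzchar(obj$probabilities)) {
    as.numeric(strsplit(obj$probabilities, " ", fixed = TRUE)[[1]])
  } else {
    numeric(0)
  }
  ends <- cumsum(obj$lengths)
  starts <- ends - obj$lengths + 1L
  dists <- lapply(seq_along(obj$lengths), function(i) {
    if (obj$lengths[i] == 0L) numeric(0)
    else probs[starts[i]:ends[i]]
  })
  structure(list(grid = grid, beta = obj$beta, tol = obj$tol,
                 points = dplyr::mutate(grid_points(grid), ok = obj$ok),
                 distributions = dists),
            class = "model_library")
}

#' Coarse negative log-likelihood surface over the library grid
#'
#' Evaluates `-LL` (or the cross-entropy surrogate `H`, when the histogram
#' carries fractional expected counts) of every library distribution against
#' one target histogram in a single pass -- no per-point refitting. The
#' argmin is the coarse maximum-likelihood estimate.
#'
#' @param hist A count histogram.
#' @param library A `"model_library"` whose `beta` matches the experiment.
#' @return The library `points` tibble with an added `minus_ll` column
#'   (`Inf` for flagged points).
#' @export
coarse_surface <- function(hist, library) {
  stopifnot(inherits(library, "model_library"))
  hist <- as_count_histogram(hist)
  x <- hist$x
  n <- hist$n
  minus_ll <- vapply(library$distributions, function(p) {
    if (length(p) == 0L) return(Inf)
    -sum(n * log(prob_at(p, x)))
  }, numeric(1))
  dplyr::mutate(library$points, minus_ll = minus_ll)
}

#' Optimization box from a coarse surface
#'
#' Derives per-parameter bounds for the fine optimisation: the box encloses
#' every grid point whose `-LL` lies within `delta` of the coarse minimum,
#' expanded by one grid step on each side and clipped to the grid range. The
#' default `delta` is the 95% profile-likelihood threshold (chi-square(1)
#' quantile / 2, ~1.92) plus a 2.0 safety margin, so the confidence region is
#' guaranteed to sit inside the box. The initial guess is the coarse argmin
#' (ties broken by lowest flat index).
#'
#' @param surface Output of [coarse_surface()].
#' @param grid The [grid_spec()] the surface was computed on.
#' @param delta Inclusion margin above the coarse minimum.
#' @return A list with `lower`, `upper` (named log10 bounds), and `init`
#'   (named log10 coordinates of the coarse argmin).
#' @export
search_bounds_from_surface <- function(surface, grid,
                                       delta = stats::qchisq(0.95, 1) / 2 + 2) {
  vals <- surface$minus_ll
  stopifnot(any(is.finite(vals)))
  best <- which.min(vals)  # lowest flat index on ties (kon-major order)
  sel <- which(vals <= min(vals) + delta)
  lower <- numeric(3); upper <- numeric(3)
  params <- c("kon", "koff", "ksyn")
  names(lower) <- names(upper) <- params
  init <- c(kon = log10(surface$kon[best]), koff = log10(surface$koff[best]),
            ksyn = log10(surface$ksyn[best]))
  for (par in params) {
    ax <- log10(grid_axis(grid, par))
    step <- if (length(ax) > 1L) ax[2] - ax[1] else 0
    sel_vals <- log10(surface[[par]][sel])
    lower[par] <- max(min(ax), min(sel_vals) - step)
    upper[par] <- min(max(ax), max(sel_vals) + step)
  }
  list(lower = lower, upper = upper, init = init)
}
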