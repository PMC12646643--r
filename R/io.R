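#' Read a genes x cells count matrix into per-gene histograms
#'
#' Accepts a dense TSV/CSV matrix (genes as rows, first column gene names,
#' header row of cell identifiers) or a MatrixMarket sparse matrix with
#' features/barcodes sidecar files, and reduces each gene to its mRNA
#' copy-number histogram. Counts must be raw nonnegative integers (UMI-like
#' molecule counts); normalised or log-transformed matrices are rejected
#' rather than silently coerced, since the likelihood is defined on raw
#' counts. Genes whose counts are all missing are skipped with a warning.
#'
#' @param path Path to the counts file (`.tsv`, `.csv`, or `.mtx`).
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`; `"auto"` picks
#'   by file extension.
#' @param features,barcodes Sidecar paths for MTX input (default: `features.tsv`
#'   and `barcodes.tsv` next to the matrix file).
#' @return A tibble with one row per gene: `gene`, `N` (cells), and
#'   `histogram` (list-column of count-histogram tibbles).
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     "tsv" = "tsv", "txt" = "tsv", "csv" = "csv",
                     "mtx" = "mtx",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    features <- features %||% file.path(dir, "features.tsv")
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    genes <- readr::read_tsv(features, col_names = FALSE,
                             show_col_types = FALSE)[[1]]
    cells <- readr::read_tsv(barcodes, col_names = FALSE,
                             show_col_types = FALSE)[[1]]
    counts <- as.matrix(m)
    rownames(counts) <- genes
    colnames(counts) <- cells
  } else {
    reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
    df <- reader(path, show_col_types = FALSE)
    genes <- as.character(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- genes
  }
  if (anyNA(counts)) stop("count matrix contains missing entries",
                          call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be raw nonnegative integers (no normalised or ",
         "log-transformed matrices)", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    xi <- counts[i, ]
    if (length(xi) == 0L) return(NULL)
    tibble::tibble(gene = rownames(counts)[i], N = length(xi),
                   histogram = list(count_histogram(as.integer(xi))))
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) warning(sum(empty), " empty gene(s) skipped")
  dplyr::bind_rows(rows[!empty])
}

#' Fit telegraph kinetics for every gene of a counts table
#'
#' Per-gene driver for the a posteriori pipeline: for each histogram it runs
#' the coarse-library fit, fine optimisation, profile likelihoods, and APM
#' classification.
#'
#' @param counts Output of [read_counts()], or any tibble with columns
#'   `gene` and `histogram` (list of count histograms).
#' @param library A `"model_library"` built at the experiment's capture rate.
#' @param config An [apm_config()].
#' @param control An [inference_control()].
#' @return A tibble with one row per gene: MLE rates, CI bounds, boundary
#'   flags, per-parameter APMs, `apm_max`, `identifiable`.
#' @export
infer_kinetics <- function(counts, library, config = apm_config(),
                           control = inference_control()) {
  stopifnot(all(c("gene", "histogram") %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    h <- counts$histogram[[i]]
    pr <- profile_likelihood(h, library, config = config, control = control)
    ci <- pr$ci
    wide <- stats::setNames(
      c(pr$mle$theta, ci$lb, ci$ub, as.numeric(ci$lb_boundary),
        as.numeric(ci$ub_boundary), ci$apm),
      c("mle_kon", "mle_koff", "mle_ksyn",
        paste0("ci_lb_", ci$param), paste0("ci_ub_", ci$param),
        paste0("lb_boundary_", ci$param), paste0("ub_boundary_", ci$param),
        paste0("apm_", ci$param)))
    dplyr::bind_cols(
      tibble::tibble(gene = counts$gene[i], N = pr$N),
      tibble::as_tibble(as.list(wide)),
      tibble::tibble(apm_max = pr$overall_apm,
                     identifiable = pr$identifiable))
  })
  dplyr::bind_rows(rows)
}

#' Write an inference results table with a provenance sidecar
#'
#' Writes the results as a TSV (deterministic column order, numeric columns
#' rounded to 6 significant digits, logical flags written as TRUE/FALSE) and
#' a JSON sidecar recording the run configuration so the output is
#' reproducible from its inputs.
#'
#' @param results A results tibble (e.g. from [infer_kinetics()]).
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @param config Optional named list of run settings stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = list()) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  out <- dplyr::mutate(results, dplyr::across(dplyr::where(is.numeric),
                                              ~ signif(.x, 6)))
  readr::write_tsv(out, path)
  sidecar <- list(package = "burstid",
                  version = as.character(utils::packageVersion("burstid")),
                  config = config)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a results sidecar
#'
#' @param path The TSV path passed to [write_results()].
#' @return The sidecar as a list.
#' @export
read_results_config <- function(path) {
  jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
}
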