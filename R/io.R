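#' Read a data matrix from delimited text
#'
#' Expected dialect (tab-separated): a header row whose first cell is a
#' label and whose remaining cells are the time values, then one row per
#' wavenumber with the wavenumber in the first column and intensities in
#' the remaining columns.  Both grids must be strictly increasing and all
#' intensities non-negative (the factorization requires a non-negative
#' input matrix) and finite.
#'
#' @param path file path.
#' @param transpose set to `TRUE` when the file stores spectra as rows
#'   (times in the first column); the matrix is transposed back to the
#'   wavenumber-by-time orientation after reading.
#' @param nonneg reject negative entries (default `TRUE`, the contract
#'   for input data matrices; factor files written by the tool may carry
#'   small negative entries and are read with `nonneg = FALSE`).
#' @return list with `M` (numeric matrix), `spectral_grid` and
#'   `time_grid`.
#' @export
read_matrix <- function(path, transpose = FALSE, nonneg = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  times <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(times))
    stop("header row must contain numeric time values", call. = FALSE)
  body <- read.table(path, sep = "\t", skip = 1L, header = FALSE,
                     colClasses = "numeric")
  if (ncol(body) != length(times) + 1L)
    stop("ragged rows: data width does not match the header", call. = FALSE)
  grid <- body[[1]]
  M <- as.matrix(body[, -1, drop = FALSE])
  dimnames(M) <- NULL
  if (anyNA(M) || any(!is.finite(M)))
    stop("non-numeric or non-finite cells in the data matrix", call. = FALSE)
  if (transpose) {
    tmp <- grid; grid <- times; times <- tmp
    M <- t(M)
  }
  neg <- if (nonneg) which(M < 0, arr.ind = TRUE) else
    matrix(integer(0), 0, 2)
  if (nrow(neg) > 0)
    stop(sprintf(paste0("negative intensity at row %d, column %d: the ",
                        "factorization requires a non-negative input ",
                        "matrix"), neg[1, 1], neg[1, 2]), call. = FALSE)
  assert_spectral_grid(grid)
  assert_time_grid(times)
  if (length(grid) != nrow(M))
    stop("grid length does not match the matrix", call. = FALSE)
  list(M = M, spectral_grid = as.numeric(grid),
       time_grid = as.numeric(times))
}

#' Write a data matrix as delimited text
#'
#' Inverse of [read_matrix()]: tab-separated, header row of time values,
#' first column the wavenumber grid.  Values are written with 17
#' significant digits, so a read/write round trip is bit-exact for
#' doubles.
#'
#' @param M numeric matrix (rows = wavenumbers).
#' @param spectral_grid,time_grid the matching grids.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, spectral_grid, time_grid, path) {
  assert_matrix(M)
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("wavenumber", fmt(time_grid)), collapse = "\t"), con)
  body <- cbind(fmt(spectral_grid),
                matrix(fmt(M), nrow = nrow(M)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a synthetic dataset with its ground truth
#'
#' Writes `matrix.tsv` (the observed matrix), `W_true.tsv` and
#' `chi_true.tsv` (ground-truth factors, same dialect, with component
#' indices standing in for the missing grid) and `scenario.yaml`
#' describing the generating configuration, into `dir`.
#'
#' @param dataset an `"nmf_dataset"` from [assemble_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "nmf_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(dataset$M, dataset$spectral_grid, dataset$time_grid,
               file.path(dir, "matrix.tsv"))
  write_matrix(dataset$W_true, dataset$spectral_grid,
               seq_len(ncol(dataset$W_true)), file.path(dir, "W_true.tsv"))
  write_matrix(t(dataset$chi_true), dataset$time_grid,
               seq_len(nrow(dataset$chi_true)),
               file.path(dir, "chi_true.tsv"))
  meta <- list(scenario = dataset$scenario$name,
               variant = dataset$scenario$variant,
               species = dataset$species,
               rate_constants = as.list(dataset$scenario$rate_constants),
               noise_sigma = dataset$noise_sigma, seed = dataset$seed)
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(meta), file.path(dir, "scenario.yaml"))
  } else {
    jsonlite::write_json(meta, file.path(dir, "scenario.json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Write a JSON run report
#'
#' Serializes everything needed to audit and replay a factorization run:
#' the configuration echo (rank, restarts, seed, penalty settings), the
#' singular values, the penalty breakdown at the optimum, the per-restart
#' log and the package version.
#'
#' @param fit an `"nmf_fit"` (or `"nmf_refined"`).
#' @param path output file path.
#' @param extra optional named list merged into the report (e.g. input
#'   path).
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, extra = list()) {
  stopifnot(inherits(fit, "nmf_fit"))
  report <- list(
    tool = "specnmf",
    version = as.character(packageVersion("specnmf")),
    config = list(rank = fit$r, restarts = length(fit$restart_log),
                  seed = fit$seed,
                  overlap_weight = fit$cfg$overlap_weight,
                  overlap_mode = fit$cfg$overlap_mode,
                  condition_cap = fit$cfg$condition_cap),
    singular_values = if (!is.null(fit$init))
      fit$init$singular_values else NULL,
    objective = fit$objective,
    penalties = as.list(fit$penalties),
    A = fit$A,
    restart_log = fit$restart_log,
    running_best = fit$running_best)
  if (inherits(fit, "nmf_refined"))
    report$refinement <- list(objective = fit$refine_objective,
                              objective_start = fit$refine_objective_start)
  report <- modifyList(report, extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
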