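# On-disk formats: dense TSV and upper-triangle COO text for matrices,
# BED-like text for partitions, YAML for pipeline configuration. All
# coordinates on disk are 0-based (half-open for intervals).

#' Write a matrix to disk
#'
#' Two plain-text dialects are supported: `"tsv"` (dense, header row of
#' 0-based bin indices) and `"coo"` (three tab-separated columns `i`, `j`,
#' `value`; 0-based; upper triangle including the diagonal only; nonzero
#' cells only; sorted by `i` then `j`). Values are written with 15
#' significant digits, so stochastic matrices round-trip to within `1e-12`
#' and integer counts exactly.
#'
#' @param M Symmetric numeric matrix.
#' @param path Output file path.
#' @param format `"tsv"` or `"coo"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path, format = c("tsv", "coo")) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  format <- match.arg(format)
  N <- nrow(M)
  if (format == "tsv") {
    df <- as.data.frame(M)
    names(df) <- as.character(seq_len(N) - 1L)
    readr::write_tsv(df, path, num_threads = 1)
  } else {
    keep <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    df <- tibble::tibble(
      i = keep[, 1L] - 1L, j = keep[, 2L] - 1L,
      value = M[keep]
    )
    df <- df[order(df$i, df$j), ]
    readr::write_tsv(df, path, num_threads = 1)
  }
  invisible(path)
}

#' Read a matrix from disk
#'
#' Inverse of [write_matrix()]. Dense input is validated for symmetry (max
#' absolute asymmetry at most `1e-9`) and symmetrized by averaging; COO input
#' stores the upper triangle and is mirrored, so symmetry is structural.
#' Negative values are rejected.
#'
#' @param path Input file path.
#' @param format `"tsv"` or `"coo"`.
#' @param n Locus count for COO input; inferred as `max(i, j) + 1` when
#'   omitted.
#' @return A symmetric numeric matrix.
#' @export
read_matrix <- function(path, format = c("tsv", "coo"), n = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "d"),
                          progress = FALSE, num_threads = 1)
    M <- unname(as.matrix(df))
    if (nrow(M) != ncol(M)) {
      stop("parse failure: dense matrix in ", path, " is not square",
           call. = FALSE)
    }
    if (any(M < 0)) stop("negative values in ", path, call. = FALSE)
    asym <- max(abs(M - t(M)))
    if (asym > 1e-9) {
      stop("matrix in ", path, " is asymmetric beyond tolerance (max |M - t(M)| = ",
           format(asym), ")", call. = FALSE)
    }
    return((M + t(M)) / 2)
  }
  df <- readr::read_tsv(path, col_types = "iid", progress = FALSE,
                        num_threads = 1)
  if (!all(c("i", "j", "value") %in% names(df))) {
    stop("parse failure: COO file ", path, " needs columns i, j, value",
         call. = FALSE)
  }
  if (any(df$value < 0)) stop("negative values in ", path, call. = FALSE)
  if (any(df$j < df$i)) {
    stop("COO file ", path, " must store the upper triangle only (i <= j)",
         call. = FALSE)
  }
  if (is.null(n)) n <- max(df$i, df$j) + 1L
  M <- matrix(0, n, n)
  M[cbind(df$i + 1L, df$j + 1L)] <- df$value
  M[cbind(df$j + 1L, df$i + 1L)] <- df$value
  M
}

#' Write a domain partition as BED-like text
#'
#' Four tab-separated columns with a header: `chrom` (a placeholder bin
#' label), 0-based half-open `start` and `end`, and `kind`
#' (`domain`/`gap`).
#'
#' @param p A [tad_partition].
#' @param path Output file path.
#' @param chrom Placeholder chromosome label.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path, chrom = "bin") {
  stopifnot(inherits(p, "tad_partition"))
  df <- tibble::tibble(chrom = chrom, start = p$start, end = p$end,
                       kind = p$kind)
  readr::write_tsv(df, path, num_threads = 1)
  invisible(path)
}

#' Read a domain partition from BED-like text
#'
#' @param path File written by [write_partition()].
#' @return A [tad_partition] (N taken as the final `end`).
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = "ciic", progress = FALSE,
                        num_threads = 1)
  tad_partition(df$start, df$end, df$kind, N = max(df$end))
}

#' Assemble a pipeline configuration
#'
#' Materializes every stage parameter — generator specs, KR tolerance,
#' smoothing grids, replicate count, seed, matrix dialect — into one object
#' that round-trips losslessly through YAML, so a run is fully described by
#' its config file (no hidden defaults).
#'
#' @param seed Master integer seed.
#' @param format Matrix dialect, `"tsv"` or `"coo"`.
#' @param ideal Optional [ideal_spec()].
#' @param biophysical Optional [biophysical_spec()].
#' @param kr_tol,kr_max_iter Balancing tolerance and iteration cap.
#' @param s_steps,alphas Smoothing grids.
#' @param n_reps Replicates for the study drivers.
#' @param rate Subsampling rate for the Study 3 design.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, format = c("tsv", "coo"),
                            ideal = NULL, biophysical = NULL,
                            kr_tol = 1e-6, kr_max_iter = 1000L,
                            s_steps = c(2, 3, 4, 5, 10),
                            alphas = c(0.05, 0.1, 0.2, 0.5),
                            n_reps = 100L, rate = 0.1) {
  format <- match.arg(format)
  if (!is.null(ideal)) stopifnot(inherits(ideal, "ideal_spec"))
  if (!is.null(biophysical)) stopifnot(inherits(biophysical, "biophysical_spec"))
  structure(
    list(seed = as.integer(seed), format = format,
         ideal = if (!is.null(ideal)) unclass(ideal),
         biophysical = if (!is.null(biophysical)) unclass(biophysical),
         kr_tol = kr_tol, kr_max_iter = as.integer(kr_max_iter),
         s_steps = as.integer(s_steps), alphas = alphas,
         n_reps = as.integer(n_reps), rate = rate),
    class = "pipeline_config"
  )
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path File written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  pipeline_config(
    seed = raw$seed, format = raw$format,
    ideal = if (!is.null(raw$ideal)) do.call(ideal_spec, raw$ideal),
    biophysical = if (!is.null(raw$biophysical)) {
      do.call(biophysical_spec, raw$biophysical)
    },
    kr_tol = raw$kr_tol, kr_max_iter = raw$kr_max_iter,
    s_steps = raw$s_steps, alphas = raw$alphas,
    n_reps = raw$n_reps, rate = raw$rate
  )
}
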