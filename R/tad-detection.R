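# Domain partitions and the built-in TAD callers: an insulation-style
# boundary detector, the degenerate consecutive-pair caller, and the trivial
# single-domain caller. External callers can be plugged in as any function
# taking a matrix and returning a `tad_partition`.

#' Construct a domain partition
#'
#' A `tad_partition` is a tibble of ordered contiguous segments with 0-based
#' half-open bin intervals `[start, end)` and a `kind` of `"domain"` or
#' `"gap"`. Segments must tile `[0, N)` exactly, in order, without overlap,
#' and be non-empty.
#'
#' @param start,end Integer vectors of 0-based half-open segment bounds.
#' @param kind Character vector, each `"domain"` or `"gap"`.
#' @param N Total locus count; must equal the last `end`.
#' @return A tibble of class `tad_partition` with attribute `N`.
#' @examples
#' tad_partition(c(0, 4), c(4, 8), c("domain", "domain"), N = 8)
#' @export
tad_partition <- function(start, end, kind, N) {
  stopifnot(length(start) == length(end), length(kind) == length(start),
            length(start) >= 1L)
  start <- as.integer(start)
  end <- as.integer(end)
  if (!all(kind %in% c("domain", "gap"))) {
    stop("`kind` entries must be \"domain\" or \"gap\"", call. = FALSE)
  }
  if (start[1L] != 0L || end[length(end)] != N ||
      any(end <= start) ||
      (length(start) > 1L && any(start[-1L] != end[-length(end)]))) {
    stop("segments must tile [0, N) exactly: contiguous, ordered, non-empty",
         call. = FALSE)
  }
  out <- tibble::tibble(start = start, end = end, kind = kind)
  attr(out, "N") <- as.integer(N)
  class(out) <- c("tad_partition", class(out))
  out
}

#' @export
print.tad_partition <- function(x, ...) {
  cat("<tad_partition> N =", attr(x, "N"), "|",
      sum(x$kind == "domain"), "domain(s),",
      sum(x$kind == "gap"), "gap(s)\n")
  NextMethod()
}

#' Number of loci covered by a partition
#' @param p A [tad_partition].
#' @return Integer locus count `N`.
#' @export
n_loci <- function(p) {
  stopifnot(inherits(p, "tad_partition"))
  attr(p, "N")
}

# Turn accepted interior boundaries (0-based cut positions) into a partition,
# flagging segments shorter than `min_domain` as gaps.
boundaries_to_partition <- function(cuts, N, min_domain) {
  edges <- c(0L, as.integer(cuts), N)
  width <- diff(edges)
  tad_partition(
    start = edges[-length(edges)], end = edges[-1L],
    kind = ifelse(width < min_domain, "gap", "domain"), N = N
  )
}

#' Insulation-style TAD caller
#'
#' For each interior boundary `b` in `1..N-1` (0-based), the insulation
#' signal is the mean of the `w x w` submatrix spanning the boundary
#' (rows `b-w..b-1`, columns `b..b+w-1`, truncated at the matrix edges). A
#' boundary is called where the signal is a strict local minimum whose value
#' lies below the profile mean minus one profile standard deviation. Segments
#' between accepted boundaries shorter than `min_domain` are emitted as gaps.
#' The caller is invariant to positive rescaling of `M`, so it applies
#' equally to raw counts and normalized or smoothed matrices.
#'
#' @param M Symmetric numeric matrix with `N > 2 * window`.
#' @param window Insulation window size `w` in bins (`>= 1`, `< N/2`).
#' @param min_domain Minimum domain width in bins; shorter intervals become
#'   gaps.
#' @return A [tad_partition] tiling `[0, N)`.
#' @export
insulation_caller <- function(M, window = 5L, min_domain = 3L) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    stop("`M` must be symmetric", call. = FALSE)
  }
  N <- nrow(M)
  w <- as.integer(window)
  if (w < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (w >= N / 2) stop("`window` must be smaller than N/2", call. = FALSE)

  signal <- vapply(seq_len(N - 1L), function(b) {
    rows <- max(1L, b - w + 1L):b
    cols <- (b + 1L):min(N, b + w)
    mean(M[rows, cols, drop = FALSE])
  }, numeric(1))

  lo <- c(Inf, signal[-length(signal)]) # left neighbor (Inf at edge)
  hi <- c(signal[-1L], Inf)             # right neighbor
  local_min <- signal < lo & signal < hi
  threshold <- mean(signal) - stats::sd(signal)
  accepted <- which(local_min & signal < threshold)
  boundaries_to_partition(accepted, N, as.integer(min_domain))
}

#' Degenerate consecutive-pair caller
#'
#' Partitions `[0, N)` into consecutive width-2 domains (the failure mode in
#' which a caller labels every pair of adjacent loci a domain). For odd `N`
#' the final width-1 segment is emitted as a domain.
#'
#' @param N Locus count, `>= 2` (N = 1 yields the single width-1 domain).
#' @return A [tad_partition] with `ceiling(N / 2)` domains.
#' @export
pair_caller <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  start <- seq.int(0L, N - 1L, by = 2L)
  end <- pmin(start + 2L, N)
  tad_partition(start, end, rep("domain", length(start)), N)
}

#' Single-domain caller
#'
#' Lumps all loci into one domain covering `[0, N)` — the degenerate output
#' of a caller that finds no structure. Its adjusted Rand index against any
#' non-trivial partition is 0.
#'
#' @param N Locus count, `>= 1`.
#' @return A [tad_partition] with one domain.
#' @export
single_domain_caller <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  tad_partition(0L, N, "domain", N)
}

#' Built-in caller set for the evaluation studies
#'
#' Convenience constructor for the named list of callers the study drivers
#' expect: functions taking a matrix and returning a [tad_partition].
#'
#' @param window,min_domain Parameters forwarded to [insulation_caller()].
#' @param include_degenerate Also include the consecutive-pair and
#'   single-domain callers (useful for reproducing degenerate baselines).
#' @return Named list of caller functions.
#' @export
default_callers <- function(window = 5L, min_domain = 3L,
                            include_degenerate = FALSE) {
  callers <- list(
    insulation = function(M) insulation_caller(M, window, min_domain)
  )
  if (include_degenerate) {
    callers$pairs <- function(M) pair_caller(nrow(M))
    callers$single <- function(M) single_domain_caller(nrow(M))
  }
  callers
}
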