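# Generators for every input the pipeline consumes: idealized TPMs with TAD
# blocks, biophysical-law count matrices with known domains, and multinomially
# subsampled "single-cell-like" matrices. All randomness is controlled through
# an explicit `seed` argument (the global RNG state is left untouched).

#' Build the idealized doubly stochastic TPM with TAD blocks
#'
#' Constructs the symmetric doubly stochastic matrix with `k` diagonal blocks:
#' all entries within block `i` (diagonal included) equal
#' `(1 - (N - n_i) d) / n_i` and all between-block entries equal `d`. The true
#' domain partition is attached as attribute `"truth"`.
#'
#' @param spec An [ideal_spec()].
#' @return An `N x N` numeric matrix with a [tad_partition] in
#'   `attr(, "truth")`.
#' @examples
#' P <- make_ideal_tpm(ideal_spec(200, c(50, 30, 20, 90, 10), d = 0.0025))
#' range(rowSums(P)) # both 1
#' @export
make_ideal_tpm <- function(spec) {
  stopifnot(inherits(spec, "ideal_spec"))
  N <- spec$N
  sizes <- spec$block_sizes
  P <- matrix(spec$d, N, N)
  offs <- cumsum(c(0L, sizes))
  for (i in seq_along(sizes)) {
    idx <- (offs[i] + 1L):offs[i + 1L]
    P[idx, idx] <- (1 - (N - sizes[i]) * spec$d) / sizes[i]
  }
  attr(P, "truth") <- tad_partition(
    start = offs[-length(offs)], end = offs[-1L],
    kind = rep("domain", length(sizes)), N = N
  )
  P
}

#' Extract the true domain partition attached to a generated matrix
#'
#' @param M A matrix produced by [make_ideal_tpm()], [simulate_biophysical()]
#'   or [subsample_counts()].
#' @return The attached [tad_partition], or `NULL` if none.
#' @export
true_partition <- function(M) attr(M, "truth")

# Run `expr` under `seed` when given, without touching the caller's RNG.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Mirror the upper triangle (diagonal included) onto the lower triangle.
mirror_upper <- function(U) {
  U[lower.tri(U)] <- t(U)[lower.tri(U)]
  U
}

#' Add symmetric uniform observation noise to a matrix
#'
#' Draws i.i.d. `Unif(0, high)` noise on the upper triangle (diagonal
#' included), mirrors it onto the lower triangle, and adds it to `P`. The
#' result is symmetric and entrywise at least `P`, but no longer stochastic;
#' re-normalization (e.g. [kr_normalize()]) is the next pipeline stage's job.
#'
#' @param P A symmetric numeric matrix.
#' @param high Upper bound of the uniform noise (non-negative).
#' @param seed Optional integer seed; fixed seeds give bitwise-identical
#'   output.
#' @return A symmetric numeric matrix `P + R`.
#' @export
add_symmetric_noise <- function(P, high = 0.02, seed = NULL) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (!is.numeric(high) || length(high) != 1L || high < 0) {
    stop("`high` must be a single non-negative number", call. = FALSE)
  }
  N <- nrow(P)
  R <- with_seed_if(seed, {
    up <- matrix(0, N, N)
    ut <- upper.tri(up, diag = TRUE)
    up[ut] <- stats::runif(sum(ut), min = 0, max = high)
    mirror_upper(up)
  })
  out <- P + R
  attr(out, "truth") <- attr(P, "truth")
  out
}

#' Simulate a Hi-C count matrix under the power-decay generative model
#'
#' Generates an observed contact matrix `E` in five stages, working on the
#' upper triangle (diagonal included) and mirroring for symmetry:
#' \enumerate{
#'   \item Expected matrix `A` with `A_ij = exp(c + d_exp log(j - i))` for
#'     `i < j` and `A_ii = exp(c1)`.
#'   \item Background `B` with `B_ij ~ NegBin(mean = A_ij, var = z A_ij)`,
#'     parameterized as `size = A_ij / (z - 1)`, `prob = 1/z`.
#'   \item A uniformly random partition of the `N` loci into `k` contiguous
#'     blocks (the true domains), via `k - 1` distinct interior cut points.
#'   \item Domain effect `D_ij ~ Poisson(lambda_b B_ij)` for cells inside
#'     block `b` (with `lambda_b ~ Unif(lambda_low, lambda_high)` drawn once
#'     per block), zero elsewhere; `E_tilde = B + D`.
#'   \item Structured zeros: a uniformly random `pi1` fraction of
#'     within-domain upper-triangle cells and a `pi2` fraction of
#'     outside-domain cells are set to zero.
#' }
#'
#' @param spec A [biophysical_spec()].
#' @param seed Optional integer seed (bitwise reproducibility).
#' @return An integer `N x N` symmetric count matrix with the true
#'   [tad_partition] in `attr(, "truth")`.
#' @export
simulate_biophysical <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "biophysical_spec"))
  N <- spec$N
  k <- spec$k

  ii <- row(diag(N))[upper.tri(diag(N), diag = TRUE)]
  jj <- col(diag(N))[upper.tri(diag(N), diag = TRUE)]
  A <- ifelse(jj > ii, exp(spec$c + spec$d_exp * log(jj - ii)), exp(spec$c1))

  with_seed_if(seed, {
    B <- stats::rnbinom(length(A), mu = A, size = A / (spec$z - 1))

    cuts <- if (k > 1L) sort(sample.int(N - 1L, k - 1L)) else integer(0)
    starts <- c(0L, cuts)
    ends <- c(cuts, N)
    block_of <- rep.int(seq_len(k), ends - starts) # block id of each locus

    lambda <- stats::runif(k, spec$lambda_low, spec$lambda_high)
    within <- block_of[ii] == block_of[jj]
    D <- integer(length(B))
    D[within] <- stats::rpois(sum(within),
                              lambda[block_of[ii[within]]] * B[within])
    E <- B + D
    stopifnot(all(E >= 0), all(E == round(E)))

    n_in <- sum(within)
    n_out <- length(E) - n_in
    drop_in <- sample(which(within), round(spec$pi1 * n_in))
    drop_out <- sample(which(!within), round(spec$pi2 * n_out))
    E[c(drop_in, drop_out)] <- 0L

    M <- matrix(0L, N, N)
    M[upper.tri(M, diag = TRUE)] <- as.integer(E)
    M <- mirror_upper(M)
    attr(M, "truth") <- tad_partition(
      start = starts, end = ends, kind = rep("domain", k), N = N
    )
    M
  })
}

#' Multinomially subsample a contact matrix to emulate shallow sequencing
#'
#' Draws `round(rate * total)` contacts (where `total` is the sum over the
#' upper triangle, diagonal included) from a multinomial distribution over
#' upper-triangle cells with probabilities proportional to the observed
#' counts, then mirrors for symmetry. With replacement, so individual cells
#' may exceed their original count, but the upper-triangle total is exact and
#' no contact lands where the input is zero.
#'
#' @param M Symmetric non-negative integer matrix with a positive total.
#' @param rate Sampling rate in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return An integer symmetric matrix; any `attr(M, "truth")` is carried
#'   over.
#' @export
subsample_counts <- function(M, rate, seed = NULL) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), all(M >= 0))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate > 1) {
    stop("`rate` must lie in (0, 1]", call. = FALSE)
  }
  ut <- upper.tri(M, diag = TRUE)
  w <- M[ut]
  total <- sum(w)
  if (total <= 0) stop("`M` has no contacts to subsample", call. = FALSE)
  size <- round(rate * total)
  drawn <- with_seed_if(seed, stats::rmultinom(1L, size = size, prob = w)[, 1L])
  out <- matrix(0L, nrow(M), ncol(M))
  out[ut] <- as.integer(drawn)
  out <- mirror_upper(out)
  attr(out, "truth") <- attr(M, "truth")
  out
}
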