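#' Specification of an idealized block transition probability matrix
#'
#' Bundles the parameters of the idealized doubly stochastic Hi-C transition
#' probability matrix (TPM) with `k` diagonal TAD blocks: `N` loci split into
#' contiguous blocks of sizes `n_1, ..., n_k`, a constant between-block
#' transition probability `d`, and within-block entries
#' `(1 - (N - n_i) d) / n_i` so that every row and column sums to one.
#'
#' @param N Total number of loci (positive integer).
#' @param block_sizes Integer vector of block (TAD) sizes `n_1..n_k`; must sum
#'   to `N`.
#' @param d Between-block transition probability, a single non-negative number.
#'   Must be small enough that every within-block entry
#'   `(1 - (N - n_i) d) / n_i` is non-negative.
#' @param noise_high Upper bound of the uniform observation noise added by
#'   [add_symmetric_noise()] in the idealized study; non-negative.
#'
#' @return An object of class `ideal_spec`.
#' @seealso [make_ideal_tpm()], [rwr_limit_ideal()]
#' @examples
#' ideal_spec(200, c(50, 30, 20, 90, 10), d = 1 / 400)
#' @export
ideal_spec <- function(N, block_sizes, d = 0, noise_high = 0.02) {
  stopifnot(
    is.numeric(N), length(N) == 1L, N >= 1, N == round(N),
    is.numeric(block_sizes), length(block_sizes) >= 1L,
    all(block_sizes >= 1), all(block_sizes == round(block_sizes)),
    is.numeric(d), length(d) == 1L, d >= 0,
    is.numeric(noise_high), length(noise_high) == 1L, noise_high >= 0
  )
  if (sum(block_sizes) != N) {
    stop("`block_sizes` must sum to `N` (got ", sum(block_sizes),
         " != ", N, ")", call. = FALSE)
  }
  diag_mass <- 1 - (N - block_sizes) * d
  if (any(diag_mass < 0)) {
    stop("`d` too large: within-block entry (1 - (N - n_i) d)/n_i negative ",
         "for block(s) ", paste(which(diag_mass < 0), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(N = as.integer(N), block_sizes = as.integer(block_sizes),
         d = d, noise_high = noise_high),
    class = "ideal_spec"
  )
}

#' @export
print.ideal_spec <- function(x, ...) {
  cat("<ideal_spec> N =", x$N, "| blocks:",
      paste(x$block_sizes, collapse = ", "),
      "| d =", format(x$d), "| noise_high =", format(x$noise_high), "\n")
  invisible(x)
}

#' Specification of the biophysical-law count-matrix generator
#'
#' Parameters of the generative model for realistic Hi-C contact matrices with
#' known domain structure. The expected background follows the power-decay law
#' `log A_ij = c + d_exp * log(j - i)` for `i < j` (natural logs) with
#' `log A_ii = c1`; counts are drawn from an over-dispersed negative binomial
#' with mean `A_ij` and variance `z * A_ij`; a Poisson domain effect with
#' block-level intensity `lambda_b ~ Unif(lambda_low, lambda_high)` is added
#' inside `k` random contiguous blocks; structured zeros are then introduced at
#' rate `pi1` inside domains and `pi2` outside.
#'
#' @param N Number of loci.
#' @param c Background log-intensity intercept (natural log scale).
#' @param c1 Diagonal log-intensity; must satisfy `c1 >= c`.
#' @param d_exp Power-decay exponent (negative).
#' @param z Variance inflation factor, strictly greater than 1.
#' @param k Number of domains (contiguous blocks).
#' @param lambda_low,lambda_high Bounds of the uniform distribution of the
#'   per-block domain effect; `0 < lambda_low <= lambda_high`.
#' @param pi1 Fraction of within-domain upper-triangle cells set to zero.
#' @param pi2 Fraction of outside-domain upper-triangle cells set to zero.
#'
#' @details Defaults reproduce the simulation's operating point:
#' `N = 1000`, `c = c1 = log(20)`, `d_exp = -0.4`, `z = 1.2`, `k = 20`,
#' `lambda ~ Unif(0.5, 1)`, `pi1 = 0.1`, `pi2 = 0.2`.
#'
#' @return An object of class `biophysical_spec`.
#' @seealso [simulate_biophysical()]
#' @export
biophysical_spec <- function(N = 1000, c = log(20), c1 = c, d_exp = -0.4,
                             z = 1.2, k = 20, lambda_low = 0.5,
                             lambda_high = 1, pi1 = 0.1, pi2 = 0.2) {
  stopifnot(
    is.numeric(N), length(N) == 1L, N >= 2, N == round(N),
    is.numeric(c), length(c) == 1L,
    is.numeric(c1), length(c1) == 1L,
    is.numeric(d_exp), length(d_exp) == 1L, d_exp < 0,
    is.numeric(z), length(z) == 1L,
    is.numeric(k), length(k) == 1L, k >= 1, k == round(k),
    is.numeric(lambda_low), is.numeric(lambda_high),
    is.numeric(pi1), is.numeric(pi2)
  )
  if (c1 < c) stop("`c1` must be at least `c`", call. = FALSE)
  if (z <= 1) {
    stop("`z` must be strictly greater than 1 (over-dispersed counts); ",
         "z = 1 (Poisson) is not supported", call. = FALSE)
  }
  if (!(lambda_low > 0 && lambda_low <= lambda_high)) {
    stop("need 0 < lambda_low <= lambda_high", call. = FALSE)
  }
  if (pi1 < 0 || pi1 > 1 || pi2 < 0 || pi2 > 1) {
    stop("`pi1` and `pi2` must lie in [0, 1]", call. = FALSE)
  }
  if (k > N) stop("`k` cannot exceed `N`", call. = FALSE)
  structure(
    list(N = as.integer(N), c = c, c1 = c1, d_exp = d_exp, z = z,
         k = as.integer(k), lambda_low = lambda_low,
         lambda_high = lambda_high, pi1 = pi1, pi2 = pi2),
    class = "biophysical_spec"
  )
}

#' @export
print.biophysical_spec <- function(x, ...) {
  cat("<biophysical_spec> N =", x$N, "| k =", x$k,
      "| c =", format(x$c), "| c1 =", format(x$c1),
      "| d_exp =", format(x$d_exp), "| z =", format(x$z), "\n",
      " lambda ~ Unif(", x$lambda_low, ",", x$lambda_high,
      ") | pi1 =", x$pi1, "| pi2 =", x$pi2, "\n")
  invisible(x)
}
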