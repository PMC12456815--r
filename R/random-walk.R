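# RWS and RWR smoothing of doubly stochastic transition probability matrices,
# including the closed-form limiting matrices.

check_tpm <- function(P, arg = "P", tol = 1e-6) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(P - t(P))) > 1e-8) {
    stop("`", arg, "` must be symmetric", call. = FALSE)
  }
  dev <- max(abs(rowSums(P) - 1))
  if (dev > tol) {
    stop("`", arg, "` is not stochastic: max row-sum deviation ",
         format(dev), " exceeds ", format(tol), call. = FALSE)
  }
  invisible(P)
}

# Matrix power by repeated squaring; s >= 1.
mat_power <- function(P, s) {
  R <- NULL
  B <- P
  while (s > 0) {
    if (s %% 2 == 1) R <- if (is.null(R)) B else R %*% B
    s <- s %/% 2
    if (s > 0) B <- B %*% B
  }
  R
}

#' Random-walk smoothing with a finite number of steps (RWS)
#'
#' Returns the `s`-step transition probability matrix `P^s`. Powers of a
#' symmetric doubly stochastic matrix remain symmetric and doubly stochastic;
#' as `s` grows the power converges to the rank-one matrix `J/N` whenever the
#' chain is irreducible, erasing any block (TAD) structure.
#'
#' @param P Symmetric doubly stochastic matrix (row sums within `1e-6` of 1).
#' @param s Number of steps, an integer `>= 1`.
#' @return The matrix `P^s` (numerically re-symmetrized).
#' @export
rws <- function(P, s) {
  check_tpm(P)
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != round(s)) {
    stop("`s` must be a single integer >= 1", call. = FALSE)
  }
  if (s == 1) return(P)
  R <- mat_power(P, as.integer(s))
  (R + t(R)) / 2
}

#' Random walk with restart: finite iterates
#'
#' Computes the `s`-th iterate of the restart recursion
#' `P(s) = (1 - alpha) P(s-1) P + alpha I`, starting from `P(0) = I`.
#' `alpha = 0` recovers plain RWS; `alpha = 1` returns the identity.
#'
#' @param P Symmetric doubly stochastic matrix.
#' @param alpha Restart probability in `[0, 1]`.
#' @param s Number of iterations, integer `>= 1`.
#' @return The iterate `P(s)`, symmetric with unit row sums.
#' @export
rwr_iterate <- function(P, alpha, s) {
  check_tpm(P)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != round(s)) {
    stop("`s` must be a single integer >= 1", call. = FALSE)
  }
  N <- nrow(P)
  I <- diag(N)
  X <- I
  for (step in seq_len(s)) {
    X <- (1 - alpha) * (X %*% P) + alpha * I
  }
  (X + t(X)) / 2
}

#' Closed-form limiting matrix of random walk with restart
#'
#' The fixed point of the restart recursion, `P* = alpha (I - (1-alpha) P)^-1`,
#' computed by a linear solve. For `alpha` in `(0, 1]` the resolvent exists
#' because the spectral radius of `(1-alpha) P` is `1 - alpha < 1`.
#'
#' @param P Symmetric doubly stochastic matrix.
#' @param alpha Restart probability in `(0, 1]`.
#' @return The limiting matrix `P*`, symmetric and doubly stochastic.
#' @export
rwr_limit <- function(P, alpha) {
  check_tpm(P)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  N <- nrow(P)
  X <- tryCatch(
    solve(diag(N) - (1 - alpha) * P, diag(alpha, N)),
    error = function(e) {
      stop("resolvent solve failed (numerically singular system): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  (X + t(X)) / 2
}

#' Closed-form RWR limit for the idealized block TPM
#'
#' For the idealized block TPM the restart limit has an explicit block form:
#' `alpha I_{n_i} + q_i J_{n_i}` on diagonal block `i` and constant
#' `q_{k+1}` between blocks, with
#' `q_i = (1 - alpha) (d + alpha (1 - N d) / n_i) / (alpha + (1 - alpha) N d)`
#' and `q_{k+1} = (1 - alpha) d / (alpha + (1 - alpha) N d)`. Rows sum to one
#' exactly in the algebra: `alpha + n_i q_i + (N - n_i) q_{k+1} = 1`. As
#' `alpha -> 0` all entries tend to `1/N`; as `alpha -> 1` the limit tends to
#' the identity.
#'
#' @param spec An [ideal_spec()].
#' @param alpha Restart probability strictly inside `(0, 1)`.
#' @return The limiting matrix built directly from the block formula; agrees
#'   with `rwr_limit(make_ideal_tpm(spec), alpha)` to within `1e-10`.
#' @export
rwr_limit_ideal <- function(spec, alpha) {
  stopifnot(inherits(spec, "ideal_spec"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  N <- spec$N
  sizes <- spec$block_sizes
  d <- spec$d
  denom <- alpha + (1 - alpha) * N * d
  q_out <- (1 - alpha) * d / denom
  P <- matrix(q_out, N, N)
  offs <- cumsum(c(0L, sizes))
  for (i in seq_along(sizes)) {
    idx <- (offs[i] + 1L):offs[i + 1L]
    q_i <- (1 - alpha) * (d + alpha * (1 - N * d) / sizes[i]) / denom
    P[idx, idx] <- q_i
  }
  diag(P) <- diag(P) + alpha
  attr(P, "truth") <- tad_partition(
    start = offs[-length(offs)], end = offs[-1L],
    kind = rep("domain", length(sizes)), N = N
  )
  P
}
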