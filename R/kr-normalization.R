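# Knight-Ruiz matrix balancing: turn a symmetric non-negative count matrix
# into a symmetric doubly stochastic transition probability matrix.

#' Repair all-zero rows before balancing
#'
#' A matrix with an all-zero row admits no positive diagonal balancing. For
#' every such row the diagonal entry is set to 1 (keeping the matrix
#' symmetric); all other entries are unchanged. Replacing rather than deleting
#' the rows avoids creating fictitious domains at the excised positions.
#'
#' @param M A symmetric numeric matrix.
#' @return `M` with unit diagonal entries in previously all-zero rows.
#' @export
repair_zero_rows <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  zero <- rowSums(M != 0) == 0L
  if (any(zero)) {
    idx <- which(zero)
    M[cbind(idx, idx)] <- 1
  }
  M
}

#' Knight-Ruiz balancing to a doubly stochastic matrix
#'
#' Finds a positive vector `x` such that `P = diag(x) M diag(x)` has all row
#' and column sums equal to 1, using the Knight-Ruiz inner-outer iteration:
#' an approximate Newton method whose inner linear systems are solved by
#' conjugate gradients, with iterates confined to a cone around the current
#' scaling. All-zero rows are repaired first (see [repair_zero_rows()]).
#' For a symmetric non-negative matrix with total support the balanced matrix
#' is unique, so any converged run is comparable across implementations.
#'
#' @param M Symmetric non-negative matrix (counts or intensities).
#' @param tol Convergence tolerance on the balancing residual, measured as the
#'   maximum absolute deviation of any row sum from 1.
#' @param max_iter Cap on outer (Newton) iterations. If reached, the best
#'   iterate is returned with `converged = FALSE` and a warning.
#' @return An object of class `kr_result`: a list with elements `matrix` (the
#'   balanced symmetric matrix), `scaling` (the positive vector `x`),
#'   `iterations`, `converged`, and `achieved_tol` (max row-sum deviation).
#' @examples
#' r <- kr_normalize(matrix(c(2, 1, 1, 2), 2))
#' r$matrix          # [[2/3, 1/3], [1/3, 2/3]]
#' r$scaling * sqrt(3) # both 1
#' @export
kr_normalize <- function(M, tol = 1e-6, max_iter = 1000L) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > 1e-8) {
    stop("`M` must be symmetric", call. = FALSE)
  }
  if (any(M < 0)) stop("`M` must be non-negative", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive", call. = FALSE)
  M <- repair_zero_rows(M)
  n <- nrow(M)

  # Inner-outer scheme; residual targets v = x * (M x) = 1 elementwise.
  delta <- 0.1
  Delta <- 3
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  x <- rep(1, n)
  rt <- tol^2
  v <- x * (M %*% x)[, 1L]
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  i <- 0L
  converged <- TRUE

  while (rout > rt) {
    if (i >= max_iter) {
      converged <- FALSE
      break
    }
    i <- i + 1L
    k <- 0L
    y <- rep(1, n)
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- numeric(n)
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        if (any(v <= 0)) {
          stop("matrix appears structurally unbalanceable ",
               "(zero pattern admits no positive scaling)", call. = FALSE)
        }
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * (M %*% (x * p))[, 1L] + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * (M %*% x)[, 1L]
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / max(res_norm, .Machine$double.eps))
  }

  P <- M * tcrossprod(x)
  P <- (P + t(P)) / 2
  achieved <- max(abs(rowSums(P) - 1))
  if (!converged) {
    warning("Knight-Ruiz balancing did not converge in ", max_iter,
            " outer iterations (residual ", format(achieved), ")",
            call. = FALSE)
  }
  structure(
    list(matrix = P, scaling = x, iterations = i, converged = converged,
         achieved_tol = achieved),
    class = "kr_result"
  )
}

#' @export
print.kr_result <- function(x, ...) {
  cat("<kr_result> N =", nrow(x$matrix),
      "| iterations =", x$iterations,
      "| converged =", x$converged,
      "| max row-sum deviation =", format(x$achieved_tol), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kr_result <- function(x, ...) {
  tibble::tibble(locus = seq_along(x$scaling) - 1L, scaling = x$scaling)
}

#' @exportS3Method generics::glance
glance.kr_result <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$matrix), iterations = x$iterations,
    converged = x$converged, achieved_tol = x$achieved_tol
  )
}
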