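ideal_s1 <- ideal_spec(200, c(50, 30, 20, 90, 10), d = 0.0025)

test_that("rws computes matrix powers and preserves double stochasticity", {
  P <- make_ideal_tpm(ideal_s1)
  expect_equal(rws(P, 1), P)

  P3 <- rws(P, 3)
  expect_equal(P3, P %*% P %*% P, ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(P3) - 1)), 1e-10)
  expect_lt(max(abs(P3 - t(P3))), 1e-12)

  # d = 0: each block is (1/n_i) J, so P is idempotent and P^s = P
  P0 <- make_ideal_tpm(ideal_spec(60, c(20, 40), d = 0))
  for (s in c(2, 5, 17)) {
    expect_equal(rws(P0, s), P0, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("rws rejects invalid steps and non-stochastic input", {
  P <- make_ideal_tpm(ideal_s1)
  expect_error(rws(P, 0), ">= 1")
  expect_error(rws(P, 2.5), ">= 1")
  expect_error(rws(P * 2, 2), "not stochastic")
  expect_error(rws(matrix(c(0.2, 0.8, 0.7, 0.3), 2), 2), "symmetric")
})

test_that("long RWS walks converge to the uniform matrix when d > 0", {
  P <- make_ideal_tpm(ideal_s1)
  P500 <- rws(P, 500)
  expect_lt(max(abs(P500 - 1 / 200)), 1e-6)
})

test_that("rwr_iterate matches its recursion anchors", {
  P <- make_ideal_tpm(ideal_spec(50, c(20, 30), d = 0.002))

  # alpha = 0 reduces to RWS
  for (s in c(1, 3, 7)) {
    expect_equal(rwr_iterate(P, 0, s), rws(P, s), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # alpha = 1 is a full restart: identity for every s
  expect_equal(rwr_iterate(P, 1, 5), diag(50))
  # first iterate from P(0) = I
  expect_equal(rwr_iterate(P, 0.3, 1), 0.7 * P + 0.3 * diag(50),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(rwr_iterate(P, -0.1, 2), "\\[0, 1\\]")
  expect_error(rwr_iterate(P, 1.1, 2), "\\[0, 1\\]")
})

test_that("rwr_limit is the fixed point of the restart recursion", {
  P <- make_ideal_tpm(ideal_spec(60, c(25, 35), d = 0.003))
  for (alpha in c(0.05, 0.2, 0.5)) {
    L <- rwr_limit(P, alpha)
    resid <- max(abs(L - ((1 - alpha) * L %*% P + alpha * diag(60))))
    expect_lt(resid, 1e-10)
    expect_lt(max(abs(rowSums(L) - 1)), 1e-10)
    expect_lt(max(abs(L - t(L))), 1e-12)
  }
  expect_equal(rwr_limit(P, 1), diag(60))
  expect_equal(rwr_limit(diag(10), 0.3), diag(10))
  expect_error(rwr_limit(P, 0), "\\(0, 1\\]")
})

test_that("rwr_limit agrees with iteration run to convergence", {
  P <- make_ideal_tpm(ideal_spec(40, c(15, 25), d = 0.004))
  alpha <- 0.1
  X <- diag(40)
  repeat {
    Xn <- (1 - alpha) * X %*% P + alpha * diag(40)
    if (max(abs(Xn - X)) < 1e-12) break
    X <- Xn
  }
  expect_lt(max(abs(rwr_limit(P, alpha) - X)), 1e-8)
})

test_that("rwr_limit_ideal evaluates the closed-form block formula", {
  # hand-evaluated: denom = 0.1 + 0.9 * 0.5 = 0.55,
  # q_out = 0.9 * 0.0025 / 0.55, q_1 = 0.9 * (0.0025 + 0.1 * 0.5 / 50) / 0.55
  L <- rwr_limit_ideal(ideal_s1, alpha = 0.1)
  expect_equal(L[1, 60], 0.9 * 0.0025 / 0.55)          # ~0.0040909
  expect_equal(L[1, 2], 0.9 * 0.0035 / 0.55)           # ~0.0057273
  expect_equal(L[1, 1], 0.1 + 0.9 * 0.0035 / 0.55)     # ~0.1057273
  expect_lt(max(abs(rowSums(L) - 1)), 1e-12)

  expect_error(rwr_limit_ideal(ideal_s1, 0), "strictly inside")
  expect_error(rwr_limit_ideal(ideal_s1, 1), "strictly inside")
})

test_that("closed-form ideal limit matches the resolvent on a parameter grid", {
  grid <- list(
    list(spec = ideal_s1, alphas = c(0.05, 0.1, 0.2, 0.5)),
    list(spec = ideal_spec(80, c(30, 50), d = 0.001), alphas = c(0.1, 0.7)),
    list(spec = ideal_spec(90, c(30, 30, 30), d = 0), alphas = c(0.3))
  )
  for (g in grid) {
    P <- make_ideal_tpm(g$spec)
    for (alpha in g$alphas) {
      expect_lt(max(abs(rwr_limit_ideal(g$spec, alpha) - rwr_limit(P, alpha))),
                1e-10)
    }
  }
})

test_that("ideal limit entries interpolate between uniform (alpha -> 0) and identity (alpha -> 1)", {
  L0 <- rwr_limit_ideal(ideal_s1, alpha = 1e-9)
  expect_lt(max(abs(L0 - 1 / 200)[upper.tri(L0)]), 1e-6) # all entries -> 1/N

  L1 <- rwr_limit_ideal(ideal_s1, alpha = 1 - 1e-9)
  expect_lt(max(abs(L1 - diag(200))), 1e-8)
})

test_that("RWR limit diagonals dominate every off-diagonal entry", {
  for (alpha in c(0.05, 0.1, 0.2, 0.5)) {
    L <- rwr_limit_ideal(ideal_s1, alpha)
    off <- L
    diag(off) <- -Inf
    expect_gt(min(diag(L)), max(off))
  }
})

test_that("rwr_iterate converges monotonically to the limit at geometric rate", {
  P <- make_ideal_tpm(ideal_spec(60, c(20, 40), d = 0.002))
  alpha <- 0.2
  L <- rwr_limit(P, alpha)
  dists <- vapply(1:10, function(s) max(abs(rwr_iterate(P, alpha, s) - L)),
                  numeric(1))
  expect_true(all(diff(dists) <= 1e-14))
  ratios <- dists[-1] / dists[-length(dists)]
  expect_true(all(ratios <= (1 - alpha) + 1e-8))
})

test_that("RWS erodes the within- vs between-block contrast monotonically toward zero", {
  P <- make_ideal_tpm(ideal_s1)
  truth <- true_partition(P)
  block_of <- rep(seq_len(nrow(truth)), truth$end - truth$start)
  within <- outer(block_of, block_of, "==")
  gaps <- vapply(1:10, function(s) {
    Ps <- rws(P, s)
    min(Ps[within]) - max(Ps[!within])
  }, numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[10], gaps[1] / 2)
})
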