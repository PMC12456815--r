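test_that("partition_to_labels applies the documented gap rules", {
  p <- tad_partition(c(0, 4), c(4, 8), c("domain", "domain"), N = 8)
  expect_equal(partition_to_labels(p), rep(1:2, each = 4))

  expect_equal(partition_to_labels(single_domain_caller(5)), rep(1L, 5))

  pg <- tad_partition(c(0, 2, 3), c(2, 3, 5), c("domain", "gap", "domain"), 5)
  expect_equal(partition_to_labels(pg), c(1L, 1L, 2L, 3L, 3L))

  # two adjacent gap segments collapse into one run under the default rule
  pgg <- tad_partition(c(0, 2, 3, 4), c(2, 3, 4, 6),
                       c("domain", "gap", "gap", "domain"), 6)
  expect_equal(partition_to_labels(pgg, "run"), c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(partition_to_labels(pgg, "singleton"), c(1L, 1L, 2L, 3L, 4L, 4L))

  # pooled: all gap loci share one cluster
  p2g <- tad_partition(c(0, 2, 3, 5), c(2, 3, 5, 6),
                       c("domain", "gap", "domain", "gap"), 6)
  lab <- partition_to_labels(p2g, "pooled")
  expect_equal(lab[3], lab[6])
  expect_equal(length(unique(lab)), 3L)
})

test_that("adjusted_rand_index anchors: identity, independence, degeneracy", {
  a <- rep(1:4, each = 5)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, 5 - a), 1) # invariant to relabeling

  # single cluster vs anything non-trivial is 0
  expect_equal(adjusted_rand_index(rep(1, 20), a), 0)

  # both trivial single clusters: degenerate 0/0 defined as 1
  expect_equal(adjusted_rand_index(rep(1, 10), rep(2, 10)), 1)
  # both all-singletons (identical partitions): also 1
  expect_equal(adjusted_rand_index(1:10, 10:1), 1)

  expect_error(adjusted_rand_index(1:4, 1:5), "same length")
})

test_that("adjusted_rand_index matches brute-force pair counting and mclust on random partitions", {
  skip_if_not_installed("mclust")
  for (seed in 1:200) {
    n <- 30 + (seed %% 4) * 10
    a <- random_labels(n, 2 + seed %% 6, seed)
    b <- random_labels(n, 2 + (seed * 7) %% 5, seed + 1000)
    ours <- adjusted_rand_index(a, b)
    expect_equal(ours, ari_pair_count(a, b), tolerance = 1e-12)
    expect_equal(ours, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    expect_equal(ours, adjusted_rand_index(b, a)) # symmetry
    expect_gte(ours, -1)
    expect_lte(ours, 1)
  }
})

test_that("adjusted_rand_index is invariant under label permutation", {
  a <- random_labels(60, 5, 3)
  b <- random_labels(60, 4, 4)
  base <- adjusted_rand_index(a, b)
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(5))
    expect_equal(adjusted_rand_index(perm[a], b), base)
  }
})

study1_spec <- ideal_spec(200, c(50, 30, 20, 90, 10), d = 0)

test_that("run_study1 with the pair caller gives the analytic 0.024 for every condition", {
  rep1 <- run_study1(
    study1_spec,
    callers = list(pairs = function(M) pair_caller(nrow(M))),
    s_steps = c(2, 10), alphas = c(0.1), seed = 5
  )
  expect_s3_class(rep1, "rw_eval")
  expect_equal(round(rep1$ari$ari, 3), rep(0.024, nrow(rep1$ari)))
  expect_setequal(rep1$ari$condition,
                  c("ideal", "noisy", "KR", "RWS2s", "RWS10s", "RWR0.1"))
})

test_that("run_study1 scores a perfect oracle at 1 and the insulation caller at 1 on the ideal matrix", {
  oracle <- function(M) true_partition(make_ideal_tpm(study1_spec))
  rep1 <- run_study1(study1_spec,
                     callers = list(oracle = oracle,
                                    insulation = function(M) {
                                      insulation_caller(M, 5, 2)
                                    }),
                     s_steps = 2, alphas = 0.1, seed = 5)
  med <- median_ari(rep1)
  expect_true(all(med$median_ari[med$caller == "oracle"] == 1))
  ideal_rows <- rep1$ari[rep1$ari$condition == "ideal", ]
  expect_equal(ideal_rows$ari[ideal_rows$caller == "insulation"], 1)
})

test_that("run_study2 is reproducible and labels its condition grid", {
  spec <- biophysical_spec(N = 100, k = 4)
  r1 <- run_study2(spec, n_reps = 2, seed = 9, s_steps = c(2, 3), alphas = 0.1)
  r2 <- run_study2(spec, n_reps = 2, seed = 9, s_steps = c(2, 3), alphas = 0.1)
  expect_identical(r1$ari, r2$ari)
  expect_identical(r1$seeds, r2$seeds)
  expect_setequal(r1$ari$condition, c("count", "KR", "RWS2s", "RWS3s", "RWR0.1"))
  expect_equal(nrow(r1$ari), 2 * 5)
  expect_true(all(r1$ari$ari >= -1 & r1$ari$ari <= 1))
})

test_that("run_study2 recovers strong clean domains from raw counts", {
  # no structured zeros, strong domain effects: the caller should do well
  spec <- biophysical_spec(N = 1000, k = 20, lambda_low = 2, lambda_high = 3,
                           pi1 = 0, pi2 = 0)
  rep2 <- run_study2(spec, n_reps = 5, seed = 31, s_steps = 2, alphas = 0.1)
  med <- median_ari(rep2)
  expect_gte(med$median_ari[med$condition == "count"], 0.9)
})

test_that("run_study3 anchors: rate-1 pair caller identity and reproducibility", {
  M <- simulate_biophysical(biophysical_spec(N = 100, k = 4), seed = 2)
  r <- run_study3(M, rate = 1,
                  callers = list(pairs = function(m) pair_caller(nrow(m))),
                  s_steps = 2, alphas = 0.1, n_reps = 2, seed = 3)
  expect_true(all(r$ari$ari == 1)) # pair partition is data-independent
  r2 <- run_study3(M, rate = 1,
                   callers = list(pairs = function(m) pair_caller(nrow(m))),
                   s_steps = 2, alphas = 0.1, n_reps = 2, seed = 3)
  expect_identical(r$ari, r2$ari)
})

test_that("subsample sparsity decreases with the sampling rate", {
  M <- simulate_biophysical(biophysical_spec(N = 100, k = 4), seed = 8)
  zf <- function(rate) {
    median(vapply(1:5, function(r) {
      mean(subsample_counts(M, rate, seed = 50 + r) == 0)
    }, numeric(1)))
  }
  expect_gt(zf(0.05), zf(0.5))
})

test_that("sparsity_sweep reports monotone zero percentages and validates rates", {
  M <- simulate_biophysical(biophysical_spec(N = 80, k = 3), seed = 12)
  sw <- sparsity_sweep(M, rates = c(0.1, 0.4, 0.8),
                       callers = list(single = function(m) {
                         single_domain_caller(nrow(m))
                       }),
                       s_steps = 2, alphas = 0.1, n_reps = 3, seed = 4)
  zero_by_rate <- unique(sw[, c("rate", "median_zero_pct")])
  expect_equal(zero_by_rate$rate, c(0.1, 0.4, 0.8))
  expect_true(all(diff(zero_by_rate$median_zero_pct) <= 0))
  expect_true(all(c("condition", "caller", "median_ari") %in% names(sw)))

  expect_error(sparsity_sweep(M, rates = numeric(0)), "non-empty")
  expect_error(sparsity_sweep(M, rates = c(0.5, 2)), "\\(0, 1\\]")
})

test_that("rw_eval tidiers and autoplot expose the report", {
  rep1 <- run_study1(study1_spec,
                     callers = list(single = function(m) {
                       single_domain_caller(nrow(m))
                     }),
                     s_steps = 2, alphas = 0.1, seed = 1)
  td <- generics::tidy(rep1)
  expect_true(all(c("replicate", "condition", "caller", "ari") %in% names(td)))
  gl <- generics::glance(rep1)
  expect_equal(gl$n_reps, 1L)
  p <- ggplot2::autoplot(rep1)
  expect_s3_class(p, "ggplot")
})
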