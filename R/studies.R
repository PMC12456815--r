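# Replicated study drivers: each condition matrix (raw counts, KR-normalized,
# RWS-smoothed, RWR-limit-smoothed) is fed to each TAD caller and scored
# against the reference partition with the adjusted Rand index.

new_rw_eval <- function(ari, n_reps, seeds, study) {
  structure(
    list(ari = ari, n_reps = as.integer(n_reps), seeds = seeds,
         study = study,
         conditions = unique(ari$condition)),
    class = "rw_eval"
  )
}

#' Per-condition median ARI of an evaluation report
#'
#' @param x An `rw_eval` report from [run_study1()], [run_study2()] or
#'   [run_study3()].
#' @return A tibble with one row per `(condition, caller)` and the median
#'   ARI across replicates.
#' @export
median_ari <- function(x) {
  stopifnot(inherits(x, "rw_eval"))
  dplyr::summarise(
    dplyr::group_by(x$ari, .data$condition, .data$caller),
    median_ari = stats::median(.data$ari), .groups = "drop"
  )
}

#' @export
print.rw_eval <- function(x, ...) {
  cat("<rw_eval>", x$study, "|", x$n_reps, "replicate(s) |",
      length(x$conditions), "condition(s)\n")
  print(tidyr::pivot_wider(median_ari(x), names_from = "caller",
                           values_from = "median_ari"), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rw_eval <- function(x, ...) x$ari

#' @exportS3Method generics::glance
glance.rw_eval <- function(x, ...) {
  med <- median_ari(x)
  best <- med[which.max(med$median_ari), ]
  tibble::tibble(
    study = x$study, n_reps = x$n_reps,
    n_conditions = length(x$conditions),
    n_callers = length(unique(x$ari$caller)),
    best_condition = best$condition, best_caller = best$caller,
    best_median_ari = best$median_ari
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rw_eval <- function(object, ...) {
  dat <- object$ari
  dat$condition <- factor(dat$condition, levels = object$conditions)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$condition, y = .data$ari))
  p <- if (object$n_reps > 1) {
    p + ggplot2::geom_violin(fill = "grey85", scale = "width") +
      ggplot2::stat_summary(fun = stats::median, geom = "point", size = 1)
  } else {
    p + ggplot2::geom_point()
  }
  p + ggplot2::facet_wrap(ggplot2::vars(.data$caller)) +
    ggplot2::labs(x = NULL, y = "adjusted Rand index") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# Standard grid of smoothed condition matrices derived from raw counts (or a
# raw noisy matrix): KR-normalize, then RWS powers and RWR limits.
condition_matrices <- function(raw, s_steps, alphas, kr_tol = 1e-6,
                               kr_max_iter = 1000L, raw_label = "count") {
  out <- list()
  out[[raw_label]] <- raw
  P <- kr_normalize(raw, tol = kr_tol, max_iter = kr_max_iter)$matrix
  out$KR <- P
  for (s in s_steps) out[[paste0("RWS", s, "s")]] <- rws(P, s)
  for (a in alphas) out[[paste0("RWR", format(a))]] <- rwr_limit(P, a)
  out
}

score_conditions <- function(mats, callers, truth_labels, replicate = 1L,
                             gap_mode = "run") {
  purrr::map_dfr(names(mats), function(cond) {
    purrr::map_dfr(names(callers), function(cl) {
      part <- callers[[cl]](mats[[cond]])
      tibble::tibble(
        replicate = replicate, condition = cond, caller = cl,
        ari = adjusted_rand_index(
          truth_labels, partition_to_labels(part, gap_mode = gap_mode)
        )
      )
    })
  })
}

derive_seeds <- function(seed, n) {
  with_seed_if(seed, sample.int(2147483646L, n))
}

#' Study 1: idealized TPM with uniform noise
#'
#' Single-realization pipeline on the idealized block TPM: build `P`, add
#' `Unif(0, noise_high)` noise, KR-normalize, smooth with the RWS step grid
#' and RWR restart grid, run every caller on every condition matrix, and
#' score each detected partition against the true blocks. Conditions are
#' labeled `ideal`, `noisy`, `KR`, `RWS{s}s`, `RWR{alpha}`.
#'
#' @param spec An [ideal_spec()]; its `noise_high` sets the noise level.
#' @param callers Named list of caller functions (matrix -> [tad_partition]),
#'   e.g. [default_callers()].
#' @param s_steps Integer vector of RWS step counts.
#' @param alphas Numeric vector of RWR restart probabilities in `(0, 1)`.
#' @param seed Integer seed for the noise draw.
#' @param gap_mode Gap-labeling rule, see [partition_to_labels()].
#' @return An `rw_eval` report (see [median_ari()], [autoplot.rw_eval()]).
#' @export
run_study1 <- function(spec, callers = default_callers(),
                       s_steps = c(2, 3, 4, 5, 10),
                       alphas = c(0.05, 0.1, 0.2, 0.5),
                       seed = 1L, gap_mode = "run") {
  stopifnot(inherits(spec, "ideal_spec"), length(callers) >= 1L)
  P <- make_ideal_tpm(spec)
  truth_labels <- partition_to_labels(true_partition(P), gap_mode = gap_mode)
  noisy <- add_symmetric_noise(P, high = spec$noise_high, seed = seed)
  mats <- condition_matrices(noisy, s_steps, alphas, raw_label = "noisy")
  mats <- c(list(ideal = unclass(P)), mats)
  mats <- mats[c("ideal", "noisy", setdiff(names(mats), c("ideal", "noisy")))]
  ari <- score_conditions(mats, callers, truth_labels, gap_mode = gap_mode)
  new_rw_eval(ari, n_reps = 1L, seeds = seed, study = "study1")
}

#' Study 2: replicated biophysical-law simulations
#'
#' For each replicate: simulate a count matrix with known domains under the
#' power-decay model, derive the condition matrices (raw counts,
#' KR-normalized, RWS powers, RWR limits), run every caller, and score
#' against the simulated truth. Replicate seeds are derived from the master
#' seed and recorded in the report.
#'
#' @param spec A [biophysical_spec()].
#' @param n_reps Number of replicates.
#' @inheritParams run_study1
#' @return An `rw_eval` report with `n_reps` replicates per condition.
#' @export
run_study2 <- function(spec, callers = default_callers(),
                       s_steps = c(2, 3, 4, 5, 10),
                       alphas = c(0.05, 0.1, 0.2, 0.5),
                       n_reps = 100L, seed = 1L, gap_mode = "run") {
  stopifnot(inherits(spec, "biophysical_spec"), n_reps >= 1L)
  seeds <- derive_seeds(seed, n_reps)
  ari <- purrr::map_dfr(seq_len(n_reps), function(r) {
    E <- simulate_biophysical(spec, seed = seeds[r])
    truth_labels <- partition_to_labels(true_partition(E), gap_mode = gap_mode)
    mats <- condition_matrices(E, s_steps, alphas)
    score_conditions(mats, callers, truth_labels, replicate = r,
                     gap_mode = gap_mode)
  })
  new_rw_eval(ari, n_reps = n_reps, seeds = seeds, study = "study2")
}

#' Study 3: multinomial subsampling of a bulk matrix
#'
#' Treats each multinomial subsample of the bulk matrix `M` as a shallow
#' "single cell". Per replicate, the subsample's condition matrices are
#' scored against each caller's partition of the full matrix `M` (the
#' stand-in truth when no ground truth exists).
#'
#' @param M Symmetric non-negative count matrix (the bulk data).
#' @param rate Subsampling rate in `(0, 1]`.
#' @inheritParams run_study2
#' @return An `rw_eval` report.
#' @export
run_study3 <- function(M, rate = 0.1, callers = default_callers(),
                       s_steps = c(2, 3, 4, 5, 10),
                       alphas = c(0.05, 0.1, 0.2, 0.5),
                       n_reps = 100L, seed = 1L, gap_mode = "run") {
  stopifnot(is.matrix(M), n_reps >= 1L)
  ref_labels <- purrr::map(callers, function(f) {
    partition_to_labels(f(M), gap_mode = gap_mode)
  })
  seeds <- derive_seeds(seed, n_reps)
  ari <- purrr::map_dfr(seq_len(n_reps), function(r) {
    S <- subsample_counts(M, rate = rate, seed = seeds[r])
    mats <- condition_matrices(S, s_steps, alphas)
    purrr::map_dfr(names(mats), function(cond) {
      purrr::map_dfr(names(callers), function(cl) {
        part <- callers[[cl]](mats[[cond]])
        tibble::tibble(
          replicate = r, condition = cond, caller = cl,
          ari = adjusted_rand_index(
            ref_labels[[cl]],
            partition_to_labels(part, gap_mode = gap_mode)
          )
        )
      })
    })
  })
  new_rw_eval(ari, n_reps = n_reps, seeds = seeds, study = "study3")
}

#' Sparsity sweep over subsampling rates
#'
#' Runs the Study 3 design over a grid of subsampling rates and summarizes,
#' per rate, the median percentage of zero entries across subsamples and the
#' median ARI per `(condition, caller)`.
#'
#' @param M Bulk count matrix.
#' @param rates Numeric vector of rates, each in `(0, 1]`; must be non-empty.
#' @inheritParams run_study3
#' @return A tibble with columns `rate`, `median_zero_pct`, `condition`,
#'   `caller`, `median_ari`.
#' @export
sparsity_sweep <- function(M, rates = seq(0.05, 0.5, by = 0.05),
                           callers = default_callers(),
                           s_steps = c(2, 3, 4, 5, 10),
                           alphas = c(0.05, 0.1, 0.2, 0.5),
                           n_reps = 100L, seed = 1L, gap_mode = "run") {
  if (length(rates) == 0L) stop("`rates` must be non-empty", call. = FALSE)
  if (any(rates <= 0 | rates > 1)) {
    stop("every rate must lie in (0, 1]", call. = FALSE)
  }
  rate_seeds <- derive_seeds(seed, length(rates))
  purrr::map_dfr(seq_along(rates), function(i) {
    rate <- rates[i]
    rep_seeds <- derive_seeds(rate_seeds[i], n_reps)
    zero_pct <- vapply(rep_seeds, function(s) {
      S <- subsample_counts(M, rate = rate, seed = s)
      100 * mean(S == 0)
    }, numeric(1))
    report <- run_study3(M, rate = rate, callers = callers,
                         s_steps = s_steps, alphas = alphas,
                         n_reps = n_reps, seed = rate_seeds[i],
                         gap_mode = gap_mode)
    dplyr::mutate(median_ari(report), rate = rate,
                  median_zero_pct = stats::median(zero_pct),
                  .before = 1L)
  })
}
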