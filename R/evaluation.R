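# Congruence scoring between domain partitions: cluster label construction
# and the Hubert-Arabie adjusted Rand index.

#' Convert a domain partition to per-locus cluster labels
#'
#' Loci of each domain share one label. Gap loci are labeled according to
#' `gap_mode`:
#' \describe{
#'   \item{`"run"`}{each maximal run of consecutive gap segments becomes one
#'     cluster (default; preserves contiguity semantics),}
#'   \item{`"singleton"`}{every gap locus is its own cluster,}
#'   \item{`"pooled"`}{all gap loci form a single background cluster.}
#' }
#' Labels are consecutive integers (from 1) in genomic order; for
#' `"pooled"` the shared gap label is assigned at the first gap run.
#'
#' @param p A [tad_partition].
#' @param gap_mode How gap loci enter the clustering; see Details.
#' @return Integer label vector of length `n_loci(p)`.
#' @examples
#' p <- tad_partition(c(0, 2, 3), c(2, 3, 5), c("domain", "gap", "domain"), 5)
#' partition_to_labels(p) # 1 1 2 3 3
#' @export
partition_to_labels <- function(p, gap_mode = c("run", "singleton", "pooled")) {
  stopifnot(inherits(p, "tad_partition"))
  gap_mode <- match.arg(gap_mode)
  width <- p$end - p$start
  is_gap <- p$kind == "gap"

  if (gap_mode == "run") {
    # Merge consecutive gap segments into one cluster per run.
    run_id <- cumsum(!is_gap | c(TRUE, !is_gap[-length(is_gap)]))
    seg_label <- match(run_id, unique(run_id))
    return(rep.int(seg_label, width))
  }

  labels <- integer(sum(width))
  nxt <- 1L
  pooled_label <- NA_integer_
  pos <- 1L
  for (s in seq_len(nrow(p))) {
    idx <- pos:(pos + width[s] - 1L)
    if (!is_gap[s]) {
      labels[idx] <- nxt
      nxt <- nxt + 1L
    } else if (gap_mode == "singleton") {
      labels[idx] <- nxt:(nxt + width[s] - 1L)
      nxt <- nxt + width[s]
    } else { # pooled
      if (is.na(pooled_label)) {
        pooled_label <- nxt
        nxt <- nxt + 1L
      }
      labels[idx] <- pooled_label
    }
    pos <- pos + width[s]
  }
  labels
}

#' Adjusted Rand index between two labelings
#'
#' The Hubert-Arabie chance-corrected Rand index,
#' `(Index - ExpectedIndex) / (MaxIndex - ExpectedIndex)`, computed from the
#' pairwise contingency table. Symmetric in its arguments, bounded in
#' `[-1, 1]`, equal to 1 exactly when the partitions coincide up to
#' relabeling. The degenerate `0/0` case (both partitions a single cluster,
#' or both all singletons) is defined as 1, since the partitions are then
#' identical.
#'
#' @param a,b Vectors of cluster labels of equal length `>= 2` (any atomic
#'   type; compared by equality).
#' @return A single number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  n <- length(a)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(n, 2)
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1) # both partitions trivial and identical
  (sum_ij - expected) / (maximum - expected)
}
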