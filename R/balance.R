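# From-scratch SMOTE: synthetic minority samples are drawn on the segment
# between a minority sample and one of its k nearest minority neighbors,
# measured by Euclidean distance on the concatenated (x1 || x2) vector so
# the two chromosomes of a synthetic sample stay coherent.

#' SMOTE oversampling of a minority feature set
#'
#' Generates exactly `target_count - n` synthetic samples from the `n`
#' minority samples. Minority points are visited round-robin; each
#' synthesis picks one of the point's `k` nearest minority neighbors `q`
#' uniformly and returns `p + u * (q - p)` with `u ~ Uniform(0, 1)`.
#' Deterministic under `seed`. When `k >= n`, `k` is reduced to `n - 1`
#' with a warning (the original algorithm's default is `k = 5`).
#'
#' @param minority a [codel_features()] holding only minority-class
#'   samples (`n >= 2`), all carrying the same label.
#' @param target_count desired minority size after oversampling
#'   (`>= n`).
#' @param k number of nearest neighbors.
#' @param seed integer seed.
#' @return a [codel_features()] of the synthetic samples only (ids
#'   `"<label>_smote_<i>"`, minority label attached); bind with the input
#'   via [bind_features()].
#' @export
smote_oversample <- function(minority, target_count, k = 5L, seed = 1L) {
  stopifnot(inherits(minority, "codel_features"))
  n <- length(minority)
  if (n < 2) stop("SMOTE needs at least 2 minority samples to interpolate")
  lab <- unique(as.character(minority$label))
  if (length(lab) != 1 || is.na(lab))
    stop("minority set must carry a single non-NA label")
  target_count <- as.integer(target_count)
  if (target_count < n)
    stop(sprintf("target_count (%d) below current minority size (%d)",
                 target_count, n))
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k >= n) {
    warning(sprintf("k = %d >= minority size %d; using k = %d", k, n, n - 1L))
    k <- n - 1L
  }
  deficit <- target_count - n
  if (deficit == 0L)
    return(minority[integer(0)])

  M <- cbind(minority$x1, minority$x2)
  D <- as.matrix(stats::dist(M))
  knn <- do.call(rbind, lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))  # ties broken by index
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }))

  p_idx <- rep(seq_len(n), length.out = deficit)  # round-robin
  synth <- with_seed(seed, {
    q_pick <- vapply(p_idx, function(i) knn[i, sample.int(k, 1)], 1L)
    u <- runif(deficit)
    M[p_idx, , drop = FALSE] +
      u * (M[q_pick, , drop = FALSE] - M[p_idx, , drop = FALSE])
  })
  n1 <- ncol(minority$x1)
  codel_features(sprintf("%s_smote_%03d", lab, seq_len(deficit)),
                 synth[, seq_len(n1), drop = FALSE],
                 synth[, -seq_len(n1), drop = FALSE],
                 lab)
}

#' Balance a labeled feature set by SMOTE
#'
#' Upsamples the minority class to the majority count and returns the
#' combined set (originals plus synthetics).
#'
#' @param features a labeled [codel_features()] containing both classes.
#' @inheritParams smote_oversample
#' @return a balanced [codel_features()].
#' @export
balance_features <- function(features, k = 5L, seed = 1L) {
  stopifnot(inherits(features, "codel_features"))
  tab <- table(features$label)
  if (any(tab == 0)) stop("both classes must be present to balance")
  if (tab[1] == tab[2]) return(features)
  min_lab <- names(tab)[which.min(tab)]
  synth <- smote_oversample(features[features$label == min_lab],
                            target_count = max(tab), k = k, seed = seed)
  bind_features(features, synth)
}
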