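# Independent oracles used across the suite. These deliberately use the
# dumbest possible algorithms (pair enumeration, per-element loops,
# double-precision replays) so they share no code path with the package.

# Mann-Whitney AUC by brute-force pair enumeration, ties counted 1/2
brute_auc <- function(labels, scores, positive = "codel") {
  pos <- scores[as.character(labels) == positive]
  neg <- scores[as.character(labels) != positive]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# sensitivity/specificity by direct confusion-matrix count
brute_sens_spec <- function(labels, scores, cutoff, positive = "codel") {
  pos <- as.character(labels) == positive
  pred <- scores >= cutoff
  c(sum(pred & pos) / sum(pos), sum(!pred & !pos) / sum(!pos))
}

# best Youden J by enumerating every candidate threshold
brute_youden <- function(labels, scores, positive = "codel") {
  best_j <- -Inf; best_t <- Inf
  for (t in c(Inf, sort(unique(scores), decreasing = TRUE))) {
    ss <- brute_sens_spec(labels, scores, t, positive)
    j <- ss[1] + ss[2] - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(cutoff = best_t, j = best_j)
}

# toy profile builder: explicit bins on one or more chromosomes
toy_profile <- function(id, chrom, start, end, log2, weight = NULL) {
  bins <- data.frame(chrom = chrom, start = start, end = end, log2 = log2,
                     stringsAsFactors = FALSE)
  if (!is.null(weight)) bins$weight <- weight
  cn_profile(id, bins)
}

# evenly spaced bins across an interval with given per-bin log2 values
spaced_bins <- function(chrom, from, to, log2) {
  n <- length(log2)
  edge <- floor(seq(from, to, length.out = n + 1))
  data.frame(chrom = chrom, start = edge[-(n + 1)], end = edge[-1],
             log2 = log2, stringsAsFactors = FALSE)
}
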