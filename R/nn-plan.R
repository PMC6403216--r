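# Compilation of an ensemble_config into the flat op plan executed by the
# C++ engine, plus weight-shape bookkeeping and initialization.
#
# A residual repeat lowers to:
#   save; conv(1,mid); relu; conv(3,mid,same); relu; conv(1,out); add(proj); relu
# The final 1x1 conv of every repeat is zero-initialized so each block starts
# as its shortcut map; with 30 stacked repeats per branch and no batch
# normalization this keeps activations and gradients bounded at the start of
# training (the stack is the identity at initialization).

new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$shapes <- list()
  reg
}

add_weight <- function(reg, nrow, ncol, init = c("he", "zero")) {
  init <- match.arg(init)
  reg$shapes[[length(reg$shapes) + 1L]] <- list(dim = c(nrow, ncol), init = init)
  length(reg$shapes)
}

compile_branch <- function(input_len, pretrain, residual_specs, iterations,
                           reg, branch, tie_idx = NULL) {
  ops <- list()
  L <- input_len
  C <- 1L
  for (li in seq_along(pretrain)) {
    k <- as.integer(pretrain[[li]][1])
    f <- as.integer(pretrain[[li]][2])
    if (k < 1L || f < 1L)
      stop(sprintf("branch %s pretraining layer %d: invalid spec", branch, li))
    if (L < k)
      stop(sprintf(
        "branch %s pretraining conv %d: kernel %d exceeds signal length %d",
        branch, li, k, L))
    w <- add_weight(reg, k * C, f, "he")
    ops <- c(ops, list(list(op = "conv", k = k, same = FALSE, w = w)),
             list(list(op = "relu")))
    L <- L - k + 1L
    if (L < 2L)
      stop(sprintf("branch %s pretraining pool %d: signal length %d too short",
                   branch, li, L))
    ops <- c(ops, list(list(op = "pool")))
    L <- L %/% 2L
    C <- f
  }
  pretrain_out <- c(len = L, channels = C)

  res_idx <- list()
  rep_count <- 0L
  for (bi in seq_along(residual_specs)) {
    mid <- as.integer(residual_specs[[bi]][1])
    out <- as.integer(residual_specs[[bi]][2])
    for (r in seq_len(iterations)) {
      rep_count <- rep_count + 1L
      if (is.null(tie_idx)) {
        w1 <- add_weight(reg, C, mid, "he")
        w2 <- add_weight(reg, 3L * mid, mid, "he")
        w3 <- add_weight(reg, mid, out, "zero")
        wp <- if (C != out) add_weight(reg, C, out, "he") else 0L
        res_idx[[rep_count]] <- c(w1, w2, w3, wp)
      } else {
        ix <- tie_idx[[rep_count]]
        w1 <- ix[1]; w2 <- ix[2]; w3 <- ix[3]; wp <- ix[4]
      }
      if (L < 3L)
        stop(sprintf("branch %s residual block %d: signal length %d below kernel 3",
                     branch, bi, L))
      ops <- c(ops, list(
        list(op = "save"),
        list(op = "conv", k = 1L, same = FALSE, w = w1),
        list(op = "relu"),
        list(op = "conv", k = 3L, same = TRUE, w = w2),
        list(op = "relu"),
        list(op = "conv", k = 1L, same = FALSE, w = w3),
        list(op = "add", w = wp),
        list(op = "relu")))
      C <- out
    }
  }
  list(ops = ops, out_len = L, out_ch = C,
       pretrain_out = pretrain_out,
       stack_out = c(len = L, channels = C),
       res_idx = res_idx)
}

compile_network <- function(config) {
  reg <- new_registry()
  b1 <- compile_branch(config$input_lens[1], config$branch1_pretrain,
                       config$residual_specs, config$residual_iterations,
                       reg, "1")
  b2 <- compile_branch(config$input_lens[2], config$branch2_pretrain,
                       config$residual_specs, config$residual_iterations,
                       reg, "2",
                       tie_idx = if (isTRUE(config$tie_weights)) b1$res_idx)
  d1 <- add_weight(reg, b1$out_ch, config$branch_feature_len, "he")
  d2 <- add_weight(reg, b2$out_ch, config$branch_feature_len, "he")
  head <- add_weight(reg, 2L * config$branch_feature_len, config$n_classes,
                     "zero")
  list(net = list(plan1 = b1$ops, plan2 = b2$ops,
                  d1 = d1, d2 = d2, head = head),
       shapes = reg$shapes,
       geometry = list(branch1 = list(pretrain_out = b1$pretrain_out,
                                      stack_out = b1$stack_out),
                       branch2 = list(pretrain_out = b2$pretrain_out,
                                      stack_out = b2$stack_out)))
}

init_weights <- function(shapes, seed) {
  with_seed(seed, lapply(shapes, function(s) {
    W <- if (s$init == "he") {
      matrix(rnorm(prod(s$dim), sd = sqrt(2 / s$dim[1])), s$dim[1], s$dim[2])
    } else {
      matrix(0, s$dim[1], s$dim[2])
    }
    list(W = W, b = rep(0, s$dim[2]))
  }))
}
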