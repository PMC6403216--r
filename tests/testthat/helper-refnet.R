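# Double-precision pure-R reference implementation of the ensemble forward
# pass (independent of the C++ engine), plus a small test configuration.

ref_conv <- function(X, W, b, k, same) {
  Cin <- ncol(X)
  if (same && k > 1) {
    pl <- (k - 1) %/% 2; pr <- k - 1 - pl
    X <- rbind(matrix(0, pl, Cin), X, matrix(0, pr, Cin))
  }
  Lout <- nrow(X) - k + 1
  Xcol <- do.call(cbind, lapply(seq_len(k), function(j)
    X[j:(j + Lout - 1), , drop = FALSE]))
  sweep(Xcol %*% W, 2, b, "+")
}

ref_pool <- function(X) {
  L <- nrow(X) %/% 2
  pmax(X[seq(1, 2 * L, 2), , drop = FALSE],
       X[seq(2, 2 * L, 2), , drop = FALSE])
}

ref_branch <- function(plan, weights, x) {
  act <- matrix(x, ncol = 1)
  stack <- list()
  for (op in plan) {
    if (op$op == "conv") {
      act <- ref_conv(act, weights[[op$w]]$W, weights[[op$w]]$b, op$k, op$same)
    } else if (op$op == "relu") {
      act <- pmax(act, 0)
    } else if (op$op == "pool") {
      act <- ref_pool(act)
    } else if (op$op == "save") {
      stack[[length(stack) + 1]] <- act
    } else if (op$op == "add") {
      S <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      act <- act + if (op$w > 0)
        ref_conv(S, weights[[op$w]]$W, weights[[op$w]]$b, 1, FALSE) else S
    }
  }
  act
}

ref_forward <- function(model, X1, X2) {
  net <- model$net
  weights <- model$weights
  t(vapply(seq_len(nrow(X1)), function(i) {
    a1 <- ref_branch(net$plan1, weights, X1[i, ])
    a2 <- ref_branch(net$plan2, weights, X2[i, ])
    f1 <- pmax(colMeans(a1) %*% weights[[net$d1]]$W + weights[[net$d1]]$b, 0)
    f2 <- pmax(colMeans(a2) %*% weights[[net$d2]]$W + weights[[net$d2]]$b, 0)
    lg <- cbind(f1, f2) %*% weights[[net$head]]$W + weights[[net$head]]$b
    e <- exp(lg - max(lg))
    as.numeric(e / sum(e))
  }, numeric(2)))
}

ref_loss <- function(model, X1, X2, y) {
  P <- ref_forward(model, X1, X2)
  -mean(log(P[cbind(seq_along(y), y + 1L)]))
}

# a small config exercising every op type (valid/same convs, pools,
# projection and identity shortcuts, both branches)
tiny_config <- function() {
  ensemble_config(input_lens = c(40L, 30L),
                  branch1_pretrain = list(c(5L, 4L), c(3L, 6L)),
                  branch2_pretrain = list(c(4L, 4L), c(3L, 6L)),
                  residual_specs = list(c(3L, 8L), c(4L, 10L)),
                  residual_iterations = 2L,
                  branch_feature_len = 7L)
}

# tiny model with all weights (incl. the zero-initialized ones) randomized
tiny_model <- function(seed = 42, jitter_seed = 7) {
  m <- build_ensemble(tiny_config(), seed = seed)
  set.seed(jitter_seed)
  m$weights <- lapply(m$weights, function(w) {
    w$W <- w$W + matrix(rnorm(length(w$W), sd = 0.3), nrow(w$W))
    w$b <- w$b + rnorm(length(w$b), sd = 0.1)
    w
  })
  m
}

# reduced-size simulation + model used to exercise the training loop fast
small_world <- function() {
  list(config = ensemble_config(input_lens = c(200L, 120L),
                                branch1_pretrain = list(c(21L, 8L),
                                                        c(11L, 16L)),
                                branch2_pretrain = list(c(15L, 8L),
                                                        c(11L, 16L)),
                                residual_specs = list(c(8L, 32L),
                                                      c(16L, 64L)),
                                residual_iterations = 2L,
                                branch_feature_len = 32L),
       target_lens = c(200L, 120L))
}
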