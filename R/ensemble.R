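#' Configuration of the two-branch ensemble 1D CNN
#'
#' Defines the architecture: per-branch pretraining blocks (valid
#' convolutions interleaved with max-pooling), a stack of three residual
#' block families applied sequentially (each repeated
#' `residual_iterations` times), global average pooling, a dense bridge to
#' the per-branch feature vector, concatenation of the two branch feature
#' vectors, and a softmax classification head.
#'
#' The defaults reproduce the published architecture: branch 1 ingests the
#' chromosome 1 signal (length 1869), branch 2 the chromosome 19 signal
#' (length 649); pretraining block A0 is
#' (170x1 conv, 32)-(pool)-(151x1 conv, 64)-(pool)-(51x1 conv, 64)-(pool),
#' B0 is (150x1 conv, 32)-(pool)-(51x1 conv, 64)-(pool)-(51x1 conv, 64)-(pool);
#' the residual families are (1x1,32)-(3x1,32)-(1x1,128),
#' (1x1,64)-(3x1,64)-(1x1,256) and (1x1,128)-(3x1,128)-(1x1,512), each
#' executed over 10 iterations; each branch is flattened to a 1024-length
#' feature vector and the head maps the 2048-length concatenation to two
#' softmax outputs (class 1 = 1p/19q co-deletion, class 2 = no co-deletion).
#'
#' Two points the published layer list does not pin down are made explicit
#' and configurable here: (i) "executed over 10 iterations" repeats each
#' residual family sequentially at its own width, with a 1x1 projection
#' shortcut on the first repeat (channel change) and identity shortcuts
#' thereafter; (ii) the residual-stack output (e.g. 150 positions x 512
#' channels) cannot be reshaped to exactly 1024, so the bridge is global
#' average pooling over positions followed by a dense ReLU layer to
#' `branch_feature_len`.
#'
#' @param input_lens lengths of the chr1 and chr19 input vectors.
#' @param branch1_pretrain,branch2_pretrain list of `c(kernel, filters)`
#'   pairs; each convolution (valid padding, ReLU) is followed by a
#'   width-2 max pool.
#' @param residual_specs list of `c(mid_channels, out_channels)` for the
#'   three residual families; the interior kernels are 1, 3 ("same"
#'   padding), 1.
#' @param residual_iterations sequential repeats of each residual family.
#' @param branch_feature_len per-branch flattened feature length.
#' @param n_classes number of softmax outputs.
#' @param tie_weights share residual-stack weights between the branches
#'   (default `FALSE`: structurally identical stacks, separate weights).
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(input_lens = c(1869L, 649L),
                            branch1_pretrain = list(c(170L, 32L),
                                                    c(151L, 64L),
                                                    c(51L, 64L)),
                            branch2_pretrain = list(c(150L, 32L),
                                                    c(51L, 64L),
                                                    c(51L, 64L)),
                            residual_specs = list(c(32L, 128L),
                                                  c(64L, 256L),
                                                  c(128L, 512L)),
                            residual_iterations = 10L,
                            branch_feature_len = 1024L,
                            n_classes = 2L,
                            tie_weights = FALSE) {
  stopifnot(length(input_lens) == 2, all(input_lens >= 1),
            residual_iterations >= 1, branch_feature_len >= 1,
            n_classes >= 2)
  cfg <- list(input_lens = as.integer(input_lens),
              branch1_pretrain = branch1_pretrain,
              branch2_pretrain = branch2_pretrain,
              residual_specs = residual_specs,
              residual_iterations = as.integer(residual_iterations),
              branch_feature_len = as.integer(branch_feature_len),
              concat_len = 2L * as.integer(branch_feature_len),
              n_classes = as.integer(n_classes),
              tie_weights = isTRUE(tie_weights))
  class(cfg) <- "ensemble_config"
  cfg
}

#' Network geometry implied by an ensemble configuration
#'
#' Computes, without allocating weights, the (length, channels) shape of
#' each branch after its pretraining block and after the residual stack,
#' and the classification-head input length. Construction errors (kernel
#' larger than the remaining signal) are raised here, naming the layer.
#'
#' @param config an [ensemble_config()].
#' @return list with `branch1`, `branch2` (each with `pretrain_out` and
#'   `stack_out` as `c(len, channels)`), `branch_feature_len`,
#'   `concat_len` and `n_parameters`.
#' @export
ensemble_geometry <- function(config) {
  stopifnot(inherits(config, "ensemble_config"))
  cm <- compile_network(config)
  n_par <- sum(vapply(cm$shapes, function(s) prod(s$dim) + s$dim[2], 0))
  c(cm$geometry,
    list(branch_feature_len = config$branch_feature_len,
         concat_len = config$concat_len,
         n_parameters = n_par))
}

#' Build an (untrained) ensemble model
#'
#' Allocates and initializes all weights: He-normal initialization for
#' convolutions and dense bridges, zeros for the final 1x1 convolution of
#' every residual repeat (so each block starts as its shortcut map) and
#' for the softmax head (so an untrained model outputs probability 0.5
#' for both classes).
#'
#' @param config an [ensemble_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `codel_ensemble`.
#' @export
build_ensemble <- function(config = ensemble_config(), seed = 1L) {
  stopifnot(inherits(config, "ensemble_config"))
  cm <- compile_network(config)
  model <- list(config = config,
                net = cm$net,
                geometry = cm$geometry,
                weights = init_weights(cm$shapes, seed),
                history = NULL,
                seeds = list(init = as.integer(seed), train = NULL),
                version = 1L)
  class(model) <- "codel_ensemble"
  model
}

#' Number of trainable parameters
#' @param model a `codel_ensemble`.
#' @return integer-valued count of weights and biases.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "codel_ensemble"))
  sum(vapply(model$weights, function(w) length(w$W) + length(w$b), 0))
}

#' Training hyperparameters
#'
#' The source method reports no training hyperparameters; these defaults
#' are conventional for small-sample 1D-CNN training and are all exposed:
#' Adam, learning rate 1e-3, batch size 16, at most 200 epochs with early
#' stopping (patience 20) on validation loss, cross-entropy objective.
#'
#' @param epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param early_stop_patience epochs without improvement before stopping;
#'   the best-scoring weights are restored.
#' @param validation_fraction fraction of the training set held out
#'   (stratified) to monitor early stopping; 0 monitors training loss.
#' @param min_delta minimum loss improvement to reset patience.
#' @param seed seed for the validation split, shuffling and minibatch order.
#' @param verbose print per-epoch losses.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 16L,
                         learning_rate = 1e-3, optimizer = "adam",
                         early_stop_patience = 20L,
                         validation_fraction = 0.2, min_delta = 1e-4,
                         seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            early_stop_patience >= 1,
            validation_fraction >= 0, validation_fraction <= 0.5)
  if (!identical(optimizer, "adam"))
    stop("only the 'adam' optimizer is implemented")
  tc <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
             learning_rate = learning_rate, optimizer = optimizer,
             early_stop_patience = as.integer(early_stop_patience),
             validation_fraction = validation_fraction,
             min_delta = min_delta, seed = as.integer(seed),
             verbose = isTRUE(verbose))
  class(tc) <- "train_config"
  tc
}

check_features_for_model <- function(model, features) {
  stopifnot(inherits(model, "codel_ensemble"),
            inherits(features, "codel_features"))
  lens <- model$config$input_lens
  if (ncol(features$x1) != lens[1] || ncol(features$x2) != lens[2])
    stop(sprintf("feature lengths (%d, %d) do not match model inputs (%d, %d)",
                 ncol(features$x1), ncol(features$x2), lens[1], lens[2]))
  invisible(TRUE)
}

#' Train the ensemble model
#'
#' Minimizes cross-entropy with Adam on minibatches. A stratified
#' validation split (per `tc$validation_fraction`) monitors early
#' stopping; the weights from the best epoch are kept. Class balancing
#' (see [smote_oversample()]) is the caller's responsibility and should be
#' applied to the training set before this call.
#'
#' @param model a `codel_ensemble` from [build_ensemble()].
#' @param features a labeled [codel_features()] set containing both classes.
#' @param tc a [train_config()].
#' @return the fitted `codel_ensemble`, with `$history` holding per-epoch
#'   loss/accuracy records.
#' @export
train_ensemble <- function(model, features, tc = train_config()) {
  check_features_for_model(model, features)
  stopifnot(inherits(tc, "train_config"))
  y <- feature_classes(features)
  if (any(is.na(y))) stop("all training samples must be labeled")
  if (length(unique(y)) < 2)
    stop("training set must contain both classes")

  n <- length(y)
  val_idx <- integer(0)
  if (tc$validation_fraction > 0) {
    val_idx <- with_seed(tc$seed, {
      unlist(lapply(split(seq_len(n), y), function(ix) {
        k <- floor(length(ix) * tc$validation_fraction)
        if (k >= 1) sample(ix, k) else integer(0)
      }), use.names = FALSE)
    })
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2)
    stop("validation split left a single-class training set; lower validation_fraction")

  hyper <- list(epochs = tc$epochs, batch_size = tc$batch_size,
                learning_rate = tc$learning_rate,
                patience = tc$early_stop_patience,
                min_delta = tc$min_delta, seed = tc$seed,
                verbose = tc$verbose)
  fit <- nn_train_cpp(model$net, model$weights,
                      features$x1[tr_idx, , drop = FALSE],
                      features$x2[tr_idx, , drop = FALSE],
                      y[tr_idx],
                      features$x1[val_idx, , drop = FALSE],
                      features$x2[val_idx, , drop = FALSE],
                      y[val_idx],
                      hyper)
  model$weights <- fit$weights
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$seeds$train <- tc$seed
  model
}

#' Class probabilities from the ensemble
#'
#' Inference is deterministic and batch-invariant. Column `p_codel` is
#' P(class 1) (1p/19q co-deletion), the probability score used for ROC
#' analysis; `p_no_codel` is P(class 2); rows sum to one.
#'
#' @param model a `codel_ensemble`.
#' @param features a [codel_features()] set (labels not required).
#' @return numeric matrix with columns `p_codel`, `p_no_codel`, one row
#'   per sample (sample ids as rownames).
#' @export
forward_proba <- function(model, features) {
  check_features_for_model(model, features)
  P <- nn_predict_cpp(model$net, model$weights, features$x1, features$x2)
  dimnames(P) <- list(features$sample_id, c("p_codel", "p_no_codel"))
  P
}

#' @export
predict.codel_ensemble <- function(object, newdata, type = c("prob", "class"),
                                   cutoff = 0.5, ...) {
  type <- match.arg(type)
  P <- forward_proba(object, newdata)
  if (type == "prob") return(P)
  factor(ifelse(P[, "p_codel"] >= cutoff, "codel", "no_codel"),
         levels = class_levels())
}

#' @export
print.codel_ensemble <- function(x, ...) {
  g <- x$geometry
  cat("<codel_ensemble>\n")
  cat(sprintf("  inputs: chr1 %d, chr19 %d\n",
              x$config$input_lens[1], x$config$input_lens[2]))
  cat(sprintf("  branch1 pretrain out: %d x %d; stack out: %d x %d\n",
              g$branch1$pretrain_out[1], g$branch1$pretrain_out[2],
              g$branch1$stack_out[1], g$branch1$stack_out[2]))
  cat(sprintf("  branch2 pretrain out: %d x %d; stack out: %d x %d\n",
              g$branch2$pretrain_out[1], g$branch2$pretrain_out[2],
              g$branch2$stack_out[1], g$branch2$stack_out[2]))
  cat(sprintf("  features: %d per branch -> %d concatenated -> %d classes\n",
              x$config$branch_feature_len, x$config$concat_len,
              x$config$n_classes))
  cat(sprintf("  parameters: %s; trained: %s\n",
              format(n_parameters(x), big.mark = ","),
              if (is.null(x$history)) "no"
              else sprintf("yes (%d epochs, best %d)",
                           nrow(x$history), x$best_epoch)))
  invisible(x)
}

#' Save / load a fitted ensemble
#'
#' The artifact is a single RDS file embedding the configuration, weights,
#' training history and seeds; a saved-then-loaded model reproduces
#' [forward_proba()] exactly.
#'
#' @param model a `codel_ensemble`.
#' @param path file path.
#' @return `save_ensemble` returns `path` invisibly; `load_ensemble`
#'   returns the model.
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "codel_ensemble"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "codel_ensemble"))
    stop("file does not contain a codel_ensemble artifact")
  model
}
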