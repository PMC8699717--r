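# The dual-branch convolutional classifier.
#
# Deep branch: the 10 x window matrix enters as a 1D sequence of window
# positions with 10 channels and passes through convolutional blocks of
# [conv(k, s=1) -> BN -> conv(k, s=1) -> max-pool(2) -> BN] (ReLU after
# each conv), then a dense head. Auxiliary branch: the 19 standardized
# features through its own dense head. The two branches are first trained
# separately (each with a temporary output layer), then concatenated into
# a joint dense layer and output for a final round of training.

#' Classifier configuration
#'
#' Defaults are the full-scale architecture: 4 blocks with filters
#' (256, 256, 512, 512), kernel 19 / stride 1, pool size 2, 2048-unit
#' branch dense heads, a 512-unit joint dense layer, 4 output classes,
#' batch size 32, Adam at learning rate 0.001. The hyperparameter menus
#' explored during tuning are carried in `tuning_grid` for reference.
#' Branch pretraining epochs and early-stopping patience are configurable
#' (overfitting is monitored on validation loss).
#'
#' @param conv_kernel Odd convolution kernel size.
#' @param conv_blocks Number of convolutional blocks.
#' @param filters_per_block Integer vector, one filter count per block.
#' @param pool_size Max-pool size (stride = pool size).
#' @param branch_dense Units in each branch dense head.
#' @param joint_dense Units in the joint dense layer.
#' @param n_classes Number of output classes (fixed at 4).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param branch_epochs,joint_epochs Epoch budgets for the branch and
#'   joint training stages.
#' @param early_stopping_patience Epochs without validation-loss
#'   improvement before a stage stops (best weights kept).
#' @param seed Integer seed controlling initialization and batch order.
#' @param input_len Encoded window length (positions).
#' @param input_channels Encoding rows (channels).
#' @param aux_dim Auxiliary feature count.
#' @return List of class `model_config`.
#' @export
model_config <- function(conv_kernel = 19L, conv_blocks = 4L,
                         filters_per_block = c(256L, 256L, 512L, 512L),
                         pool_size = 2L, branch_dense = 2048L,
                         joint_dense = 512L, n_classes = 4L,
                         batch_size = 32L, learning_rate = 0.001,
                         branch_epochs = 20L, joint_epochs = 10L,
                         early_stopping_patience = 5L, seed = 42L,
                         input_len = 600L, input_channels = 10L,
                         aux_dim = 19L) {
  cfg <- list(conv_kernel = as.integer(conv_kernel),
              conv_blocks = as.integer(conv_blocks),
              filters_per_block = as.integer(filters_per_block),
              pool_size = as.integer(pool_size),
              branch_dense = as.integer(branch_dense),
              joint_dense = as.integer(joint_dense),
              n_classes = as.integer(n_classes),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              branch_epochs = as.integer(branch_epochs),
              joint_epochs = as.integer(joint_epochs),
              early_stopping_patience = as.integer(early_stopping_patience),
              seed = as.integer(seed),
              input_len = as.integer(input_len),
              input_channels = as.integer(input_channels),
              aux_dim = as.integer(aux_dim),
              tuning_grid = list(kernel = c(9L, 11L, 19L, 21L),
                                 blocks = c(3L, 4L, 5L),
                                 dense = c(1024L, 2048L, 4096L),
                                 filters = c(32L, 128L, 256L)))
  problems <- c(
    if (cfg$conv_kernel %% 2 != 1) "conv_kernel must be odd",
    if (cfg$n_classes != 4L) "n_classes must be 4",
    if (length(cfg$filters_per_block) != cfg$conv_blocks)
      "filters_per_block must have one entry per block",
    if (any(c(cfg$filters_per_block, cfg$branch_dense, cfg$joint_dense,
              cfg$batch_size, cfg$conv_blocks) < 1))
      "all sizes must be >= 1")
  if (length(problems) > 0)
    stop("invalid model_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(cfg, class = "model_config")
}

# length of the position axis after the convolutional blocks
.deep_out_len <- function(config) {
  L <- config$input_len
  for (i in seq_len(config$conv_blocks)) L <- L %/% config$pool_size
  L
}

.build_deep_layers <- function(config) {
  layers <- list()
  C <- config$input_channels
  for (i in seq_len(config$conv_blocks)) {
    f <- config$filters_per_block[i]
    layers <- c(layers, list(
      nn_conv1d(C, f, config$conv_kernel), nn_relu(), nn_bn(f),
      nn_conv1d(f, f, config$conv_kernel), nn_relu(),
      nn_pool(f, config$pool_size), nn_bn(f)))
    C <- f
  }
  flat <- C * .deep_out_len(config)
  c(layers, list(nn_dense(flat, config$branch_dense), nn_relu()))
}

.build_aux_layers <- function(config) {
  list(nn_dense(config$aux_dim, config$branch_dense), nn_relu())
}

.build_joint_layers <- function(config) {
  list(nn_dense(2L * config$branch_dense, config$joint_dense), nn_relu(),
       nn_dense(config$joint_dense, config$n_classes))
}

#' Build the (untrained) dual-branch model
#'
#' @param config A [model_config()].
#' @return Object of class `core_classifier` with `trained = FALSE`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  structure(list(config = config,
                 deep = .build_deep_layers(config),
                 aux = .build_aux_layers(config),
                 joint = .build_joint_layers(config),
                 enc_stats = NULL, feat_stats = NULL,
                 history = NULL, trained = FALSE,
                 classes = CLASS_LEVELS),
            class = "core_classifier")
}

#' Architecture description for introspection
#'
#' @param model A `core_classifier`.
#' @return data.frame with one row per layer: `branch`, `type`, and the
#'   layer's filters/kernel/units where applicable.
#' @export
describe_architecture <- function(model) {
  one <- function(branch, layers) {
    do.call(rbind, lapply(layers, function(ly) {
      data.frame(branch = branch, type = ly$type,
                 filters = if (ly$type == "conv") ly$F else NA_integer_,
                 kernel = if (ly$type == "conv") ly$K else NA_integer_,
                 units = if (ly$type == "dense") nrow(ly$W) else NA_integer_)
    }))
  }
  rbind(one("deep", model$deep), one("aux", model$aux),
        one("joint", model$joint))
}

# one-hot (K, B) from class labels
.onehot <- function(labels) {
  y <- matrix(0, length(CLASS_LEVELS), length(labels))
  y[cbind(match(labels, CLASS_LEVELS), seq_along(labels))] <- 1
  y
}

# train one layer list (single branch + temporary head) with Adam and
# early stopping on validation loss; returns layers + history
.train_net <- function(layers, x_train, y_train, x_val, y_val, config,
                       epochs, tag) {
  n <- ncol(x_train)
  state <- adam_init(layers)
  t <- 0L
  best <- list(loss = Inf, layers = layers)
  wait <- 0L
  history <- data.frame()
  for (epoch in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    tr_loss <- 0
    tr_n <- 0L
    for (s in starts) {
      b <- idx[s:min(s + config$batch_size - 1L, n)]
      fw <- nn_forward(layers, x_train[, b, drop = FALSE], training = TRUE)
      layers <- fw$layers
      ce <- nn_softmax_xent(fw$out, y_train[, b, drop = FALSE])
      bw <- nn_backward(layers, fw$caches, ce$dlogits)
      t <- t + 1L
      up <- adam_step(layers, bw$grads, state, config$learning_rate, t)
      layers <- up$layers
      state <- up$state
      tr_loss <- tr_loss + ce$loss * length(b)
      tr_n <- tr_n + length(b)
    }
    val <- nn_forward(layers, x_val, training = FALSE)
    vl <- nn_softmax_xent(val$out, y_val)$loss
    vacc <- mean(CLASS_LEVELS[max.col(t(val$out))] ==
                   CLASS_LEVELS[max.col(t(y_val))])
    history <- rbind(history,
                     data.frame(stage = tag, epoch = epoch,
                                train_loss = tr_loss / tr_n,
                                val_loss = vl, val_accuracy = vacc))
    if (vl < best$loss) {
      best <- list(loss = vl, layers = layers)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stopping_patience) break
    }
  }
  list(layers = best$layers, history = history)
}

# joint forward over both branches
.joint_forward <- function(model, x_deep, x_aux, training = FALSE) {
  fd <- nn_forward(model$deep, x_deep, training)
  fa <- nn_forward(model$aux, x_aux, training)
  z <- rbind(fd$out, fa$out)
  fj <- nn_forward(model$joint, z, training)
  list(out = fj$out, fd = fd, fa = fa, fj = fj,
       model = {
         model$deep <- fd$layers
         model$aux <- fa$layers
         model$joint <- fj$layers
         model
       })
}

#' Fit the dual-branch cis-regulatory element classifier
#'
#' Staged training: the convolutional (deep) branch and the auxiliary
#' feature branch are first trained separately, each with its own dense
#' head and a temporary output layer, monitoring validation loss; their
#' dense-head outputs are then concatenated into the joint dense layer for
#' a final round of training of all parameters. Feature standardization
#' statistics are fitted on the training split and stored with the model.
#'
#' @param encodings A `peak_encoding_set` from [encode_dataset()], or a
#'   raw `10 x window_len x n` array.
#' @param features n x 19 raw feature matrix ([feature_matrix()]).
#' @param labels Character vector of true classes.
#' @param splits Character vector: `"train"` / `"validation"` (rows with
#'   other values are ignored for fitting).
#' @param config A [model_config()].
#' @param verbose Print per-epoch progress.
#' @return A fitted `core_classifier` with training `history`.
#' @export
core_classifier <- function(encodings, features, labels, splits,
                            config = model_config(), verbose = FALSE) {
  enc_stats <- NULL
  if (inherits(encodings, "peak_encoding_set")) {
    enc_stats <- encodings$stats
    encodings <- encodings$encodings
  }
  stopifnot(length(dim(encodings)) == 3,
            dim(encodings)[1] == config$input_channels,
            dim(encodings)[2] == config$input_len,
            dim(encodings)[3] == length(labels),
            nrow(features) == length(labels),
            ncol(features) == config$aux_dim,
            length(splits) == length(labels))
  if (!all(labels %in% CLASS_LEVELS))
    stop("labels must be one of: ", paste(CLASS_LEVELS, collapse = ", "),
         call. = FALSE)
  if (!any(splits == "validation"))
    stop("a validation split is required for staged training",
         call. = FALSE)
  model <- build_model(config)
  model$enc_stats <- enc_stats
  tr <- which(splits == "train")
  va <- which(splits == "validation")
  fs <- standardize_features(features[tr, , drop = FALSE])
  model$feat_stats <- fs$stats
  n_all <- length(labels)
  x_deep <- matrix(encodings, config$input_channels * config$input_len,
                   n_all)
  x_aux <- t(apply_feature_stats(features, fs$stats))
  y <- .onehot(labels)
  set.seed(config$seed)
  # stage 1: branches with temporary output layers
  head_deep <- list(nn_dense(config$branch_dense, config$n_classes))
  r1 <- .train_net(c(model$deep, head_deep),
                   x_deep[, tr, drop = FALSE], y[, tr, drop = FALSE],
                   x_deep[, va, drop = FALSE], y[, va, drop = FALSE],
                   config, config$branch_epochs, "deep_branch")
  model$deep <- r1$layers[seq_along(model$deep)]
  head_aux <- list(nn_dense(config$branch_dense, config$n_classes))
  r2 <- .train_net(c(model$aux, head_aux),
                   x_aux[, tr, drop = FALSE], y[, tr, drop = FALSE],
                   x_aux[, va, drop = FALSE], y[, va, drop = FALSE],
                   config, config$branch_epochs, "aux_branch")
  model$aux <- r2$layers[seq_along(model$aux)]
  # stage 2: concatenate and train the unified model end to end
  state <- list(deep = adam_init(model$deep), aux = adam_init(model$aux),
                joint = adam_init(model$joint))
  t <- 0L
  best <- list(loss = Inf, model = model)
  wait <- 0L
  hist3 <- data.frame()
  n_tr <- length(tr)
  for (epoch in seq_len(config$joint_epochs)) {
    idx <- sample(tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    tr_loss <- 0
    for (s in starts) {
      b <- idx[s:min(s + config$batch_size - 1L, n_tr)]
      jf <- .joint_forward(model, x_deep[, b, drop = FALSE],
                           x_aux[, b, drop = FALSE], training = TRUE)
      model <- jf$model
      ce <- nn_softmax_xent(jf$out, y[, b, drop = FALSE])
      bj <- nn_backward(model$joint, jf$fj$caches, ce$dlogits)
      nd <- ncol(jf$fd$out) # == length(b)
      k <- nrow(jf$fd$out)
      bd <- nn_backward(model$deep, jf$fd$caches,
                        bj$dx[seq_len(k), , drop = FALSE])
      ba <- nn_backward(model$aux, jf$fa$caches,
                        bj$dx[(k + 1L):nrow(bj$dx), , drop = FALSE])
      t <- t + 1L
      uj <- adam_step(model$joint, bj$grads, state$joint,
                      config$learning_rate, t)
      model$joint <- uj$layers
      state$joint <- uj$state
      ud <- adam_step(model$deep, bd$grads, state$deep,
                      config$learning_rate, t)
      model$deep <- ud$layers
      state$deep <- ud$state
      ua <- adam_step(model$aux, ba$grads, state$aux,
                      config$learning_rate, t)
      model$aux <- ua$layers
      state$aux <- ua$state
      tr_loss <- tr_loss + ce$loss * length(b)
    }
    jv <- .joint_forward(model, x_deep[, va, drop = FALSE],
                         x_aux[, va, drop = FALSE], training = FALSE)
    vl <- nn_softmax_xent(jv$out, y[, va, drop = FALSE])$loss
    vacc <- mean(CLASS_LEVELS[max.col(t(jv$out))] == labels[va])
    hist3 <- rbind(hist3,
                   data.frame(stage = "joint", epoch = epoch,
                              train_loss = tr_loss / n_tr, val_loss = vl,
                              val_accuracy = vacc))
    if (verbose)
      message(sprintf("joint epoch %d: train %.4f val %.4f acc %.3f",
                      epoch, tr_loss / n_tr, vl, vacc))
    if (vl < best$loss) {
      best <- list(loss = vl, model = model)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stopping_patience) break
    }
  }
  model <- best$model
  model$history <- rbind(r1$history, r2$history, hist3)
  model$trained <- TRUE
  model
}

#' Predict class probabilities for encoded peaks
#'
#' Inputs must be encoded/standardized the same way as at training time
#' (the model carries its feature-standardization statistics and applies
#' them; encodings carry their own dataset-level statistics). Batch
#' normalization uses stored running moments, so results are independent
#' of batch composition and order.
#'
#' @param object A fitted `core_classifier`.
#' @param encodings `peak_encoding_set` or raw `10 x L x n` array.
#' @param features n x 19 raw feature matrix.
#' @param batch_size Prediction chunk size (does not affect results).
#' @param ... Unused.
#' @return n x 4 probability matrix, columns `prob_promoter`,
#'   `prob_enhancer`, `prob_insulator`, `prob_other`.
#' @export
predict.core_classifier <- function(object, encodings, features,
                                    batch_size = 256L, ...) {
  if (!isTRUE(object$trained))
    stop("model is not trained", call. = FALSE)
  if (inherits(encodings, "peak_encoding_set"))
    encodings <- encodings$encodings
  config <- object$config
  if (length(dim(encodings)) != 3 ||
      dim(encodings)[1] != config$input_channels ||
      dim(encodings)[2] != config$input_len)
    stop(sprintf("encodings must be %d x %d x n",
                 config$input_channels, config$input_len), call. = FALSE)
  n <- dim(encodings)[3]
  stopifnot(nrow(features) == n)
  if (is.null(object$feat_stats))
    stop("model carries no feature statistics", call. = FALSE)
  x_deep <- matrix(encodings, config$input_channels * config$input_len, n)
  x_aux <- t(apply_feature_stats(features, object$feat_stats))
  out <- matrix(0, n, 4,
                dimnames = list(NULL, paste0("prob_", CLASS_LEVELS)))
  for (s in seq(1L, n, by = batch_size)) {
    b <- s:min(s + batch_size - 1L, n)
    jf <- .joint_forward(object, x_deep[, b, drop = FALSE],
                         x_aux[, b, drop = FALSE], training = FALSE)
    out[b, ] <- t(.softmax(jf$out))
  }
  out
}

#' @export
print.core_classifier <- function(x, ...) {
  cfg <- x$config
  cat("Dual-branch cis-RE classifier",
      if (isTRUE(x$trained)) "(trained)" else "(untrained)", "\n")
  cat(sprintf(" deep branch : %d conv blocks, filters [%s], kernel %d\n",
              cfg$conv_blocks,
              paste(cfg$filters_per_block, collapse = ", "),
              cfg$conv_kernel))
  cat(sprintf(" dense       : branch %d, joint %d, classes %d\n",
              cfg$branch_dense, cfg$joint_dense, cfg$n_classes))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(" final       : stage %s epoch %d, val loss %.4f, val acc %.3f\n",
                last$stage, last$epoch, last$val_loss, last$val_accuracy))
  }
  invisible(x)
}

#' @method summary core_classifier
#' @export
summary.core_classifier <- function(object, ...) {
  print(object)
  arch <- describe_architecture(object)
  cat("\nLayers:\n")
  print(arch, row.names = FALSE)
  invisible(arch)
}

#' @method plot core_classifier
#' @export
plot.core_classifier <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history", call. = FALSE)
  stages <- unique(h$stage)
  graphics::plot(seq_len(nrow(h)), h$train_loss, type = "l",
                 xlab = "epoch (stages concatenated)", ylab = "loss",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(seq_len(nrow(h)), h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(h)
}

#' Save / load a fitted classifier
#'
#' The model directory holds the parameters plus a JSON manifest of the
#' configuration; loading checks the manifest against the stored object.
#'
#' @param model A `core_classifier`.
#' @param dir Directory to create/read.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "core_classifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  cfg$tuning_grid <- NULL
  manifest <- paste(names(cfg), vapply(cfg, function(v)
    paste(v, collapse = ","), character(1)), sep = "=", collapse = "\n")
  writeLines(manifest, file.path(dir, "config.txt"))
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  model <- readRDS(file.path(dir, "model.rds"))
  stopifnot(inherits(model, "core_classifier"))
  cfg <- model$config
  cfg$tuning_grid <- NULL
  manifest <- paste(names(cfg), vapply(cfg, function(v)
    paste(v, collapse = ","), character(1)), sep = "=", collapse = "\n")
  stored <- paste(readLines(file.path(dir, "config.txt")), collapse = "\n")
  if (!identical(manifest, stored))
    stop("model directory manifest does not match stored configuration",
         call. = FALSE)
  model
}
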