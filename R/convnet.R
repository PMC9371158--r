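## Declarative CNN architectures, the training protocol with macro-F1
## checkpointing, prediction, and the activation/gradient access that
## grad-CAM requires.

#' Define one convolutional block
#'
#' A block is `n_conv_layers` length-preserving 1D convolutions (each
#' followed by ReLU), optionally followed by a max-pooling stage of size 2,
#' stride 2 (ceiling mode).
#'
#' @param n_conv_layers convolutions per block (default 2).
#' @param n_filters feature maps per convolution (default 100).
#' @param kernel_size convolution kernel width.
#' @param followed_by_pool whether a pooling stage follows the block.
#' @return a `conv_block` list.
#' @export
conv_block <- function(n_conv_layers = 2L, n_filters = 100L, kernel_size = 8L,
                       followed_by_pool = TRUE) {
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size),
                 followed_by_pool = isTRUE(followed_by_pool)),
            class = "conv_block")
}

#' Construct a CNN model specification
#'
#' Architecture: the convolutional blocks, a flatten stage, one dropout
#' layer, and a softmax classifier head of width `n_classes`.
#'
#' @param blocks list of [conv_block()].
#' @param n_classes number of output classes (>= 2).
#' @param name architecture tag (`"CNN1"`, `"CNN2"` or `"custom"`).
#' @param input_length samples per window (default 151).
#' @param input_axes channels per window (default 3).
#' @param dropout_rate dropout before the classifier head (default 0.5).
#' @return an object of class `model_spec`.
#' @export
cnn_spec <- function(blocks, n_classes, name = "custom", input_length = 151L,
                     input_axes = 3L, dropout_rate = 0.5) {
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  structure(list(name = name, blocks = blocks,
                 n_classes = as.integer(n_classes),
                 input_length = as.integer(input_length),
                 input_axes = as.integer(input_axes),
                 pool_size = 2L, pool_stride = 2L,
                 dropout_rate = dropout_rate),
            class = "model_spec")
}

#' Build the CNN1 or CNN2 reference architecture
#'
#' CNN1: 4 blocks of 2 convolutions (100 feature maps, kernel 8) with
#' pooling after blocks 1-3 (8 convolutional layers in total; final temporal
#' resolution 19 for a 151-sample input). CNN2: 3 such blocks with kernel 4
#' and pooling after blocks 1-2 (6 convolutional layers; resolution 38).
#'
#' @param name `"CNN1"` or `"CNN2"`.
#' @param n_classes softmax width (activity count for HAR, subject count for
#'   per-activity biometric identification).
#' @param input_length,input_axes input window shape (defaults 151 x 3).
#' @return a `model_spec`.
#' @export
build_architecture <- function(name = c("CNN1", "CNN2"), n_classes,
                               input_length = 151L, input_axes = 3L) {
  name <- match.arg(name)
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  if (name == "CNN1") {
    blocks <- lapply(1:4, function(i)
      conv_block(2L, 100L, 8L, followed_by_pool = i <= 3))
  } else {
    blocks <- lapply(1:3, function(i)
      conv_block(2L, 100L, 4L, followed_by_pool = i <= 2))
  }
  cnn_spec(blocks, n_classes, name = name, input_length = input_length,
           input_axes = input_axes)
}

#' @export
print.model_spec <- function(x, ...) {
  n_conv <- sum(vapply(x$blocks, `[[`, integer(1), "n_conv_layers"))
  cat(sprintf("<model_spec %s> %d blocks (%d conv layers), %d classes, input %d x %d\n",
              x$name, length(x$blocks), n_conv, x$n_classes,
              x$input_length, x$input_axes))
  invisible(x)
}

#' Temporal length of the final convolutional layer's feature maps
#'
#' Convolutions are length-preserving; each pooling stage halves the length
#' in ceiling mode. A pure function of the spec and the input length. For a
#' 151-sample input this yields 19 for CNN1 (151 -> 76 -> 38 -> 19) and 38
#' for CNN2.
#'
#' @param spec a `model_spec`.
#' @param input_length input window length (default the spec's).
#' @return integer number of temporal positions.
#' @export
last_conv_length <- function(spec, input_length = spec$input_length) {
  L <- as.integer(input_length)
  for (b in spec$blocks) if (b$followed_by_pool) L <- as.integer(ceiling(L / 2))
  L
}

#' Training protocol configuration
#'
#' The reference protocol is Adam with default hyperparameters, categorical
#' cross-entropy, 300 epochs, batch size 256, and per-epoch checkpointing on
#' validation macro F1 (earliest epoch on ties). Reduced epoch/batch values
#' are intended for desk-scale experiments; the defaults remain the
#' protocol-faithful values.
#'
#' @param epochs training epochs (default 300).
#' @param batch_size minibatch size (default 256).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @param standardize if `TRUE`, standardize each channel using training-set
#'   statistics; the default feeds raw windows.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 256L,
                         learning_rate = 1e-3, seed = 0L,
                         standardize = FALSE, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 checkpoint_metric = "val_macro_f1",
                 standardize = isTRUE(standardize),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

## Expand a model_spec into the internal layer list. The designated layer
## (whose activations/gradients grad-CAM consumes) is the ReLU output of the
## last convolution.
build_layers <- function(spec) {
  layers <- list()
  in_ch <- spec$input_axes
  for (b in spec$blocks) {
    for (j in seq_len(b$n_conv_layers)) {
      layers[[length(layers) + 1L]] <- layer_conv(b$kernel_size, in_ch,
                                                  b$n_filters)
      layers[[length(layers) + 1L]] <- list(type = "relu")
      in_ch <- b$n_filters
    }
    if (b$followed_by_pool) layers[[length(layers) + 1L]] <- list(type = "pool")
  }
  designated <- length(layers)
  while (layers[[designated]]$type != "relu") designated <- designated - 1L
  flat_dim <- last_conv_length(spec) * in_ch
  layers[[length(layers) + 1L]] <- list(type = "flatten")
  layers[[length(layers) + 1L]] <- list(type = "dropout",
                                        rate = spec$dropout_rate)
  layers[[length(layers) + 1L]] <- list(type = "dense",
                                        W = matrix(0, flat_dim, spec$n_classes),
                                        b = numeric(spec$n_classes))
  list(layers = layers, designated = designated)
}

plan_labels <- function(dataset, plan) {
  idx <- c(plan$train_indices, plan$val_indices)
  if (plan$target == "subject") {
    class_labels <- as.character(sort(unique(dataset$meta$subject[idx])))
    y <- match(as.character(dataset$meta$subject), class_labels)
  } else {
    class_labels <- dataset$activity_vocabulary
    y <- match(dataset$meta$activity, class_labels)
  }
  list(class_labels = class_labels, y = y)
}

forward_logits <- function(model, X, chunk = 512L) {
  n <- dim(X)[1]
  out <- matrix(NA_real_, n, model$spec$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    Xb <- X[s:e, , , drop = FALSE]
    out[s:e, ] <- net_forward(model$layers, Xb, train = FALSE)$out
  }
  out
}

#' Train a CNN on a split plan
#'
#' Minimizes categorical cross-entropy with Adam. After every epoch the
#' validation macro F1 is recorded and the parameters achieving the best
#' value are checkpointed (earliest epoch wins ties); the returned model
#' carries those checkpointed parameters. Class targets come from the plan:
#' activities for HAR plans, subject identities for BUI plans.
#'
#' @param spec a `model_spec`; `n_classes` must match the plan's classes.
#' @param dataset a `har_dataset`.
#' @param plan a `split_plan`.
#' @param config a [train_config()].
#' @return an object of class `har_cnn` with elements `spec`, `layers`,
#'   `class_labels`, `history` (epoch, train_loss, val_macro_f1),
#'   `checkpoint_epoch`, `designated_layer`, `warnings`.
#' @export
train_model <- function(spec, dataset, plan, config = train_config()) {
  if (length(plan$train_indices) == 0) {
    stop("training set is empty", call. = FALSE)
  }
  lab <- plan_labels(dataset, plan)
  if (length(lab$class_labels) != spec$n_classes) {
    stop(sprintf("spec has %d classes but the plan targets %d",
                 spec$n_classes, length(lab$class_labels)), call. = FALSE)
  }
  warnings <- character()
  missing_cls <- setdiff(unique(lab$y[plan$val_indices]),
                         unique(lab$y[plan$train_indices]))
  if (length(missing_cls)) {
    w <- paste("classes present in validation but absent in training:",
               paste(lab$class_labels[missing_cls], collapse = ", "))
    warnings <- c(warnings, w)
    warning(w, call. = FALSE)
  }

  Xtr <- dataset$values[plan$train_indices, , , drop = FALSE]
  Xva <- dataset$values[plan$val_indices, , , drop = FALSE]
  ytr <- lab$y[plan$train_indices]
  yva <- lab$y[plan$val_indices]
  center <- NULL; scale_ <- NULL
  if (config$standardize) {
    center <- apply(Xtr, 3, mean)
    scale_ <- pmax(apply(Xtr, 3, stats::sd), 1e-8)
    for (a in seq_len(dim(Xtr)[3])) {
      Xtr[, , a] <- (Xtr[, , a] - center[a]) / scale_[a]
      Xva[, , a] <- (Xva[, , a] - center[a]) / scale_[a]
    }
  }

  with_preserved_rng({
    set.seed(config$seed)
    bl <- build_layers(spec)
    layers <- lapply(bl$layers, init_layer_params)
    state <- adam_init(layers)
    model <- structure(
      list(spec = spec, layers = layers, class_labels = lab$class_labels,
           designated_layer = bl$designated, target = plan$target,
           standardize = config$standardize, center = center,
           scale = scale_, warnings = warnings),
      class = "har_cnn")

    n_tr <- length(ytr)
    onehot <- diag(spec$n_classes)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_macro_f1 = numeric())
    best_f1 <- -Inf; best_layers <- layers; best_epoch <- NA_integer_
    step_t <- 0L

    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_tr)
      losses <- numeric(0)
      for (s in seq(1L, n_tr, by = config$batch_size)) {
        bidx <- perm[s:min(n_tr, s + config$batch_size - 1L)]
        Xb <- Xtr[bidx, , , drop = FALSE]
        yb <- ytr[bidx]
        fw <- net_forward(layers, Xb, train = TRUE)
        P <- softmax_rows(fw$out)
        losses <- c(losses, -mean(log(pmax(P[cbind(seq_along(yb), yb)], 1e-12))))
        dZ <- (P - onehot[yb, , drop = FALSE]) / length(yb)
        bw <- net_backward(layers, fw$caches, dZ)
        step_t <- step_t + 1L
        upd <- adam_step(layers, bw$grads, state, step_t,
                         lr = config$learning_rate)
        layers <- upd$layers; state <- upd$state
      }
      model$layers <- layers
      pred <- max.col(forward_logits(model, Xva), ties.method = "first")
      cm <- confusion_matrix(lab$class_labels[yva], lab$class_labels[pred],
                             lab$class_labels)
      f1 <- aggregate_metrics(per_class_metrics(cm))$macro$f1
      history[epoch, ] <- list(epoch, mean(losses), f1)
      if (f1 > best_f1) {
        best_f1 <- f1; best_layers <- layers; best_epoch <- epoch
      }
      if (config$verbose) {
        message(sprintf("epoch %3d  loss %.4f  val macro F1 %.4f",
                        epoch, mean(losses), f1))
      }
    }
    model$layers <- best_layers
    model$history <- history
    model$checkpoint_epoch <- best_epoch
    model
  })
}

as_window_array <- function(model, newdata) {
  sp <- model$spec
  if (inherits(newdata, "har_dataset")) {
    X <- newdata$values
  } else if (inherits(newdata, "signal_window")) {
    X <- array(newdata$values, dim = c(1L, dim(newdata$values)))
  } else if (is.list(newdata)) {
    X <- array(0, dim = c(length(newdata), sp$input_length, sp$input_axes))
    for (i in seq_along(newdata)) X[i, , ] <- newdata[[i]]$values
  } else if (is.array(newdata) && length(dim(newdata)) == 3L) {
    X <- newdata
  } else if (is.matrix(newdata)) {
    X <- array(newdata, dim = c(1L, dim(newdata)))
  } else {
    stop("cannot interpret newdata as windows", call. = FALSE)
  }
  if (dim(X)[2] != sp$input_length || dim(X)[3] != sp$input_axes) {
    stop(sprintf("window shape %d x %d does not match model input %d x %d",
                 dim(X)[2], dim(X)[3], sp$input_length, sp$input_axes),
         call. = FALSE)
  }
  if (isTRUE(model$standardize)) {
    for (a in seq_len(dim(X)[3])) {
      X[, , a] <- (X[, , a] - model$center[a]) / model$scale[a]
    }
  }
  X
}

#' Predict class scores for windows
#'
#' @param object a trained `har_cnn`.
#' @param newdata a `har_dataset`, a `signal_window`, a list of windows, a
#'   `timesteps x axes` matrix, or a 3-d array of windows.
#' @param ... unused.
#' @return list with `scores` (softmax probabilities, one row per window),
#'   `class` (1-based index of the predicted class; exact ties resolve to
#'   the lowest index) and `label` (predicted class label).
#' @export
predict.har_cnn <- function(object, newdata, ...) {
  X <- as_window_array(object, newdata)
  P <- softmax_rows(forward_logits(object, X))
  cls <- max.col(P, ties.method = "first")
  list(scores = P, class = cls, label = object$class_labels[cls])
}

#' @export
print.har_cnn <- function(x, ...) {
  cat(sprintf("<har_cnn %s> %d classes (%s target)",
              x$spec$name, x$spec$n_classes, x$target))
  if (!is.null(x$checkpoint_epoch)) {
    cat(sprintf(" | checkpoint epoch %d, val macro F1 %.3f",
                x$checkpoint_epoch,
                x$history$val_macro_f1[x$checkpoint_epoch]))
  }
  cat("\n")
  invisible(x)
}

## Forward pass from the designated layer's output (feature maps Z x K) to
## the classifier logits. Used by grad-CAM's finite-difference oracle.
forward_from_designated <- function(model, A) {
  X <- array(A, dim = c(1L, nrow(A), ncol(A)))
  net_forward(model$layers, X, train = FALSE,
              from = model$designated_layer + 1L)$out[1, ]
}

#' Feature maps and class-score gradient at the last convolutional layer
#'
#' Runs the window through the network and returns the designated layer's
#' activations (the post-ReLU feature maps of the last convolution) together
#' with the gradient of the class score with respect to them, computed by
#' backpropagation. By default the score is the pre-softmax logit of
#' `class_index`; set `post_softmax = TRUE` to differentiate the softmax
#' probability instead.
#'
#' @param model a trained `har_cnn`.
#' @param window a `signal_window` or `timesteps x axes` matrix.
#' @param class_index 1-based class index (<= `n_classes`).
#' @param post_softmax differentiate the softmax output instead of the logit.
#' @return list with `feature_maps` and `gradient`, both
#'   `positions x n_filters` matrices of identical shape.
#' @export
activations_and_gradient <- function(model, window, class_index,
                                     post_softmax = FALSE) {
  if (class_index < 1 || class_index > model$spec$n_classes) {
    stop(sprintf("class_index must lie in [1, %d]", model$spec$n_classes),
         call. = FALSE)
  }
  X <- as_window_array(model, window)
  if (dim(X)[1] != 1L) stop("supply a single window", call. = FALSE)
  fw <- net_forward(model$layers, X, train = FALSE)
  logits <- fw$out
  dZ <- matrix(0, 1L, model$spec$n_classes)
  if (post_softmax) {
    p <- softmax_rows(logits)[1, ]
    dZ[1, ] <- -p[class_index] * p
    dZ[1, class_index] <- p[class_index] * (1 - p[class_index])
  } else {
    dZ[1, class_index] <- 1
  }
  bw <- net_backward(model$layers, fw$caches, dZ,
                     from = length(model$layers),
                     to = model$designated_layer + 1L)
  ## recover the designated layer's output from the relu cache of the next
  ## forward evaluation: recompute activations up to the designated layer
  A <- net_forward(model$layers, X, train = FALSE,
                   to = model$designated_layer)$out
  Amat <- A[1, , ]
  dim(Amat) <- dim(A)[2:3]
  G <- bw$dX[1, , ]
  dim(G) <- dim(bw$dX)[2:3]
  list(feature_maps = Amat, gradient = G)
}

#' Save a trained model to a directory
#'
#' Writes `params.npy` (all parameters, flattened), `model.json` (the spec,
#' class labels, checkpoint epoch and parameter shapes) and `history.tsv`.
#'
#' @param model a `har_cnn`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  params <- numeric(0); shapes <- list()
  for (j in seq_along(model$layers)) {
    l <- model$layers[[j]]
    if (!is.null(l$W)) {
      shapes[[as.character(j)]] <- list(W = dim(l$W), b = length(l$b))
      params <- c(params, as.vector(l$W), l$b)
    }
  }
  write_npy(params, file.path(path, "params.npy"), dtype = "float64")
  spec <- model$spec
  meta <- list(
    name = spec$name, n_classes = spec$n_classes,
    input_length = spec$input_length, input_axes = spec$input_axes,
    dropout_rate = spec$dropout_rate,
    blocks = lapply(spec$blocks, function(b) b[1:4]),
    class_labels = model$class_labels, target = model$target,
    designated_layer = model$designated_layer,
    checkpoint_epoch = model$checkpoint_epoch,
    standardize = isTRUE(model$standardize),
    center = model$center, scale = model$scale,
    shapes = shapes
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(path, "model.json"), useBytes = TRUE)
  if (!is.null(model$history)) {
    utils::write.table(model$history, file.path(path, "history.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path model directory.
#' @return a `har_cnn`.
#' @export
load_model <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "model.json"),
                             simplifyDataFrame = FALSE)
  blocks <- lapply(meta$blocks, function(b)
    conv_block(b$n_conv_layers, b$n_filters, b$kernel_size,
               b$followed_by_pool))
  spec <- cnn_spec(blocks, meta$n_classes, name = meta$name,
                   input_length = meta$input_length,
                   input_axes = meta$input_axes,
                   dropout_rate = meta$dropout_rate)
  bl <- build_layers(spec)
  layers <- bl$layers
  params <- read_npy(file.path(path, "params.npy"))
  pos <- 1L
  for (j in seq_along(layers)) {
    l <- layers[[j]]
    if (!is.null(l$W)) {
      nw <- length(l$W); nb <- length(l$b)
      layers[[j]]$W <- matrix(params[pos:(pos + nw - 1L)], nrow(l$W), ncol(l$W))
      pos <- pos + nw
      layers[[j]]$b <- params[pos:(pos + nb - 1L)]
      pos <- pos + nb
    }
  }
  hist_path <- file.path(path, "history.tsv")
  history <- if (file.exists(hist_path)) {
    utils::read.delim(hist_path)
  } else NULL
  structure(
    list(spec = spec, layers = layers,
         class_labels = as.character(unlist(meta$class_labels)),
         designated_layer = bl$designated, target = meta$target,
         standardize = isTRUE(meta$standardize),
         center = unlist(meta$center), scale = unlist(meta$scale),
         warnings = character(), history = history,
         checkpoint_epoch = meta$checkpoint_epoch),
    class = "har_cnn")
}
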