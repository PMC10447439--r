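# Fitting interface for the ConvBiLSTM delineator.  The compiled core
# (src/conv_bilstm.cpp) does the numerics; this file owns configuration,
# seeded initialization, and the S3 modelling surface.

#' Delineator architecture configuration
#'
#' Four 1-D convolution layers ('same' padding, stride 1, ReLU, no
#' pooling, so per-node resolution is preserved) followed by one
#' bidirectional LSTM and a per-node softmax over the five classes.
#' The layer count and class count are fixed by the architecture; filter
#' counts and LSTM width are tunable.  The defaults are sized for
#' single-CPU training at desk scale.
#'
#' @param conv_filters Integer vector of 4 filter counts.
#' @param conv_kernel Odd kernel width (default 5).
#' @param bilstm_units Hidden units per LSTM direction.
#' @param input_length Beat length `L` in samples (default 512).
#' @param n_classes Number of label classes (fixed at 5).
#' @return A list of class `convbilstm_config`.
#' @export
model_config <- function(conv_filters = c(8L, 16L, 32L, 32L),
                         conv_kernel = 5L, bilstm_units = 32L,
                         input_length = 512L, n_classes = 5L) {
  if (length(conv_filters) != 4L)
    stop("the architecture has exactly 4 convolution layers; ",
         "`conv_filters` must have length 4", call. = FALSE)
  if (n_classes != 5L)
    stop("the delineator labels exactly 5 classes (",
         paste(ecg_classes(), collapse = ", "), ")", call. = FALSE)
  conv_filters <- as.integer(conv_filters)
  if (any(conv_filters < 1L) || bilstm_units < 1L || input_length < 1L)
    stop("all layer sizes must be >= 1", call. = FALSE)
  if (conv_kernel < 1L || conv_kernel %% 2L == 0L)
    stop("`conv_kernel` must be a positive odd width", call. = FALSE)
  structure(list(n_conv_layers = 4L, conv_filters = conv_filters,
                 conv_kernel = as.integer(conv_kernel),
                 bilstm_units = as.integer(bilstm_units),
                 input_length = as.integer(input_length),
                 n_classes = 5L),
            class = "convbilstm_config")
}

#' Training configuration
#'
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param epochs Number of passes over the training set (0 returns an
#'   untrained model).
#' @param seed Integer seed controlling weight initialization and
#'   shuffling; a fit is fully reproducible given the seed.
#' @return A list of class `train_config`.  The optimizer is Adam and
#'   the loss categorical cross-entropy, by construction.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-3,
                         epochs = 30L, seed = 1L) {
  if (batch_size < 1L || epochs < 0L || learning_rate <= 0)
    stop("need batch_size >= 1, epochs >= 0, learning_rate > 0",
         call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = as.numeric(learning_rate),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = "Adam", loss = "categorical_cross_entropy"),
            class = "train_config")
}

# seeded Glorot-uniform initialization of all parameter matrices
.init_params <- function(config, seed) {
  glorot <- function(nr, nc, fan_in = nc, fan_out = nr) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  .with_seed(seed, {
    k <- config$conv_kernel
    ch <- c(1L, config$conv_filters)
    P <- list()
    for (l in 1:4) {
      P[[paste0("W", l)]] <- glorot(k * ch[l], ch[l + 1L],
                                    fan_in = k * ch[l], fan_out = ch[l + 1L])
      P[[paste0("b", l)]] <- matrix(0, ch[l + 1L], 1)
    }
    H <- config$bilstm_units
    C <- ch[5L]
    for (d in c("f", "b")) {
      P[[paste0("Wx_", d)]] <- glorot(4L * H, C)
      P[[paste0("Wh_", d)]] <- glorot(4L * H, H)
      b <- matrix(0, 4L * H, 1)
      b[(H + 1L):(2L * H), 1] <- 1  # forget-gate bias at 1
      P[[paste0("b_", d)]] <- b
    }
    P$Wy_f <- glorot(config$n_classes, H)
    P$Wy_b <- glorot(config$n_classes, H)
    P$b_y <- matrix(0, config$n_classes, 1)
    P
  })
}

.coerce_beats <- function(x, y, L) {
  if (is.list(x) && length(x) && inherits(x[[1L]], "ecg_beat")) {
    m <- beats_to_matrices(x)
    if (m$L != L)
      stop("beats have length ", m$L, " but the model expects L = ", L,
           call. = FALSE)
    return(m)
  }
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(is.matrix(x))
  if (ncol(x) != L)
    stop("input has ", ncol(x), " columns but the model expects L = ", L,
         call. = FALSE)
  yi <- NULL
  if (!is.null(y)) {
    if (is.character(y)) y <- matrix(match(y, ecg_classes()), nrow(x), L)
    if (is.numeric(y)) yi <- matrix(as.integer(y), nrow(x), ncol(x))
    if (anyNA(yi) || any(yi < 1L) || any(yi > 5L))
      stop("labels must code the five classes (1..5 or class names)",
           call. = FALSE)
  }
  list(x = x, y = yi, L = L)
}

#' Fit a ConvBiLSTM delineator
#'
#' Trains the per-node classifier with Adam on the categorical
#' cross-entropy.  With `control$epochs = 0` (or `x = NULL`) the
#' seeded, initialized but untrained model is returned, which is useful
#' for inspecting the architecture or as a fixed starting point.
#'
#' @param x Training beats: a list of labeled [ecg_beat] objects, or an
#'   `n x L` signal matrix (then `y` is required).
#' @param y Optional `n x L` label matrix (class names or codes 1..5)
#'   when `x` is a matrix.
#' @param model A [model_config].
#' @param control A [train_config].
#' @param validation Optional held-out beats in the same form as `x`
#'   (or `list(x = , y = )`); evaluated after every epoch.
#' @return An object of class `conv_bilstm` with elements `params`
#'   (weights), `model`, `control` and `history` (per-epoch loss and
#'   node accuracy for training and validation).
#' @export
conv_bilstm <- function(x = NULL, y = NULL, model = model_config(),
                        control = train_config(), validation = NULL) {
  stopifnot(inherits(model, "convbilstm_config"),
            inherits(control, "train_config"))
  params <- .init_params(model, control$seed)
  fit <- structure(list(params = params, model = model, control = control,
                        history = data.frame()),
                   class = "conv_bilstm")
  if (is.null(x) || control$epochs == 0L) return(fit)
  tr <- .coerce_beats(x, y, model$input_length)
  if (is.null(tr$y))
    stop("training requires labeled beats", call. = FALSE)
  if (nrow(tr$x) == 0L) stop("empty training set", call. = FALSE)
  va <- NULL
  if (!is.null(validation)) {
    va <- if (is.list(validation) && !is.null(validation$x))
      .coerce_beats(validation$x, validation$y, model$input_length)
    else .coerce_beats(validation, NULL, model$input_length)
    if (is.null(va$y)) stop("validation beats must be labeled", call. = FALSE)
  }
  shuffle <- .with_seed(control$seed + 1L,
    t(vapply(seq_len(control$epochs),
             function(e) sample.int(nrow(tr$x)), integer(nrow(tr$x)))))
  res <- cb_train_cpp(tr$x, tr$y, params, model$conv_kernel,
                      model$n_classes,
                      control$epochs, control$batch_size,
                      control$learning_rate, shuffle,
                      if (is.null(va)) NULL else va$x,
                      if (is.null(va)) NULL else va$y)
  fit$params <- res$params
  fit$history <- data.frame(epoch = seq_len(control$epochs),
                            loss = res$loss, accuracy = res$accuracy,
                            val_loss = res$val_loss,
                            val_accuracy = res$val_accuracy)
  fit
}

#' Predict per-node classes or probabilities
#'
#' Prediction is a pure function of the weights and the input.  Argmax
#' ties are broken toward the lower class index in [ecg_classes] order.
#'
#' @param object A fitted [conv_bilstm].
#' @param x A length-`L` signal vector, an `n x L` matrix, or a list of
#'   [ecg_beat] objects.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return For a single signal: a character vector of length `L`
#'   (`type = "class"`) or an `L x 5` probability matrix.  For several:
#'   an `n x L` character matrix or an `L x 5 x n` array.
#' @export
predict.conv_bilstm <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  single <- is.numeric(x) && is.null(dim(x))
  d <- .coerce_beats(x, NULL, object$model$input_length)
  prob <- cb_forward_cpp(d$x, object$params, object$model$conv_kernel,
                         object$model$n_classes)
  dimnames(prob) <- list(NULL, ecg_classes(), NULL)
  if (type == "prob")
    return(if (single) prob[, , 1L] else prob)
  cls <- ecg_classes()
  lab <- apply(prob, 3L, function(p) cls[max.col(p, ties.method = "first")])
  if (single) as.vector(lab) else t(lab)
}

#' Per-node delineation of one beat
#'
#' Convenience wrapper returning both the label sequence and the
#' probability matrix for a single length-`L` signal.
#'
#' @param model A fitted [conv_bilstm].
#' @param signal Numeric vector of length `L`.
#' @return List with `labels` (character, length `L`) and `prob`
#'   (`L x 5` matrix; rows sum to 1).
#' @export
predict_nodes <- function(model, signal) {
  stopifnot(is.numeric(signal), is.null(dim(signal)))
  prob <- predict(model, signal, type = "prob")
  list(labels = ecg_classes()[max.col(prob, ties.method = "first")],
       prob = prob)
}

#' @export
print.conv_bilstm <- function(x, ...) {
  m <- x$model
  cat(sprintf("<conv_bilstm> L = %d, conv filters %s (kernel %d), BiLSTM %d/direction, %d classes\n",
              m$input_length, paste(m$conv_filters, collapse = "-"),
              m$conv_kernel, m$bilstm_units, m$n_classes))
  if (nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs (batch %d, lr %g): loss %.4f, node accuracy %.2f%%",
                nrow(x$history), x$control$batch_size,
                x$control$learning_rate, h$loss, 100 * h$accuracy))
    if (!is.na(h$val_accuracy))
      cat(sprintf(" | val %.4f / %.2f%%", h$val_loss, 100 * h$val_accuracy))
    cat("\n")
  } else cat("  untrained (initialized with seed ", x$control$seed, ")\n",
             sep = "")
  invisible(x)
}

#' @export
summary.conv_bilstm <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$params, length, 0L))
  cat(sprintf("  %d trainable parameters in %d tensors\n",
              n_par, length(object$params)))
  if (nrow(object$history)) {
    cat("  history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.conv_bilstm <- function(object, ...) object$params

#' Plot the training history
#'
#' @param x A fitted [conv_bilstm].
#' @param ... Passed to [graphics::matplot].
#' @export
plot.conv_bilstm <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot", call. = FALSE)
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l",
                    lty = 1:2, col = c("black", "red"),
                    xlab = "epoch", ylab = "cross-entropy", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Save / load a fitted delineator
#'
#' Single-file checkpoints via R serialization.
#'
#' @param model A fitted [conv_bilstm].
#' @param path Checkpoint file path.
#' @return `save_delineator` returns `path` invisibly; `load_delineator`
#'   the restored model.
#' @export
save_delineator <- function(model, path) {
  stopifnot(inherits(model, "conv_bilstm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_delineator
#' @export
load_delineator <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "conv_bilstm"))
    stop("'", path, "' is not a conv_bilstm checkpoint", call. = FALSE)
  m
}
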