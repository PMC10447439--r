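# Grid search over batch size / learning rate / epochs, and node-level
# evaluation with one-vs-rest accuracy, sensitivity and precision.

#' Hyperparameter grid
#'
#' Default axes: batch sizes 8/16/32, learning rates 1e-3/1e-4/1e-5 and
#' epoch counts 100/200/300/400 — 36 combinations.
#'
#' @param batch_sizes,learning_rates,epoch_counts Non-empty axes.
#' @return A list of class `hyper_grid`.
#' @export
hyper_grid <- function(batch_sizes = c(8L, 16L, 32L),
                       learning_rates = c(1e-3, 1e-4, 1e-5),
                       epoch_counts = c(100L, 200L, 300L, 400L)) {
  if (!length(batch_sizes) || !length(learning_rates) ||
      !length(epoch_counts))
    stop("every grid axis must be non-empty", call. = FALSE)
  structure(list(batch_sizes = as.integer(batch_sizes),
                 learning_rates = as.numeric(learning_rates),
                 epoch_counts = as.integer(epoch_counts)),
            class = "hyper_grid")
}

#' Enumerate a grid as training configurations
#'
#' Cartesian product in lexicographic order: batch size varies slowest,
#' then learning rate, then epochs.
#'
#' @param grid A [hyper_grid].
#' @param seed Seed attached to every configuration.
#' @return A `data.frame` with columns `batch_size`, `learning_rate`,
#'   `epochs`; one row per combination.
#' @export
enumerate_grid <- function(grid = hyper_grid(), seed = 1L) {
  stopifnot(inherits(grid, "hyper_grid"))
  out <- expand.grid(epochs = grid$epoch_counts,
                     learning_rate = grid$learning_rates,
                     batch_size = grid$batch_sizes,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[, c("batch_size", "learning_rate", "epochs")]
  out$seed <- as.integer(seed)
  rownames(out) <- NULL
  out
}

#' Node-level evaluation report
#'
#' One-vs-rest confusion counts over all nodes for each of the five
#' classes, with accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)` and
#' precision `TP/(TP+FP)` in percent, and unweighted macro averages over
#' the classes present in the union of true and predicted labels.
#' Metrics with a zero denominator are `NA` and are excluded from the
#' macro means rather than coerced to zero.
#'
#' @param true,pred Aligned label vectors (class names or codes 1..5).
#' @return An object of class `ecg_eval`: list with `per_class`
#'   (data.frame), `average` (named vector `acc`/`sen`/`pre`) and
#'   `n_nodes`.
#' @export
evaluate_nodes <- function(true, pred) {
  if (length(true) != length(pred))
    stop("true and pred must have the same length", call. = FALSE)
  cls <- ecg_classes()
  if (is.numeric(true)) true <- cls[true]
  if (is.numeric(pred)) pred <- cls[pred]
  n <- length(true)
  tab <- table(factor(true, levels = cls), factor(pred, levels = cls))
  per <- data.frame(class = cls, TP = NA_real_, TN = NA_real_,
                    FP = NA_real_, FN = NA_real_, acc = NA_real_,
                    sen = NA_real_, pre = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cls)) {
    tp <- tab[i, i]
    fn <- sum(tab[i, ]) - tp
    fp <- sum(tab[, i]) - tp
    tn <- n - tp - fn - fp
    per[i, c("TP", "TN", "FP", "FN")] <- c(tp, tn, fp, fn)
    per$acc[i] <- 100 * (tp + tn) / n
    per$sen[i] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    per$pre[i] <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  }
  present <- cls %in% union(true, pred)
  avg <- c(acc = mean(per$acc[present]),
           sen = mean(per$sen[present], na.rm = TRUE),
           pre = mean(per$pre[present], na.rm = TRUE))
  structure(list(per_class = per, average = avg, n_nodes = n),
            class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  cat(sprintf("<ecg_eval> %d nodes\n", x$n_nodes))
  print(transform(x$per_class, acc = round(acc, 2), sen = round(sen, 2),
                  pre = round(pre, 2)), row.names = FALSE)
  cat(sprintf("  macro average: Acc %.2f%%  Sen %.2f%%  Pre %.2f%%\n",
              x$average["acc"], x$average["sen"], x$average["pre"]))
  invisible(x)
}

#' Record-level train/validation split
#'
#' Seeded shuffle, then the first `floor(n * train_fraction)` ids train
#' and the remainder validate; the split is disjoint at the record
#' level so beats from one record never straddle the split.
#'
#' @param record_ids Character or integer vector of record ids.
#' @param train_fraction Fraction in (0, 1) (default 0.9).
#' @param seed Integer seed.
#' @return List with `train` and `validation` id vectors.
#' @export
split_records <- function(record_ids, train_fraction = 0.9, seed = 1L) {
  n <- length(record_ids)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  shuffled <- .with_seed(seed, sample(record_ids))
  n_train <- floor(n * train_fraction)
  list(train = shuffled[seq_len(n_train)],
       validation = shuffled[(n_train + 1L):n])
}

#' Grid-search the delineator's hyperparameters
#'
#' Trains one model per grid combination (all from the same seed, so
#' runs differ only in hyperparameters), evaluates every model on all
#' validation nodes (padding class included), and selects the best by
#' highest macro accuracy, ties broken by higher macro sensitivity,
#' then by enumeration order.
#'
#' @param beats_train,beats_val Non-empty lists of labeled [ecg_beat]s.
#' @param grid A [hyper_grid].
#' @param model A [model_config].
#' @param seed Integer seed used for every training run.
#' @return An object of class `grid_search`: list with `results` (one
#'   row per combination: hyperparameters + macro metrics), `reports`
#'   (the [evaluate_nodes] objects), `best_index` and `best_model`.
#' @export
grid_search <- function(beats_train, beats_val, grid = hyper_grid(),
                        model = model_config(), seed = 1L) {
  if (!length(beats_train) || !length(beats_val))
    stop("train and validation beat sets must be non-empty", call. = FALSE)
  configs <- enumerate_grid(grid, seed)
  va <- beats_to_matrices(beats_val)
  truth <- as.vector(t(va$y))
  results <- configs
  results$acc <- results$sen <- results$pre <- NA_real_
  reports <- vector("list", nrow(configs))
  fits <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    tc <- train_config(batch_size = configs$batch_size[i],
                       learning_rate = configs$learning_rate[i],
                       epochs = configs$epochs[i], seed = seed)
    fit <- tryCatch(
      conv_bilstm(beats_train, model = model, control = tc),
      error = function(e)
        stop(sprintf("training failed for batch %d / lr %g / epochs %d: %s",
                     tc$batch_size, tc$learning_rate, tc$epochs,
                     conditionMessage(e)), call. = FALSE))
    pred <- predict(fit, va$x, type = "class")
    rep <- evaluate_nodes(ecg_classes()[truth], as.vector(t(pred)))
    reports[[i]] <- rep
    fits[[i]] <- fit
    results$acc[i] <- rep$average["acc"]
    results$sen[i] <- rep$average["sen"]
    results$pre[i] <- rep$average["pre"]
  }
  ord <- order(-results$acc, -results$sen, seq_len(nrow(results)))
  best <- ord[1L]
  structure(list(results = results, reports = reports,
                 best_index = best, best_model = fits[[best]]),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search> %d configurations\n", nrow(x$results)))
  print(transform(x$results, acc = round(acc, 3), sen = round(sen, 3),
                  pre = round(pre, 3)), row.names = FALSE)
  b <- x$results[x$best_index, ]
  cat(sprintf("  best: batch %d, lr %g, epochs %d (Acc %.3f%%)\n",
              b$batch_size, b$learning_rate, b$epochs, b$acc))
  invisible(x)
}
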