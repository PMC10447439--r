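test_that("the default grid enumerates 36 configurations in order", {
  g <- enumerate_grid(hyper_grid())
  expect_identical(nrow(g), 36L)
  # batch size varies slowest, epochs fastest
  expect_identical(g$batch_size, rep(c(8L, 16L, 32L), each = 12L))
  expect_identical(g$epochs[1:4], c(100L, 200L, 300L, 400L))
  expect_identical(g$learning_rate[c(1, 5, 9)], c(1e-3, 1e-4, 1e-5))
})

test_that("grid enumeration is the exact Cartesian product", {
  g <- enumerate_grid(hyper_grid(c(8L, 16L), c(1e-3, 1e-4), c(10L, 20L)))
  hand <- data.frame(
    batch_size = c(8L, 8L, 8L, 8L, 16L, 16L, 16L, 16L),
    learning_rate = rep(c(1e-3, 1e-3, 1e-4, 1e-4), 2),
    epochs = rep(c(10L, 20L), 4))
  expect_identical(g[, 1:3], hand)
  expect_identical(nrow(enumerate_grid(hyper_grid(8L, 1e-3, 100L))), 1L)
  expect_error(hyper_grid(integer(), 1e-3, 100L), "non-empty")
})

test_that("node metrics match a brute-force confusion computation", {
  # worked 4-node example
  ev <- evaluate_nodes(c("P", "P", "QRS", "ISO"),
                       c("P", "QRS", "QRS", "ISO"))
  p <- ev$per_class[ev$per_class$class == "P", ]
  expect_equal(p$sen, 50)
  expect_equal(p$pre, 100)
  expect_equal(p$acc, 75)
  # perfect prediction
  ev2 <- evaluate_nodes(c("P", "T", "ISO"), c("P", "T", "ISO"))
  expect_true(all(ev2$per_class$acc == 100))
  expect_equal(unname(ev2$average), c(100, 100, 100))
  # brute-force oracle over seeded random label pairs
  brute <- function(true, pred) {
    out <- list()
    for (cl in ecg_classes()) {
      tp <- tn <- fp <- fn <- 0
      for (i in seq_along(true)) {
        if (true[i] == cl && pred[i] == cl) tp <- tp + 1
        else if (true[i] == cl) fn <- fn + 1
        else if (pred[i] == cl) fp <- fp + 1
        else tn <- tn + 1
      }
      out[[cl]] <- c(TP = tp, TN = tn, FP = fp, FN = fn,
                     acc = 100 * (tp + tn) / length(true),
                     sen = if (tp + fn > 0) 100 * tp / (tp + fn) else NA,
                     pre = if (tp + fp > 0) 100 * tp / (tp + fp) else NA)
    }
    out
  }
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(50:400, 1)
    true <- sample(ecg_classes(), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.7, true,
                   sample(ecg_classes(), n, replace = TRUE))
    ev <- evaluate_nodes(true, pred)
    bf <- brute(true, pred)
    for (cl in ecg_classes()) {
      row <- ev$per_class[ev$per_class$class == cl, ]
      expect_identical(unname(unlist(row[c("TP", "TN", "FP", "FN")])),
                       unname(bf[[cl]][1:4]))
      expect_equal(row$acc, unname(bf[[cl]]["acc"]))
    }
    expect_identical(sum(ev$per_class[1, c("TP", "TN", "FP", "FN")]),
                     as.numeric(n))
  }
})

test_that("degenerate classes are excluded from macro averages", {
  ev <- evaluate_nodes(c("P", "P", "ISO"), c("P", "P", "ISO"))
  per <- ev$per_class
  expect_true(is.na(per$sen[per$class == "T"]))
  # macro mean over the two present classes only
  expect_equal(unname(ev$average["sen"]), 100)
  expect_error(evaluate_nodes(c("P", "P"), "P"), "same length")
})

test_that("record splits are seeded, sized and disjoint", {
  ids <- sprintf("rec%03d", 1:200)
  sp <- split_records(ids, 0.9, seed = 13)
  expect_length(sp$train, 180L)
  expect_length(sp$validation, 20L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(split_records(ids, 0.9, seed = 13), sp)
  expect_false(identical(split_records(ids, 0.9, seed = 14), sp))
  two <- split_records(c("a", "b"), 0.5, seed = 1)
  expect_length(two$train, 1L)
  expect_length(two$validation, 1L)
  expect_error(split_records("a", 0.5), "at least 2")
  expect_error(split_records(ids, 1.2), "in \\(0, 1\\)")
})

test_that("grid search ranks deterministically and returns its best", {
  beats <- tiny_beats()
  grid <- hyper_grid(batch_sizes = c(4L, 8L), learning_rates = 3e-3,
                     epoch_counts = c(2L, 5L))
  gs1 <- grid_search(beats[1:16], beats[17:24], grid = grid,
                     model = tiny_model(), seed = 11)
  expect_identical(nrow(gs1$results), 4L)
  gs2 <- grid_search(beats[1:16], beats[17:24], grid = grid,
                     model = tiny_model(), seed = 11)
  expect_identical(gs1$results, gs2$results)
  expect_identical(gs1$best_index, gs2$best_index)
  # the winner is in the table and undominated on (acc, sen)
  best <- gs1$results[gs1$best_index, ]
  dominated <- with(gs1$results,
                    any(acc > best$acc |
                          (acc == best$acc & sen > best$sen &
                             seq_along(acc) < gs1$best_index)))
  expect_false(dominated)
  single <- grid_search(beats[1:16], beats[17:24],
                        grid = hyper_grid(4L, 3e-3, 2L),
                        model = tiny_model(), seed = 11)
  expect_identical(single$best_index, 1L)
  expect_identical(nrow(single$results), 1L)
  expect_error(grid_search(list(), beats[17:24], grid = grid), "non-empty")
})
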