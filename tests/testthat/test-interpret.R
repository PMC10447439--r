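test_that("run-length decoding finds maximal wave runs", {
  labels <- c(rep("ISO", 10), rep("P", 20), rep("ISO", 5), rep("QRS", 15),
              rep("ISO", 10))
  signal <- seq_along(labels) / 60
  seg <- extract_segments(labels, signal, 500)
  expect_identical(seg$wave_type, c("P", "QRS"))
  expect_identical(seg$onset, c(10L, 35L))
  expect_identical(seg$offset, c(29L, 49L))
  # a 1-node run is 2 ms at 500 Hz, under the 20 ms floor
  flick <- c(rep("ISO", 5), "QRS", rep("ISO", 5))
  expect_identical(nrow(extract_segments(flick, numeric(11), 500)), 0L)
  # peaks sit on the largest |amplitude| inside the run
  sig2 <- numeric(60)
  sig2[21] <- -2
  seg2 <- extract_segments(c(rep("ISO", 10), rep("QRS", 20), rep("ISO", 30)),
                           sig2, 500)
  expect_identical(seg2$peak, 20L)
})

test_that("label round-trip recovers annotation boundaries exactly", {
  set.seed(41)
  for (rep in 1:20) {
    n_waves <- sample(1:6, 1)
    # non-adjacent intervals with >= 2 ISO samples between them
    starts <- cumsum(sample(15:30, n_waves))
    widths <- sample(11:13, n_waves, replace = TRUE)
    ann <- wave_annotations(sample(c("P", "QRS", "T"), n_waves,
                                   replace = TRUE),
                            onset = starts, peak = NA_integer_,
                            offset = starts + widths)
    n <- max(ann$offset) + 5L
    labels <- annotations_to_node_labels(ann, n)
    seg <- extract_segments(labels, rnorm(n), 500)
    expect_identical(seg$onset, ann$onset)
    expect_identical(seg$offset, ann$offset)
    expect_identical(seg$wave_type, ann$wave_type)
  }
})

test_that("RR intervals difference successive QRS peaks", {
  seg <- wave_annotations(rep("QRS", 3), onset = c(0L, 495L, 995L),
                          peak = c(0L, 500L, 1000L),
                          offset = c(5L, 505L, 1005L))
  rr <- rr_intervals(seg, 500)
  expect_equal(as.numeric(rr), c(1000, 1000))
  expect_false(attr(rr, "insufficient_beats"))
  one <- rr_intervals(seg[1, ], 500)
  expect_length(one, 0L)
  expect_true(attr(one, "insufficient_beats"))
})

test_that("generated RR schedules are recovered within one sample", {
  g <- generate_rhythm(rhythm_spec("NSR", duration_s = 30, seed = 44))
  rr <- rr_intervals(g$annotations, 500)
  sched <- g$rr_ms
  # QRS peaks sit at a fixed offset inside each beat, so rr[i] is the
  # length of beat i, i.e. the drawn interval up to sample rounding
  expect_gte(length(rr), length(sched) - 2L)
  expect_lt(max(abs(rr - sched[seq_along(rr)])), 2 * 1000 / 500)
})

test_that("regularity is a CV threshold on the RR intervals", {
  expect_true(rhythm_regularity(c(800, 800, 800)))
  set.seed(45)
  rr <- 700 * exp(rnorm(50, 0, 0.25))
  cv <- sd(rr) / mean(rr)
  expect_gt(cv, 0.10)
  expect_false(rhythm_regularity(rr))
  expect_true(rhythm_regularity(rr, cv_threshold = cv + 0.05))
  expect_error(rhythm_regularity(800), "indeterminate")
})

test_that("heart-rate classes split at 60 and 100 BPM inclusive", {
  expect_identical(heart_rate_class(59), "BRADY")
  expect_identical(heart_rate_class(60), "NORMAL")
  expect_identical(heart_rate_class(80), "NORMAL")
  expect_identical(heart_rate_class(100), "NORMAL")
  expect_identical(heart_rate_class(101), "TACHY")
  expect_error(heart_rate_class(0), "positive")
})

test_that("P presence requires a P segment shortly before most QRS", {
  seg <- wave_annotations(
    rep(c("P", "QRS"), 3),
    onset  = c(100L, 200L, 600L, 700L, 1100L, 1200L),
    peak   = c(120L, 220L, 620L, 720L, 1120L, 1220L),
    offset = c(140L, 240L, 640L, 740L, 1140L, 1240L))
  expect_true(detect_p_presence(seg, 500))     # P ends 120 ms before QRS
  qrs_only <- seg[seg$wave_type == "QRS", ]
  expect_false(detect_p_presence(qrs_only, 500))
  p_only <- seg[seg$wave_type == "P", ]
  expect_error(detect_p_presence(p_only, 500), "indeterminate")
  # P too far ahead of the QRS is not associated
  expect_false(detect_p_presence(seg, 500, search_window_ms = 50))
})

test_that("the rule table is exhaustive over the four combinations", {
  expect_identical(interpret_rhythm(TRUE, TRUE), "NSR")
  expect_identical(interpret_rhythm(FALSE, FALSE), "AF")
  expect_identical(interpret_rhythm(FALSE, TRUE), "AFL")
  expect_identical(interpret_rhythm(TRUE, FALSE), "OTHER_ARRHYTHMIA")
  expect_error(interpret_rhythm(NA, TRUE))
})

test_that("ground-truth labels interpret to the generating rhythm", {
  for (ty in c("NSR", "AF_LIKE", "AFL_LIKE", "OTHER_IRREGULAR")) {
    spec <- rhythm_spec(ty, duration_s = 60, seed = 47)
    g <- generate_rhythm(spec)
    itp <- interpret_labels(g$labels, g$record$signal, 500)
    expect_identical(itp$decision, rhythm_decision(ty))
    expect_equal(itp$mean_hr_bpm * mean(itp$rr_intervals_ms), 60000)
    expect_null(itp$reason)
  }
})

test_that("too few QRS complexes yield an indeterminate interpretation", {
  labels <- c(rep("ISO", 50), rep("QRS", 30), rep("ISO", 100))
  itp <- interpret_labels(labels, rnorm(180), 500)
  expect_true(is.na(itp$decision))
  expect_match(itp$reason, "insufficient QRS")
})

test_that("interpret_record runs the full pipeline on a short record", {
  fit <- conv_bilstm(tiny_beats()[1:16], model = tiny_model(),
                     control = train_config(batch_size = 4L,
                                            learning_rate = 3e-3,
                                            epochs = 40L, seed = 8))
  g <- generate_rhythm(rhythm_spec("NSR", duration_s = 20,
                                   sampling_rate = 250, seed = 48))
  noisy <- add_noise(g$record$signal, noise_spec(seed = 48), 250)$noisy
  rec <- ecg_record(noisy, 250, "e2e")
  itp <- interpret_record(rec, fit)
  expect_s3_class(itp, "rhythm_interpretation")
  if (is.na(itp$decision)) {
    expect_match(itp$reason, "insufficient")
  } else {
    # internal consistency of the report fields
    expect_equal(itp$mean_hr_bpm * mean(itp$rr_intervals_ms), 60000)
    expect_identical(itp$hr_class, heart_rate_class(itp$mean_hr_bpm))
    expect_identical(itp$decision,
                     interpret_rhythm(itp$p_wave_present, itp$rr_regular))
  }
})
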