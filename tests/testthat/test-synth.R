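test_that("beat templates label exactly the configured intervals", {
  b <- generate_beat_template(rr_ms = 800, sampling_rate = 500)
  expect_identical(nrow(b$annotations), 3L)
  expect_setequal(b$annotations$wave_type, c("P", "QRS", "T"))
  # labels and annotations agree sample-for-sample
  expect_identical(annotations_to_node_labels(b$annotations,
                                              length(b$labels)),
                   b$labels)
  # QRS dominates the P-wave in amplitude
  expect_gt(max(abs(b$signal[b$labels == "QRS"])),
            max(abs(b$signal[b$labels == "P"])))
  nop <- generate_beat_template(rr_ms = 800, p_present = FALSE)
  expect_false(any(nop$labels == "P"))
  expect_false(any(nop$annotations$wave_type == "P"))
  expect_error(generate_beat_template(rr_ms = 800, p_ms = 200, pr_ms = 150),
               "overlapping intervals")
})

test_that("segment extraction recovers the template's intervals", {
  b <- generate_beat_template(rr_ms = 900)
  seg <- extract_segments(b$labels, b$signal, 500)
  expect_identical(seg$onset, b$annotations$onset)
  expect_identical(seg$offset, b$annotations$offset)
  expect_identical(seg$wave_type, b$annotations$wave_type)
})

test_that("rhythm records have the requested length, rate and identity", {
  g <- generate_rhythm(rhythm_spec("NSR", duration_s = 10,
                                   sampling_rate = 500, seed = 4))
  expect_length(g$record$signal, 5000L)
  expect_length(g$labels, 5000L)
  expect_lt(max(g$annotations$offset), 5000L)
  g2 <- generate_rhythm(rhythm_spec("NSR", duration_s = 10,
                                    sampling_rate = 500, seed = 4))
  expect_identical(g$record$signal, g2$record$signal)
  expect_identical(as.data.frame(g$annotations), as.data.frame(g2$annotations))
})

test_that("generated heart rate tracks the specification", {
  g <- generate_rhythm(rhythm_spec("NSR", mean_hr_bpm = 75, rr_cv = 0.02,
                                   duration_s = 60, seed = 6))
  rr <- rr_intervals(g$annotations, 500)
  hr <- 60000 / mean(rr)
  expect_lt(abs(hr - 75), 2)
})

test_that("empirical RR variability approaches the specified CV", {
  for (ty in c("NSR", "AF_LIKE", "AFL_LIKE", "OTHER_IRREGULAR")) {
    spec <- rhythm_spec(ty, duration_s = 60, seed = 17)
    g <- generate_rhythm(spec)
    rr <- rr_intervals(g$annotations, spec$sampling_rate)
    cv <- stats::sd(rr) / mean(rr)
    expect_lt(abs(cv - spec$rr_cv), 0.3 * spec$rr_cv + 0.01)
    # P-wave labels occur iff the spec draws P-waves
    expect_identical(any(g$labels == "P"), spec$p_present)
  }
})

test_that("rhythm specs enforce their type invariants", {
  expect_error(rhythm_spec("NSR", p_present = FALSE), "invariants")
  expect_error(rhythm_spec("NSR", rr_cv = 0.3), "invariants")
  expect_error(rhythm_spec("AF_LIKE", rr_cv = 0.05), "invariants")
  expect_error(rhythm_spec("AFL_LIKE", p_present = TRUE), "invariants")
  expect_error(rhythm_spec("NSR", mean_hr_bpm = -5), "positive")
})

test_that("noise is seeded, scalable to a target SNR, and additive", {
  clean <- sin(2 * pi * 5 * (0:2999) / 500)
  silent <- noise_spec(baseline_amp = 0, powerline_amp = 0, gaussian_sd = 0)
  nz <- add_noise(clean, silent, 500)
  expect_identical(nz$noisy, clean)
  expect_identical(nz$noise, numeric(3000))
  tgt <- noise_spec(target_input_snr_db = 5, seed = 9)
  nz5 <- add_noise(clean, tgt, 500)
  expect_lt(abs(input_snr(clean, nz5$noise) - 5), 0.1)
  expect_equal(nz5$noisy, clean + nz5$noise)
  expect_identical(add_noise(clean, tgt, 500)$noisy, nz5$noisy)
  silent$target_input_snr_db <- 5
  expect_error(add_noise(clean, silent, 500), "zero noise")
})

test_that("suites land on disk with a manifest the rules agree with", {
  dir <- withr::local_tempdir()
  specs <- lapply(c("NSR", "AF_LIKE", "AFL_LIKE", "OTHER_IRREGULAR"),
                  function(ty) rhythm_spec(ty, duration_s = 20, seed = 23))
  manifest <- generate_suite(specs, noise_spec(seed = 2), dir)
  expect_identical(nrow(manifest), 4L)
  expect_setequal(manifest$decision,
                  c("NSR", "AF", "AFL", "OTHER_ARRHYTHMIA"))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  for (i in seq_len(4)) {
    path <- file.path(dir, manifest$record_id[i])
    rec <- read_ecg_record(path)
    expect_length(rec$signal, 20L * 500L)
    ann <- read_wave_annotations(paste0(path, ".ann"))
    labels <- annotations_to_node_labels(ann, length(rec$signal))
    itp <- interpret_labels(labels, rec$signal, rec$sampling_rate)
    expect_identical(itp$decision, manifest$decision[i])
  }
})

test_that("training beats are preprocessed, labeled and of mixed class", {
  beats <- tiny_beats()
  expect_length(beats, 24L)
  labs <- unlist(lapply(beats, `[[`, "labels"))
  expect_true(all(labs %in% ecg_classes()))
  expect_true(all(c("P", "QRS", "T", "ISO") %in% labs))
  sig <- unlist(lapply(beats, `[[`, "signal"))
  expect_true(all(sig >= 0 & sig <= 1))
})
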