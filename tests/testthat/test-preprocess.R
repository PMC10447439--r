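test_that("input SNR matches the energy-ratio definition", {
  expect_equal(input_snr(10, 10), 0)
  expect_equal(input_snr(10, 1), 20)
  set.seed(11)
  x <- rnorm(1000)
  r <- rnorm(1000, sd = 0.3)
  # independent direct-summation evaluation of the definition
  expect_equal(input_snr(x, r), 10 * log10(sum(x * x) / sum(r * r)),
               tolerance = 1e-12)
  expect_error(input_snr(x, numeric(1000)), "zero")
  expect_error(input_snr(x, r[-1]), "same length")
})

test_that("output SNR is denoised energy over residual energy", {
  expect_identical(output_snr(c(1, 2, 3), c(1, 2, 3)), Inf)
  expect_equal(output_snr(1, 2), 10 * log10(4), tolerance = 1e-12)
  set.seed(12)
  x <- sin(seq(0, 20, length.out = 500)) + rnorm(500, sd = 0.1)
  d <- sin(seq(0, 20, length.out = 500))
  expect_equal(output_snr(x, d), 10 * log10(sum(d^2) / sum((d - x)^2)),
               tolerance = 1e-12)
  # invariant under common positive scaling
  expect_equal(output_snr(3.7 * x, 3.7 * d), output_snr(x, d))
})

test_that("zero-threshold wavelet pipeline is the identity", {
  set.seed(13)
  x <- rnorm(5000)
  for (w in c("haar", "db4", "sym8", "bior3.5", "coif5")) {
    back <- dwt_denoise(x, denoising_config(w, 8L), threshold_scale = 0)
    expect_lt(sqrt(mean((x - back)^2)), 1e-8)
  }
  expect_identical(dwt_denoise(numeric(100) , denoising_config("coif5", 4L)),
                   numeric(100))
})

test_that("denoising raises the SNR of a noisy sine", {
  fs <- 500
  clean <- sin(2 * pi * 5 * (0:4999) / fs)
  nz <- add_noise(clean, noise_spec(baseline_amp = 0, powerline_amp = 0,
                                    gaussian_sd = 1,
                                    target_input_snr_db = 5, seed = 21),
                  fs)
  denoised <- dwt_denoise(nz$noisy, denoising_config("coif5", 8L))
  expect_gt(output_snr(clean, denoised), input_snr(clean, nz$noise))
})

test_that("decomposition depth is capped with a warning", {
  expect_warning(d <- dwt_transform(rnorm(64), "haar", 12L),
                 "reducing decomposition depth")
  expect_lt(d$levels, 12L)
  expect_error(dwt_transform(c(1, NA, 3), "haar", 2L), "finite")
  expect_error(dwt_transform(rnorm(64), "morlet", 2L), "unknown wavelet")
})

test_that("wavelet comparison reports every family, deterministically", {
  g <- generate_rhythm(rhythm_spec("NSR", seed = 30, duration_s = 6))
  ns <- noise_spec(target_input_snr_db = 5, seed = 5)
  rep1 <- compare_wavelets(list(g$record$signal), ns)
  expect_s3_class(rep1, "snr_report")
  expect_identical(nrow(rep1), 14L)
  expect_setequal(rep1$wavelet, wavelet_families())
  expect_false(is.unsorted(rev(rep1$averaged_snr_db)))
  rep2 <- compare_wavelets(list(g$record$signal), ns)
  expect_identical(rep1, rep2)
  # a single signal and wavelet reduces to one output_snr evaluation
  nz <- add_noise(g$record$signal, ns, 500)
  one <- compare_wavelets(list(g$record$signal), ns, wavelets = "db4")
  expect_equal(one$averaged_snr_db,
               output_snr(g$record$signal,
                          dwt_denoise(nz$noisy, denoising_config("db4"))))
  expect_error(compare_wavelets(list(g$record$signal), ns, "sinc"),
               "unknown wavelet")
})

test_that("bounds normalization maps to [0, 1] and is idempotent", {
  expect_equal(normalize_bounds(c(0, 5, 10)), c(0, 0.5, 1))
  expect_error(normalize_bounds(c(3, 3, 3)), "degenerate")
  set.seed(14)
  x <- rnorm(300)
  nx <- normalize_bounds(x)
  expect_equal(range(nx), c(0, 1))
  expect_identical(order(nx), order(x))
  expect_equal(normalize_bounds(nx), nx)
})

test_that("beat segmentation windows P onset to P onset", {
  fx <- three_p_record()
  beats <- segment_beats(fx$record, fx$labels, fx$annotations, L = 512L)
  expect_length(beats, 2L)
  for (b in beats) {
    expect_identical(b$valid_length, 500L)
    expect_identical(b$signal[501:512], numeric(12))
    expect_identical(b$labels[501:512], rep("PAD", 12))
    expect_identical(b$labels[1], "P")      # boundary = P onset exactly
    expect_true(any(b$labels == "QRS"))
  }
  expect_identical(vapply(beats, `[[`, 0L, "start_sample"), c(100L, 600L))
})

test_that("segmentation drops QRS-free and over-long windows", {
  fx <- three_p_record()
  # remove the middle QRS: window [600, 1100) has no R peak
  lab <- fx$labels
  lab[751:801] <- "ISO"
  ann <- fx$annotations[-4, ]
  beats <- segment_beats(fx$record, lab, ann, L = 512L)
  expect_length(beats, 1L)
  expect_identical(beats[[1]]$start_sample, 100L)
  # L smaller than the window: dropped with a warning
  expect_warning(none <- segment_beats(fx$record, fx$labels,
                                       fx$annotations, L = 256L),
                 "longer than L")
  expect_length(none, 0L)
  # no P onsets at all
  qrs_only <- fx$annotations[fx$annotations$wave_type == "QRS", ]
  expect_warning(none2 <- segment_beats(fx$record, fx$labels, qrs_only),
                 "no P-wave onsets")
  expect_length(none2, 0L)
  # a single P onset has no closing onset
  one <- fx$annotations[1, ]
  expect_length(segment_beats(fx$record, fx$labels, one), 0L)
})

test_that("fixed windows tile the record and zero-pad the tail", {
  rec <- ecg_record(rnorm(5000), 500, "w")
  win <- window_segments(rec, L = 512L)
  expect_length(win, 10L)
  expect_identical(win[[10]]$valid_length, 5000L - 9L * 512L)
  expect_identical(win[[10]]$signal[(win[[10]]$valid_length + 1):512],
                   numeric(512 - win[[10]]$valid_length))
  stitched <- unlist(lapply(win, function(b) b$signal[seq_len(b$valid_length)]))
  expect_identical(stitched, rec$signal)
  short <- window_segments(ecg_record(rnorm(100), 500, "s"), L = 512L)
  expect_length(short, 1L)
  expect_identical(short[[1]]$valid_length, 100L)
})
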