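# Seeded synthetic ECG generator: parametric P-QRS-T templates on
# configurable rhythm schedules, with exact ground-truth node labels by
# construction, plus additive baseline-wander / powerline / broadband noise.

# run `code` under `seed` without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.ms2samp <- function(ms, fs) as.integer(round(ms * fs / 1000))

#' Rhythm specification for the synthetic generator
#'
#' The four rhythm types encode the combinations of P-wave presence and
#' RR regularity the rule-based interpreter distinguishes: normal sinus
#' rhythm (P present, regular), atrial-fibrillation-like (P absent,
#' irregular), atrial-flutter-like (P absent, regular, typically rapid)
#' and other-irregular (P present, irregular).
#'
#' @param rhythm_type One of `"NSR"`, `"AF_LIKE"`, `"AFL_LIKE"`,
#'   `"OTHER_IRREGULAR"`.
#' @param mean_hr_bpm Target mean heart rate (defaults per type: 75, 100,
#'   140, 80).
#' @param rr_cv Coefficient of variation of the RR intervals (defaults
#'   0.02 for the regular types, 0.25 for the irregular ones).
#' @param p_present Whether P-waves are drawn (forced by the type's
#'   invariants).
#' @param duration_s Record duration in seconds.
#' @param sampling_rate Sampling frequency in Hz.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return A list of class `rhythm_spec`.
#' @export
rhythm_spec <- function(rhythm_type = c("NSR", "AF_LIKE", "AFL_LIKE",
                                        "OTHER_IRREGULAR"),
                        mean_hr_bpm = NULL, rr_cv = NULL, p_present = NULL,
                        duration_s = 10, sampling_rate = 500, seed = 1L) {
  rhythm_type <- match.arg(rhythm_type)
  defaults <- list(
    NSR             = list(hr = 75,  cv = 0.02, p = TRUE),
    AF_LIKE         = list(hr = 100, cv = 0.25, p = FALSE),
    AFL_LIKE        = list(hr = 140, cv = 0.02, p = FALSE),
    OTHER_IRREGULAR = list(hr = 80,  cv = 0.25, p = TRUE))[[rhythm_type]]
  if (is.null(mean_hr_bpm)) mean_hr_bpm <- defaults$hr
  if (is.null(rr_cv)) rr_cv <- defaults$cv
  if (is.null(p_present)) p_present <- defaults$p
  ok <- switch(rhythm_type,
    NSR             = p_present && rr_cv <= 0.05,
    AF_LIKE         = !p_present && rr_cv >= 0.2,
    AFL_LIKE        = !p_present && rr_cv <= 0.05,
    OTHER_IRREGULAR = p_present && rr_cv >= 0.2)
  if (!ok)
    stop(rhythm_type, " violates its rhythm invariants (p_present = ",
         p_present, ", rr_cv = ", rr_cv, ")", call. = FALSE)
  if (mean_hr_bpm <= 0 || duration_s <= 0 || sampling_rate <= 0)
    stop("mean_hr_bpm, duration_s and sampling_rate must be positive",
         call. = FALSE)
  structure(list(rhythm_type = rhythm_type, mean_hr_bpm = mean_hr_bpm,
                 rr_cv = rr_cv, p_present = p_present,
                 duration_s = duration_s, sampling_rate = sampling_rate,
                 seed = as.integer(seed)),
            class = "rhythm_spec")
}

#' Ground-truth decision implied by a rhythm type
#'
#' @param rhythm_type A rhythm type as in [rhythm_spec].
#' @return `"NSR"`, `"AF"`, `"AFL"` or `"OTHER_ARRHYTHMIA"`.
#' @export
rhythm_decision <- function(rhythm_type) {
  unname(c(NSR = "NSR", AF_LIKE = "AF", AFL_LIKE = "AFL",
           OTHER_IRREGULAR = "OTHER_ARRHYTHMIA")[rhythm_type])
}

#' Generate one templated beat
#'
#' A beat spans one RR interval starting at the P-wave onset: a Gaussian
#' P bump, a biphasic QRS spike and a Gaussian T bump at the configured
#' intervals, with labels marking exactly the configured wave samples.
#' On short RR intervals the QT span (and with it the T-wave) is
#' compressed so the waves never overlap.
#'
#' @param rr_ms Beat duration in ms.
#' @param p_present Draw (and label) the P-wave?
#' @param pr_ms PR interval, P onset to QRS onset.
#' @param qrs_ms QRS duration.
#' @param qt_ms QT span, QRS onset to T offset.
#' @param p_ms,t_ms P- and T-wave durations.
#' @param amplitudes Named amplitudes in mV for `p`, `qrs`, `t`; the QRS
#'   amplitude must exceed the P amplitude.
#' @param sampling_rate Sampling frequency in Hz.
#' @return List with `signal`, `labels` and beat-relative `annotations`.
#' @export
generate_beat_template <- function(rr_ms = 800, p_present = TRUE,
                                   pr_ms = 160, qrs_ms = 90, qt_ms = 360,
                                   p_ms = 100, t_ms = 160,
                                   amplitudes = c(p = 0.15, qrs = 1.0, t = 0.3),
                                   sampling_rate = 500) {
  if (amplitudes[["qrs"]] <= amplitudes[["p"]])
    stop("QRS amplitude must exceed P amplitude", call. = FALSE)
  if (p_ms >= pr_ms)
    stop("overlapping intervals: the P-wave (", p_ms,
         " ms) must end before the QRS onset at PR = ", pr_ms, " ms",
         call. = FALSE)
  # compress the QT span (and on very short beats the QRS too), keeping
  # 40 ms of trailing baseline
  qt_eff <- min(qt_ms, rr_ms - pr_ms - 40)
  qrs_eff <- min(qrs_ms, 0.45 * qt_eff)
  t_eff <- min(t_ms, qt_eff - qrs_eff - 20)
  if (t_eff < 20)
    stop("overlapping intervals: QRS (", qrs_eff,
         " ms) leaves no room for the T-wave within QT = ", qt_eff, " ms",
         call. = FALSE)
  qrs_ms <- qrs_eff
  fs <- sampling_rate
  n <- max(.ms2samp(rr_ms, fs), .ms2samp(pr_ms + qt_eff, fs) + 2L)
  sig <- numeric(n)
  lab <- rep("ISO", n)
  gauss <- function(center, sd, amp)
    amp * exp(-((seq_len(n) - 1L - center)^2) / (2 * sd^2))

  add_wave <- function(from, len, type, wavefun) {
    to <- from + len - 1L
    sig <<- sig + wavefun(from, to)
    lab[(from:to) + 1L] <<- type
    c(from, to)
  }

  ann <- list()
  if (p_present) {
    n_p <- .ms2samp(p_ms, fs)
    span <- add_wave(0L, n_p, "P", function(f, t)
      gauss((f + t) / 2, n_p / 6, amplitudes[["p"]]))
    ann$P <- span
  }
  q0 <- .ms2samp(pr_ms, fs)
  n_q <- .ms2samp(qrs_ms, fs)
  span <- add_wave(q0, n_q, "QRS", function(f, t) {
    c0 <- (f + t) / 2
    gauss(c0, n_q / 12, amplitudes[["qrs"]]) -
      gauss(c0 - n_q / 3.5, n_q / 14, 0.15 * amplitudes[["qrs"]]) -
      gauss(c0 + n_q / 3.5, n_q / 14, 0.25 * amplitudes[["qrs"]])
  })
  ann$QRS <- span
  t0 <- .ms2samp(pr_ms + qt_eff - t_eff, fs)
  n_t <- .ms2samp(t_eff, fs)
  span <- add_wave(t0, n_t, "T", function(f, t)
    gauss((f + t) / 2, n_t / 6, amplitudes[["t"]]))
  ann$T <- span

  types <- names(ann)
  onsets <- vapply(ann, `[[`, 0L, 1L)
  offsets <- vapply(ann, `[[`, 0L, 2L)
  peaks <- mapply(function(f, t) f + which.max(abs(sig[(f:t) + 1L])) - 1L,
                  onsets, offsets)
  list(signal = sig, labels = lab,
       annotations = wave_annotations(types, onsets, peaks, offsets))
}

#' Generate a synthetic rhythm record
#'
#' RR intervals are drawn from a log-normal distribution with the
#' specified mean (`60000 / mean_hr_bpm` ms) and coefficient of
#' variation, beats are concatenated, and the record is truncated to
#' exactly `duration_s * sampling_rate` samples.  AF-like records add a
#' fibrillatory undulation and AFL-like records a sawtooth flutter wave;
#' both distractors are labeled isoelectric.
#'
#' @param spec A [rhythm_spec].
#' @param ... Template arguments forwarded to [generate_beat_template].
#' @return List with the `record` ([ecg_record]), ground-truth `labels`,
#'   `annotations` (absolute 0-based indices), the drawn `rr_ms`
#'   schedule and the `spec`.
#' @export
generate_rhythm <- function(spec, ...) {
  stopifnot(inherits(spec, "rhythm_spec"))
  fs <- spec$sampling_rate
  n_target <- as.integer(round(spec$duration_s * fs))
  .with_seed(spec$seed, {
    mean_rr <- 60000 / spec$mean_hr_bpm
    sdlog <- sqrt(log1p(spec$rr_cv^2))
    meanlog <- log(mean_rr) - sdlog^2 / 2
    sig <- numeric(0)
    lab <- character(0)
    ann <- list()
    rr_sched <- numeric(0)
    while (length(sig) < n_target) {
      rr <- stats::rlnorm(1, meanlog, sdlog)
      rr <- min(max(rr, 330), 2200)
      beat <- generate_beat_template(rr_ms = rr, p_present = spec$p_present,
                                     sampling_rate = fs, ...)
      a <- beat$annotations
      a$onset <- a$onset + length(sig)
      a$peak <- a$peak + length(sig)
      a$offset <- a$offset + length(sig)
      ann[[length(ann) + 1L]] <- a
      sig <- c(sig, beat$signal)
      lab <- c(lab, beat$labels)
      rr_sched <- c(rr_sched, rr)
    }
    tvec <- (seq_len(length(sig)) - 1L) / fs
    if (spec$rhythm_type == "AF_LIKE") {
      # fibrillatory f-waves: ~7 Hz undulation with a wandering phase
      phase <- cumsum(stats::rnorm(length(sig), 0, 0.15))
      sig <- sig + 0.05 * sin(2 * pi * 7 * tvec + phase)
    } else if (spec$rhythm_type == "AFL_LIKE") {
      # flutter waves: ~5 Hz sawtooth between QRS complexes, labeled ISO
      sig <- sig + 0.1 * (2 * ((5 * tvec) %% 1) - 1)
    }
    sig <- sig[seq_len(n_target)]
    lab <- lab[seq_len(n_target)]
    annotations <- do.call(rbind, ann)
    annotations <- validate_wave_annotations(
      annotations[annotations$offset < n_target, , drop = FALSE])
    rec_id <- sprintf("synth_%s_%03d", tolower(spec$rhythm_type), spec$seed)
    list(record = ecg_record(sig, fs, rec_id),
         labels = lab, annotations = annotations,
         rr_ms = rr_sched, spec = spec)
  })
}

#' Additive noise specification
#'
#' @param baseline_amp,baseline_freq Baseline-wander sinusoid amplitude
#'   (mV) and frequency (Hz, default 0.3).
#' @param powerline_amp,powerline_freq Powerline sinusoid amplitude (mV)
#'   and frequency (default 50 Hz).
#' @param gaussian_sd Broadband Gaussian noise standard deviation (mV).
#' @param target_input_snr_db Optional target input SNR; when set, the
#'   summed noise is rescaled so the achieved input SNR matches it.
#' @param seed Integer seed for the noise realization.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0.1, baseline_freq = 0.3,
                       powerline_amp = 0.02, powerline_freq = 50,
                       gaussian_sd = 0.02, target_input_snr_db = NULL,
                       seed = 1L) {
  if (baseline_amp < 0 || powerline_amp < 0 || gaussian_sd < 0)
    stop("noise amplitudes must be >= 0", call. = FALSE)
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq,
                 gaussian_sd = gaussian_sd,
                 target_input_snr_db = target_input_snr_db,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add seeded noise to a clean signal
#'
#' The pure noise component is returned alongside the noisy signal so
#' the input SNR is computable against the clean reference.
#'
#' @param clean Clean amplitude vector.
#' @param noise A [noise_spec].
#' @param sampling_rate Sampling frequency in Hz (needed for the sinusoid
#'   components).
#' @return List with `noisy` and `noise` vectors.
#' @export
add_noise <- function(clean, noise = noise_spec(), sampling_rate = 500) {
  stopifnot(inherits(noise, "noise_spec"), all(is.finite(clean)))
  n <- length(clean)
  tvec <- (seq_len(n) - 1L) / sampling_rate
  r <- .with_seed(noise$seed, {
    ph <- stats::runif(2, 0, 2 * pi)
    noise$baseline_amp * sin(2 * pi * noise$baseline_freq * tvec + ph[1]) +
      noise$powerline_amp * sin(2 * pi * noise$powerline_freq * tvec + ph[2]) +
      stats::rnorm(n, 0, noise$gaussian_sd)
  })
  if (!is.null(noise$target_input_snr_db)) {
    energy <- sum(r^2)
    if (energy == 0)
      stop("cannot scale zero noise to a target SNR", call. = FALSE)
    r <- r * sqrt(sum(clean^2) / energy /
                    10^(noise$target_input_snr_db / 10))
  }
  list(noisy = clean + r, noise = r)
}

#' Default synthetic rhythm suite
#'
#' `n_per_type` records for each of the four rhythm types, with
#' deterministic per-replicate heart-rate offsets and consecutive seeds.
#'
#' @param n_per_type Records per rhythm type.
#' @param duration_s Record duration in seconds.
#' @param seed Base seed; record `i` uses `seed + i - 1`.
#' @return List of [rhythm_spec] objects.
#' @export
default_rhythm_suite <- function(n_per_type = 5, duration_s = 60, seed = 1L) {
  types <- c("NSR", "AF_LIKE", "AFL_LIKE", "OTHER_IRREGULAR")
  base_hr <- c(NSR = 75, AF_LIKE = 100, AFL_LIKE = 140, OTHER_IRREGULAR = 80)
  jitter <- seq(-8, 8, length.out = n_per_type)
  specs <- list()
  k <- 0L
  for (ty in types) for (j in seq_len(n_per_type)) {
    k <- k + 1L
    specs[[k]] <- rhythm_spec(ty, mean_hr_bpm = base_hr[[ty]] + jitter[j],
                              duration_s = duration_s,
                              seed = as.integer(seed) + k - 1L)
  }
  specs
}

#' Generate a suite of annotated records on disk
#'
#' One WFDB-style record (noisy signal) plus ground-truth annotation file
#' per spec, and a `manifest.csv` mapping record ids to their rhythm
#' type and ground-truth decision.
#'
#' @param specs List of [rhythm_spec] objects.
#' @param noise A [noise_spec] (record `i` uses `noise$seed + i - 1`);
#'   `NULL` writes clean signals.
#' @param out_dir Output directory (created if missing).
#' @param ... Template arguments forwarded to [generate_rhythm].
#' @return The manifest `data.frame`, invisibly.
#' @export
generate_suite <- function(specs, noise = noise_spec(), out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    g <- generate_rhythm(specs[[i]], ...)
    sig <- g$record$signal
    if (!is.null(noise)) {
      ns <- noise
      ns$seed <- noise$seed + i - 1L
      sig <- add_noise(sig, ns, g$record$sampling_rate)$noisy
    }
    rec <- g$record
    rec$signal <- sig
    write_ecg_record(rec, file.path(out_dir, rec$record_id),
                     annotations = g$annotations)
    rows[[i]] <- data.frame(
      record_id = rec$record_id,
      rhythm_type = g$spec$rhythm_type,
      decision = rhythm_decision(g$spec$rhythm_type),
      mean_hr_bpm = g$spec$mean_hr_bpm, rr_cv = g$spec$rr_cv,
      p_present = g$spec$p_present, duration_s = g$spec$duration_s,
      sampling_rate = g$spec$sampling_rate, seed = g$spec$seed,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Generate preprocessed training beats
#'
#' Draws short records with varied heart rate, morphology and P-wave
#' presence, runs each through the standard preprocessing chain (additive
#' noise, wavelet denoising, unit-interval normalization) and segments
#' them: P-present records beat-to-beat at P onsets, P-absent records as
#' fixed windows carrying their ground-truth labels.
#'
#' @param n_beats Number of beats to return.
#' @param L Beat length in samples.
#' @param sampling_rate Sampling frequency in Hz.
#' @param seed Integer seed.
#' @param p_absent_fraction Fraction of source records drawn without
#'   P-waves (AF/AFL-like distractors).  P-present records alternate
#'   between P-onset-aligned beats and randomly offset fixed windows so
#'   the classifier sees every wave at every within-window position.
#' @param denoise Apply [dwt_denoise] before normalization?
#' @return List of labeled [ecg_beat] objects of length `n_beats`.
#' @export
synth_training_beats <- function(n_beats = 800, L = 512L,
                                 sampling_rate = 500, seed = 1L,
                                 p_absent_fraction = 0.3, denoise = TRUE) {
  beats <- list()
  cfg <- denoising_config()
  .with_seed(seed, {
    rec_i <- 0L
    while (length(beats) < n_beats) {
      rec_i <- rec_i + 1L
      absent <- stats::runif(1) < p_absent_fraction
      ty <- if (absent) sample(c("AF_LIKE", "AFL_LIKE"), 1L) else
        sample(c("NSR", "OTHER_IRREGULAR"), 1L, prob = c(0.7, 0.3))
      hr <- switch(ty, NSR = stats::runif(1, 62, 105),
                   OTHER_IRREGULAR = stats::runif(1, 65, 95),
                   AF_LIKE = stats::runif(1, 90, 130),
                   AFL_LIKE = stats::runif(1, 120, 150))
      spec <- rhythm_spec(ty, mean_hr_bpm = hr, duration_s = 10,
                          sampling_rate = sampling_rate,
                          seed = seed + 7919L * rec_i)
      amp <- c(p = stats::runif(1, 0.1, 0.2),
               qrs = stats::runif(1, 0.8, 1.2),
               t = stats::runif(1, 0.25, 0.4))
      g <- generate_rhythm(spec, amplitudes = amp,
                           pr_ms = stats::runif(1, 140, 180),
                           qt_ms = stats::runif(1, 330, 390))
      ns <- noise_spec(baseline_amp = stats::runif(1, 0.03, 0.12),
                       gaussian_sd = stats::runif(1, 0.01, 0.03),
                       seed = seed + 104729L * rec_i)
      sig <- add_noise(g$record$signal, ns, sampling_rate)$noisy
      if (denoise) sig <- suppressWarnings(dwt_denoise(sig, cfg))
      rec <- g$record
      rec$signal <- normalize_bounds(sig)
      # alternate P-onset-aligned beats with randomly offset fixed
      # windows so the classifier does not learn absolute wave positions
      new <- if (spec$p_present && rec_i %% 2L == 0L) {
        suppressWarnings(segment_beats(rec, g$labels, g$annotations, L = L))
      } else {
        j <- sample.int(L, 1L) - 1L
        shifted <- rec
        shifted$signal <- rec$signal[(j + 1L):length(rec$signal)]
        window_segments(shifted, L = L,
                        labels = g$labels[(j + 1L):length(g$labels)])
      }
      beats <- c(beats, new)
    }
  })
  beats[seq_len(n_beats)]
}
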