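# Rule-based rhythm interpretation on top of per-node delineation output:
# run-length decoding into wave segments, RR-interval statistics, P-wave
# presence, heart-rate class, and the four medical-knowledge rules
# mapping (P presence, RR regularity) to NSR / AF / AFL / other.

#' Decode a label sequence into wave segments
#'
#' Maximal runs of the P/QRS/T classes become segments; runs shorter
#' than `min_duration_ms` are discarded (classifier flicker), and the
#' isoelectric and padding classes produce no segments.  Each segment's
#' peak is the sample with the largest absolute amplitude in the run.
#'
#' @param labels Per-sample label sequence.
#' @param signal Aligned amplitude vector.
#' @param sampling_rate Sampling frequency in Hz.
#' @param min_duration_ms Minimum segment duration (default 20 ms).
#' @return A [wave_annotations] table of segments (0-based indices).
#' @export
extract_segments <- function(labels, signal, sampling_rate = 500,
                             min_duration_ms = 20) {
  stopifnot(length(labels) == length(signal))
  seg <- node_labels_to_annotations(labels, signal)
  if (!nrow(seg)) return(seg)
  dur_ms <- (seg$offset - seg$onset + 1L) * 1000 / sampling_rate
  seg <- seg[dur_ms >= min_duration_ms, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' RR intervals from delineated segments
#'
#' Successive differences of the QRS peak indices, in milliseconds.
#' Peaks closer than `refractory_ms` to the previously accepted peak are
#' discarded first: the ventricles cannot re-depolarize that fast, so
#' such doublets are delineation flicker (a split QRS), not beats.
#' With fewer than two QRS segments an empty vector is returned with the
#' attribute `insufficient_beats` set to `TRUE`.
#'
#' @param segments A [wave_annotations] table sorted by onset.
#' @param sampling_rate Sampling frequency in Hz.
#' @param refractory_ms Minimum physiological beat-to-beat distance
#'   (default 200 ms, i.e. 300 BPM); 0 disables the guard.
#' @return Numeric vector of RR intervals (ms).
#' @export
rr_intervals <- function(segments, sampling_rate = 500,
                         refractory_ms = 200) {
  peaks <- sort(segments$peak[segments$wave_type == "QRS"])
  if (length(peaks) > 1L && refractory_ms > 0) {
    min_gap <- refractory_ms * sampling_rate / 1000
    kept <- peaks[1L]
    for (p in peaks[-1L])
      if (p - kept[length(kept)] >= min_gap) kept <- c(kept, p)
    peaks <- kept
  }
  if (length(peaks) < 2L) {
    out <- numeric(0)
    attr(out, "insufficient_beats") <- TRUE
    return(out)
  }
  rr <- diff(peaks) * 1000 / sampling_rate
  attr(rr, "insufficient_beats") <- FALSE
  rr
}

#' RR-interval regularity
#'
#' A rhythm is regular when the coefficient of variation (standard
#' deviation over mean) of its RR intervals is below the threshold.
#'
#' @param rr Numeric vector of RR intervals (ms), length >= 2.
#' @param cv_threshold Regularity threshold on the CV (default 0.10).
#' @return `TRUE` (regular) or `FALSE` (irregular).
#' @export
rhythm_regularity <- function(rr, cv_threshold = 0.10) {
  if (length(rr) < 2L)
    stop("regularity is indeterminate with fewer than 2 RR intervals",
         call. = FALSE)
  stats::sd(rr) / mean(rr) < cv_threshold
}

#' Classify the mean heart rate
#'
#' A resting rate below 60 BPM is bradycardia, one above 100 BPM is
#' tachycardia; 60-100 BPM inclusive is normal.
#'
#' @param mean_hr_bpm Mean heart rate in beats per minute.
#' @return `"BRADY"`, `"NORMAL"` or `"TACHY"`.
#' @export
heart_rate_class <- function(mean_hr_bpm) {
  if (!is.finite(mean_hr_bpm) || mean_hr_bpm <= 0)
    stop("mean heart rate must be positive", call. = FALSE)
  if (mean_hr_bpm < 60) "BRADY"
  else if (mean_hr_bpm > 100) "TACHY"
  else "NORMAL"
}

#' Detect P-wave presence
#'
#' A QRS complex "has" a P-wave when some P segment ends within
#' `search_window_ms` before the QRS onset; the record's P-wave is
#' present when at least `presence_fraction` of its QRS complexes have
#' one.
#'
#' @param segments A [wave_annotations] table of delineated segments.
#' @param sampling_rate Sampling frequency in Hz.
#' @param search_window_ms Pre-QRS search window (default 300 ms).
#' @param presence_fraction Minimum fraction of QRS complexes with an
#'   associated P-wave (default 0.5).
#' @return `TRUE` or `FALSE`.
#' @export
detect_p_presence <- function(segments, sampling_rate = 500,
                              search_window_ms = 300,
                              presence_fraction = 0.5) {
  qrs_on <- segments$onset[segments$wave_type == "QRS"]
  if (!length(qrs_on))
    stop("P-wave presence is indeterminate without QRS segments",
         call. = FALSE)
  p_off <- segments$offset[segments$wave_type == "P"]
  win <- search_window_ms * sampling_rate / 1000
  has_p <- vapply(qrs_on, function(on)
    any(p_off < on & p_off >= on - win), logical(1))
  mean(has_p) >= presence_fraction
}

#' Apply the four rhythm-interpretation rules
#'
#' (i) P present and regular rhythm: normal sinus rhythm; (ii) P absent
#' and irregular: atrial fibrillation; (iii) P absent and regular:
#' atrial flutter; (iv) P present and irregular: other arrhythmia.
#' Exhaustive and mutually exclusive over the four input combinations.
#'
#' @param p_wave_present Logical.
#' @param rr_regular Logical.
#' @return `"NSR"`, `"AF"`, `"AFL"` or `"OTHER_ARRHYTHMIA"`.
#' @export
interpret_rhythm <- function(p_wave_present, rr_regular) {
  stopifnot(is.logical(p_wave_present), !is.na(p_wave_present),
            is.logical(rr_regular), !is.na(rr_regular))
  if (p_wave_present && rr_regular) "NSR"
  else if (!p_wave_present && !rr_regular) "AF"
  else if (!p_wave_present && rr_regular) "AFL"
  else "OTHER_ARRHYTHMIA"
}

# shared tail of the interpretation pipeline, from decoded segments
.interpret_segments <- function(segments, sampling_rate, cv_threshold,
                                search_window_ms, presence_fraction) {
  rr <- rr_intervals(segments, sampling_rate)
  if (attr(rr, "insufficient_beats")) {
    return(structure(list(p_wave_present = NA, rr_regular = NA,
                          rr_intervals_ms = numeric(0), mean_hr_bpm = NA_real_,
                          hr_class = NA_character_, decision = NA_character_,
                          reason = "insufficient QRS segments for RR analysis",
                          segments = segments),
                     class = "rhythm_interpretation"))
  }
  p_present <- detect_p_presence(segments, sampling_rate,
                                 search_window_ms, presence_fraction)
  regular <- rhythm_regularity(rr, cv_threshold)
  hr <- 60000 / mean(rr)
  structure(list(p_wave_present = p_present, rr_regular = regular,
                 rr_intervals_ms = as.numeric(rr), mean_hr_bpm = hr,
                 hr_class = heart_rate_class(hr),
                 decision = interpret_rhythm(p_present, regular),
                 reason = NULL, segments = segments),
            class = "rhythm_interpretation")
}

#' Interpret a rhythm from a label sequence
#'
#' Runs the decoding and rule chain on an existing per-sample label
#' sequence (ground truth or model output).
#'
#' @param labels Per-sample label sequence.
#' @param signal Aligned amplitude vector.
#' @param sampling_rate Sampling frequency in Hz.
#' @param cv_threshold,search_window_ms,presence_fraction,min_duration_ms
#'   Interpretation thresholds (see [rhythm_regularity],
#'   [detect_p_presence], [extract_segments]).
#' @return A `rhythm_interpretation` object.
#' @export
interpret_labels <- function(labels, signal, sampling_rate = 500,
                             cv_threshold = 0.10, search_window_ms = 300,
                             presence_fraction = 0.5, min_duration_ms = 20) {
  segments <- extract_segments(labels, signal, sampling_rate,
                               min_duration_ms)
  .interpret_segments(segments, sampling_rate, cv_threshold,
                      search_window_ms, presence_fraction)
}

#' End-to-end interpretation of a record
#'
#' Preprocesses the record (optional wavelet denoising, unit-interval
#' normalization), runs the delineator over half-overlapping windows and
#' keeps each window's central region (samples near a window edge lack
#' sequence context on one side, so the overlapping neighbor's central
#' prediction is used there instead), decodes segments and applies the
#' rhythm rules.
#'
#' @param record An [ecg_record].
#' @param model A fitted [conv_bilstm] delineator.
#' @param denoise Apply [dwt_denoise] first (default `TRUE`).
#' @param cv_threshold,search_window_ms,presence_fraction,min_duration_ms
#'   Interpretation thresholds.
#' @return A `rhythm_interpretation` object (decision `NA` with a reason
#'   when too few QRS complexes are found).
#' @export
interpret_record <- function(record, model, denoise = TRUE,
                             cv_threshold = 0.10, search_window_ms = 300,
                             presence_fraction = 0.5, min_duration_ms = 20) {
  stopifnot(inherits(record, "ecg_record"), inherits(model, "conv_bilstm"))
  sig <- record$signal
  if (denoise) sig <- suppressWarnings(dwt_denoise(sig))
  sig <- normalize_bounds(sig)
  proc <- record
  proc$signal <- sig
  L <- model$model$input_length
  n <- length(sig)
  if (n <= L) {
    pad <- c(sig, numeric(L - n))
    labels <- predict(model, pad, type = "class")[seq_len(n)]
  } else {
    starts <- seq(0L, n - L, by = L %/% 2L)           # 0-based
    if (starts[length(starts)] != n - L) starts <- c(starts, n - L)
    pred <- predict(model, t(vapply(starts, function(s)
      sig[(s + 1L):(s + L)], numeric(L))), type = "class")
    labels <- character(n)
    # cut between neighbors at the middle of their overlap
    cuts <- c(0L, floor((starts[-length(starts)] + starts[-1L] + L) / 2),
              n)
    for (i in seq_along(starts)) {
      keep <- (cuts[i] + 1L):cuts[i + 1L]
      labels[keep] <- pred[i, keep - starts[i]]
    }
  }
  interpret_labels(labels, sig, record$sampling_rate, cv_threshold,
                   search_window_ms, presence_fraction, min_duration_ms)
}

#' @export
print.rhythm_interpretation <- function(x, ...) {
  cat("<rhythm_interpretation>\n")
  if (!is.null(x$reason)) {
    cat("  decision: indeterminate (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  P-wave present: %s | RR regular: %s (CV %.3f)\n",
              x$p_wave_present, x$rr_regular,
              stats::sd(x$rr_intervals_ms) / mean(x$rr_intervals_ms)))
  cat(sprintf("  mean HR: %.1f BPM (%s), %d RR intervals\n",
              x$mean_hr_bpm, x$hr_class, length(x$rr_intervals_ms)))
  cat(sprintf("  decision: %s\n", x$decision))
  invisible(x)
}
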