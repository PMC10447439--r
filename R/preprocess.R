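# Amplitude normalization and beat-to-beat segmentation.

#' Normalize amplitudes to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1 (rank order
#' preserved).  Idempotent.
#'
#' @param signal Non-constant numeric vector.
#' @return Normalized vector in `[0, 1]`.
#' @export
normalize_bounds <- function(signal) {
  rng <- range(signal)
  if (!all(is.finite(rng)))
    stop("signal must be finite everywhere", call. = FALSE)
  if (rng[1] == rng[2])
    stop("constant signal: amplitude range is degenerate", call. = FALSE)
  (signal - rng[1]) / (rng[2] - rng[1])
}

#' Construct a fixed-length beat
#'
#' A beat is a window of at most `L` samples zero-padded to exactly `L`,
#' with an aligned label sequence whose padded tail is the `PAD` class.
#'
#' @param signal Window samples (length <= `L`).
#' @param labels Aligned labels, same length as `signal`, or `NULL` for
#'   unannotated inference windows.
#' @param L Fixed beat length in samples.
#' @param source_record Identifier of the originating record.
#' @param start_sample 0-based index of the window start in the record.
#' @return An object of class `ecg_beat`.
#' @export
ecg_beat <- function(signal, labels = NULL, L = 512L,
                     source_record = "", start_sample = 0L) {
  v <- length(signal)
  if (v > L) stop("window longer than the beat length L", call. = FALSE)
  sig <- c(signal, numeric(L - v))
  lab <- if (is.null(labels)) NULL else {
    stopifnot(length(labels) == v)
    c(labels, rep("PAD", L - v))
  }
  structure(list(signal = sig, labels = lab,
                 source_record = as.character(source_record),
                 start_sample = as.integer(start_sample),
                 valid_length = as.integer(v)),
            class = "ecg_beat")
}

#' @export
print.ecg_beat <- function(x, ...) {
  cat(sprintf("<ecg_beat> %d/%d valid samples from '%s' @ %d%s\n",
              x$valid_length, length(x$signal), x$source_record,
              x$start_sample,
              if (is.null(x$labels)) " (unlabeled)" else ""))
  invisible(x)
}

#' Beat-to-beat segmentation at P-wave onsets
#'
#' Slices the record from each P-wave onset to the next P-wave onset
#' (half-open windows), keeps windows containing at least one QRS-labeled
#' sample, zero-pads windows shorter than `L` (labels padded with `PAD`),
#' and drops windows longer than `L` with a warning.
#'
#' @param record An [ecg_record].
#' @param labels Per-sample label sequence aligned with the record.
#' @param annotations [wave_annotations] for the record (source of the P
#'   onsets and sorted by onset).
#' @param L Beat length in samples (default 512).
#' @return List of [ecg_beat] objects.
#' @export
segment_beats <- function(record, labels, annotations, L = 512L) {
  stopifnot(inherits(record, "ecg_record"),
            length(labels) == length(record$signal))
  p_onsets <- annotations$onset[annotations$wave_type == "P"]
  if (length(p_onsets) < 1L) {
    warning("no P-wave onsets in record '", record$record_id,
            "': nothing to segment")
    return(list())
  }
  p_onsets <- sort(p_onsets)
  beats <- list()
  n_long <- 0L
  for (i in seq_len(length(p_onsets) - 1L)) {
    from <- p_onsets[i]                  # 0-based, inclusive
    to <- p_onsets[i + 1L]               # 0-based, exclusive
    w <- to - from
    if (w > L) { n_long <- n_long + 1L; next }
    idx <- (from + 1L):to
    if (!any(labels[idx] == "QRS")) next   # a beat needs an R peak
    beats[[length(beats) + 1L]] <-
      ecg_beat(record$signal[idx], labels[idx], L = L,
               source_record = record$record_id, start_sample = from)
  }
  if (n_long > 0L)
    warning(sprintf("record '%s': dropped %d window(s) longer than L = %d",
                    record$record_id, n_long, L))
  beats
}

#' Fixed windows over an unannotated record
#'
#' Consecutive non-overlapping windows of length `L` covering the whole
#' record; the last window is zero-padded.  Used at inference time, where
#' no P onsets are available yet.
#'
#' @param record An [ecg_record].
#' @param L Window length in samples.
#' @param labels Optional aligned label sequence to carry along (padded
#'   with `PAD` like the signal); omitted by default.
#' @return List of [ecg_beat] objects.
#' @export
window_segments <- function(record, L = 512L, labels = NULL) {
  n <- length(record$signal)
  if (!is.null(labels)) stopifnot(length(labels) == n)
  n_win <- ceiling(n / L)
  lapply(seq_len(n_win), function(i) {
    from <- (i - 1L) * L
    idx <- (from + 1L):min(i * L, n)
    ecg_beat(record$signal[idx],
             if (is.null(labels)) NULL else labels[idx],
             L = L, source_record = record$record_id, start_sample = from)
  })
}

# Stack beats into the (n x L) signal and integer-label matrices the
# compiled trainer consumes.  Label codes are 1..5 in ecg_classes() order.
beats_to_matrices <- function(beats) {
  stopifnot(length(beats) > 0L)
  L <- length(beats[[1L]]$signal)
  x <- t(vapply(beats, function(b) b$signal, numeric(L)))
  y <- NULL
  if (!is.null(beats[[1L]]$labels)) {
    cls <- ecg_classes()
    y <- t(vapply(beats, function(b) {
      m <- match(b$labels, cls)
      if (anyNA(m)) stop("beat labels outside the five classes", call. = FALSE)
      m
    }, integer(L)))
  }
  list(x = x, y = y, L = L)
}
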