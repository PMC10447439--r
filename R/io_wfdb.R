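# Minimal WFDB-style record I/O: text .hea header, format-16 little-endian
# .dat signal, and a plain-text wave annotation dialect using the WFDB
# "(" / wave-symbol / ")" marker convention (one "sample symbol" pair per
# line).  Only the subset needed for single-lead delineation is supported.

#' Node label classes
#'
#' The five per-sample classes used throughout the package, in their fixed
#' order: isoelectric line, P-wave, QRS-complex, T-wave and zero-padding.
#' The order matters: argmax ties in model predictions are broken toward
#' the lower class index.
#'
#' @return Character vector of length 5.
#' @export
ecg_classes <- function() c("ISO", "P", "QRS", "T", "PAD")

.wave_types <- c("P", "QRS", "T")
.wave_symbols <- c(P = "p", QRS = "N", T = "t")

#' Construct a single-lead ECG record
#'
#' @param signal Numeric vector of amplitudes in millivolts.
#' @param sampling_rate Sampling frequency in Hz (LUDB-style records use
#'   500 Hz).
#' @param record_id Record identifier used as the WFDB record name.
#' @param lead_name Lead label; lead II is the conventional rhythm lead.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, sampling_rate = 500, record_id = "record",
                       lead_name = "II") {
  if (!is.numeric(signal) || length(signal) < 1L)
    stop("`signal` must be a numeric vector of length >= 1", call. = FALSE)
  if (!all(is.finite(signal)))
    stop("`signal` must be finite everywhere", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  structure(
    list(record_id = as.character(record_id),
         sampling_rate = as.numeric(sampling_rate),
         signal = as.numeric(signal),
         lead_name = as.character(lead_name)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> lead %s, %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead_name, length(x$signal), x$sampling_rate,
              length(x$signal) / x$sampling_rate))
  invisible(x)
}

#' Construct a wave annotation table
#'
#' Annotations are inclusive `[onset, offset]` intervals in 0-based sample
#' indices, matching WFDB marker semantics where the onset and offset
#' markers sit on samples.
#'
#' @param wave_type Character vector of wave types (`"P"`, `"QRS"`, `"T"`).
#' @param onset,offset Integer 0-based sample indices.
#' @param peak Optional integer 0-based peak sample index (`NA` if absent).
#' @return A `data.frame` of class `wave_annotations`, sorted by onset.
#' @export
wave_annotations <- function(wave_type = character(), onset = integer(),
                             peak = NA_integer_, offset = integer()) {
  n <- length(wave_type)
  if (n == 0L) peak <- integer(0)
  else if (length(peak) == 1L && n > 1L) peak <- rep(peak, n)
  df <- data.frame(wave_type = as.character(wave_type),
                   onset = as.integer(onset),
                   peak = as.integer(peak),
                   offset = as.integer(offset),
                   stringsAsFactors = FALSE)
  validate_wave_annotations(df)
}

validate_wave_annotations <- function(df) {
  if (nrow(df)) {
    if (!all(df$wave_type %in% .wave_types))
      stop("wave_type must be one of ", paste(.wave_types, collapse = ", "),
           call. = FALSE)
    if (any(df$onset < 0L) || any(df$onset > df$offset))
      stop("annotations require 0 <= onset <= offset", call. = FALSE)
    has_peak <- !is.na(df$peak)
    if (any(df$onset[has_peak] > df$peak[has_peak]) ||
        any(df$peak[has_peak] > df$offset[has_peak]))
      stop("annotations require onset <= peak <= offset", call. = FALSE)
    df <- df[order(df$onset), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("wave_annotations", "data.frame")
  df
}

#' Write a WFDB-style record
#'
#' Writes `<path>.hea` (text header) and `<path>.dat` (16-bit little-endian
#' samples at an ADC gain of 1000 units/mV).  If annotations are supplied
#' (or derivable from `labels`), a `<path>.ann` text annotation file is
#' written as well.
#'
#' @param record An [ecg_record].
#' @param path Record path without extension.
#' @param labels Optional per-sample label sequence (see [ecg_classes]);
#'   converted to wave annotations by run-length decoding, with each wave's
#'   peak placed at its largest absolute amplitude.
#' @param annotations Optional [wave_annotations] table; takes precedence
#'   over `labels`.
#' @return Invisibly, the paths written.
#' @export
write_ecg_record <- function(record, path, labels = NULL, annotations = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$signal) < 1L)
    stop("cannot write a zero-length signal", call. = FALSE)
  gain <- 1000
  adc <- as.integer(round(record$signal * gain))
  if (any(abs(adc) > 32767L))
    stop("signal exceeds the format-16 amplitude range (+/-32.767 mV)",
         call. = FALSE)
  rec <- basename(path)
  hea <- c(sprintf("%s 1 %g %d", rec, record$sampling_rate, length(adc)),
           sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 %s",
                   rec, gain, adc[1L], record$lead_name))
  hea_path <- paste0(path, ".hea")
  dat_path <- paste0(path, ".dat")
  tryCatch({
    writeLines(hea, hea_path)
    con <- file(dat_path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(adc, con, size = 2L, endian = "little")
  }, error = function(e) {
    stop("failed to write record files at '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  written <- c(hea_path, dat_path)
  if (is.null(annotations) && !is.null(labels))
    annotations <- node_labels_to_annotations(labels, record$signal)
  if (!is.null(annotations) && nrow(annotations)) {
    ann_path <- paste0(path, ".ann")
    write_wave_annotations(annotations, ann_path)
    written <- c(written, ann_path)
  }
  invisible(written)
}

#' Read a WFDB-style record
#'
#' Parses the `.hea` header, locates the requested lead among the signal
#' description fields, reads the interleaved format-16 `.dat` file and
#' rescales to millivolts using the header gain and baseline.
#'
#' @param path Record path without extension.
#' @param lead_name Lead to extract (default `"II"`).
#' @return An [ecg_record].
#' @export
read_ecg_record <- function(path, lead_name = "II") {
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path))
    stop("record header not found: '", hea_path, "'", call. = FALSE)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n_sig <- as.integer(top[2L])
  fs <- as.numeric(top[3L])
  n_samp <- as.integer(top[4L])
  sig_lines <- lines[1L + seq_len(n_sig)]
  leads <- character(n_sig)
  gains <- numeric(n_sig)
  baselines <- integer(n_sig)
  for (i in seq_len(n_sig)) {
    f <- strsplit(trimws(sig_lines[i]), "\\s+")[[1L]]
    gspec <- f[3L]                      # e.g. "1000(0)/mV"
    gains[i] <- as.numeric(sub("^([-0-9.eE+]+).*", "\\1", gspec))
    baselines[i] <- if (grepl("\\(", gspec))
      as.integer(sub(".*\\(([-0-9]+)\\).*", "\\1", gspec)) else 0L
    leads[i] <- paste(f[-(1:8)], collapse = " ")
  }
  idx <- match(lead_name, leads)
  if (is.na(idx))
    stop("lead '", lead_name, "' not found in record '", path,
         "' (available: ", paste(leads, collapse = ", "), ")", call. = FALSE)
  dat_path <- paste0(path, ".dat")
  if (!file.exists(dat_path))
    stop("signal file not found: '", dat_path, "'", call. = FALSE)
  con <- file(dat_path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "integer", n = n_sig * n_samp, size = 2L,
                 endian = "little", signed = TRUE)
  sig <- raw[seq.int(idx, by = n_sig, length.out = n_samp)]
  ecg_record((sig - baselines[idx]) / gains[idx], sampling_rate = fs,
             record_id = sub("\\.hea$", "", basename(hea_path)),
             lead_name = lead_name)
}

#' Write wave annotations as a text marker file
#'
#' One `sample symbol` pair per line; `(` marks the onset, `)` the offset,
#' and the interior symbol (`p`, `N` or `t`) marks the wave's peak and
#' carries its type.  Annotations without a peak index cannot be encoded.
#'
#' @param annotations A [wave_annotations] table with peaks present.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_wave_annotations <- function(annotations, path) {
  annotations <- validate_wave_annotations(as.data.frame(annotations))
  if (any(is.na(annotations$peak)))
    stop("cannot encode annotations without peak indices", call. = FALSE)
  rows <- character(0)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    rows <- c(rows,
              sprintf("%d (", a$onset),
              sprintf("%d %s", a$peak, .wave_symbols[[a$wave_type]]),
              sprintf("%d )", a$offset))
  }
  writeLines(c("# sample symbol", rows), path)
  invisible(path)
}

#' Read a text wave annotation file
#'
#' @param path Annotation file written by [write_wave_annotations] (or the
#'   same dialect produced elsewhere).
#' @return A [wave_annotations] table sorted by onset.
#' @export
read_wave_annotations <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: '", path, "'", call. = FALSE)
  rec <- basename(path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  state <- 0L  # 0 = expect "(", 1 = expect wave symbol, 2 = expect ")"
  cur <- NULL
  bad <- function(sample, what)
    stop(sprintf("malformed annotation in '%s' at sample %d: %s",
                 rec, sample, what), call. = FALSE)
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    sample <- suppressWarnings(as.integer(f[1L]))
    sym <- f[2L]
    if (is.na(sample) || is.na(sym)) bad(-1L, paste("unparseable line:", ln))
    if (sym == "(") {
      if (state != 0L) bad(sample, "onset marker before previous wave closed")
      cur <- list(onset = sample)
      state <- 1L
    } else if (sym %in% .wave_symbols) {
      if (state != 1L) bad(sample, "wave symbol without preceding onset marker")
      cur$peak <- sample
      cur$wave_type <- names(.wave_symbols)[match(sym, .wave_symbols)]
      state <- 2L
    } else if (sym == ")") {
      if (state != 2L) bad(sample, "offset marker without onset/peak markers")
      cur$offset <- sample
      out[[length(out) + 1L]] <- cur
      state <- 0L
    } else bad(sample, paste("unknown symbol", sym))
  }
  if (state != 0L)
    bad(cur$onset, "onset marker lacking a matching offset marker")
  if (!length(out)) return(wave_annotations())
  wave_annotations(wave_type = vapply(out, `[[`, "", "wave_type"),
                   onset = vapply(out, `[[`, 0L, "onset"),
                   peak = vapply(out, `[[`, 0L, "peak"),
                   offset = vapply(out, `[[`, 0L, "offset"))
}

#' Expand wave annotations into a per-sample label sequence
#'
#' Samples inside each inclusive `[onset, offset]` interval receive the
#' wave's class; all remaining samples are the isoelectric class.  The
#' padding class is never emitted here.
#'
#' @param annotations A [wave_annotations] table (non-overlapping).
#' @param n_samples Length of the target label sequence.
#' @return Character vector of length `n_samples` over [ecg_classes].
#' @export
annotations_to_node_labels <- function(annotations, n_samples) {
  labels <- rep("ISO", n_samples)
  if (!nrow(annotations)) return(labels)
  if (any(annotations$offset >= n_samples))
    stop("annotation indices must be < n_samples", call. = FALSE)
  ann <- annotations[order(annotations$onset), , drop = FALSE]
  if (nrow(ann) > 1L) {
    prev_end <- ann$offset[-nrow(ann)]
    nxt_start <- ann$onset[-1L]
    ov <- which(nxt_start <= prev_end)
    if (length(ov)) {
      i <- ov[1L]
      stop(sprintf(
        "overlapping annotations: %s [%d,%d] and %s [%d,%d]",
        ann$wave_type[i], ann$onset[i], ann$offset[i],
        ann$wave_type[i + 1L], ann$onset[i + 1L], ann$offset[i + 1L]),
        call. = FALSE)
    }
  }
  for (i in seq_len(nrow(ann)))
    labels[(ann$onset[i]:ann$offset[i]) + 1L] <- ann$wave_type[i]
  labels
}

#' Run-length decode a label sequence into wave annotations
#'
#' Inverse of [annotations_to_node_labels]: maximal runs of wave classes
#' become annotations; the peak is the sample with the largest absolute
#' amplitude inside the run (requires `signal`).
#'
#' @param labels Per-sample label sequence.
#' @param signal Aligned amplitude vector used to locate peaks.
#' @return A [wave_annotations] table.
#' @export
node_labels_to_annotations <- function(labels, signal) {
  stopifnot(length(labels) == length(signal))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% .wave_types
  if (!any(keep)) return(wave_annotations())
  starts <- starts[keep]; ends <- ends[keep]; types <- r$values[keep]
  peaks <- mapply(function(s, e) s + which.max(abs(signal[s:e])) - 1L,
                  starts, ends)
  wave_annotations(wave_type = types, onset = starts - 1L,
                   peak = peaks - 1L, offset = ends - 1L)
}

#' Count annotated waveforms by type
#'
#' @param annotations A [wave_annotations] table (possibly pooled over a
#'   whole dataset).
#' @return Named numeric vector with elements `P`, `QRS`, `T` and `total`.
#' @export
count_waveforms <- function(annotations) {
  counts <- vapply(.wave_types,
                   function(w) sum(annotations$wave_type == w), 0)
  c(counts, total = sum(counts))
}
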