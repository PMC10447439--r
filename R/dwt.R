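# Periodized discrete wavelet transform and soft-threshold denoising.
# The transform is a circular two-channel filter bank; with the banks in
# .wavelet_filter_banks it reconstructs perfectly (the synthesis output is
# the input circularly shifted by filter_length - 1, which is undone here).

.get_filter_bank <- function(wavelet) {
  fb <- .wavelet_filter_banks[[wavelet]]
  if (is.null(fb))
    stop("unknown wavelet '", wavelet, "'; supported families: ",
         paste(wavelet_families(), collapse = ", "), call. = FALSE)
  fb
}

# circular shift: positive k moves elements toward the front
.roll <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) x else c(x[(k + 1L):n], x[1:k])
}

# one analysis step: cyclic convolution with `f` sampled at odd indices.
# x must have even length.
.dwt_step <- function(x, f) {
  n <- length(x)
  half <- n %/% 2L
  out <- numeric(half)
  # out[k] = sum_j f[j+1] * x[(2k + 1 - j) mod n],  k = 0..half-1
  for (j in seq_along(f) - 1L) {
    idx <- (seq.int(1L, by = 2L, length.out = half) - j) %% n
    out <- out + f[j + 1L] * x[idx + 1L]
  }
  out
}

# one synthesis step; returns a vector of length 2 * length(a)
.idwt_step <- function(a, d, g0, g1) {
  n <- 2L * length(a)
  u0 <- numeric(n); u1 <- numeric(n)
  u0[seq.int(2L, n, by = 2L)] <- a
  u1[seq.int(2L, n, by = 2L)] <- d
  y <- numeric(n)
  for (j in seq_along(g0) - 1L)
    y <- y + g0[j + 1L] * .roll(u0, -j) + g1[j + 1L] * .roll(u1, -j)
  # undo the filter-bank delay of (L - 1) samples
  .roll(y, length(g0) - 1L)
}

#' Multilevel discrete wavelet decomposition
#'
#' Periodized pyramid decomposition.  Odd-length stages are extended by
#' replicating the last sample (recorded and undone on reconstruction).
#' If the requested depth would leave fewer than 2 approximation
#' coefficients the depth is reduced with a warning.
#'
#' @param signal Finite numeric vector, length >= 2.
#' @param wavelet Wavelet family name (see [wavelet_families]).
#' @param levels Decomposition depth (default 8).
#' @return A list of class `dwt_decomposition` with the approximation
#'   band, the detail bands (finest first) and bookkeeping fields.
#' @export
dwt_transform <- function(signal, wavelet = "coif5", levels = 8L) {
  if (!all(is.finite(signal)))
    stop("signal must be finite everywhere", call. = FALSE)
  if (length(signal) < 2L)
    stop("signal must have length >= 2", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  max_lev <- max(1L, floor(log2(length(signal))) - 1L)
  if (levels > max_lev) {
    warning(sprintf("reducing decomposition depth from %d to %d for a %d-sample signal",
                    levels, max_lev, length(signal)))
    levels <- max_lev
  }
  fb <- .get_filter_bank(wavelet)
  details <- vector("list", levels)
  lengths <- integer(levels)
  a <- as.numeric(signal)
  for (l in seq_len(levels)) {
    lengths[l] <- length(a)
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    details[[l]] <- .dwt_step(a, fb$dec_hi)
    a <- .dwt_step(a, fb$dec_lo)
  }
  structure(list(approx = a, details = details, lengths = lengths,
                 wavelet = wavelet, levels = levels),
            class = "dwt_decomposition")
}

#' Reconstruct a signal from its wavelet decomposition
#'
#' @param decomposition A `dwt_decomposition` from [dwt_transform].
#' @return Numeric vector of the original signal length.
#' @export
dwt_inverse <- function(decomposition) {
  stopifnot(inherits(decomposition, "dwt_decomposition"))
  fb <- .get_filter_bank(decomposition$wavelet)
  a <- decomposition$approx
  for (l in rev(seq_len(decomposition$levels))) {
    a <- .idwt_step(a, decomposition$details[[l]], fb$rec_lo, fb$rec_hi)
    a <- a[seq_len(decomposition$lengths[l])]   # drop odd-length padding
  }
  a
}

#' Denoising configuration
#'
#' @param wavelet Wavelet family (default `"coif5"`, the family with the
#'   best averaged output SNR among the candidates compared here).
#' @param levels Decomposition depth (default 8).
#' @return A list of class `denoising_config`.
#' @export
denoising_config <- function(wavelet = "coif5", levels = 8L) {
  .get_filter_bank(wavelet)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  structure(list(wavelet = wavelet, levels = levels,
                 threshold_mode = "soft",
                 threshold_rule = "universal_per_level"),
            class = "denoising_config")
}

.soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Wavelet soft-threshold denoising
#'
#' Decomposes the signal, soft-thresholds every detail band with the
#' per-level universal threshold `sigma * sqrt(2 * log(N_j))`, leaves
#' the approximation band untouched, and reconstructs.  The noise scale
#' `sigma` is estimated once, as `median(|d_1|) / 0.6745` from the
#' finest detail band, where broadband noise dominates; estimating it
#' per band would read large coarse-band signal coefficients as noise
#' and erase the waves themselves.  Soft thresholding zeroes
#' coefficients below the threshold and shrinks the rest toward zero.
#'
#' @param signal Finite numeric vector.
#' @param config A [denoising_config].
#' @param threshold_scale Multiplier on the universal threshold; 0 turns
#'   denoising into the identity pipeline (up to reconstruction error).
#' @return Denoised signal, same length as the input.
#' @export
dwt_denoise <- function(signal, config = denoising_config(),
                        threshold_scale = 1) {
  stopifnot(inherits(config, "denoising_config"))
  dec <- dwt_transform(signal, config$wavelet, config$levels)
  sigma <- stats::median(abs(dec$details[[1L]])) / 0.6745
  dec$details <- lapply(dec$details, function(d) {
    thr <- threshold_scale * sigma * sqrt(2 * log(length(d)))
    .soft_threshold(d, thr)
  })
  dwt_inverse(dec)
}

#' Input signal-to-noise ratio
#'
#' `10 * log10(sum(x^2) / sum(r^2))` for a clean signal `x` and the added
#' noise `r`, in decibels.
#'
#' @param clean Clean signal.
#' @param noise Added noise, same length.
#' @return SNR in dB.
#' @export
input_snr <- function(clean, noise) {
  if (length(clean) != length(noise))
    stop("clean and noise must have the same length", call. = FALSE)
  noise_energy <- sum(noise^2)
  if (noise_energy == 0)
    stop("noise energy is zero; input SNR is undefined", call. = FALSE)
  10 * log10(sum(clean^2) / noise_energy)
}

#' Output signal-to-noise ratio
#'
#' `10 * log10(sum(xd^2) / sum((xd - x)^2))` for a reference signal `x`
#' and a denoised signal `xd`: denoised energy over residual energy.
#' When the residual is exactly zero the ratio is unbounded and `Inf` is
#' returned.
#'
#' @param original Reference signal `x`.
#' @param denoised Denoised signal `xd`, same length.
#' @return SNR in dB (`Inf` when `denoised` equals `original` exactly).
#' @export
output_snr <- function(original, denoised) {
  if (length(original) != length(denoised))
    stop("original and denoised must have the same length", call. = FALSE)
  resid <- sum((denoised - original)^2)
  if (resid == 0) return(Inf)
  10 * log10(sum(denoised^2) / resid)
}

#' Compare wavelet families by averaged output SNR
#'
#' For every clean signal a noise realization is drawn once from the
#' seeded noise specification and shared across all wavelets; each
#' wavelet denoises each noisy signal and is scored by the mean output
#' SNR against the clean reference.
#'
#' @param clean_signals A list of clean amplitude vectors (or a single
#'   vector).
#' @param noise A [noise_spec] describing the additive noise.
#' @param wavelets Character vector of family names (default: all 14
#'   supported families).
#' @param levels Decomposition depth used for every wavelet.
#' @return A `data.frame` (class `snr_report`) with columns `wavelet`,
#'   `averaged_snr_db` and `n_records`, sorted by `averaged_snr_db`
#'   descending.
#' @export
compare_wavelets <- function(clean_signals, noise = noise_spec(),
                             wavelets = wavelet_families(), levels = 8L) {
  if (is.numeric(clean_signals)) clean_signals <- list(clean_signals)
  if (!length(clean_signals) || !length(wavelets))
    stop("need at least one signal and one wavelet", call. = FALSE)
  unknown <- setdiff(wavelets, wavelet_families())
  if (length(unknown))
    stop("unknown wavelet(s) ", paste(unknown, collapse = ", "),
         "; supported families: ",
         paste(wavelet_families(), collapse = ", "), call. = FALSE)
  noisy <- vector("list", length(clean_signals))
  for (i in seq_along(clean_signals)) {
    ns <- noise
    ns$seed <- noise$seed + i - 1L
    noisy[[i]] <- add_noise(clean_signals[[i]], ns)$noisy
  }
  snr <- vapply(wavelets, function(w) {
    cfg <- denoising_config(wavelet = w, levels = levels)
    mean(vapply(seq_along(clean_signals), function(i) {
      den <- suppressWarnings(dwt_denoise(noisy[[i]], cfg))
      output_snr(clean_signals[[i]], den)
    }, 0))
  }, 0)
  out <- data.frame(wavelet = wavelets, averaged_snr_db = as.numeric(snr),
                    n_records = length(clean_signals),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$averaged_snr_db), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snr_report", "data.frame")
  out
}
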