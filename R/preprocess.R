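#' Denoising configuration
#'
#' The pipeline's default applies no denoising at all: the embedding
#' network tolerates the raw signal and filtering can distort beat
#' morphology. The operators exist for the denoise-vs-not comparison.
#'
#' @param use_fir_notch apply band-stop FIR filters at `notch_freqs`.
#' @param notch_freqs frequencies (Hz) to suppress; defaults target 60 Hz
#'   power-line pickup and 100 Hz fluorescent-light interference.
#' @param use_median_baseline subtract a two-stage running-median baseline.
#' @param median_windows the two (odd) median window lengths in samples.
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(use_fir_notch = FALSE, notch_freqs = c(60, 100),
                           use_median_baseline = FALSE,
                           median_windows = c(71, 215)) {
  if (any(median_windows %% 2 == 0) || any(median_windows <= 0))
    stop("median windows must be odd and positive")
  structure(list(use_fir_notch = use_fir_notch, notch_freqs = notch_freqs,
                 use_median_baseline = use_median_baseline,
                 median_windows = median_windows),
            class = "denoise_config")
}

#' Hyperbolic-tangent amplitude normalization
#'
#' Squashes each sample into (-1, 1) via (e^x - e^-x)/(e^x + e^-x). Values
#' near zero are nearly unchanged while large deflections (the R peak)
#' saturate, which evens out the dynamic range seen by the embedder. This
#' is applied per extracted beat, directly on the mV values.
#'
#' @param x numeric vector of finite values.
#' @return Vector of the same length, strictly inside (-1, 1).
#' @export
#' @examples
#' tanh_normalize(c(0, 1, 20))
tanh_normalize <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite")
  tanh(x)
}

# Reflect-pad a vector by p samples on each side.
reflect_pad <- function(x, p) {
  n <- length(x)
  if (p >= n) stop("padding exceeds signal length")
  c(x[(p + 1):2], x, x[(n - 1):(n - p)])
}

#' Remove baseline wander with a two-stage running median
#'
#' Estimates the baseline as running-median(running-median(x, w1), w2) --
#' the short window strips beat features, the long window follows only the
#' slow wander -- and subtracts it. Edges are handled by reflection.
#'
#' @param x numeric signal.
#' @param w1,w2 odd window lengths in samples (defaults 71 and 215, roughly
#'   0.2 s and 0.6 s at 360 Hz).
#' @return `x` minus the estimated baseline.
#' @export
median_baseline_remove <- function(x, w1 = 71, w2 = 215) {
  if (w1 %% 2 == 0 || w2 %% 2 == 0 || w1 <= 0 || w2 <= 0)
    stop("median windows must be odd and positive")
  if (length(x) <= w2) stop("signal must be longer than w2")
  p <- max(w1, w2)
  xp <- reflect_pad(x, p)
  b <- stats::runmed(xp, w1, endrule = "median")
  b <- stats::runmed(b, w2, endrule = "median")
  x - b[(p + 1):(p + length(x))]
}

# Cache FIR designs: key on (order, fs, f, width).
.fir_cache <- new.env(parent = emptyenv())

bandstop_taps <- function(f, fs, width, order) {
  key <- paste(order, fs, f, width, sep = "_")
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  taps <- signal::fir1(order, c(f - width, f + width) / (fs / 2),
                       type = "stop")
  .fir_cache[[key]] <- as.numeric(taps)
  taps
}

#' Band-stop FIR filtering of narrowband interference
#'
#' Applies a cascade of linear-phase windowed-sinc (Hamming) band-stop FIR
#' filters, one per entry of `freqs`. Each notch attenuates its target
#' frequency by at least 20 dB while leaving the sub-40 Hz ECG band within
#' 1 dB. The group delay is compensated and edges are reflection-padded,
#' so the output is aligned with the input.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param freqs notch centre frequencies, each < fs/2.
#' @param width half-width of each stop band in Hz.
#' @param order FIR order (even; `order + 1` taps).
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, freqs = c(60, 100), width = 8, order = 440) {
  if (any(freqs >= fs / 2)) stop("notch frequency must be < fs/2")
  if (order %% 2 != 0) stop("order must be even (linear phase, type I)")
  delay <- order / 2
  for (f in freqs) {
    taps <- bandstop_taps(f, fs, width, order)
    xp <- reflect_pad(x, order)
    y <- stats::filter(xp, taps, method = "convolution", sides = 1)
    x <- as.numeric(y[(order + delay + 1):(order + delay + length(x))])
  }
  x
}

#' Apply a denoising configuration to a record
#'
#' Operator order when both stages are enabled: FIR notch filtering first,
#' then median baseline removal.
#'
#' @param record an [ecg_record()].
#' @param config a [denoise_config()].
#' @return A new [ecg_record()] with the filtered signal.
#' @export
apply_denoise <- function(record, config = denoise_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "denoise_config"))
  x <- record$samples
  if (config$use_fir_notch)
    x <- notch_filter(x, record$fs, config$notch_freqs)
  if (config$use_median_baseline)
    x <- median_baseline_remove(x, config$median_windows[1],
                                config$median_windows[2])
  ecg_record(record$record_id, x, record$fs, record$lead)
}

#' Tanh-normalize every beat of a heartbeat set
#'
#' @param beats a [heartbeat_set()].
#' @return The set with each beat passed through [tanh_normalize()].
#' @export
normalize_beats <- function(beats) {
  stopifnot(inherits(beats, "heartbeat_set"))
  beats$samples <- tanh(beats$samples)
  beats
}
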