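# Gaussian bump: the elementary waveform component used for P, Q, R, S, T.
gauss_bump <- function(t, amp, center, sd) {
  amp * exp(-((t - center)^2) / (2 * sd^2))
}

# Fixed wave centres (seconds relative to the R peak). The P wave sits one
# PR interval before the QRS; the T wave follows ventricular repolarisation.
P_CENTER <- -0.22
T_CENTER <- 0.30

#' Morphology parameters for a synthetic heartbeat
#'
#' Describes one beat as a sum of Gaussian bumps for the P wave, the Q/R/S
#' deflections and the T wave. The two built-in presets contrast a normal
#' sinus beat with a premature ventricular contraction (PVC): the PVC has no
#' P wave (the impulse originates in the ventricle, not the atrium), a QRS
#' complex that is both wider and taller, and a T wave of opposite polarity
#' to its R wave.
#'
#' @param cls `"normal"` or `"pvc"`; selects the preset the overrides are
#'   applied to.
#' @param ... named overrides of any field: `p_amp`, `p_width`, `q_amp`,
#'   `r_amp`, `s_amp`, `qrs_width`, `t_amp`, `t_width` (amplitudes in mV,
#'   widths in seconds).
#' @return An object of class `beat_morph_params`.
#' @export
#' @examples
#' beat_morph_params("pvc", r_amp = -1.2, t_amp = 0.4) # negative-going PVC
beat_morph_params <- function(cls = c("normal", "pvc"), ...) {
  cls <- match.arg(cls)
  defaults <- if (cls == "normal") {
    list(p_amp = 0.15, p_width = 0.08, q_amp = -0.10, r_amp = 1.00,
         s_amp = -0.20, qrs_width = 0.08, t_amp = 0.30, t_width = 0.16)
  } else {
    list(p_amp = 0.00, p_width = 0.08, q_amp = -0.05, r_amp = 1.40,
         s_amp = -0.30, qrs_width = 0.16, t_amp = -0.45, t_width = 0.20)
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop("unknown morphology field(s): ", paste(unknown, collapse = ", "))
  morph <- utils::modifyList(defaults, overrides)
  widths <- c("p_width", "qrs_width", "t_width")
  if (any(unlist(morph[widths]) <= 0))
    stop("all widths must be > 0")
  structure(c(morph, list(cls = cls)), class = "beat_morph_params")
}

#' Rhythm specification for a synthetic record
#'
#' Controls how PVCs are interleaved with normal beats. The repeating
#' patterns follow the clinical definitions: bigeminy (every other beat a
#' PVC), trigeminy (every third), quadrigeminy (every fourth), couplet (two
#' consecutive PVCs). `random` draws each beat independently with
#' probability `pvc_fraction`. A PVC arrives early by `prematurity *
#' base_rr` and the next sinus beat stays on the underlying grid, so an
#' isolated PVC shows the full compensatory pause: the RR interval before
#' plus after it equals two base RR intervals.
#'
#' @param pattern one of `"none"`, `"bigeminy"`, `"trigeminy"`,
#'   `"quadrigeminy"`, `"couplet"`, `"random"`.
#' @param pvc_fraction probability a beat is a PVC when `pattern = "random"`.
#' @param base_rr base RR interval in seconds.
#' @param prematurity fraction of `base_rr` by which a PVC arrives early,
#'   strictly in (0, 1).
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(pattern = c("none", "bigeminy", "trigeminy",
                                    "quadrigeminy", "couplet", "random"),
                        pvc_fraction = 0.3, base_rr = 0.8,
                        prematurity = 0.25) {
  pattern <- match.arg(pattern)
  if (pvc_fraction < 0 || pvc_fraction > 1)
    stop("pvc_fraction must be in [0, 1]")
  if (base_rr <= 0) stop("base_rr must be > 0")
  if (prematurity <= 0 || prematurity >= 1)
    stop("prematurity must be strictly in (0, 1)")
  structure(list(pattern = pattern, pvc_fraction = pvc_fraction,
                 base_rr = base_rr, prematurity = prematurity),
            class = "rhythm_spec")
}

#' Additive noise specification
#'
#' Models the disturbances typical of ambulatory (Holter) recordings:
#' broadband sensor noise, 60 Hz power-line pickup, 100 Hz interference from
#' fluorescent lighting, and low-frequency baseline wander from respiration
#' and electrode motion.
#'
#' @param gaussian_sd standard deviation of white Gaussian noise (mV).
#' @param powerline_amp amplitude of the 60 Hz sinusoid (mV).
#' @param fluorescent_amp amplitude of the 100 Hz sinusoid (mV).
#' @param baseline_amp amplitude of the baseline-wander sinusoid (mV).
#' @param baseline_freq baseline-wander frequency (Hz).
#' @param seed integer seed driving all randomness of one record, or `NULL`
#'   to draw from the current RNG stream.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sd = 0.02, powerline_amp = 0.01,
                       fluorescent_amp = 0.01, baseline_amp = 0.05,
                       baseline_freq = 0.3, seed = NULL) {
  amps <- c(gaussian_sd, powerline_amp, fluorescent_amp, baseline_amp)
  if (any(amps < 0)) stop("all noise amplitudes must be >= 0")
  if (baseline_freq <= 0) stop("baseline_freq must be > 0")
  structure(list(gaussian_sd = gaussian_sd, powerline_amp = powerline_amp,
                 fluorescent_amp = fluorescent_amp,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 seed = seed),
            class = "noise_spec")
}

# Evaluate the five-bump beat model at times t (seconds relative to the R
# peak). The R bump's sd is qrs_width/4, so its full width at half maximum
# scales linearly with qrs_width.
beat_waveform <- function(t, morph) {
  w <- morph$qrs_width
  gauss_bump(t, morph$p_amp, P_CENTER, morph$p_width / 2.355) +
    gauss_bump(t, morph$q_amp, -w / 2, w / 7) +
    gauss_bump(t, morph$r_amp, 0, w / 4) +
    gauss_bump(t, morph$s_amp, w / 2, w / 7) +
    gauss_bump(t, morph$t_amp, T_CENTER, morph$t_width / 2.355)
}

#' Generate one synthetic heartbeat cycle
#'
#' Samples the Gaussian-bump P-QRS-T model over one beat cycle
#' (-0.35 s to +0.5 s around the R peak). With the built-in presets the PVC
#' beat has no P bump, a wider and taller QRS, and an inverted T wave.
#'
#' @param cls `"normal"` or `"pvc"`.
#' @param morph a [beat_morph_params()] object; defaults to the preset for
#'   `cls`.
#' @param fs sampling rate in Hz.
#' @return Numeric waveform (mV); attribute `"t"` holds the sample times
#'   relative to the R peak and `"r_offset"` the 1-based index of the R
#'   sample.
#' @export
generate_beat <- function(cls = c("normal", "pvc"),
                          morph = beat_morph_params(cls), fs = 360) {
  cls <- match.arg(cls)
  if (fs <= 0) stop("fs must be > 0")
  stopifnot(inherits(morph, "beat_morph_params"))
  t <- seq(-0.35, 0.5, by = 1 / fs)
  y <- beat_waveform(t, morph)
  structure(y, t = t, r_offset = which.min(abs(t)))
}

# Run code with a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rhythm_labels <- function(n_beats, rhythm) {
  switch(rhythm$pattern,
    none = rep("N", n_beats),
    bigeminy = rep_len(c("N", "V"), n_beats),
    trigeminy = rep_len(c("N", "N", "V"), n_beats),
    quadrigeminy = rep_len(c("N", "N", "N", "V"), n_beats),
    couplet = {
      lab <- rep("N", n_beats)
      mid <- min(max(1L, n_beats %/% 2L), n_beats - 1L)
      lab[c(mid, mid + 1L)] <- "V"
      lab
    },
    random = ifelse(stats::runif(n_beats) < rhythm$pvc_fraction, "V", "N")
  )
}

#' Generate an annotated synthetic ECG record
#'
#' Lays beats on an underlying RR grid, shifts each PVC early by
#' `prematurity * base_rr` while keeping the following sinus beat on the
#' grid (full compensatory pause), sums the per-beat waveforms, and adds
#' the noise components. All randomness (random rhythm draws, noise) is
#' driven by `noise$seed`, so the same seed reproduces the record bit for
#' bit.
#'
#' @param n_beats number of beats (>= 2).
#' @param rhythm a [rhythm_spec()].
#' @param morph_normal,morph_pvc [beat_morph_params()] for the two classes.
#' @param noise a [noise_spec()].
#' @param fs sampling rate in Hz.
#' @param record_id identifier stored on the record.
#' @return A list with `record` (an [ecg_record()]) and `annotations`
#'   (data.frame with 0-based `sample_index` and `symbol` in `{"N","V"}`).
#' @export
generate_record <- function(n_beats, rhythm = rhythm_spec(),
                            morph_normal = beat_morph_params("normal"),
                            morph_pvc = beat_morph_params("pvc"),
                            noise = noise_spec(), fs = 360,
                            record_id = "synth") {
  if (n_beats < 2) stop("n_beats must be >= 2")
  stopifnot(inherits(rhythm, "rhythm_spec"), inherits(noise, "noise_spec"))
  with_seed(noise$seed, {
    labels <- rhythm_labels(n_beats, rhythm)
    base <- rhythm$base_rr
    # lead-in long enough that a 433-sample window at 360 Hz fits the first
    # beat; scaled with base_rr for slower rhythms
    t0 <- 0.65 + 0.5 * base
    nominal <- t0 + (seq_len(n_beats) - 1) * base
    r_times <- nominal - ifelse(labels == "V", rhythm$prematurity * base, 0)
    total_t <- r_times[n_beats] + 0.65 + 0.5 * base
    n_samp <- ceiling(total_t * fs)
    tt <- (seq_len(n_samp) - 1) / fs
    clean <- numeric(n_samp)
    half_support <- 0.6
    for (k in seq_len(n_beats)) {
      morph <- if (labels[k] == "V") morph_pvc else morph_normal
      lo <- max(1L, floor((r_times[k] - half_support) * fs))
      hi <- min(n_samp, ceiling((r_times[k] + half_support) * fs))
      idx <- lo:hi
      clean[idx] <- clean[idx] + beat_waveform(tt[idx] - r_times[k], morph)
    }
    phases <- stats::runif(3, 0, 2 * pi)
    sig <- clean
    if (noise$powerline_amp > 0)
      sig <- sig + noise$powerline_amp * sin(2 * pi * 60 * tt + phases[1])
    if (noise$fluorescent_amp > 0)
      sig <- sig + noise$fluorescent_amp * sin(2 * pi * 100 * tt + phases[2])
    if (noise$baseline_amp > 0)
      sig <- sig + noise$baseline_amp *
        sin(2 * pi * noise$baseline_freq * tt + phases[3])
    if (noise$gaussian_sd > 0)
      sig <- sig + stats::rnorm(n_samp, 0, noise$gaussian_sd)
    r_index <- round(r_times * fs)  # 0-based sample indices
    list(record = ecg_record(record_id, sig, fs, lead = "MLII"),
         annotations = data.frame(sample_index = as.integer(r_index),
                                  symbol = labels,
                                  stringsAsFactors = FALSE),
         clean = clean)
  })
}
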