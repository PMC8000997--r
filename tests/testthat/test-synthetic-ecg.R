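test_that("normal beat is R-dominated and PVC QRS is wider", {
  fs <- 360
  nb <- generate_beat("normal", fs = fs)
  t <- attr(nb, "t")
  qrs_w <- beat_morph_params("normal")$qrs_width
  peak_t <- t[which.max(abs(nb))]
  expect_lte(abs(peak_t), qrs_w)

  fwhm <- function(beat) {
    t <- attr(beat, "t")
    half <- max(beat) / 2
    # width of the central lobe above half maximum
    above <- which(beat >= half & abs(t) < 0.2)
    t[max(above)] - t[min(above)]
  }
  pb <- generate_beat("pvc", fs = fs)
  expect_gt(fwhm(abs(pb)), fwhm(nb))
})

test_that("a P-less normal beat equals the default beat minus its P bump", {
  fs <- 360
  full <- generate_beat("normal", fs = fs)
  nop <- generate_beat("normal", beat_morph_params("normal", p_amp = 0),
                       fs = fs)
  t <- attr(full, "t")
  morph <- beat_morph_params("normal")
  p_bump <- morph$p_amp * exp(-((t + 0.22)^2) /
                                (2 * (morph$p_width / 2.355)^2))
  expect_equal(as.numeric(full - p_bump), as.numeric(nop), tolerance = 1e-12)
})

test_that("generate_beat rejects bad inputs", {
  expect_error(generate_beat("ventricular"), "arg")
  expect_error(beat_morph_params("normal", qrs_width = -1), "widths")
  expect_error(generate_beat("normal", fs = 0), "fs")
})

test_that("bigeminy alternates N and V; pvc_fraction 0 yields no PVCs", {
  rec <- generate_record(10, rhythm_spec("bigeminy"),
                         noise = noise_spec(seed = 3))
  expect_identical(rec$annotations$symbol, rep(c("N", "V"), 5))

  rec0 <- generate_record(50, rhythm_spec("random", pvc_fraction = 0),
                          noise = noise_spec(seed = 3))
  expect_identical(sum(rec0$annotations$symbol == "V"), 0L)
  expect_equal(nrow(rec0$annotations), 50)
})

test_that("identical seeds give bit-identical records", {
  a <- generate_record(20, rhythm_spec("random", pvc_fraction = 0.3),
                       noise = noise_spec(seed = 7))
  b <- generate_record(20, rhythm_spec("random", pvc_fraction = 0.3),
                       noise = noise_spec(seed = 7))
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$annotations, b$annotations)
  expect_error(generate_record(1), "n_beats")
})

test_that("annotated R indices sit on the clean-signal beat maxima", {
  rec <- make_record(30, "trigeminy", seed = 5)
  for (i in seq_len(nrow(rec$annotations))) {
    r <- rec$annotations$sample_index[i] + 1  # 1-based
    lo <- r - 60; hi <- r + 60
    local_max <- lo - 1 + which.max(abs(rec$clean[lo:hi]))
    expect_lte(abs(local_max - r), 2)
  }
})

test_that("isolated PVCs show a full compensatory pause", {
  rec <- generate_record(40, rhythm_spec("random", pvc_fraction = 0.2),
                         noise = noise_spec(seed = 13))
  sym <- rec$annotations$symbol
  idx <- rec$annotations$sample_index
  base_samp <- 0.8 * 360
  isolated <- which(sym == "V")
  isolated <- isolated[isolated > 1 & isolated < length(sym) &
                         sym[isolated - 1] == "N" & sym[isolated + 1] == "N"]
  expect_gt(length(isolated), 0)
  for (k in isolated) {
    rr_prev <- idx[k] - idx[k - 1]
    rr_next <- idx[k + 1] - idx[k]
    expect_lte(abs((rr_prev + rr_next) - 2 * base_samp), 1)
  }
})

test_that("couplet and quadrigeminy patterns follow their definitions", {
  cp <- generate_record(12, rhythm_spec("couplet"),
                        noise = noise_spec(seed = 2))
  v <- which(cp$annotations$symbol == "V")
  expect_length(v, 2)
  expect_equal(diff(v), 1)

  qg <- generate_record(12, rhythm_spec("quadrigeminy"),
                        noise = noise_spec(seed = 2))
  expect_identical(which(qg$annotations$symbol == "V"), c(4L, 8L, 12L))
})

test_that("pure powerline noise peaks at 60 Hz in the periodogram", {
  flat <- beat_morph_params("normal", p_amp = 0, q_amp = 0, r_amp = 0,
                            s_amp = 0, t_amp = 0)
  rec <- generate_record(10, rhythm_spec("none"),
                         morph_normal = flat,
                         noise = noise_spec(gaussian_sd = 0, powerline_amp = 0.5,
                                            fluorescent_amp = 0,
                                            baseline_amp = 0, seed = 1))
  x <- rec$record$samples
  spec <- stats::spec.pgram(stats::ts(x, frequency = 360), plot = FALSE,
                            taper = 0)
  peak_freq <- spec$freq[which.max(spec$spec)]
  bin <- spec$freq[2] - spec$freq[1]
  expect_lte(abs(peak_freq - 60), bin + 1e-9)
})
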