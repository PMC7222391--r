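# Filtering, instantaneous phase and the phase lag index.

tone_trial <- function(freq, fs = 128, dur = 8, phase = 0, n_ch = 2) {
  t <- (0:(fs * dur - 1)) / fs
  x <- cos(2 * pi * freq * t + phase)
  trial_recording(matrix(rep(x, n_ch), nrow = n_ch, byrow = TRUE), fs = fs)
}

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  tr <- tone_trial(10)
  interior <- 300:700
  # 10 Hz through alpha (7-13): amplitude preserved within 5%
  alpha <- bandpass(tr, "alpha")
  ratio <- sd(alpha$data[1, interior]) / sd(tr$data[1, interior])
  expect_equal(ratio, 1, tolerance = 0.05)
  # 10 Hz through gamma (31-45): attenuated by at least 20 dB
  gamma <- bandpass(tr, "gamma")
  atten <- 20 * log10(sd(gamma$data[1, interior]) / sd(tr$data[1, interior]))
  expect_lt(atten, -20)
  # zero in, zero out
  z <- trial_recording(matrix(0, 2, 1024), fs = 128)
  expect_equal(max(abs(bandpass(z, "alpha")$data)), 0)
  # design is logged
  expect_true(is.list(attr(alpha, "filter_design")))
  expect_error(bandpass(tr, band_definition("bad", 30, 70)), "Nyquist")
})

test_that("instantaneous phase advances at the tone frequency", {
  fs <- 128
  tr <- tone_trial(10, fs = fs, dur = 8)
  ph <- instantaneous_phase(bandpass(tr, "alpha"), edge_trim = 0.5)
  # unwrapped-phase slope regression on the trimmed interior
  unwrapped <- cumsum(c(ph[1, 1], wrap_phase(diff(ph[1, ]))))
  slope <- coef(lm(unwrapped ~ seq_along(unwrapped)))[2] * fs
  expect_equal(unname(slope), 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
})

test_that("a quarter-cycle shifted copy shows a constant pi/2 difference", {
  fs <- 128; t <- (0:(8 * fs - 1)) / fs
  x <- rbind(cos(2 * pi * 10 * t), cos(2 * pi * 10 * t - pi / 2))
  tr <- trial_recording(x, fs = fs)
  ph <- instantaneous_phase(bandpass(tr, "alpha"))
  d <- wrap_phase(ph[1, ] - ph[2, ])
  expect_true(all(abs(d - pi / 2) < 0.05))
})

test_that("degenerate and too-short inputs are refused", {
  z <- trial_recording(rbind(rep(0, 1024), rnorm(1024)), fs = 128)
  expect_error(instantaneous_phase(bandpass(z, "alpha")), "degenerate")
  short <- trial_recording(matrix(rnorm(2 * 100), 2), fs = 128)
  expect_error(instantaneous_phase(short, edge_trim = 0.5), "edge trim")
})

test_that("PLI matches its defining sign statistic", {
  # constant positive lag: all signs identical
  expect_equal(pli_from_phase_diff(rep(pi / 3, 64)), 1)
  # balanced alternating lags: symmetric sign distribution
  expect_equal(pli_from_phase_diff(rep(c(pi / 6, -pi / 6), 32)), 0)
  # hand evaluation: 5 positive vs 3 negative signs out of 8
  dphi <- c(0.4, 1.1, 2.0, 0.3, 0.9, -0.5, -1.2, -2.2)
  expect_equal(pli_from_phase_diff(dphi), abs(5 - 3) / 8)
  # exact 0 and pi contribute sign 0
  expect_equal(pli_from_phase_diff(c(0, pi, -pi, 0)), 0)
  expect_equal(pli_from_phase_diff(c(0, 0, 1, 1)), 0.5)
  expect_error(pli_from_phase_diff(c(1, NA)), "NA")
})

test_that("pli_matrix obeys its invariants", {
  set.seed(7)
  n <- 600
  ph <- rbind(runif(n, -pi, pi),
              runif(n, -pi, pi))
  ph <- rbind(ph, wrap_phase(ph[1, ] + pi / 3))  # constant lag partner
  m <- pli_matrix(ph)
  expect_true(isSymmetric(m$values))
  expect_equal(diag(m$values), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(m$values >= 0 & m$values <= 1))
  expect_equal(m$values[1, 3], 1)                 # constant lag pair
  expect_lt(m$values[1, 2], 3 / sqrt(n))          # independent channels
  # global phase shift leaves PLI unchanged
  m2 <- pli_matrix(wrap_phase(ph + 1.234))
  expect_equal(m$values, m2$values)
  expect_error(pli_matrix(ph[, 1:100]), "512")
  ph_bad <- ph; ph_bad[1, 1] <- NA
  expect_error(pli_matrix(ph_bad), "NaN/NA")
})

test_that("zero-lag mixtures are statistically indistinguishable from 0", {
  # two channels sharing one source with different gains but no lag:
  # the volume-conduction surrogate PLI is built to reject
  set.seed(21)
  fs <- 128; dur <- 30; n <- dur * fs
  src <- rnorm(n)
  x <- rbind(1.0 * src + 0.2 * rnorm(n), 0.5 * src + 0.2 * rnorm(n))
  tr <- trial_recording(x, fs = fs)
  m <- trial_pli(tr, "gamma")
  # noise floor in units of independent narrowband samples: consecutive
  # filtered samples decorrelate over ~1/bandwidth seconds
  n_eff <- (dur - 1) * (45 - 31)
  expect_lt(m$values[1, 2], 3 / sqrt(n_eff))
})

test_that("mean_pli averages the 496 channel pairs", {
  v <- matrix(0.3, 32, 32); diag(v) <- 0
  m <- connectivity_matrix(v)
  expect_equal(mean_pli(m), 0.3)
  one <- matrix(0, 32, 32); one[1, 2] <- one[2, 1] <- 1
  expect_equal(mean_pli(connectivity_matrix(one)), 1 / 496)
  expect_equal(mean_pli(connectivity_matrix(matrix(0, 32, 32))), 0)
})

test_that("condition averaging is an element-wise mean with provenance", {
  mk <- function(fill) {
    v <- matrix(fill, 4, 4); diag(v) <- 0
    connectivity_matrix(v, band = "gamma", subject_id = 1)
  }
  one <- condition_matrix(list(mk(0.2)))
  expect_equal(one$values, mk(0.2)$values)
  two <- condition_matrix(list(mk(0.2), mk(0.6)))
  expect_equal(two$values[1, 2], 0.4)
  expect_equal(two$n_trials_averaged, 2L)
  # brute-force mean oracle on random valid matrices
  set.seed(3)
  ms <- lapply(1:3, function(k) {
    v <- rand_sym_matrix(5); diag(v) <- 0
    connectivity_matrix(v, band = "gamma", subject_id = 1)
  })
  avg <- condition_matrix(ms)
  expect_equal(avg$values,
               (ms[[1]]$values + ms[[2]]$values + ms[[3]]$values) / 3)
  bad <- mk(0.2); bad$band <- "alpha"
  expect_error(condition_matrix(list(mk(0.2), bad)), "mixed bands")
  bad2 <- mk(0.2); bad2$subject_id <- 2
  expect_error(condition_matrix(list(mk(0.2), bad2)), "mixed subjects")
})

test_that("connectivity matrices enforce their invariants", {
  v <- matrix(0.5, 3, 3)
  expect_error(connectivity_matrix(v), "diagonal")
  v2 <- matrix(c(0, 1, 2, 0), 2); expect_error(connectivity_matrix(v2),
                                               "symmetric")
  v3 <- matrix(c(0, 2, 2, 0), 2)
  expect_error(connectivity_matrix(v3), "\\[0, 1\\]")
})
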