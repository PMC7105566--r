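test_that("preprocessing is zero-phase, unit-variance and band-selective", {
  fs <- 1000
  tt <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 5 * tt)
  ps <- preprocess(x, fs, c(3, 7))
  expect_equal(mean(ps$samples), 0, tolerance = 1e-9)
  expect_equal(sd(ps$samples), 1, tolerance = 1e-9)
  # a z-scored sinusoid has amplitude sqrt(2); zero phase lag vs input
  mid <- seq(round(2 * fs), round(18 * fs))
  expect_equal(max(ps$samples[mid]), sqrt(2), tolerance = 1e-2)
  cc <- ccf(ps$samples[mid], x[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # out-of-band component attenuated by > 40 dB: amplitude ratio oracle
  # from the discrete Fourier transform of input and output
  y <- sin(2 * pi * 5 * tt) + sin(2 * pi * 50 * tt)
  out <- signal::filtfilt(signal::butter(2, c(3, 7) / (fs / 2), "pass"), y)
  amp_at <- function(v, f) {
    n <- length(v)
    2 * Mod(fft(v)[round(f * n / fs) + 1]) / n
  }
  gain50 <- amp_at(out[mid], 50) / amp_at(y[mid], 50)
  gain5 <- amp_at(out[mid], 5) / amp_at(y[mid], 5)
  expect_lt(20 * log10(gain50), -40)
  expect_gt(gain5, 0.95)
  expect_error(preprocess(x, fs, c(3, 499)), "Nyquist")
})

test_that("analytic signal recovers envelope, phase slope and the input", {
  fs <- 500
  tt <- seq(0, 10, by = 1 / fs)
  A <- 1.7
  x <- A * cos(2 * pi * 5 * tt)
  an <- analytic_signal(x)
  mid <- seq(round(fs), round(9 * fs))
  expect_equal(mean(an$envelope[mid]), A, tolerance = 1e-3)
  slope <- mean(diff(an$phase[mid])) * fs
  expect_equal(slope, 2 * pi * 5, tolerance = 1e-3)
  # reconstruction env * cos(phase) equals the input in the interior
  recon <- an$envelope * cos(an$phase)
  expect_lt(sqrt(mean((recon[mid] - x[mid])^2)), 1e-6)
  # envelope tracks a known amplitude modulation
  m <- 1 + 0.4 * sin(2 * pi * 0.3 * tt)
  an2 <- analytic_signal(m * cos(2 * pi * 5 * tt))
  expect_lt(max(abs(an2$envelope[mid] - m[mid])), 0.02)
})

test_that("block phase response measures injected phase and frequency changes", {
  fs <- 1000
  tt <- seq(0, 8, by = 1 / fs)
  mk <- function(phase_fun) cos(phase_fun(tt))
  get_dphi <- function(x, t0 = 2, t1 = 7) {
    an <- analytic_signal(x)
    ref <- which(tt >= t0 - 1 & tt < t0)
    i_end <- which.min(abs(tt - t1))
    as.numeric(block_phase_response(tt[ref], an$phase[ref],
                                    tt[i_end], an$phase[i_end]))
  }
  # unperturbed constant frequency
  expect_lt(abs(get_dphi(mk(function(t) 2 * pi * 5 * t))), 0.05)
  # instantaneous phase advance of pi/6 inside the block
  adv <- function(t) 2 * pi * 5 * t + (pi / 6) * (t > 4)
  expect_equal(get_dphi(mk(adv)), pi / 6, tolerance = pi / 6 * 0.1)
  # frequency increased by df mid-block: dphi = 2 pi df (span after change)
  df <- 0.25
  chg <- function(t) 2 * pi * 5 * t + 2 * pi * df * pmax(t - 4, 0)
  expect_equal(get_dphi(mk(chg)), 2 * pi * df * 3, tolerance = 0.1)
  expect_error(block_phase_response(c(0, 0.1), c(0, 1), 1, 10), "0.5 s")
})

test_that("block amplitude response measures envelope changes", {
  fs <- 1000
  tt <- seq(0, 8, by = 1 / fs)
  env_of <- function(x) analytic_signal(x)$envelope
  win <- function(t0, t1) which(tt >= t0 & tt < t1)
  x0 <- cos(2 * pi * 5 * tt)
  e0 <- env_of(x0)
  expect_lt(abs(block_amp_response(e0[win(1, 2)], e0[win(6, 7)])), 0.01)
  # amplitude doubled mid-block: change equals the original envelope
  x2 <- (1 + (tt > 3)) * cos(2 * pi * 5 * tt)
  e2 <- env_of(x2)
  expect_equal(block_amp_response(e2[win(1, 2)], e2[win(6, 7)]), 1,
               tolerance = 0.02)
  # amplitude halved: change is minus half
  x3 <- (1 - 0.5 * (tt > 3)) * cos(2 * pi * 5 * tt)
  e3 <- env_of(x3)
  expect_equal(block_amp_response(e3[win(1, 2)], e3[win(6, 7)]), -0.5,
               tolerance = 0.02)
})

test_that("realised stimulation phase is a two-level circular mean", {
  th <- 2.1
  expect_equal(as.numeric(realized_stim_phase(list(rep(th, 5), th))), th)
  expect_equal(as.numeric(realized_stim_phase(list(0, pi / 2))), pi / 4)
  amb <- realized_stim_phase(list(0, pi))
  expect_true(attr(amb, "ambiguous"))
  # wrap-around: angles near 0 and 2*pi average to ~0
  m <- realized_stim_phase(list(0.1, 2 * pi - 0.1))
  expect_lt(min(as.numeric(m), 2 * pi - as.numeric(m)), 1e-9)
})

test_that("binning normalises per pulse and assigns by realised phase", {
  mkblocks <- function(phi, dphi, denv, np) {
    data.frame(Phi_stim = phi, delta_phi = dphi, delta_env = denv,
               n_pulses = np, excluded = FALSE)
  }
  # constant responses: every bin mean = c / n_pulses
  phi <- rep(phase_bin_centers(12), each = 4)
  b <- mkblocks(phi, dphi = 1.2, denv = -0.6, np = 6)
  rc <- bin_responses(b)
  expect_equal(rc$bprc$mean, rep(1.2 / 6, 12))
  expect_equal(rc$barc$mean, rep(-0.6 / 6, 12))
  expect_equal(rc$bprc$n, rep(4L, 12))
  # a block with target 120 deg but realised 95 deg lands in the 90 bin
  b2 <- mkblocks(95 * pi / 180, 1, 0, 1)
  b2$target_phase <- 120 * pi / 180
  rc2 <- bin_responses(b2)
  expect_equal(which(rc2$bprc$n == 1), 4L)  # centres 0, 30, 60, *90*
  # sinusoidal ground truth recovered at the bin centres
  phi3 <- runif(2400, 0, 2 * pi)
  b3 <- mkblocks(phi3, sin(phi3), 0, 1)
  rc3 <- bin_responses(b3)
  expect_equal(rc3$bprc$mean, sin(rc3$bprc$bin_center), tolerance = 0.02)
  # bin partition property
  expect_equal(sum(rc3$bprc$n), nrow(b3))
  # empty bins are NA, not zero
  b4 <- mkblocks(c(0.01, pi), c(1, 2), c(0, 0), 1)
  rc4 <- bin_responses(b4)
  expect_true(is.na(rc4$bprc$mean[4]))
  expect_error(bin_responses(mkblocks(1, 1, 1, 0)), "no usable blocks")
})

test_that("per-pulse normalisation makes the bPRC independent of pulses per burst", {
  g <- function(phi) -0.02 * sin(phi)
  rc4 <- extract_response_curves(make_injected_recording(
    g = g, proto = stim_protocol(pulses_per_burst = 4),
    n_trials = 96, noise = 0.05, seed = 3), band = c(3, 7))
  rc6 <- extract_response_curves(make_injected_recording(
    g = g, proto = stim_protocol(pulses_per_burst = 6),
    n_trials = 96, noise = 0.05, seed = 4), band = c(3, 7))
  a4 <- fit_cosine(rc4$bprc$bin_center, rc4$bprc$mean)$c2
  a6 <- fit_cosine(rc6$bprc$bin_center, rc6$bprc$mean)$c2
  expect_equal(a4, a6, tolerance = 0.25)
})

test_that("full extraction recovers an injected response curve shape", {
  inj <- make_injected_recording(g = function(phi) -0.01 * sin(phi),
                                 h = 0, n_trials = 144, noise = 0.1,
                                 seed = 7)
  rc <- extract_response_curves(inj, band = c(3, 7))
  expect_equal(sum(rc$bprc$n), sum(!rc$blocks$excluded))
  r <- cor(rc$bprc$mean, -sin(rc$bprc$bin_center))
  expect_gt(r, 0.9)
})
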