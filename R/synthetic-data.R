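#' Synthetic patient-like recording
#'
#' Wraps [run_block_experiment()] with the fitted parameter sets: the
#' excitatory-population activity E is exported as the tremor proxy
#' (tremor is modelled by the activity of the excitatory population; no
#' accelerometer transfer function is simulated), together with the
#' trigger channel and the block manifest.  By default 10 trials per
#' phase bin, mirroring the amount of patient data available per bin.
#'
#' @param patient patient id (1, 5, 6) or a [wc_params()] object.
#' @param proto a [stim_protocol()].
#' @param n_trials number of blocks (default `12 * trials_per_phase`).
#' @param dt integration step (s).
#' @param seed integer seed.
#' @param record_every trajectory thinning factor.
#' @return A `wc_recording` with manifest and ground-truth `params`.
#' @export
make_patient_recording <- function(patient, proto = stim_protocol(),
                                   n_trials = NULL, dt = 1e-3, seed = 1L,
                                   record_every = 1L) {
  p <- if (inherits(patient, "wc_params")) patient else patient_params(patient)
  rec <- run_block_experiment(p, proto, n_trials = n_trials, dt = dt,
                              seed = seed, record_every = record_every)
  rec$ground_truth <- list(kind = "wc_params", params = p)
  rec
}

#' Surrogate recording with injected per-pulse responses
#'
#' Phase-oscillator surrogate with known ground truth, independent of the
#' Wilson-Cowan model: a noisy ~5 Hz sinusoid whose phase advances by
#' `g(phi)` and whose log-amplitude shifts by `h(phi)` at each stimulation
#' pulse, `phi` being the true oscillator phase at the pulse.  Bursts are
#' delivered once per period at the block's target phase, in 5-s blocks
#' separated by 1-s gaps.  Injected log-amplitude shifts relax back with
#' time constant `tau_amp` so successive blocks stay comparable.
#'
#' @param g,h per-pulse phase-shift (rad) and log-amplitude-shift
#'   functions on `[0, 2*pi)`; numbers are promoted to constant functions.
#' @param proto a [stim_protocol()].
#' @param n_trials number of blocks.
#' @param noise standard deviation of additive white observation noise.
#' @param seed integer seed.
#' @param fs sampling rate (Hz).
#' @param f0 oscillator frequency (Hz).
#' @param tau_amp relaxation time of injected amplitude shifts (s).
#' @param lead_in stimulation-free lead-in (s).
#' @return A `wc_recording`-compatible bundle: channel `E`, `fs`,
#'   `pulses`, `bursts`, `manifest`, and a `ground_truth` list holding
#'   `g`, `h` and the per-pulse true phases.
#' @export
make_injected_recording <- function(g = 0, h = 0, proto = stim_protocol(),
                                    n_trials = 120L, noise = 0.1,
                                    seed = 1L, fs = 1000, f0 = 5,
                                    tau_amp = 2.5, lead_in = 2) {
  gf <- if (is.function(g)) g else function(phi) rep(g, length(phi))
  hf <- if (is.function(h)) h else function(phi) rep(h, length(phi))
  set.seed(seed)
  sched <- .block_schedule(proto, n_trials, lead_in)
  duration <- max(sched$t_end) + 0.5
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  dt <- 1 / fs

  # event generation: once per period at the target phase (true phase)
  max_p <- n_trials * ceiling(proto$block_duration * (f0 + 2)) *
    proto$pulses_per_burst
  pulse_t <- pulse_block <- pulse_burst <- numeric(max_p)
  pulse_gjump <- pulse_hjump <- pulse_phase <- numeric(max_p)
  max_b <- n_trials * ceiling(proto$block_duration * (f0 + 2))
  burst_t <- burst_block <- burst_np <- numeric(max_b)
  npulse <- 0L; nburst <- 0L
  phase_offset <- 2 * pi * runif(1)  # phase at t = 0
  cum_jump <- 0                      # accumulated injected phase
  for (b in seq_len(n_trials)) {
    t0 <- sched$t_start[b]; t1 <- sched$t_end[b]
    target <- sched$target_phase[b]
    # first crossing of the target phase after t0
    phi_t0 <- 2 * pi * f0 * t0 + phase_offset + cum_jump
    k <- ceiling((phi_t0 - target) / (2 * pi))
    t_burst <- (target + 2 * pi * k - phase_offset - cum_jump) / (2 * pi * f0)
    while (t_burst < t1) {
      nburst <- nburst + 1L
      np <- 0
      for (j in seq_len(proto$pulses_per_burst) - 1) {
        tp <- t_burst + j / proto$pulse_rate
        if (tp > t1) break
        phi_p <- (2 * pi * f0 * tp + phase_offset + cum_jump) %% (2 * pi)
        gj <- gf(phi_p); hj <- hf(phi_p)
        cum_jump <- cum_jump + gj
        npulse <- npulse + 1L
        pulse_t[npulse] <- tp; pulse_block[npulse] <- b
        pulse_burst[npulse] <- nburst
        pulse_gjump[npulse] <- gj; pulse_hjump[npulse] <- hj
        pulse_phase[npulse] <- phi_p
        np <- np + 1
      }
      burst_t[nburst] <- t_burst; burst_block[nburst] <- b
      burst_np[nburst] <- np
      # next crossing one full period later (phase jumps shift it)
      phi_now <- 2 * pi * f0 * t_burst + phase_offset + cum_jump
      k2 <- ceiling((phi_now - target) / (2 * pi) - 1e-9) + 1
      t_burst <- (target + 2 * pi * k2 - phase_offset - cum_jump) /
        (2 * pi * f0)
    }
  }
  keep_p <- seq_len(npulse); keep_b <- seq_len(nburst)
  pulse_t <- pulse_t[keep_p]; pulse_block <- pulse_block[keep_p]
  pulse_burst <- pulse_burst[keep_p]
  pulse_gjump <- pulse_gjump[keep_p]; pulse_hjump <- pulse_hjump[keep_p]
  pulse_phase <- pulse_phase[keep_p]
  burst_t <- burst_t[keep_b]; burst_block <- burst_block[keep_b]
  burst_np <- burst_np[keep_b]

  # sample-grid series: piecewise phase jumps and relaxing log-amplitude
  jump_series <- amp_series <- numeric(n)
  if (length(pulse_t)) {
    idx <- pmin(n, floor(pulse_t * fs) + 1)
    for (i in seq_along(idx)) {
      jump_series[idx[i]] <- jump_series[idx[i]] + pulse_gjump[i]
      amp_series[idx[i]] <- amp_series[idx[i]] + pulse_hjump[i]
    }
  }
  theta <- 2 * pi * f0 * tt + phase_offset + cumsum(jump_series)
  log_amp <- as.numeric(stats::filter(amp_series, exp(-dt / tau_amp),
                                      method = "recursive"))
  x <- exp(log_amp) * cos(theta) + rnorm(n, sd = noise)

  sched$n_pulses <- vapply(seq_len(n_trials), function(b) {
    sum(pulse_block == b)
  }, numeric(1))
  structure(list(
    time = tt, E = x, I = NULL, fs = fs, dt_sim = dt,
    pulses = data.frame(t = pulse_t, block = pulse_block,
                        burst = pulse_burst),
    bursts = data.frame(t = burst_t, block = burst_block,
                        n_pulses = burst_np),
    manifest = sched, protocol = proto, seed = seed,
    ground_truth = list(kind = "injected", g = gf, h = hf,
                        pulse_phase = pulse_phase, f0 = f0,
                        tau_amp = tau_amp)), class = "wc_recording")
}

#' Published per-dataset p-values of the two statistical tests
#'
#' The 24 printed p-values (Kruskal-Wallis ANOVA and cosine-model F-test,
#' for the bPRC and bARC of each of the six datasets), usable as a
#' fixture for the FDR machinery.
#'
#' @return Data frame with columns `dataset`, `curve`, `anova_p`, `f_p`.
#' @export
table1_pvalues <- function() {
  data.frame(
    dataset = rep(c("1", "3", "4R", "4L", "5", "6"), each = 2),
    curve = rep(c("bPRC", "bARC"), 6),
    anova_p = c(0.0113, 0.1733,
                0.1097, 0.1591,
                0.3463, 0.2064,
                0.2895, 0.0077,
                4.925e-04, 4.012e-06,
                4.815e-04, 0.0527),
    f_p = c(0.00993, 0.0365,
            0.448, 0.500,
            0.581, 0.057,
            0.352, 0.200,
            0.00906, 0.00142,
            0.0122, 0.0341))
}
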