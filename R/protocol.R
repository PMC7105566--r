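#' Phase-locked stimulation protocol
#'
#' Describes the experimental block design: 5-s stimulation blocks with a
#' 1-s stimulation-free gap before each block, 12 target phases, and one
#' burst of high-frequency pulses per tremor period at the target phase.
#'
#' @param n_phase_bins number of target phases (12 in the experiments).
#' @param block_duration stimulation block length (s).
#' @param gap_duration stimulation-free gap between blocks (s); the last
#'   second before each block is the reference period.
#' @param pulses_per_burst pulses in each burst (4-6 in the experiments).
#' @param pulse_rate intra-burst pulse rate (Hz, >= 130).
#' @param trials_per_phase nominal number of blocks per target phase.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(n_phase_bins = 12L, block_duration = 5,
                          gap_duration = 1, pulses_per_burst = 6L,
                          pulse_rate = 130, trials_per_phase = 10L) {
  stopifnot(block_duration > gap_duration, gap_duration > 0,
            pulses_per_burst %in% 4:6, pulse_rate >= 130,
            n_phase_bins >= 1, trials_per_phase >= 1)
  structure(list(n_phase_bins = as.integer(n_phase_bins),
                 block_duration = block_duration,
                 gap_duration = gap_duration,
                 pulses_per_burst = as.integer(pulses_per_burst),
                 pulse_rate = pulse_rate,
                 trials_per_phase = as.integer(trials_per_phase)),
            class = "stim_protocol")
}

#' Bin centres of the target-phase design
#'
#' Twelve equally spaced phases with centres at 0, 30, ..., 330 degrees.
#'
#' @param n_bins number of bins.
#' @return Bin centres in radians.
#' @export
phase_bin_centers <- function(n_bins = 12L) {
  2 * pi * (seq_len(n_bins) - 1) / n_bins
}

# Balanced, shuffled target-phase sequence and block window layout.
.block_schedule <- function(proto, n_trials, lead_in) {
  centers <- phase_bin_centers(proto$n_phase_bins)
  targets <- rep(centers, length.out = n_trials)
  targets <- sample(targets)   # balanced draw across the bins
  period <- proto$block_duration + proto$gap_duration
  t_start <- lead_in + proto$gap_duration + period * (seq_len(n_trials) - 1)
  data.frame(block = seq_len(n_trials),
             target_phase = targets,
             t_start = t_start,
             t_end = t_start + proto$block_duration)
}

#' Run a phase-locked block stimulation experiment
#'
#' Simulates alternating 1-s reference / 5-s stimulation segments with the
#' online zero-crossing phase tracker triggering at most one burst per
#' tremor period at the block's target phase.  Target phases are drawn to
#' balance the 12 bins.  Works for the full Wilson-Cowan model (`model` a
#' [wc_params()]) or for a linearised focus (`model` a
#' `focus_linearization`, with `zeta`, `delta_E` and `delta_t_stim`
#' supplied explicitly).
#'
#' @param model a [wc_params()] or [focus_linearization()] object.
#' @param proto a [stim_protocol()].
#' @param n_trials number of stimulation blocks; defaults to
#'   `n_phase_bins * trials_per_phase`.
#' @param dt integration step (s).
#' @param seed integer seed.
#' @param lead_in transient discarded before the first block (s).
#' @param record_every trajectory thinning factor.
#' @param zeta,delta_E,delta_t_stim only used when `model` is a
#'   linearisation (for a `wc_params` they are taken from the object).
#' @param init initial state; sensible defaults per model type.
#' @return A `wc_recording` whose `manifest` field holds the per-block
#'   table (block, target_phase, t_start, t_end, n_pulses).
#' @export
run_block_experiment <- function(model, proto = stim_protocol(),
                                 n_trials = NULL, dt = 1e-3, seed = NULL,
                                 lead_in = 5, record_every = 1L,
                                 zeta = NULL, delta_E = NULL,
                                 delta_t_stim = NULL, init = NULL) {
  stopifnot(inherits(proto, "stim_protocol"))
  if (is.null(n_trials)) n_trials <- proto$n_phase_bins * proto$trials_per_phase
  if (!is.null(seed)) set.seed(seed)
  sched <- .block_schedule(proto, n_trials, lead_in)
  duration <- max(sched$t_end) + 0.5

  if (inherits(model, "wc_params")) {
    if (is.null(init)) init <- c(0.5, 0.5)
    res <- cpp_simulate(
      model = 0L,
      wc = c(model$w_EE, model$w_EI, model$w_IE, model$theta_E,
             model$theta_I, model$beta, model$tau),
      J = diag(2), fixed_point = c(0, 0),
      zeta = model$zeta, delta_amp = model$delta_E,
      stim_delay = model$delta_t_stim,
      dt = dt, duration = duration,
      block_start = sched$t_start, block_end = sched$t_end,
      block_phase = sched$target_phase,
      pulses_per_burst = proto$pulses_per_burst,
      pulse_rate = proto$pulse_rate,
      ext_pulses = numeric(0), init = init,
      mean_window = 2, refractory = 0.05,
      record_every = as.integer(record_every))
    rec <- .as_recording(res, dt, record_every, params = model, seed = seed)
  } else if (inherits(model, "focus_linearization")) {
    stopifnot(!is.null(zeta), !is.null(delta_E), !is.null(delta_t_stim))
    if (is.null(init)) init <- model$fixed_point
    res <- cpp_simulate(
      model = 1L, wc = numeric(7),
      J = model$J, fixed_point = model$fixed_point,
      zeta = zeta, delta_amp = delta_E, stim_delay = delta_t_stim,
      dt = dt, duration = duration,
      block_start = sched$t_start, block_end = sched$t_end,
      block_phase = sched$target_phase,
      pulses_per_burst = proto$pulses_per_burst,
      pulse_rate = proto$pulse_rate,
      ext_pulses = numeric(0), init = init,
      mean_window = 2, refractory = 0.05,
      record_every = as.integer(record_every))
    rec <- .as_recording(res, dt, record_every, seed = seed)
  } else {
    stop("`model` must be a wc_params or focus_linearization object")
  }

  n_pulses <- vapply(seq_len(n_trials), function(b) {
    sum(rec$pulses$block == b)
  }, integer(1))
  sched$n_pulses <- n_pulses
  rec$manifest <- sched
  rec$protocol <- proto
  rec
}

#' Track phase online with the zero-crossing scheme
#'
#' Applies the simulator's live phase estimator to an arbitrary sampled
#' signal: phase 0 is assigned at upward crossings of the signal minus its
#' running mean, and the phase advances linearly at `2*pi / previous
#' period`.  The estimate is `NA` until two crossings have been observed.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param mean_window running-mean window (s).
#' @param refractory minimum spacing between accepted crossings (s).
#' @return List with `phase` (radians, possibly exceeding `2*pi` within a
#'   period) and `crossings` (times of accepted upward crossings, s).
#' @export
track_phase_online <- function(x, fs, mean_window = 2, refractory = 0.05) {
  stopifnot(fs > 0, length(x) > 2)
  cpp_track_phase(as.numeric(x), 1 / fs, mean_window, refractory)
}

#' Write / read a recording bundle as delimited text
#'
#' The recording is stored as a tab-separated table with columns `time_s`,
#' `E` (or the acceleration-like channel), `I` (if present) and `trigger`
#' (0/1 pulse indicator), together with a block-manifest table.
#'
#' @param rec a `wc_recording` (or compatible bundle with `time`, channel,
#'   `pulses` and `manifest`).
#' @param path_signal,path_manifest output file paths.
#' @return `write_recording()` invisibly returns the file paths;
#'   `read_recording()` returns a list with `signal` and `manifest`
#'   data frames.
#' @export
write_recording <- function(rec, path_signal, path_manifest) {
  idx <- pmin(length(rec$time), pmax(1, round(rec$pulses$t * rec$fs) + 1))
  trig <- tabulate(idx, nbins = length(rec$time))
  sig <- data.frame(time_s = rec$time, E = rec$E, trigger = trig)
  if (!is.null(rec$I)) sig$I <- rec$I
  write.table(sig, path_signal, sep = "\t", row.names = FALSE,
              quote = FALSE)
  man <- rec$manifest
  man$target_phase_deg <- man$target_phase * 180 / pi
  write.table(man, path_manifest, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(path_signal, path_manifest))
}

#' @rdname write_recording
#' @export
read_recording <- function(path_signal, path_manifest) {
  list(signal = read.table(path_signal, header = TRUE, sep = "\t"),
       manifest = read.table(path_manifest, header = TRUE, sep = "\t"))
}
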