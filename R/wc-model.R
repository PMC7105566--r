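#' Wilson-Cowan model parameters
#'
#' Bundles the ten quantities describing the stochastic two-population
#' Wilson-Cowan tremor model and its phase-locked stimulation: synaptic
#' weights, constant inputs, sigmoid steepness, time constant, noise
#' standard deviation, per-pulse stimulation magnitude, and the delay
#' between the stimulation trigger and the actual delivery of stimulation
#' to the excitatory population.
#'
#' The deterministic drift is
#' \deqn{F_1 = (-E + f(\theta_E + w_{EE} E - w_{IE} I))/\tau, \quad
#'       F_2 = (-I + f(\theta_I + w_{EI} E))/\tau,}
#' with sigmoid \eqn{f(x) = 1/(1 + e^{-\beta(x-1)})}; Gaussian white noise
#' of standard deviation `zeta` is added to both populations.
#'
#' @param w_EE,w_EI,w_IE dimensionless synaptic weights (`w_PR` is the
#'   weight of the projection from population P to population R).
#' @param theta_E,theta_I dimensionless constant inputs.
#' @param beta sigmoid steepness (> 0).
#' @param tau time constant in seconds (> 0).
#' @param zeta noise standard deviation (>= 0).
#' @param delta_E stimulation magnitude added to E per pulse (>= 0).
#' @param delta_t_stim stimulation delay in seconds (>= 0).
#' @return An object of class `wc_params`.
#' @seealso [patient_params()] for the fitted parameter sets.
#' @export
wc_params <- function(w_EE, w_EI, w_IE, theta_E, theta_I, beta, tau, zeta,
                      delta_E = 0, delta_t_stim = 0) {
  stopifnot(tau > 0, beta > 0, zeta >= 0, delta_E >= 0, delta_t_stim >= 0)
  p <- list(w_EE = w_EE, w_EI = w_EI, w_IE = w_IE,
            theta_E = theta_E, theta_I = theta_I,
            beta = beta, tau = tau, zeta = zeta,
            delta_E = delta_E, delta_t_stim = delta_t_stim)
  stopifnot(all(vapply(p, is.finite, logical(1))))
  structure(p, class = "wc_params")
}

#' Best-fit parameter sets for the three selected patients
#'
#' Returns the published best-fit Wilson-Cowan parameters for the datasets
#' whose response curves pass the significance criterion (patients 1, 5
#' and 6).  Stimulation delay is stored in seconds.
#'
#' @param id patient identifier: 1, 5 or 6.
#' @return A [wc_params()] object.
#' @export
patient_params <- function(id) {
  tab <- list(
    `1` = wc_params(w_EE = 6.7541,  w_EI = 9.6306,  w_IE = 9.4014,
                    theta_E = 1.42402, theta_I = -3.2345,
                    beta = 1.1853, tau = 0.0758, zeta = 0.0457,
                    delta_E = 0.001684, delta_t_stim = 0.1388366),
    `5` = wc_params(w_EE = 1.548,   w_EI = 25.3384, w_IE = 26.048,
                    theta_E = 22.8621, theta_I = -9.9279,
                    beta = 2.4234, tau = 0.29984, zeta = 0.013707,
                    delta_E = 0.00598, delta_t_stim = 0.4441573),
    `6` = wc_params(w_EE = 2.7514,  w_EI = 24.4813, w_IE = 5.2064,
                    theta_E = 2.9127, theta_I = -3.4008,
                    beta = 4.1933, tau = 0.2513, zeta = 0.0263,
                    delta_E = 0.001686, delta_t_stim = 0.1834711))
  key <- as.character(id)
  if (!key %in% names(tab)) {
    stop("no fitted parameter set for patient ", id,
         " (available: 1, 5, 6)")
  }
  tab[[key]]
}

#' @export
print.wc_params <- function(x, ...) {
  cat("Wilson-Cowan parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Sigmoid activation function
#'
#' `f(x) = 1 / (1 + exp(-beta * (x - 1)))`, strictly increasing with values
#' in (0, 1).  `wc_sigmoid_deriv()` is its derivative in `x`.
#'
#' @param x input (any real).
#' @param beta steepness parameter (> 0).
#' @return Rate in (0, 1) (or its derivative).
#' @export
wc_sigmoid <- function(x, beta) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * (x - 1)))
}

#' @rdname wc_sigmoid
#' @export
wc_sigmoid_deriv <- function(x, beta) {
  s <- wc_sigmoid(x, beta)
  beta * s * (1 - s)
}

#' Deterministic drift of the Wilson-Cowan model
#'
#' @param E,I population activities (rates).
#' @param p a [wc_params()] object.
#' @return Named vector `c(F1, F2)` in rate/s.
#' @export
wc_drift <- function(E, I, p) {
  f1 <- (-E + wc_sigmoid(p$theta_E + p$w_EE * E - p$w_IE * I, p$beta)) / p$tau
  f2 <- (-I + wc_sigmoid(p$theta_I + p$w_EI * E, p$beta)) / p$tau
  c(F1 = f1, F2 = f2)
}

.as_recording <- function(res, dt, record_every, params = NULL, seed = NULL) {
  if (isTRUE(res$failed)) {
    stop("simulation diverged to a non-finite state at t = ",
         signif(res$fail_t, 4), " s")
  }
  structure(list(
    time = res$time, E = res$E, I = res$I,
    tracked_phase = res$tracked_phase,
    fs = 1 / (dt * record_every), dt_sim = dt,
    pulses = data.frame(t = res$pulse_t,
                        block = res$pulse_block + 1L,
                        burst = res$pulse_burst + 1L),
    bursts = data.frame(t = res$burst_t,
                        block = res$burst_block + 1L,
                        n_pulses = res$burst_npulses),
    crossings = res$crossings,
    params = params, seed = seed), class = "wc_recording")
}

#' @export
print.wc_recording <- function(x, ...) {
  cat(sprintf(
    "Simulated recording: %.1f s at fs = %g Hz, %d pulses, %d bursts\n",
    max(x$time), x$fs, nrow(x$pulses), nrow(x$bursts)))
  invisible(x)
}

#' Simulate the stochastic Wilson-Cowan model
#'
#' Euler-Maruyama integration of the two-population model.  Optional
#' open-loop stimulation adds `delta_E` to E in the update at each of the
#' given pulse times.  With the same seed, dt and parameters the trajectory
#' is reproducible exactly.
#'
#' @param p a [wc_params()] object.
#' @param duration simulated time (s).
#' @param dt integration time step (s).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param stim_times optional numeric vector of pulse application times (s).
#' @param init initial state `c(E, I)`; defaults to `c(0.5, 0.5)`.
#' @param record_every keep every `record_every`-th sample of the
#'   trajectory (the integration always runs at `dt`).
#' @param mean_window running-mean window (s) used to mean-reference E
#'   before zero-crossing detection.
#' @return A `wc_recording` with fields `time`, `E`, `I`, `tracked_phase`,
#'   `pulses`, `bursts`, `crossings`, `fs`.
#' @export
simulate_wc <- function(p, duration, dt = 1e-3, seed = NULL,
                        stim_times = numeric(0), init = c(0.5, 0.5),
                        record_every = 1L, mean_window = 2) {
  stopifnot(inherits(p, "wc_params"), dt > 0, duration > 10 * dt)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate(
    model = 0L,
    wc = c(p$w_EE, p$w_EI, p$w_IE, p$theta_E, p$theta_I, p$beta, p$tau),
    J = diag(2), fixed_point = c(0, 0),
    zeta = p$zeta, delta_amp = p$delta_E, stim_delay = p$delta_t_stim,
    dt = dt, duration = duration,
    block_start = numeric(0), block_end = numeric(0),
    block_phase = numeric(0),
    pulses_per_burst = 0L, pulse_rate = 130,
    ext_pulses = sort(stim_times), init = init,
    mean_window = mean_window, refractory = 0.05,
    record_every = as.integer(record_every))
  .as_recording(res, dt, record_every, params = p, seed = seed)
}

#' Simulate the linearised focus model
#'
#' Euler-Maruyama integration of
#' \eqn{dX = J (X - X^*) dt + \zeta dW}, the linearisation of the
#' Wilson-Cowan model about a fixed point, with the same closed-loop
#' stimulation machinery as [simulate_wc()].
#'
#' @param lin a `focus_linearization` (see [focus_linearization()]).
#' @param zeta noise standard deviation.
#' @param duration,dt,seed,init,record_every,mean_window as in
#'   [simulate_wc()].
#' @param delta_E,delta_t_stim stimulation magnitude and delay.
#' @param stim_times optional open-loop pulse times (s).
#' @return A `wc_recording`.
#' @export
simulate_linearized <- function(lin, zeta, duration, dt = 1e-3, seed = NULL,
                                stim_times = numeric(0), init = NULL,
                                delta_E = 0, delta_t_stim = 0,
                                record_every = 1L, mean_window = 2) {
  stopifnot(inherits(lin, "focus_linearization"), dt > 0)
  if (is.null(init)) init <- lin$fixed_point
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate(
    model = 1L, wc = numeric(7),
    J = lin$J, fixed_point = lin$fixed_point,
    zeta = zeta, delta_amp = delta_E, stim_delay = delta_t_stim,
    dt = dt, duration = duration,
    block_start = numeric(0), block_end = numeric(0),
    block_phase = numeric(0),
    pulses_per_burst = 0L, pulse_rate = 130,
    ext_pulses = sort(stim_times), init = init,
    mean_window = mean_window, refractory = 0.05,
    record_every = as.integer(record_every))
  .as_recording(res, dt, record_every, seed = seed)
}

#' Classify the noise-free regime of a parameter set
#'
#' Forward-simulates the deterministic model from a state visited by the
#' noisy system, and labels the asymptotic behaviour as a stable focus
#' (oscillations decay towards the fixed point) or a limit cycle
#' (oscillations persist at a stationary amplitude).
#'
#' @param p a [wc_params()] object.
#' @param dt integration step (s); the default stays inside the explicit
#'   Euler stability region of lightly damped foci
#'   (`dt < 2|sigma|/(sigma^2+omega^2)`).
#' @param t_noisy length of the preliminary noisy run used to pick a
#'   starting state inside the region the stochastic system occupies.
#' @param t_free length of the deterministic run.
#' @param tol amplitude (in E units) below which oscillations are
#'   considered decayed.
#' @param seed seed for the preliminary noisy run.
#' @return One of `"stable_focus"`, `"limit_cycle"`, `"unclassified"`,
#'   with attribute `amplitude` (the asymptotic E oscillation amplitude).
#' @export
classify_regime <- function(p, dt = 2.5e-4, t_noisy = 10, t_free = 40,
                            tol = 1e-5, seed = 1L) {
  noisy <- simulate_wc(p, duration = t_noisy, dt = dt, seed = seed)
  n <- length(noisy$E)
  start <- c(noisy$E[n], noisy$I[n])
  pf <- p; pf$zeta <- 0
  free <- simulate_wc(pf, duration = t_free, dt = dt, init = start)
  m <- length(free$E)
  win <- function(frac_lo, frac_hi) {
    idx <- seq(floor(m * frac_lo) + 1, floor(m * frac_hi))
    e <- free$E[idx]
    (max(e) - min(e)) / 2
  }
  amp_last <- win(0.8, 1.0)
  amp_prev <- win(0.6, 0.8)
  label <- if (amp_last < tol) {
    "stable_focus"
  } else if (amp_last > 100 * tol &&
             abs(amp_last - amp_prev) < 0.05 * amp_last) {
    "limit_cycle"
  } else {
    "unclassified"
  }
  structure(label, amplitude = amp_last)
}
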