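#' Band-pass filter and z-score a tremor signal
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass
#' followed by z-scoring, as used on the accelerometer recordings: a 4-Hz
#' band encompassing the tremor frequency content avoids phase distortion
#' of the Hilbert phase.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param band numeric length-2, band edges (Hz); must lie inside
#'   `(0, fs/2)`.
#' @return An object of class `processed_signal`: list with z-scored
#'   `samples`, `fs` and `band`.
#' @export
preprocess <- function(x, fs, band) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  if (band[2] >= 0.95 * fs / 2) {
    stop("upper band edge too close to the Nyquist frequency")
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y <- (y - mean(y)) / sd(y)
  structure(list(samples = y, fs = fs, band = band),
            class = "processed_signal")
}

#' Analytic signal: Hilbert phase and envelope
#'
#' Computes the analytic signal `x + i H(x)` by FFT half-spectrum
#' doubling, and returns the unwrapped Hilbert phase and the Hilbert
#' envelope (modulus).  Intended for narrow-band inputs.
#'
#' @param x a `processed_signal` or plain numeric vector.
#' @return List with `phase` (unwrapped, rad), `wrapped_phase` in
#'   `[-pi, pi)`, `envelope` (>= 0) and the complex `analytic` series.
#' @export
analytic_signal <- function(x) {
  s <- if (inherits(x, "processed_signal")) x$samples else as.numeric(x)
  n <- length(s)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- fft(fft(s) * h, inverse = TRUE) / n
  wrapped <- Arg(a)
  list(phase = .unwrap(wrapped), wrapped_phase = wrapped,
       envelope = Mod(a), analytic = a)
}

.unwrap <- function(phi) {
  d <- diff(phi)
  jumps <- round(d / (2 * pi))
  phi - c(0, cumsum(jumps)) * 2 * pi
}

#' Circular mean of angles
#'
#' `atan2(mean(sin), mean(cos))`, reported in `[0, 2*pi)`.  The attribute
#' `resultant` carries the mean resultant length; values near zero mean
#' the angles carry no common direction.
#'
#' @param theta angles in radians.
#' @return Circular mean in `[0, 2*pi)` with attribute `resultant`.
#' @export
circ_mean <- function(theta) {
  s <- mean(sin(theta)); c <- mean(cos(theta))
  structure(atan2(s, c) %% (2 * pi), resultant = sqrt(s^2 + c^2))
}

#' Per-block phase response
#'
#' Fits a least-squares line to the unwrapped Hilbert phase over the 1-s
#' reference period before the block, and returns the difference between
#' the actual phase at the end of the block and the reference line
#' extrapolated to the block end.  The result is not wrapped, so changes
#' beyond +/- pi are representable.
#'
#' @param t_ref,phi_ref times and unwrapped phases over the reference
#'   window (>= 0.5 s of data required).
#' @param t_end block end time (s).
#' @param phi_end unwrapped phase at the block end.
#' @return `delta_phi` in radians, with attributes `slope` and
#'   `intercept` of the reference line.
#' @export
block_phase_response <- function(t_ref, phi_ref, t_end, phi_end) {
  if (length(t_ref) < 2 || diff(range(t_ref)) < 0.5) {
    stop("reference window shorter than 0.5 s")
  }
  # closed-form least-squares line
  mt <- mean(t_ref); mp <- mean(phi_ref)
  slope <- sum((t_ref - mt) * (phi_ref - mp)) / sum((t_ref - mt)^2)
  intercept <- mp - slope * mt
  structure(phi_end - (intercept + slope * t_end),
            slope = slope, intercept = intercept)
}

#' Per-block amplitude response
#'
#' Difference between the mean Hilbert envelope over the last second of
#' the block and the mean envelope over the 1-s reference period.
#'
#' @param env_ref envelope samples over the reference window.
#' @param env_stim_last envelope samples over the last second of the block.
#' @return `delta_env` in z-units.
#' @export
block_amp_response <- function(env_ref, env_stim_last) {
  if (length(env_ref) < 2 || length(env_stim_last) < 2) {
    stop("reference window shorter than 0.5 s")
  }
  mean(env_stim_last) - mean(env_ref)
}

#' Realised stimulation phase of a block
#'
#' Two-level circular mean: first the circular mean of the Hilbert phase
#' during each burst, then the circular mean of the burst angles.  Blocks
#' whose burst angles have near-zero resultant are flagged as
#' phase-ambiguous.
#'
#' @param burst_phases list of numeric vectors, the Hilbert phase samples
#'   during each burst of the block.
#' @param min_resultant blocks with block-level mean resultant below this
#'   are flagged.
#' @return Phase in `[0, 2*pi)`; attribute `ambiguous` is `TRUE` when the
#'   resultant vector length is near zero.
#' @export
realized_stim_phase <- function(burst_phases, min_resultant = 0.1) {
  stopifnot(length(burst_phases) >= 1)
  angles <- vapply(burst_phases, function(ph) as.numeric(circ_mean(ph)),
                   numeric(1))
  m <- circ_mean(angles)
  structure(as.numeric(m),
            ambiguous = attr(m, "resultant") < min_resultant)
}

#' Bin per-block responses into response curves
#'
#' Assigns each block to one of `n_bins` half-open phase bins (centres at
#' 0, 30, ..., 330 degrees) according to its realised stimulation phase,
#' and averages the per-pulse responses within bins.  Each block's
#' response is normalised by its own delivered pulse count before
#' averaging, which reduces to the constant-`n_pulses` convention when all
#' blocks deliver the same number of pulses.  Empty bins are reported as
#' `NA`, not zero.
#'
#' @param blocks data frame with columns `Phi_stim`, `delta_phi`,
#'   `delta_env`, `n_pulses` and logical `excluded`.
#' @param n_bins number of phase bins.
#' @return List with two `response_curve` objects `bprc` (rad/pulse) and
#'   `barc` (z-units/pulse); each has `bin_center`, `mean`, `sem`, `n` and
#'   the per-bin sample lists.
#' @export
bin_responses <- function(blocks, n_bins = 12L) {
  use <- !blocks$excluded & blocks$n_pulses > 0
  if (!any(use)) stop("no usable blocks: all bins empty")
  b <- blocks[use, ]
  centers <- phase_bin_centers(n_bins)
  half <- pi / n_bins
  idx <- floor(((b$Phi_stim + half) %% (2 * pi)) / (2 * half)) + 1
  idx[idx > n_bins] <- 1L
  mk <- function(values) {
    per_pulse <- values / b$n_pulses
    samples <- split(per_pulse, factor(idx, levels = seq_len(n_bins)))
    n <- vapply(samples, length, integer(1))
    mu <- vapply(samples, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
    sem <- vapply(samples, function(v) {
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1))
    structure(list(bin_center = centers, mean = unname(mu),
                   sem = unname(sem), n = unname(n),
                   samples = samples), class = "response_curve")
  }
  bprc <- mk(b$delta_phi); bprc$kind <- "bPRC"
  barc <- mk(b$delta_env); barc$kind <- "bARC"
  list(bprc = bprc, barc = barc)
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("%s over %d phase bins (%d blocks)\n", x$kind,
              length(x$bin_center), sum(x$n)))
  print(data.frame(bin_deg = round(x$bin_center * 180 / pi),
                   mean = signif(x$mean, 4), sem = signif(x$sem, 3),
                   n = x$n))
  invisible(x)
}

#' Extract block-method response curves from a recording
#'
#' The full block method: band-pass filter and z-score the tremor channel,
#' take the Hilbert phase and envelope, compute per-block phase and
#' amplitude responses and the realised stimulation phase, and bin into
#' 12-bin bPRC/bARC normalised per pulse.
#'
#' @param rec a `wc_recording` (from [run_block_experiment()] or a
#'   synthetic-data generator) with a `manifest`; or any list with
#'   `E`-like channel given via `channel`.
#' @param band band edges (Hz); `NULL` picks a 4-Hz band centred on the
#'   spectral peak of the signal.
#' @param n_bins number of phase bins.
#' @param edge_trim seconds excluded at each end of the recording from the
#'   envelope/phase means (Hilbert edge effects).
#' @param channel name of the tremor channel in `rec` (default "E").
#' @return List of class `rc_extraction` with the per-block table
#'   `blocks`, curves `bprc` and `barc`, the band used, and the number of
#'   excluded blocks.
#' @export
extract_response_curves <- function(rec, band = NULL, n_bins = 12L,
                                    edge_trim = 0.25, channel = "E") {
  man <- rec$manifest
  stopifnot(!is.null(man), nrow(man) >= 1)
  x <- rec[[channel]]
  fs <- rec$fs
  if (is.null(band)) {
    pk <- .psd_peak(x, fs)
    band <- c(pk - 2, pk + 2)
    if (band[1] <= 0) band <- c(0.5, 4.5)
  }
  ps <- preprocess(x, fs, band)
  an <- analytic_signal(ps)
  tt <- rec$time
  n <- length(tt)
  t_ok <- c(tt[1] + edge_trim, tt[n] - edge_trim)
  iof <- function(t) pmin(n, pmax(1, round((t - tt[1]) * fs) + 1))
  pulse_split <- split(rec$pulses$t, rec$pulses$burst)
  burst_of_block <- split(seq_len(nrow(rec$bursts)),
                          factor(rec$bursts$block,
                                 levels = seq_len(nrow(man))))

  rows <- lapply(seq_len(nrow(man)), function(k) {
    t0 <- man$t_start[k]; t1 <- man$t_end[k]
    ref_i <- iof(max(t0 - 1, t_ok[1])):(iof(t0) - 1)
    end_i <- iof(min(t1, t_ok[2]))
    last_i <- iof(t1 - 1):(iof(t1) - 1)
    dphi <- tryCatch(
      as.numeric(block_phase_response(tt[ref_i], an$phase[ref_i],
                                      tt[end_i], an$phase[end_i])),
      error = function(e) NA_real_)
    denv <- tryCatch(
      block_amp_response(an$envelope[ref_i], an$envelope[last_i]),
      error = function(e) NA_real_)
    bursts_k <- burst_of_block[[k]]
    bursts_k <- bursts_k[rec$bursts$n_pulses[bursts_k] > 0]
    phi_stim <- NA_real_; ambiguous <- TRUE
    if (length(bursts_k) > 0) {
      bp <- lapply(bursts_k, function(j) {
        span <- range(pulse_split[[as.character(j)]])
        an$wrapped_phase[iof(span[1]):iof(span[2])]
      })
      ph <- realized_stim_phase(bp)
      phi_stim <- as.numeric(ph); ambiguous <- isTRUE(attr(ph, "ambiguous"))
    }
    list(block = man$block[k], target_phase = man$target_phase[k],
         t_start = t0, t_end = t1,
         delta_phi = dphi, delta_env = denv,
         Phi_stim = phi_stim, n_pulses = man$n_pulses[k],
         excluded = ambiguous || !is.finite(dphi) || !is.finite(denv) ||
           !is.finite(phi_stim))
  })
  blocks <- do.call(rbind, lapply(rows, as.data.frame))
  curves <- bin_responses(blocks, n_bins = n_bins)
  structure(list(blocks = blocks, bprc = curves$bprc, barc = curves$barc,
                 band = band, n_excluded = sum(blocks$excluded)),
            class = "rc_extraction")
}

# dominant spectral frequency, used to centre the default filter band
.psd_peak <- function(x, fs, fmin = 1) {
  ps <- welch_psd(x, fs, seg_len = min(length(x), round(4 * fs)))
  sel <- ps$freq >= fmin
  ps$freq[sel][which.max(ps$psd[sel])]
}
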