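#' Power spectral density by averaged modified periodograms
#'
#' Welch-style estimate: the signal is split into Hann-windowed segments
#' with 50% overlap and the periodograms are averaged.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param seg_len segment length in samples (default 2-s segments).
#' @param overlap fractional overlap between segments.
#' @param fmax keep frequencies up to `fmax` (Hz); `NULL` keeps all.
#' @return Data frame with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = round(2 * fs), overlap = 0.5,
                      fmax = NULL) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / scale
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything but DC (and Nyquist when present)
  psd[-1] <- 2 * psd[-1]
  if (seg_len %% 2 == 0) psd[nf] <- psd[nf] / 2
  freq <- (seq_len(nf) - 1) * fs / seg_len
  out <- data.frame(freq = freq, psd = psd)
  if (!is.null(fmax)) out <- out[out$freq <= fmax + 1e-9, ]
  out
}

#' Feature-extraction configuration
#'
#' Grids and trial counts for the four fitted features: tremor PSD
#' (0-20 Hz), Hilbert-envelope PDF (40 bins over the data range),
#' envelope PSD (0-4 Hz), and the block-method bPRC on 12 bins.
#'
#' @param psd_fmax,env_psd_fmax upper frequency limits (Hz).
#' @param pdf_bins number of envelope-PDF bins.
#' @param n_trials_features trials' worth of signal used for the
#'   dynamical features.
#' @param n_trials_bprc stimulation blocks used for the model bPRC.
#' @param seg_len_s periodogram segment length (s).
#' @return List of class `feature_config`.
#' @export
feature_config <- function(psd_fmax = 20, env_psd_fmax = 4, pdf_bins = 40L,
                           n_trials_features = 9L, n_trials_bprc = 60L,
                           seg_len_s = 2) {
  structure(list(psd_fmax = psd_fmax, env_psd_fmax = env_psd_fmax,
                 pdf_bins = as.integer(pdf_bins),
                 n_trials_features = as.integer(n_trials_features),
                 n_trials_bprc = as.integer(n_trials_bprc),
                 seg_len_s = seg_len_s), class = "feature_config")
}

#' Compute the four fitted features from a tremor signal
#'
#' PSD of the z-scored signal, envelope PDF, envelope PSD and (if a block
#' manifest is available) the bPRC.  For recorded (accelerometer-like)
#' data the signal is band-pass filtered before the envelope features; for
#' model output the raw z-scored signal is used (`filter_dynamics =
#' FALSE`), so the model is forced to generate the tremor band itself.
#'
#' @param x numeric tremor signal (or a `wc_recording`, in which case the
#'   E channel and the manifest are used).
#' @param fs sampling rate (Hz); taken from the recording if `x` is one.
#' @param cfg a [feature_config()].
#' @param filter_dynamics band-pass the signal before envelope features?
#' @param band band to use when filtering (and for the bPRC); `NULL`
#'   centres a 4-Hz band on the PSD peak.
#' @param pdf_range envelope range for the PDF grid; `NULL` uses the
#'   observed range.  Pass the data feature set's range when computing
#'   model features so the grids match.
#' @param bprc optionally, a precomputed `response_curve`.
#' @return List of class `feature_set` with elements `psd`, `env_pdf`,
#'   `env_psd`, `bprc` (each a list with `grid` and `y`).
#' @export
compute_features <- function(x, fs = NULL, cfg = feature_config(),
                             filter_dynamics = FALSE, band = NULL,
                             pdf_range = NULL, bprc = NULL) {
  rec <- NULL
  if (inherits(x, "wc_recording")) {
    rec <- x
    fs <- rec$fs
    x <- rec$E
  }
  stopifnot(!is.null(fs))
  if (length(x) < 4 * fs) stop("recording too short for feature extraction")
  z <- (x - mean(x)) / sd(x)
  psd <- welch_psd(z, fs, seg_len = round(cfg$seg_len_s * fs),
                   fmax = cfg$psd_fmax)
  if (is.null(band)) {
    pk <- psd$freq[which.max(psd$psd * (psd$freq >= 1))]
    band <- c(max(pk - 2, 0.5), pk + 2)
  }
  zd <- if (filter_dynamics) preprocess(x, fs, band)$samples else z
  env <- analytic_signal(zd)$envelope
  trim <- round(0.25 * fs)
  env_i <- env[(trim + 1):(length(env) - trim)]
  if (is.null(pdf_range)) pdf_range <- range(env_i)
  brks <- seq(pdf_range[1], pdf_range[2], length.out = cfg$pdf_bins + 1)
  cnt <- tabulate(findInterval(env_i, brks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = cfg$pdf_bins)
  dens <- cnt / (sum(cnt) * diff(brks)[1])
  env_psd <- welch_psd(env_i - mean(env_i), fs,
                       seg_len = round(4 * cfg$seg_len_s * fs),
                       fmax = cfg$env_psd_fmax)
  if (is.null(bprc) && !is.null(rec) && !is.null(rec$manifest)) {
    bprc <- extract_response_curves(rec, band = band)$bprc
  }
  structure(list(
    psd = list(grid = psd$freq, y = psd$psd),
    env_pdf = list(grid = (brks[-1] + brks[-length(brks)]) / 2, y = dens,
                   range = pdf_range),
    env_psd = list(grid = env_psd$freq, y = env_psd$psd),
    bprc = if (!is.null(bprc)) list(grid = bprc$bin_center, y = bprc$mean),
    band = band), class = "feature_set")
}

#' Normalised model-data discrepancy
#'
#' The cost averages, over the four features, the sum of squared
#' differences normalised by the data feature's total sum of squares
#' about its own mean:
#' \deqn{c = \frac14 \sum_n \frac{\sum_i (y^{data}_{n,i} - y^{model}_{n,i})^2}
#'   {\sum_i (y^{data}_{n,i} - \bar y^{data}_n)^2}.}
#' A perfect fit gives `c = 0` (`R^2 = 1 - c = 1`); a model that merely
#' reproduces each data-feature mean gives `c = 1`.
#'
#' @param data,model `feature_set` objects on identical grids.
#' @return The cost `c`.
#' @export
feature_cost <- function(data, model) {
  keys <- c("psd", "env_pdf", "env_psd", "bprc")
  terms <- vapply(keys, function(k) {
    yd <- data[[k]]$y; ym <- model[[k]]$y
    if (is.null(yd) || is.null(ym)) stop("feature '", k, "' missing")
    if (length(yd) != length(ym)) stop("feature '", k, "' grids differ")
    keep <- is.finite(yd) & is.finite(ym)
    yd <- yd[keep]; ym <- ym[keep]
    denom <- sum((yd - mean(yd))^2)
    if (denom == 0) stop("zero-variance data feature '", k, "'")
    sum((yd - ym)^2) / denom
  }, numeric(1))
  mean(terms)
}

#' Generalized pattern search
#'
#' Derivative-free coordinate-poll minimisation: from the incumbent,
#' objective values are polled at `+/- mesh * scale` along each parameter;
#' the first improving move is accepted and the mesh expanded, otherwise
#' the mesh is contracted.  Objective evaluations returning `NA`/`Inf`
#' (failed simulations) are treated as `+Inf` and routed around.
#'
#' @param fn objective function of a numeric vector.
#' @param x0 start point.
#' @param lower,upper bounds (finite).
#' @param mesh0 initial mesh size as a fraction of the parameter range.
#' @param budget maximum number of objective evaluations.
#' @param mesh_tol stop when the mesh falls below this fraction.
#' @param expand,shrink mesh update factors.
#' @param target stop early once the objective falls at or below this.
#' @return List with `par`, `value`, `evals`, `mesh`.
#' @export
pattern_search <- function(fn, x0, lower, upper, mesh0 = 0.25,
                           budget = 200L, mesh_tol = 1e-4,
                           expand = 2, shrink = 0.5, target = NULL) {
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower), length(x0) == length(lower))
  scale <- upper - lower
  clamp <- function(x) pmin(pmax(x, lower), upper)
  evals <- 0L
  f <- function(x) {
    evals <<- evals + 1L
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  x <- clamp(x0); fx <- f(x)
  mesh <- mesh0
  d <- length(x)
  done <- function() !is.null(target) && fx <= target
  while (evals < budget && mesh > mesh_tol && !done()) {
    improved <- FALSE
    for (i in sample(d)) {
      for (s in c(1, -1)) {
        if (evals >= budget) break
        xt <- x; xt[i] <- xt[i] + s * mesh * scale[i]
        xt <- clamp(xt)
        if (all(xt == x)) next
        ft <- f(xt)
        if (ft < fx) {
          x <- xt; fx <- ft; improved <- TRUE
          break
        }
      }
      if (improved || evals >= budget || done()) break
    }
    mesh <- if (improved) min(mesh * expand, mesh0) else mesh * shrink
  }
  list(par = x, value = fx, evals = evals, mesh = mesh)
}

#' Mean frequency of a signal
#'
#' Number of upward crossings of the mean-subtracted signal per second
#' (minus one crossing, over the recorded span).
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @return Mean frequency (Hz).
#' @export
mean_frequency <- function(x, fs) {
  y <- x - mean(x)
  up <- which(y[-length(y)] < 0 & y[-1] >= 0)
  max(length(up) - 1, 0) / (length(x) / fs)
}

#' Model effective stimulation per unit time
#'
#' \eqn{\Xi = (\delta E / E_\sigma) \bar f_E}: the fitted per-pulse
#' stimulation magnitude scaled by the standard deviation of the raw
#' (non-z-scored) E trace, times the mean frequency of E.  A model-side
#' surrogate for the electrical energy delivered per unit time under
#' once-per-period burst stimulation.
#'
#' @param p a [wc_params()] object (supplies `delta_E`).
#' @param rec a `wc_recording` of the model without z-scoring.
#' @return Xi (1/s).
#' @export
effective_stimulation <- function(p, rec) {
  e_sd <- sd(rec$E)
  if (e_sd == 0) stop("E trace has zero standard deviation")
  p$delta_E / e_sd * mean_frequency(rec$E, rec$fs)
}

# Model-side feature computation on phase-locked block-experiment output,
# mirroring how the data features are measured: the bPRC uses all
# `n_trials_bprc` blocks, the (more robust) dynamical features only the
# first `n_trials_features` trials' worth of signal.  Grids are matched
# to `data`.
model_features <- function(p, data, cfg = feature_config(), dt = 1e-3,
                           seed = 1L, record_every = NULL) {
  # record at ~500 Hz regardless of integration step: ample for 4-8 Hz
  # tremor content and keeps feature extraction cheap inside optimisation
  if (is.null(record_every)) record_every <- max(1L, round(1 / (500 * dt)))
  proto <- stim_protocol(trials_per_phase = max(
    1L, cfg$n_trials_bprc %/% 12L))
  brec <- run_block_experiment(p, proto, n_trials = cfg$n_trials_bprc,
                               dt = dt, seed = seed,
                               record_every = record_every)
  if (sd(brec$E) < 1e-12) stop("degenerate (constant) model output")
  rc <- extract_response_curves(brec)
  n_dyn <- min(length(brec$E),
               round(cfg$n_trials_features * 6 * brec$fs))
  compute_features(brec$E[seq_len(n_dyn)], fs = brec$fs, cfg = cfg,
                   filter_dynamics = FALSE,
                   pdf_range = data$env_pdf$range, bprc = rc$bprc)
}

#' Fit the Wilson-Cowan model to tremor features
#'
#' Multi-restart generalized pattern search over the ten model parameters
#' against the cost of [feature_cost()], followed by re-optimisation of
#' the best results (optionally with a finer integration step).  The
#' parameters span orders of magnitude, so restart points are drawn
#' log-uniformly within the bounds and the search polls in
#' log-magnitude space (every parameter has a fixed sign).  Ranking is
#' by `R^2 = 1 - c`; on a tie (cost difference below the standard error
#' of the mean of the tied costs) stable foci are preferred over limit
#' cycles.
#'
#' @param data a `feature_set` of the target recording.
#' @param n_restarts number of random restarts.
#' @param budget objective evaluations per restart.
#' @param bounds 2 x 10 matrix of lower/upper parameter bounds; defaults
#'   bracket physiologically plausible values.
#' @param dt_coarse,dt_fine integration steps for the search and the
#'   refinement stage (equal steps make the refinement a plain polish).
#' @param top_k how many of the best coarse results to refine.
#' @param refine_budget evaluations per refinement.
#' @param cfg a [feature_config()].
#' @param seed integer seed.
#' @param classify label the regime of the ranked results?
#' @param target stop a refinement early when the cost reaches this.
#' @param polish_budget extra evaluations spent polishing the single
#'   best refined result.
#' @return List of class `wc_fit` with `results` (ranked data frame:
#'   cost, R2, regime, parameters) and `best` (a [wc_params()]).
#' @export
fit_patient <- function(data, n_restarts = 50L, budget = 40L,
                        bounds = default_fit_bounds(),
                        dt_coarse = 1e-3, dt_fine = 2.5e-4,
                        top_k = 3L, refine_budget = 30L,
                        cfg = feature_config(), seed = 1L,
                        classify = TRUE, target = NULL,
                        polish_budget = 0L) {
  par_names <- colnames(bounds)
  sgn <- sign(bounds[2, ])            # every parameter keeps its sign
  to_x <- function(s) sgn * exp(s)    # search space -> parameters
  lo_s <- pmin(log(abs(bounds[1, ])), log(abs(bounds[2, ])))
  hi_s <- pmax(log(abs(bounds[1, ])), log(abs(bounds[2, ])))
  to_params <- function(s) {
    do.call(wc_params, as.list(setNames(to_x(s), par_names)))
  }
  objective <- function(s, dt) {
    p <- to_params(s)
    mf <- model_features(p, data, cfg = cfg, dt = dt, seed = seed)
    feature_cost(data, mf)
  }
  set.seed(seed)
  starts <- matrix(runif(n_restarts * length(lo_s), rep(lo_s, each = n_restarts),
                         rep(hi_s, each = n_restarts)),
                   nrow = n_restarts)
  runs <- lapply(seq_len(n_restarts), function(r) {
    res <- pattern_search(function(s) objective(s, dt_coarse),
                          x0 = starts[r, ], lower = lo_s, upper = hi_s,
                          mesh0 = 0.15, budget = budget, target = target)
    c(list(restart = r), res[c("par", "value")])
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  ord <- order(vals)
  refined <- lapply(head(ord, top_k), function(r) {
    res <- pattern_search(function(s) objective(s, dt_fine),
                          x0 = runs[[r]]$par, lower = lo_s, upper = hi_s,
                          mesh0 = 0.1, budget = refine_budget,
                          target = target)
    list(restart = runs[[r]]$restart, par = res$par, value = res$value)
  })
  if (polish_budget > 0 && length(refined)) {
    rvals <- vapply(refined, `[[`, numeric(1), "value")
    b <- which.min(rvals)
    par <- refined[[b]]$par; val <- rvals[b]
    left <- polish_budget
    meshes <- c(0.12, 0.08, 0.05)
    cycle <- 1L
    # repeated polish cycles, each re-entering with a wider mesh, so the
    # search can step out of a mesh-converged point
    while (left > 30 && cycle <= 6L &&
           (is.null(target) || val > target)) {
      res <- pattern_search(function(s) objective(s, dt_fine),
                            x0 = par, lower = lo_s, upper = hi_s,
                            mesh0 = meshes[min(cycle, 3L)],
                            budget = min(left, 250L), target = target)
      left <- left - res$evals
      if (res$value < val) { par <- res$par; val <- res$value }
      cycle <- cycle + 1L
    }
    refined[[b]]$par <- par
    refined[[b]]$value <- val
  }
  all_runs <- c(refined, runs[setdiff(ord, head(ord, top_k))])
  costs <- vapply(all_runs, `[[`, numeric(1), "value")
  ord2 <- order(costs)
  all_runs <- all_runs[ord2]; costs <- costs[ord2]
  regimes <- rep(NA_character_, length(all_runs))
  if (classify) {
    for (i in seq_len(min(length(all_runs), top_k))) {
      if (is.finite(costs[i])) {
        regimes[i] <- as.character(
          classify_regime(to_params(all_runs[[i]]$par)))
      }
    }
    pref <- rank_fits(costs, regimes)
    all_runs <- all_runs[pref]
    costs <- costs[pref]
    regimes <- regimes[pref]
  }
  pars <- do.call(rbind, lapply(all_runs, function(r) to_x(r$par)))
  colnames(pars) <- par_names
  results <- data.frame(rank = seq_along(all_runs),
                        restart = vapply(all_runs, `[[`, numeric(1),
                                         "restart"),
                        cost = costs, R2 = 1 - costs,
                        regime = regimes)
  results <- cbind(results, as.data.frame(pars))
  best <- do.call(wc_params, as.list(pars[1, ]))
  structure(list(results = results, best = best, seed = seed),
            class = "wc_fit")
}

#' Rank fit results with the focus-over-limit-cycle tie-break
#'
#' Orders fits by cost, except that results whose cost difference from
#' the best is below the standard error of the mean of the finite costs
#' are treated as tied, and within a tie stable foci are ranked above
#' limit cycles.
#'
#' @param costs numeric costs, sorted ascending (NA/Inf allowed at the
#'   tail).
#' @param regimes character regime labels aligned with `costs`
#'   (`"stable_focus"`, `"limit_cycle"` or `NA` for unclassified).
#' @return An integer permutation of `seq_along(costs)`.
#' @export
rank_fits <- function(costs, regimes) {
  out <- seq_along(costs)
  fin <- which(is.finite(costs))
  if (length(fin) > 1) {
    sem <- sd(costs[fin]) / sqrt(length(fin))
    tied <- which(costs - costs[1] <= sem & !is.na(regimes))
    if (length(tied) > 1) {
      out[tied] <- tied[order(regimes[tied] != "stable_focus",
                              costs[tied])]
    }
  }
  out
}

#' Default parameter bounds for fitting
#'
#' Bounds bracketing the published best-fit values by roughly a factor of
#' ten either way for the positive parameters (sign-preserving for the
#' inhibitory input).
#'
#' @return 2 x 10 matrix; columns named as the [wc_params()] arguments.
#' @export
default_fit_bounds <- function() {
  b <- rbind(
    lower = c(w_EE = 0.15, w_EI = 2.5, w_IE = 0.9,
              theta_E = 0.15, theta_I = -35, beta = 0.4, tau = 0.02,
              zeta = 0.002, delta_E = 2e-4, delta_t_stim = 0.01),
    upper = c(w_EE = 70, w_EI = 260, w_IE = 260,
              theta_E = 60, theta_I = -0.3, beta = 12, tau = 0.8,
              zeta = 0.15, delta_E = 0.02, delta_t_stim = 0.6))
  b
}
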