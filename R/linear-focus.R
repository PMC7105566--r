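#' Linearisation of a 2D focus
#'
#' Packages a 2x2 Jacobian with complex eigenvalues `sigma +/- i*omega`
#' together with its fixed point and the real/imaginary parts of the right
#' eigenvector `k = a + i b` associated with the eigenvalue with positive
#' imaginary part.  The eigenvector gauge is fixed so that `b1 = 0` and
#' `a1 > 0` (always possible when the first coordinate oscillates);
#' response-curve quantities are invariant under this choice.
#'
#' @param J 2x2 real matrix (units 1/s).
#' @param fixed_point fixed point `c(E*, I*)` the linearisation is about.
#' @param eigvec_scale optional non-zero complex number multiplying the
#'   eigenvector, to work in a different gauge (response-curve results do
#'   not depend on it).
#' @return An object of class `focus_linearization` with fields `J`,
#'   `fixed_point`, `sigma`, `omega`, `a1`, `b1`, `a2`, `b2`.
#' @export
focus_linearization <- function(J, fixed_point = c(0, 0),
                                eigvec_scale = NULL) {
  stopifnot(is.matrix(J), all(dim(J) == 2), all(is.finite(J)))
  sigma <- (J[1, 1] + J[2, 2]) / 2
  disc <- det(J) - sigma^2
  if (disc <= 0) {
    stop("no rotation: the Jacobian has real eigenvalues")
  }
  omega <- sqrt(disc)
  # right eigenvector of lambda+ = sigma + i*omega; J[1,2] != 0 whenever
  # the eigenvalues are complex, so k = (J12, lambda - J11) works, and is
  # already in the b1 = 0 gauge up to sign
  s <- sign(J[1, 2])
  a1 <- abs(J[1, 2]); b1 <- 0
  a2 <- s * (sigma - J[1, 1]); b2 <- s * omega
  if (!is.null(eigvec_scale)) {
    stopifnot(Mod(eigvec_scale) > 0)
    k1 <- complex(real = a1, imaginary = b1) * eigvec_scale
    k2 <- complex(real = a2, imaginary = b2) * eigvec_scale
    a1 <- Re(k1); b1 <- Im(k1); a2 <- Re(k2); b2 <- Im(k2)
  }
  structure(list(J = J, fixed_point = fixed_point,
                 sigma = sigma, omega = omega,
                 a1 = a1, b1 = b1, a2 = a2, b2 = b2),
            class = "focus_linearization")
}

#' @export
print.focus_linearization <- function(x, ...) {
  cat(sprintf(
    "2D focus linearisation: sigma = %.4g 1/s, omega = %.4g rad/s (f = %.3g Hz)\n",
    x$sigma, x$omega, x$omega / (2 * pi)))
  cat(sprintf("  |sigma|/omega = %.3g; eigenvector a = (%.4g, %.4g), b = (%.4g, %.4g)\n",
              abs(x$sigma) / x$omega, x$a1, x$a2, x$b1, x$b2))
  invisible(x)
}

#' All fixed points of the deterministic Wilson-Cowan model
#'
#' Scans E in (0, 1) for sign changes of the scalar fixed-point condition
#' (I is eliminated through its own equilibrium equation) and polishes each
#' root; reports the Jacobian eigenvalues at every fixed point.
#'
#' @param p a [wc_params()] object.
#' @param n_grid resolution of the sign-change scan.
#' @return Data frame with columns `E`, `I`, `sigma_like` (real part),
#'   `omega_like` (imaginary part, 0 for real eigenvalues), `complex`.
#' @export
wc_fixed_points <- function(p, n_grid = 20001L) {
  g <- function(E) {
    I <- wc_sigmoid(p$theta_I + p$w_EI * E, p$beta)
    -E + wc_sigmoid(p$theta_E + p$w_EE * E - p$w_IE * I, p$beta)
  }
  Es <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  gv <- vapply(Es, g, numeric(1))
  idx <- which(diff(sign(gv)) != 0)
  if (!length(idx)) stop("no fixed point found in E in (0, 1)")
  roots <- vapply(idx, function(i) {
    uniroot(g, c(Es[i], Es[i + 1]), tol = 1e-14)$root
  }, numeric(1))
  rows <- lapply(roots, function(E) {
    I <- wc_sigmoid(p$theta_I + p$w_EI * E, p$beta)
    J <- .wc_jacobian(p, E, I)
    ev <- eigen(J, only.values = TRUE)$values[1]
    data.frame(E = E, I = I, sigma_like = Re(ev),
               omega_like = abs(Im(ev)), complex = Im(ev) != 0)
  })
  do.call(rbind, rows)
}

# analytic Jacobian of the WC drift at (E, I)
.wc_jacobian <- function(p, E, I) {
  u <- p$theta_E + p$w_EE * E - p$w_IE * I
  v <- p$theta_I + p$w_EI * E
  fpu <- wc_sigmoid_deriv(u, p$beta)
  fpv <- wc_sigmoid_deriv(v, p$beta)
  matrix(c((-1 + fpu * p$w_EE) / p$tau, fpv * p$w_EI / p$tau,
           -fpu * p$w_IE / p$tau, -1 / p$tau), 2, 2)
}

#' Jacobian of the Wilson-Cowan model at its focus fixed point
#'
#' Locates the fixed points, evaluates the analytic Jacobian, and returns
#' the linearisation about the fixed point with complex eigenvalues.  When
#' several such fixed points exist, the one closest to the time-average of
#' a short noisy trajectory is selected (the one the stochastic system
#' orbits).
#'
#' @param p a [wc_params()] object.
#' @return A [focus_linearization()].
#' @export
jacobian_at_fixed_point <- function(p) {
  fps <- wc_fixed_points(p)
  cand <- fps[fps$complex, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no focus: no fixed point with complex eigenvalues")
  }
  if (nrow(cand) > 1) {
    rec <- simulate_wc(p, duration = 10, dt = 1e-3, seed = 1L)
    ctr <- c(mean(rec$E), mean(rec$I))
    d <- (cand$E - ctr[1])^2 + (cand$I - ctr[2])^2
    cand <- cand[which.min(d), , drop = FALSE]
  }
  E <- cand$E[1]; I <- cand$I[1]
  focus_linearization(.wc_jacobian(p, E, I), fixed_point = c(E, I))
}

#' Reference and stimulated trajectory coefficients
#'
#' The general solution of the linearised dynamics is
#' \deqn{X(t) = \{K (a\cos\omega t - b\sin\omega t)
#'               + K' (a\sin\omega t + b\cos\omega t)\} e^{\sigma t}.}
#' `reference_coefficients()` solves for `(K, K')` so that the first
#' coordinate has a maximum of height `X1_0` at `t = 0` (hence
#' `alpha/beta = -sigma/omega`).  `stimulated_coefficients()` applies an
#' instantaneous pulse `delta_X1` to the first coordinate at phase `phi0`
#' and solves for the coefficients of the post-stimulation trajectory.
#'
#' @param lin a [focus_linearization()].
#' @param X1_0 peak amplitude of the first coordinate at `t = 0`.
#' @return A list of class `trajectory_coefficients` with `K`, `Kp`,
#'   `alpha`, `beta_lin`, `role`, plus `phi0`/`delta_X1` for the
#'   stimulated case.
#' @export
reference_coefficients <- function(lin, X1_0) {
  a1 <- lin$a1; b1 <- lin$b1
  if (a1 == 0 && b1 == 0) stop("degenerate eigenvector: a1 = b1 = 0")
  # K a1 + K' b1 = X1_0 ; K' a1 - K b1 = -(sigma/omega) X1_0
  rhs <- c(X1_0, -lin$sigma / lin$omega * X1_0)
  M <- matrix(c(a1, -b1, b1, a1), 2, 2)
  kk <- solve(M, rhs)
  structure(list(K = kk[1], Kp = kk[2],
                 alpha = kk[2] * a1 - kk[1] * b1,
                 beta_lin = kk[1] * a1 + kk[2] * b1,
                 X1_0 = X1_0, role = "ref"),
            class = "trajectory_coefficients")
}

#' @rdname reference_coefficients
#' @param ref reference-trajectory coefficients.
#' @param phi0 stimulation phase in `[0, 2*pi)`.
#' @param delta_X1 pulse magnitude applied to the first coordinate.
#' @export
stimulated_coefficients <- function(lin, ref, phi0, delta_X1) {
  stopifnot(phi0 >= 0, phi0 < 2 * pi)
  t0 <- phi0 / lin$omega
  x_minus <- trajectory_point(lin, ref, t0)
  x_plus <- x_minus + c(delta_X1, 0)
  a <- c(lin$a1, lin$a2); b <- c(lin$b1, lin$b2)
  u <- a * cos(phi0) - b * sin(phi0)
  v <- a * sin(phi0) + b * cos(phi0)
  M <- cbind(u, v) * exp(lin$sigma * t0)
  kk <- unname(solve(M, x_plus))
  structure(list(K = kk[1], Kp = kk[2],
                 alpha = kk[2] * lin$a1 - kk[1] * lin$b1,
                 beta_lin = kk[1] * lin$a1 + kk[2] * lin$b1,
                 X1_0 = ref$X1_0, phi0 = phi0, delta_X1 = delta_X1,
                 role = "stim"),
            class = "trajectory_coefficients")
}

#' Evaluate a linearised trajectory
#'
#' @param lin a [focus_linearization()].
#' @param co trajectory coefficients from [reference_coefficients()] or
#'   [stimulated_coefficients()].
#' @param t time (s), vectorised.
#' @return For `trajectory_point()`, the state `c(X1, X2)` (single `t`);
#'   for `trajectory_X1()`, the first coordinate at each `t`.
#' @export
trajectory_point <- function(lin, co, t) {
  a <- c(lin$a1, lin$a2); b <- c(lin$b1, lin$b2)
  wt <- lin$omega * t
  (co$K * (a * cos(wt) - b * sin(wt)) +
     co$Kp * (a * sin(wt) + b * cos(wt))) * exp(lin$sigma * t)
}

#' @rdname trajectory_point
#' @export
trajectory_X1 <- function(lin, co, t) {
  wt <- lin$omega * t
  (co$beta_lin * cos(wt) + co$alpha * sin(wt)) * exp(lin$sigma * t)
}

#' Phase of the next maximum on the stimulated trajectory
#'
#' The first coordinate of a linearised trajectory is
#' `R e^{sigma t} cos(omega t - psi)`; its maxima occur where
#' `omega t = psi + atan(sigma/omega) + 2k pi`.  The smallest such time
#' after the stimulation instant gives `phi_max = omega t_max - 2*pi`, the
#' phase lag/advance of the next peak relative to the unstimulated peak at
#' phase `2*pi`.
#'
#' @param lin a [focus_linearization()].
#' @param stim stimulated-trajectory coefficients.
#' @return `phi_max` in radians.
#' @export
phi_max <- function(lin, stim) {
  psi <- atan2(stim$alpha, stim$beta_lin)
  d0 <- atan(lin$sigma / lin$omega)
  t0 <- if (!is.null(stim$phi0)) stim$phi0 / lin$omega else 0
  # candidate maxima over a generous window, smallest strictly after t0
  k <- seq(-2, 3)
  t_cand <- (psi + d0 + 2 * pi * k) / lin$omega
  t_cand <- t_cand[t_cand > t0 + 1e-12]
  t_max <- min(t_cand)
  lin$omega * t_max - 2 * pi
}

#' First-order response constants of the linearised focus
#'
#' The constants entering the first-order response curves and their
#' derivative relationship:
#' \deqn{A = (a_1 a_2 + b_1 b_2)\omega - (a_1 b_2 - a_2 b_1)\sigma}
#' \deqn{B = (a_1 b_2 - a_2 b_1)\omega + (a_1 a_2 + b_1 b_2)\sigma}
#' \deqn{C = \omega / ((\omega^2+\sigma^2)(a_1 b_2 - a_2 b_1))}
#' \deqn{D = (a_1 a_2 + b_1 b_2)/(a_1 b_2 - a_2 b_1)}
#' together with `F` and `G` from the derivative of the first-order phase
#' response.  For purely rotational flows (`a2 = b1 = 0`, `sigma = 0`)
#' `F = 1` and `G = D = 0`.
#'
#' @param lin a [focus_linearization()].
#' @return List with `A`, `B`, `C`, `D`, `F`, `G`.
#' @export
response_constants <- function(lin) {
  a1 <- lin$a1; b1 <- lin$b1; a2 <- lin$a2; b2 <- lin$b2
  s <- lin$sigma; w <- lin$omega
  cross <- a1 * b2 - a2 * b1
  dot <- a1 * a2 + b1 * b2
  if (cross == 0) stop("degenerate eigenvector: a1*b2 - a2*b1 = 0")
  A <- dot * w - cross * s
  B <- cross * w + dot * s
  C <- w / ((w^2 + s^2) * cross)
  D <- dot / cross
  F <- cross * (w^2 + s^2) /
    (cross * (w^2 - s^2) + 2 * dot * w * s) * exp(2 * pi * s / w)
  G <- (dot * (w^2 - s^2) - 2 * cross * w * s) /
    (cross * (w^2 - s^2) + 2 * dot * w * s)
  list(A = A, B = B, C = C, D = D, F = F, G = G)
}

#' First-order phase and amplitude response curves of a linearised focus
#'
#' `hPRC1()` is the change in phase and `hARC1()` the change in first
#' coordinate amplitude caused by an instantaneous pulse `delta_X1`
#' applied at phase `phi0`, both measured at the next peak of the first
#' coordinate.  Mode `"exact"` measures the responses on the actual
#' stimulated trajectory (through [phi_max()]); mode `"first_order"`
#' evaluates the leading-order Taylor expansions
#' \deqn{hPRC^{(1)} \approx (\delta X_1/X_1^0)(A\cos\phi_0 - B\sin\phi_0)
#'   C e^{-\sigma\phi_0/\omega},}
#' \deqn{hARC^{(1)} \approx \delta X_1 (\cos\phi_0 + D\sin\phi_0)
#'   e^{-\sigma(\phi_0 - 2\pi)/\omega}.}
#'
#' @param lin a [focus_linearization()].
#' @param phi0 stimulation phase(s) in `[0, 2*pi)` (vectorised).
#' @param delta_X1 pulse magnitude.
#' @param X1_0 peak amplitude at the start of the period.
#' @param mode `"exact"` or `"first_order"`.
#' @return Phase change in radians (`hPRC1`) or amplitude change in the
#'   units of the first coordinate (`hARC1`).
#' @export
hPRC1 <- function(lin, phi0, delta_X1, X1_0,
                  mode = c("exact", "first_order")) {
  mode <- match.arg(mode)
  if (mode == "first_order") {
    k <- response_constants(lin)
    return(delta_X1 / X1_0 * (k$A * cos(phi0) - k$B * sin(phi0)) * k$C *
             exp(-lin$sigma * phi0 / lin$omega))
  }
  ref <- reference_coefficients(lin, X1_0)
  vapply(phi0, function(p0) {
    stim <- stimulated_coefficients(lin, ref, p0, delta_X1)
    -phi_max(lin, stim)
  }, numeric(1))
}

#' @rdname hPRC1
#' @export
hARC1 <- function(lin, phi0, delta_X1, X1_0,
                  mode = c("exact", "first_order")) {
  mode <- match.arg(mode)
  if (mode == "first_order") {
    k <- response_constants(lin)
    return(delta_X1 * (cos(phi0) + k$D * sin(phi0)) *
             exp(-lin$sigma * (phi0 - 2 * pi) / lin$omega))
  }
  ref <- reference_coefficients(lin, X1_0)
  x1_ref_peak <- trajectory_X1(lin, ref, 2 * pi / lin$omega)
  vapply(phi0, function(p0) {
    stim <- stimulated_coefficients(lin, ref, p0, delta_X1)
    pm <- phi_max(lin, stim)
    trajectory_X1(lin, stim, (2 * pi + pm) / lin$omega) - x1_ref_peak
  }, numeric(1))
}

#' Derivative relationship between the first-order response curves
#'
#' In general the exact scaling factor of the derivative is `F * X1_0`:
#' `-F X1_0 * d hPRC1/d phi0 = delta_X1 (cos phi0 + G sin phi0)
#' e^{-sigma(phi0 - 2 pi)/omega}`, which differs from the first-order ARC
#' only through `G` in place of `D`.  For slow decay `F ~ 1` and `G ~ D`,
#' giving the simpler approximate relationship
#' `-X1_0 * d hPRC1/d phi0 ~ hARC1`; for `sigma = 0` both forms are
#' exact.  Returns the `F`-scaled derivative curve (the one compared
#' against the ARC graphically) and the plain `X1_0`-scaled one, with
#' their maximum discrepancies from the ARC as fractions of the ARC
#' amplitude.
#'
#' @param lin a [focus_linearization()].
#' @param phi0 phase grid in radians.
#' @param delta_X1,X1_0 stimulation and peak amplitudes.
#' @return List with `phi0`, `neg_scaled_prc_deriv` (`F X1_0` scaling),
#'   `neg_deriv_plain` (`X1_0` scaling, the slow-decay approximation),
#'   `harc`, `max_discrepancy`, `rel_discrepancy` (for the `F`-scaled
#'   curve) and `rel_discrepancy_plain`.
#' @export
prc_derivative_relation <- function(lin, phi0 = seq(0, 2 * pi,
                                                    length.out = 241),
                                    delta_X1 = 2e-4, X1_0 = 1e-3) {
  k <- response_constants(lin)
  dec <- exp(-lin$sigma * (phi0 - 2 * pi) / lin$omega)
  dprc_F <- delta_X1 * (cos(phi0) + k$G * sin(phi0)) * dec
  dprc_plain <- dprc_F / k$F
  harc <- hARC1(lin, phi0, delta_X1, X1_0, mode = "first_order")
  amp <- max(abs(harc))
  disc_F <- max(abs(dprc_F - harc))
  disc_plain <- max(abs(dprc_plain - harc))
  list(phi0 = phi0, neg_scaled_prc_deriv = dprc_F,
       neg_deriv_plain = dprc_plain, harc = harc,
       max_discrepancy = disc_F,
       rel_discrepancy = disc_F / amp,
       rel_discrepancy_plain = disc_plain / amp)
}

#' Wilson-Cowan parameters realising a given Jacobian
#'
#' Inverse mapping: chooses the fixed point at `(E*, I*) = (0.5, 0.5)`
#' (sigmoid arguments equal 1, derivative `beta/4`) and solves the
#' analytic Jacobian entries for the weights and inputs.  The time
#' constant is forced by the second diagonal entry, `tau = -1/J[2,2]`, so
#' Jacobians with a non-negative `J[2,2]` cannot be realised.
#'
#' @param J target 2x2 Jacobian (1/s).
#' @param beta sigmoid steepness to use (free choice).
#' @return A [wc_params()] with `zeta = 0`, whose Jacobian at its focus
#'   fixed point reproduces `J`.
#' @export
params_from_jacobian <- function(J, beta = 2) {
  stopifnot(is.matrix(J), all(dim(J) == 2))
  if (J[2, 2] >= 0) {
    stop("cannot realise this Jacobian: the second diagonal term is -1/tau < 0")
  }
  tau <- -1 / J[2, 2]
  fp <- beta / 4        # sigmoid slope at argument 1
  w_EE <- (1 + tau * J[1, 1]) / fp
  w_IE <- -tau * J[1, 2] / fp
  w_EI <- tau * J[2, 1] / fp
  theta_E <- 1 - 0.5 * w_EE + 0.5 * w_IE
  theta_I <- 1 - 0.5 * w_EI
  wc_params(w_EE = w_EE, w_EI = w_EI, w_IE = w_IE,
            theta_E = theta_E, theta_I = theta_I,
            beta = beta, tau = tau, zeta = 0)
}

#' Stationary standard deviation of the linearised model
#'
#' Solves the continuous Lyapunov equation
#' `J S + S J' + zeta^2 I = 0` for the stationary covariance of the
#' linearised stochastic dynamics and returns the standard deviation of
#' the first coordinate, `sqrt(S[1,1])`.
#'
#' @param lin a [focus_linearization()] with `sigma < 0`.
#' @param zeta noise standard deviation.
#' @return Standard deviation of the first coordinate.
#' @export
stationary_std <- function(lin, zeta) {
  if (lin$sigma >= 0) stop("no stationary state: sigma >= 0")
  J <- lin$J
  Amat <- kronecker(diag(2), J) + kronecker(J, diag(2))
  Svec <- solve(Amat, -zeta^2 * as.numeric(diag(2)))
  sqrt(Svec[1])
}

#' Gallery of simple linear focus systems
#'
#' The illustrative 2x2 matrices: a circular flow without decay, circular
#' flows with slow and fast decay, and a tilted elliptic flow without
#' decay.
#'
#' @return Named list of 2x2 matrices `circ`, `circ_slow`, `circ_fast`,
#'   `ellip`.
#' @export
simple_focus_systems <- function() {
  list(circ = matrix(c(0, 1, -1, 0), 2, 2),
       circ_slow = matrix(c(-5e-3, 1, -1, -5e-3), 2, 2),
       circ_fast = matrix(c(-0.2, 1, -1, -0.2), 2, 2),
       ellip = matrix(c(1, 2, -1, -1), 2, 2))
}
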