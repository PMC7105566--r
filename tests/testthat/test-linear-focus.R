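test_that("patient Jacobians reproduce the published matrices", {
  J1_pub <- matrix(c(11.9723, 34.9513, -35.0323, -13.1953), 2, 2)
  J5_pub <- matrix(c(-0.2252, 23.2880, -52.3293, -3.3351), 2, 2)
  J6_pub <- matrix(c(2.8269, 101.6943, -12.8784, -3.9789), 2, 2)
  lin1 <- patient1_lin()
  lin5 <- jacobian_at_fixed_point(patient_params(5))
  lin6 <- jacobian_at_fixed_point(patient_params(6))
  expect_lt(max(abs(lin1$J - J1_pub) / abs(J1_pub)), 0.005)
  expect_lt(max(abs(lin5$J - J5_pub) / abs(J5_pub)), 0.005)
  expect_lt(max(abs(lin6$J - J6_pub) / abs(J6_pub)), 0.005)
  # the (2,2) entry is exactly -1/tau
  expect_equal(lin5$J[2, 2], -1 / patient_params(5)$tau)
  expect_equal(lin5$J[2, 2], -3.3351, tolerance = 1e-4)
})

test_that("eigenstructure gives the decay/rotation split", {
  lc <- focus_linearization(simple_focus_systems()$circ)
  expect_equal(lc$sigma, 0)
  expect_equal(lc$omega, 1)
  expect_equal(c(lc$a2, lc$b1), c(0, 0))  # eigenvector (1, -i) gauge
  # decay-to-rotation ratios of the patient linearisations
  r5 <- with(jacobian_at_fixed_point(patient_params(5)),
             abs(sigma) / omega)
  expect_equal(r5, 0.05, tolerance = 0.1)
  for (id in c(1, 6)) {
    lin <- jacobian_at_fixed_point(patient_params(id))
    expect_lt(abs(lin$sigma) / lin$omega, 0.02)
  }
  expect_error(focus_linearization(matrix(c(1, 0, 0, 2), 2, 2)),
               "real eigenvalues")
})

test_that("reference trajectory peaks at t = 0 with the prescribed amplitude", {
  set.seed(6)
  for (i in 1:5) {
    lin <- focus_linearization(random_focus())
    X0 <- 10^runif(1, -3, 0)
    ref <- reference_coefficients(lin, X0)
    expect_equal(trajectory_X1(lin, ref, 0), X0, tolerance = 1e-12)
    h <- 1e-7
    d0 <- (trajectory_X1(lin, ref, h) - trajectory_X1(lin, ref, -h)) / (2 * h)
    expect_lt(abs(d0), 1e-5 * X0 * lin$omega)
    expect_equal(ref$alpha / ref$beta_lin, -lin$sigma / lin$omega,
                 tolerance = 1e-12)
  }
})

test_that("stimulated trajectory is continuous and only moves the first coordinate", {
  lin <- patient1_lin()
  ref <- reference_coefficients(lin, 1e-3)
  phi0 <- 2.2; d <- 2e-4
  stim <- stimulated_coefficients(lin, ref, phi0, d)
  t0 <- phi0 / lin$omega
  before <- trajectory_point(lin, ref, t0)
  after <- trajectory_point(lin, stim, t0)
  expect_equal(after[1], before[1] + d, tolerance = 1e-12)
  expect_equal(after[2], before[2], tolerance = 1e-12)
  # zero stimulation: identical coefficients
  stim0 <- stimulated_coefficients(lin, ref, phi0, 0)
  expect_equal(stim0$K, ref$K, tolerance = 1e-12)
  expect_equal(stim0$Kp, ref$Kp, tolerance = 1e-12)
  expect_equal(phi_max(lin, stim0), 0, tolerance = 1e-9)
})

test_that("closed-form phi_max agrees with dense grid maximisation", {
  set.seed(7)
  for (i in 1:20) {
    lin <- focus_linearization(random_focus())
    ref <- reference_coefficients(lin, 1e-3)
    p0 <- runif(1, 0.2, 2 * pi - 0.2)
    stim <- stimulated_coefficients(lin, ref, p0, 2e-4)
    pm <- phi_max(lin, stim)
    # brute-force oracle: coarse grid bracket + golden-section refinement
    t0 <- p0 / lin$omega
    tg <- seq(t0 + 1e-9, t0 + 4 * pi / lin$omega, length.out = 20001)
    x1 <- trajectory_X1(lin, stim, tg)
    j <- which(diff(sign(diff(x1))) == -2)[1] + 1
    opt <- optimize(function(t) -trajectory_X1(lin, stim, t),
                    c(tg[j - 1], tg[j + 1]), tol = 1e-12)
    pm_oracle <- lin$omega * opt$minimum - 2 * pi
    expect_equal(pm, pm_oracle, tolerance = 1e-6)
  }
})

test_that("first-order responses match closed forms for the circular flow", {
  lc <- focus_linearization(simple_focus_systems()$circ)
  phi <- seq(0, 2 * pi, length.out = 37)[-37]
  d <- 2e-4; X0 <- 1e-3
  expect_equal(hPRC1(lc, phi, d, X0, "first_order"),
               -(d / X0) * sin(phi), tolerance = 1e-10)
  expect_equal(hARC1(lc, phi, d, X0, "first_order"),
               d * cos(phi), tolerance = 1e-10)
  expect_equal(hPRC1(lc, pi / 2, d, X0, "first_order"), -0.2,
               tolerance = 1e-10)
  # proportionality: linear in delta_X1, inverse in X1_0 (PRC only)
  expect_equal(hPRC1(lc, 1, 2 * d, X0, "first_order"),
               2 * hPRC1(lc, 1, d, X0, "first_order"))
  expect_equal(hPRC1(lc, 1, d, 2 * X0, "first_order"),
               hPRC1(lc, 1, d, X0, "first_order") / 2)
  expect_equal(hARC1(lc, 1, d, 2 * X0, "first_order"),
               hARC1(lc, 1, d, X0, "first_order"))
})

test_that("exact responses converge to the first-order expansions as O(delta^2)", {
  for (id in c(1, 5, 6)) {
    lin <- jacobian_at_fixed_point(patient_params(id))
    X0 <- 1e-3
    phi <- seq(0.3, 2 * pi - 0.3, length.out = 20)
    err <- function(d) {
      max(abs(hPRC1(lin, phi, d, X0, "exact") -
                hPRC1(lin, phi, d, X0, "first_order")),
          abs(hARC1(lin, phi, d, X0, "exact") -
                hARC1(lin, phi, d, X0, "first_order")) / X0)
    }
    e1 <- err(4e-5); e2 <- err(2e-5)
    expect_gt(e1 / e2, 3)   # halving delta divides the error by ~4
    expect_lt(e2 / 2e-5, err(8e-5) / 8e-5)  # error/delta decreasing
  }
})

test_that("response constants reduce correctly in the simple systems", {
  sys <- simple_focus_systems()
  kc <- response_constants(focus_linearization(sys$circ))
  expect_equal(kc$F, 1)
  expect_equal(kc$G, 0)
  expect_equal(kc$D, 0)
  # sigma = 0: derivative relationship exact (G = D, F covers the tilt)
  ke <- response_constants(focus_linearization(sys$ellip))
  expect_equal(ke$G, ke$D)
  r_ellip <- prc_derivative_relation(focus_linearization(sys$ellip))
  expect_lt(r_ellip$rel_discrepancy, 1e-12)
  # slow decay: |F - 1| <= 2|D - pi||sigma/omega| + O((sigma/omega)^2)
  for (J in list(sys$circ_slow, patient_params(1))) {
    lin <- if (inherits(J, "wc_params")) jacobian_at_fixed_point(J)
           else focus_linearization(J)
    k <- response_constants(lin)
    rat <- abs(lin$sigma) / lin$omega
    expect_lte(abs(k$F - 1), 2 * abs(k$D - pi) * rat + 10 * rat^2)
  }
})

test_that("the derivative relationship holds for slow decay and fails for fast", {
  sys <- simple_focus_systems()
  expect_lt(prc_derivative_relation(
    focus_linearization(sys$circ_slow))$rel_discrepancy, 0.02)
  expect_gt(prc_derivative_relation(
    focus_linearization(sys$circ_fast))$rel_discrepancy, 0.10)
})

test_that("responses are invariant under the eigenvector gauge", {
  J <- patient1_lin()$J
  phi <- seq(0.2, 6, length.out = 15)
  base <- focus_linearization(J)
  r0p <- hPRC1(base, phi, 2e-4, 1e-3, "first_order")
  r0a <- hARC1(base, phi, 2e-4, 1e-3, "first_order")
  e0p <- hPRC1(base, phi, 2e-4, 1e-3, "exact")
  for (sc in list(2, complex(real = 0, imaginary = 0.5),
                  complex(real = -1.3, imaginary = 0.4))) {
    lin <- focus_linearization(J, eigvec_scale = sc)
    expect_equal(hPRC1(lin, phi, 2e-4, 1e-3, "first_order"), r0p,
                 tolerance = 1e-9)
    expect_equal(hARC1(lin, phi, 2e-4, 1e-3, "first_order"), r0a,
                 tolerance = 1e-9)
    expect_equal(hPRC1(lin, phi, 2e-4, 1e-3, "exact"), e0p,
                 tolerance = 1e-9)
    k <- response_constants(lin)
    expect_equal(k$D, response_constants(base)$D, tolerance = 1e-9)
    expect_equal(k$F, response_constants(base)$F, tolerance = 1e-9)
    expect_equal(k$G, response_constants(base)$G, tolerance = 1e-9)
  }
})

test_that("cosine fits to slow-decay first-order curves give a shift near pi/2", {
  phi <- phase_bin_centers(12)
  for (J in list(simple_focus_systems()$circ_slow, patient1_lin()$J)) {
    lin <- focus_linearization(J)
    cp <- fit_cosine(phi, hPRC1(lin, phi, 2e-4, 1e-3, "first_order"))
    ca <- fit_cosine(phi, hARC1(lin, phi, 2e-4, 1e-3, "first_order"))
    shift <- prc_arc_shift(cp$c3, ca$c3)
    expect_lt(abs(shift - pi / 2), 0.1)
  }
})

test_that("inverse parameter mapping round-trips through the Jacobian", {
  sys <- simple_focus_systems()
  expect_error(params_from_jacobian(sys$circ), "second diagonal")
  p_slow <- params_from_jacobian(sys$circ_slow)
  expect_equal(p_slow$w_EE, 0)
  expect_equal(p_slow$w_IE, p_slow$w_EI)
  set.seed(8)
  for (i in 1:5) {
    J <- random_focus(sigma = -runif(1, 0.1, 2), omega = runif(1, 5, 40))
    if (J[2, 2] >= 0) next
    p <- params_from_jacobian(J, beta = runif(1, 1, 4))
    lin <- jacobian_at_fixed_point(p)
    expect_equal(lin$J, J, tolerance = 1e-6)
  }
})

test_that("stationary std solves the Lyapunov equation and matches simulation", {
  # uncoupled case: scalar Ornstein-Uhlenbeck with known variance
  Jd <- matrix(c(-3, 1e-9, -1e-9, -3), 2, 2)  # tiny rotation keeps a focus
  lin_d <- focus_linearization(Jd)
  expect_equal(stationary_std(lin_d, 0.2), 0.2 / sqrt(2 * 3),
               tolerance = 1e-6)
  lin_s <- focus_linearization(simple_focus_systems()$circ_slow)
  # linear scaling in zeta
  expect_equal(stationary_std(lin_s, 0.02), 2 * stationary_std(lin_s, 0.01))
  # Monte-Carlo oracle
  rec <- simulate_linearized(lin_s, zeta = 0.01, duration = 6000,
                             dt = 2e-4, seed = 3, record_every = 50)
  expect_equal(sd(rec$E), stationary_std(lin_s, 0.01), tolerance = 0.05)
  expect_error(stationary_std(focus_linearization(
    simple_focus_systems()$circ), 0.01), "sigma >= 0")
})

test_that("the linearised phase definition matches the Hilbert phase for slow decay", {
  # omega >= 50 |sigma|: phi_Hilbert ~ omega t with zero at the X1 maximum
  w <- 2 * pi * 5
  J <- matrix(c(-0.1, w, -w, -0.1), 2, 2)
  lin <- focus_linearization(J)
  ref <- reference_coefficients(lin, 1)
  fs <- 1000
  tt <- seq(-3 * 2 * pi / w, 6 * 2 * pi / w, by = 1 / fs)
  x <- trajectory_X1(lin, ref, tt)
  an <- analytic_signal(x)
  win <- tt >= 0 & tt <= 3 * 2 * pi / w
  err <- an$phase[win] - an$phase[which.min(abs(tt))] - w * tt[win]
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("linearised simulation oscillates at the eigenfrequency", {
  lin <- patient1_lin()
  p <- patient_params(1)
  rec <- simulate_linearized(lin, zeta = p$zeta, duration = 60, dt = 1e-3,
                             seed = 9)
  ps <- welch_psd(rec$E - mean(rec$E), rec$fs, seg_len = 16000, fmax = 12)
  sel <- ps$freq >= 2
  fpk <- ps$freq[sel][which.max(ps$psd[sel])]
  expect_equal(fpk, lin$omega / (2 * pi), tolerance = 0.1)
  # zeta = 0 from the fixed point: constant
  rec0 <- simulate_linearized(lin, zeta = 0, duration = 1)
  expect_lt(max(abs(rec0$E - lin$fixed_point[1])), 1e-12)
})
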