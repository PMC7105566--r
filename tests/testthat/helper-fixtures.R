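# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# short patient-1 block experiment shared across response-curve tests
patient1_blocks <- function() {
  fixture("p1_blocks", function() {
    run_block_experiment(patient_params(1), stim_protocol(),
                         n_trials = 36, dt = 1e-3, seed = 42)
  })
}

patient1_lin <- function() {
  fixture("p1_lin", function() jacobian_at_fixed_point(patient_params(1)))
}

# random 2x2 matrices guaranteed to be stable foci: J = P R P^-1 with
# R the canonical (sigma, omega) rotation block and P a random change of
# basis -- an independent construction used as a test-case generator
random_focus <- function(sigma = NULL, omega = NULL) {
  if (is.null(sigma)) sigma <- -runif(1, 0.01, 1)
  if (is.null(omega)) omega <- runif(1, 1, 50)
  repeat {
    P <- matrix(rnorm(4), 2, 2)
    if (abs(det(P)) > 0.1) break
  }
  R <- matrix(c(sigma, omega, -omega, sigma), 2, 2)
  J <- P %*% R %*% solve(P)
  if (J[1, 2] == 0) return(random_focus(sigma, omega))
  J
}
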