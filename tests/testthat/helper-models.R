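## Shared fixtures: small sweeps keep the suite fast while preserving the
## geometry being tested.

sphere_model <- function(...) {
  default_model(
    tibial_groove = list(inception = -62, termination = -22, flattening = 0,
                         trough_frac = 0.7, face_tilt = 0),
    fibular_groove = list(inception = -69, termination = -33, flattening = 0,
                          trough_frac = 0.3, face_tilt = 0),
    ...)
}

small_sweep <- function(model, n = 60) {
  sweep_joint(model, sweep_spec(model$sweep$theta0, model$sweep$thetaM, n,
                                warn = FALSE))
}

## A random rigid transform (seeded by the caller).
random_rigid <- function() {
  ang <- runif(1, -180, 180)
  list(R = rot2(ang_deg <- ang), t = runif(2, -20, 20))
}

rot2 <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_lt(max(abs(object - expected)), tol)
}
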