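# Independent oracles used across tests.

# Monte-Carlo circle-overlap fraction: uniform points in the aperture disc,
# fraction falling inside the shadow disc.
mc_occlusion <- function(shadow_center, shadow_diameter, aperture_center,
                         aperture_diameter, n = 4e6) {
  r <- aperture_diameter / 2 * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- aperture_center + r * cos(th)
  y <- r * sin(th)
  mean((x - shadow_center)^2 + y^2 <= (shadow_diameter / 2)^2)
}

# Closed-form terminal velocity, written out independently of the package
# (SI units throughout, converted at the edges).
oracle_terminal_velocity <- function(d_mm, sg_drop, mu_drop_cP, sg_phase,
                                     mu_phase_cP, omega, r_mm) {
  drho <- (sg_drop - sg_phase) * 1000
  kappa <- mu_drop_cP / mu_phase_cP
  h <- (1 + kappa) / (2 / 3 + kappa)
  v <- drho * omega^2 * (r_mm * 1e-3) * (d_mm * 1e-3)^2 * h /
    (18 * mu_phase_cP * 1e-3)
  v * 1e3
}
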