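#' Dispersed droplet specification
#'
#' @param diameter_d Droplet diameter, mm.
#' @param specific_gravity Density relative to water.
#' @param viscosity Dispersed-phase dynamic viscosity, cP.
#' @param medium Optional [optical_medium()] of the droplet fluid.
#' @return Object of class `droplet_spec`.
#' @export
droplet_spec <- function(diameter_d = 1, specific_gravity = 1, viscosity = 1,
                         medium = optical_medium("water")) {
  stopifnot(diameter_d > 0, specific_gravity > 0, viscosity > 0)
  structure(list(diameter_d = diameter_d, specific_gravity = specific_gravity,
                 viscosity = viscosity, medium = medium),
            class = "droplet_spec")
}

#' Continuous phase specification
#'
#' @param viscosity_mu Dynamic viscosity, cP.
#' @param specific_gravity Density relative to water.
#' @param medium Optional [optical_medium()] of the continuous fluid.
#' @return Object of class `phase_spec`.
#' @export
phase_spec <- function(viscosity_mu = 75, specific_gravity = 0.92,
                       medium = optical_medium("oil")) {
  stopifnot(viscosity_mu > 0, specific_gravity > 0)
  structure(list(viscosity_mu = viscosity_mu,
                 specific_gravity = specific_gravity, medium = medium),
            class = "phase_spec")
}

#' Spin protocol
#'
#' Constant rotation rate or a piecewise-constant schedule.
#'
#' @param rpm Either a single non-negative rotation rate (rev/min) or a
#'   two-column data frame / matrix `(time_s, rpm)` defining a
#'   piecewise-constant schedule (left-continuous steps).
#' @param direction +1 (counterclockwise) or -1.
#' @return Object of class `spin_protocol` with `omega(t)` in rad/s.
#' @export
spin_protocol <- function(rpm = 64, direction = 1) {
  stopifnot(direction %in% c(-1, 1))
  if (is.numeric(rpm) && length(rpm) == 1) {
    stopifnot(rpm >= 0)
    omega_fun <- local({
      w <- rpm * 2 * pi / 60
      function(t) rep_len(w, length(t))
    })
    rpm_tab <- NULL
  } else {
    rpm <- as.matrix(rpm)
    stopifnot(ncol(rpm) == 2, all(rpm[, 2] >= 0),
              !is.unsorted(rpm[, 1], strictly = TRUE))
    sf <- stats::stepfun(rpm[-1, 1], rpm[, 2], right = FALSE)
    omega_fun <- function(t) sf(t) * 2 * pi / 60
    rpm_tab <- rpm
  }
  structure(list(rpm = if (is.null(rpm_tab)) rpm else rpm_tab,
                 direction = direction, omega = omega_fun),
            class = "spin_protocol")
}

#' Rotor frame
#'
#' Radial mounting of the channel on the disc. `r0` is the radial position
#' of the channel's inner end; the channel axis is assumed radial, so a
#' droplet at axial position x sits at radius `r0 + x`. In practice `r0` is
#' obtained by [fit_effective_radius()], which lumps the unknown mounting
#' radius and residual wall effects into one calibration constant.
#'
#' @param r0 Radial position of the channel inner end, mm (>= 0).
#' @return Object of class `rotor_frame`.
#' @export
rotor_frame <- function(r0) {
  stopifnot(is.numeric(r0), length(r0) == 1, r0 >= 0, is.finite(r0))
  structure(list(r0 = r0), class = "rotor_frame")
}

#' Hadamard-Rybczynski mobility factor
#'
#' `H = (1 + kappa) / (2/3 + kappa)` for viscosity ratio
#' `kappa = mu_drop / mu_phase`; tends to 1 in the rigid-sphere limit
#' (pure Stokes drag) and to 3/2 for an inviscid bubble.
#'
#' @param kappa Viscosity ratio (dispersed over continuous), >= 0.
#' @return Mobility factor in \[1, 1.5\].
#' @export
hadamard_rybczynski <- function(kappa) {
  stopifnot(all(kappa >= 0))
  (1 + kappa) / (2 / 3 + kappa)
}

#' Terminal droplet velocity under centrifugation
#'
#' Stokes force balance in the rotating frame with Hadamard-Rybczynski
#' mobility: `v = |drho| omega^2 r d^2 H(kappa) / (18 mu)`, signed so that
#' a denser-than-phase droplet moves outward (positive). Wall retardation
#' is not modeled; it is absorbed into the effective radius calibration.
#'
#' @param drop A [droplet_spec()].
#' @param phase A [phase_spec()].
#' @param omega Rotation rate, rad/s (vectorized).
#' @param r Radial position, mm (vectorized).
#' @return Velocity, mm/s (sign = sign of the density contrast).
#' @export
terminal_velocity <- function(drop, phase, omega, r) {
  stopifnot(inherits(drop, "droplet_spec"), inherits(phase, "phase_spec"),
            all(omega >= 0), all(r >= 0))
  drho <- (drop$specific_gravity - phase$specific_gravity) * 1000  # kg/m^3
  mu <- phase$viscosity_mu * 1e-3                                  # Pa s
  d <- drop$diameter_d * 1e-3                                      # m
  h <- hadamard_rybczynski(drop$viscosity / phase$viscosity_mu)
  v <- drho * omega^2 * (r * 1e-3) * d^2 * h / (18 * mu)           # m/s
  v * 1e3                                                          # mm/s
}

#' Calibrate the effective radius from one observed velocity
#'
#' Inverts the terminal-velocity closed form for the radial position that
#' reproduces one observed (rpm, velocity) pair. This single lumped
#' constant absorbs the unprinted channel mounting radius and residual
#' wall/hindrance effects; predictions at other rotation rates then follow
#' the omega-squared scaling of the centrifugal force.
#'
#' @param rpm Rotation rate of the observation, rev/min (> 0).
#' @param velocity Observed terminal velocity, mm/s (> 0).
#' @param drop A [droplet_spec()].
#' @param phase A [phase_spec()].
#' @return Effective radius, mm.
#' @export
fit_effective_radius <- function(rpm, velocity, drop = droplet_spec(),
                                 phase = phase_spec()) {
  stopifnot(rpm > 0, velocity > 0)
  omega <- rpm * 2 * pi / 60
  v1 <- terminal_velocity(drop, phase, omega, r = 1)
  if (v1 == 0) stop("zero density contrast: effective radius is unidentifiable")
  velocity / abs(v1)
}

#' Droplet trajectory in the rotating channel
#'
#' Integrates the reduced-order axial force balance
#' `m dv/dt = drho V omega(t)^2 r(t) - 18 mu V v / (d^2 H)` with
#' `r(t) = r0 + x(t)` (the centrifugal term grows as the droplet moves
#' outward; set `fixed_r = TRUE` to freeze it at `r0`). Added-mass and
#' history forces are neglected (creeping flow). Integration uses an
#' adaptive solver at relative tolerance 1e-6; the trajectory is truncated
#' (position clamped, velocity zeroed) at the channel end when
#' `channel_length` is given.
#'
#' @param drop A [droplet_spec()].
#' @param phase A [phase_spec()].
#' @param spin A [spin_protocol()].
#' @param frame A [rotor_frame()].
#' @param t_span Length-2 time span, s.
#' @param dt Output sampling interval, s.
#' @param x0,v0 Initial axial position (mm) and velocity (mm/s).
#' @param channel_length Optional channel length, mm; motion stops there.
#' @param fixed_r Freeze the centrifugal radius at `r0`.
#' @return Data frame `time_s, x_mm, v_mm_s`.
#' @export
droplet_trajectory <- function(drop, phase, spin, frame, t_span, dt = 0.01,
                               x0 = 0, v0 = 0, channel_length = NULL,
                               fixed_r = FALSE) {
  stopifnot(inherits(spin, "spin_protocol"), inherits(frame, "rotor_frame"),
            length(t_span) == 2, all(is.finite(t_span)),
            t_span[2] > t_span[1], dt > 0)
  drho <- (drop$specific_gravity - phase$specific_gravity) * 1000
  rho_d <- drop$specific_gravity * 1000
  mu <- phase$viscosity_mu * 1e-3
  d <- drop$diameter_d * 1e-3
  h <- hadamard_rybczynski(drop$viscosity / phase$viscosity_mu)
  beta <- 18 * mu / (d^2 * h)                # drag / (V v), kg m^-3 s^-1
  r0_m <- frame$r0 * 1e-3
  times <- seq(t_span[1], t_span[2], by = dt)
  deriv <- function(t, y, parms) {
    w <- spin$omega(t)
    r <- if (fixed_r) r0_m else r0_m + y[1]
    a <- (drho * w^2 * r - beta * y[2]) / rho_d
    list(c(y[2], a))
  }
  sol <- deSolve::ode(y = c(x = x0 * 1e-3, v = v0 * 1e-3), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-6, atol = 1e-12)
  if (any(!is.finite(sol[, 2:3]))) stop("trajectory integration diverged")
  out <- data.frame(time_s = sol[, 1], x_mm = sol[, 2] * 1e3,
                    v_mm_s = sol[, 3] * 1e3)
  if (!is.null(channel_length)) {
    past <- out$x_mm >= channel_length
    if (any(past)) {
      out$x_mm[past] <- channel_length
      out$v_mm_s[past] <- 0
    }
  }
  out
}

#' Coriolis deflection index
#'
#' Ratio of the Coriolis to the viscous stress scale for flow at rotation
#' rate omega in a channel of width w: `2 rho omega w^2 / mu` (the mean
#' velocity cancels between the two scales and is accepted only for
#' interface compatibility). Larger values mean stronger lateral deflection
#' toward a side wall; low-viscosity phases deflect, viscous ones do not.
#'
#' @param phase A [phase_spec()].
#' @param omega Rotation rate, rad/s.
#' @param mean_velocity Mean axial velocity, mm/s (cancels; ignored).
#' @param channel_width Channel width, mm.
#' @param threshold Deflection flag threshold (default 1).
#' @return List with `index` (dimensionless) and logical `deflecting`.
#' @export
coriolis_index <- function(phase, omega, mean_velocity = NULL,
                           channel_width = 2, threshold = 1) {
  stopifnot(inherits(phase, "phase_spec"), all(omega >= 0),
            channel_width > 0, threshold > 0)
  rho <- phase$specific_gravity * 1000
  mu <- phase$viscosity_mu * 1e-3
  w <- channel_width * 1e-3
  idx <- 2 * rho * omega * w^2 / mu
  list(index = idx, deflecting = idx > threshold)
}
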