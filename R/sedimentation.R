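#' Channel geometry
#'
#' @param length_d0 Channel length d0, mm.
#' @param width Channel width, mm.
#' @param depth Channel depth (optical path), mm.
#' @return Object of class `channel_geometry`.
#' @export
channel_geometry <- function(length_d0 = 41, width = 1, depth = 2) {
  stopifnot(length_d0 > 0, width > 0, depth > 0)
  structure(list(length_d0 = length_d0, width = width, depth = depth),
            class = "channel_geometry")
}

# Steady-state sedimentation indices the suspension presets are calibrated to.
si_endpoints <- c(normal = 0.68, GA_0.01 = 0.64, GA_0.02 = 0.50,
                  patient = 0.63)

#' RBC suspension specification
#'
#' Parameters of the two-front kinematic sedimentation model. Deformability
#' enters solely through the packing fraction of the sedimented bed
#' (`phi_max`): deformable cells pack denser, so the packed column is
#' shorter and the steady sedimentation index `SI = 1 - phi0/phi_max`
#' higher. Settling speed follows Richardson-Zaki hindrance
#' `v = v_ref (omega/omega_ref)^2 (1 - phi0)^n`.
#'
#' @param phi0 Initial RBC volume fraction (0 < phi0 < phi_max).
#' @param phi_max Packing fraction of the bed, in (phi0, 1\].
#' @param v_ref Single-cell settling scale at the reference rotation rate,
#'   mm/s.
#' @param rz_exponent_n Richardson-Zaki hindrance exponent (default 4.65).
#' @param omega_ref_rpm Reference rotation rate for `v_ref`, rev/min.
#' @param label Class label (free text; see [suspension_preset()]).
#' @return Object of class `suspension_spec`.
#' @export
suspension_spec <- function(phi0 = 0.30, phi_max = 0.9375, v_ref = 0.23,
                            rz_exponent_n = 4.65, omega_ref_rpm = 1600,
                            label = "custom") {
  stopifnot(phi0 > 0, phi_max <= 1, v_ref > 0, rz_exponent_n >= 0,
            omega_ref_rpm > 0)
  if (phi0 >= phi_max)
    stop("phi0 must be strictly below the packing fraction phi_max")
  structure(list(phi0 = phi0, phi_max = phi_max, v_ref = v_ref,
                 rz_exponent_n = rz_exponent_n,
                 omega_ref_rpm = omega_ref_rpm, label = label),
            class = "suspension_spec")
}

#' Calibrated suspension presets
#'
#' Presets for the four RBC classes, with packing fractions calibrated so
#' the steady sedimentation index `1 - phi0/phi_max` equals the measured
#' endpoints: normal 0.68, glutaraldehyde-stiffened 0.01% 0.64 and
#' 0.02% 0.50, sickle-cell patient 0.63. The default in-channel hematocrit
#' is 0.30 so all packing fractions stay physical (<= 1).
#'
#' @param label One of `"normal"`, `"GA_0.01"`, `"GA_0.02"`, `"patient"`.
#' @param phi0 Initial volume fraction.
#' @param v_ref Settling scale at the reference rotation rate, mm/s.
#' @return A [suspension_spec()].
#' @export
suspension_preset <- function(label = c("normal", "GA_0.01", "GA_0.02",
                                        "patient"),
                              phi0 = 0.30, v_ref = 0.23) {
  label <- match.arg(label)
  si_inf <- si_endpoints[[label]]
  suspension_spec(phi0 = phi0, phi_max = phi0 / (1 - si_inf),
                  v_ref = v_ref, label = label)
}

#' Sedimentation index
#'
#' `SI = (d0 - d1) / d0`, where d0 is the channel length and d1 the RBC
#' sedimentation column height measured from the channel's outer end.
#' Higher SI means a shorter column, i.e. denser packing and more
#' deformable cells.
#'
#' @param d0 Channel length, mm (> 0).
#' @param d1 Sedimentation height, mm, in \[0, d0\] (vectorized).
#' @return SI in \[0, 1\].
#' @export
sedimentation_index <- function(d0, d1) {
  stopifnot(d0 > 0)
  if (any(d1 < 0) || any(d1 > d0))
    stop("d1 must lie within [0, d0]")
  (d0 - d1) / d0
}

#' Two-front kinematic sedimentation under centrifugation
#'
#' Kynch-style kinematics with two sharp fronts. The clear (plasma)
#' front advances outward from the channel inner end at the hindered
#' settling speed `v = v_ref (omega/omega_ref)^2 (1 - phi0)^n`; the packed
#' bed grows inward from the outer end by cell mass conservation
#' (`phi0 d0 = phi0 (bed - clear) + phi_max (d0 - bed)` at all times).
#' Fronts merge when the suspension zone vanishes; thereafter the state is
#' constant. The sedimentation height d1 is the full RBC-containing column
#' (suspension plus bed), `d1 = d0 - clear_front`, so
#' `SI(t) = clear_front / d0` rises monotonically to the mass-conservation
#' ceiling `1 - phi0/phi_max`.
#'
#' @param spec A [suspension_spec()].
#' @param channel A [channel_geometry()].
#' @param spin A [spin_protocol()] (constant-rate; the rate at t = 0 is
#'   used).
#' @param t_span Length-2 time span, s.
#' @param dt Output sampling interval, s.
#' @return Data frame `time_s, clear_front_mm, bed_front_mm, d1_mm, SI`
#'   with attributes `t_merge` (s) and `si_inf`.
#' @export
settle <- function(spec, channel = channel_geometry(),
                   spin = spin_protocol(1600), t_span = c(0, 3600), dt = 1) {
  stopifnot(inherits(spec, "suspension_spec"),
            inherits(channel, "channel_geometry"),
            inherits(spin, "spin_protocol"),
            length(t_span) == 2, t_span[2] > t_span[1], dt > 0)
  d0 <- channel$length_d0
  omega <- spin$omega(t_span[1])
  omega_ref <- spec$omega_ref_rpm * 2 * pi / 60
  v_s <- spec$v_ref * (omega / omega_ref)^2 * (1 - spec$phi0)^spec$rz_exponent_n
  c_star <- d0 * (1 - spec$phi0 / spec$phi_max)   # clear-front merge position
  time <- seq(t_span[1], t_span[2], by = dt)
  clear <- pmin(v_s * (time - t_span[1]), c_star)
  bed <- d0 - (spec$phi0 / (spec$phi_max - spec$phi0)) * clear
  bed <- pmax(bed, d0 - c_star * spec$phi0 / (spec$phi_max - spec$phi0))
  d1 <- d0 - clear
  out <- data.frame(time_s = time, clear_front_mm = clear,
                    bed_front_mm = bed, d1_mm = d1,
                    SI = sedimentation_index(d0, d1))
  attr(out, "t_merge") <- t_span[1] + if (v_s > 0) c_star / v_s else Inf
  attr(out, "si_inf") <- 1 - spec$phi0 / spec$phi_max
  attr(out, "v_settle") <- v_s
  out
}

#' Virtual sensor occupancy during sedimentation
#'
#' A sensor is covered when its aperture center lies within the
#' RBC-containing column (below the sedimentation height d1, measured from
#' the channel's outer end), and clear when it sits in the separated
#' plasma/PBS zone.
#'
#' @param d1 Sedimentation height, mm from the outer end (vectorized).
#' @param positions_outer Aperture center positions, mm from the outer end.
#' @param d0 Channel length, mm (positions must lie within \[0, d0\]).
#' @return If `d1` is scalar, a character vector (`"covered"`/`"clear"`)
#'   per sensor; otherwise a logical matrix `[length(d1) x n_sensors]`,
#'   TRUE = covered.
#' @export
virtual_sensor_occupancy <- function(d1, positions_outer, d0 = 41) {
  stopifnot(all(positions_outer >= 0), all(positions_outer <= d0),
            all(d1 >= 0), all(d1 <= d0))
  covered <- outer(d1, positions_outer, function(a, p) p < a)
  if (length(d1) == 1)
    return(ifelse(covered[1, ], "covered", "clear"))
  covered
}

#' Fit settling parameters from an observed SI(t) curve
#'
#' Least-squares fit of the two-front model's piecewise-linear
#' `SI(t) = min(v_s t, c_star) / d0` to a (possibly noisy) sedimentation
#' index series, then back-transforms to the physical parameters:
#' `v_ref = v_s / ((omega/omega_ref)^2 (1 - phi0)^n)` and
#' `phi_max = phi0 / (1 - c_star/d0)`. Initial values come from the early
#' slope and the late plateau; refinement is derivative-free (Nelder-Mead).
#'
#' @param time Time vector, s.
#' @param si Observed SI values.
#' @param channel A [channel_geometry()].
#' @param spin A [spin_protocol()].
#' @param phi0,rz_exponent_n,omega_ref_rpm Known model constants.
#' @return List with `v_ref`, `phi_max`, `v_settle`, `si_inf`, `rss`.
#' @export
fit_sedimentation <- function(time, si, channel = channel_geometry(),
                              spin = spin_protocol(1600), phi0 = 0.30,
                              rz_exponent_n = 4.65, omega_ref_rpm = 1600) {
  stopifnot(length(time) == length(si), length(time) >= 4)
  d0 <- channel$length_d0
  omega <- spin$omega(time[1])
  omega_ref <- omega_ref_rpm * 2 * pi / 60
  hind <- (omega / omega_ref)^2 * (1 - phi0)^rz_exponent_n
  plateau <- stats::median(si[time >= stats::quantile(time, 0.8)]) * d0
  early <- si * d0 < 0.5 * plateau & time > time[1]
  v0 <- if (any(early)) stats::median((si * d0)[early] / (time[early] - time[1]))
        else plateau / (max(time) - time[1])
  obj <- function(p) {
    v <- exp(p[1]); cs <- exp(p[2])
    sum((pmin(v * (time - time[1]), cs) / d0 - si)^2)
  }
  fit <- stats::optim(log(c(max(v0, 1e-8), max(plateau, 1e-6))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  v_s <- exp(fit$par[1]); c_star <- exp(fit$par[2])
  list(v_ref = v_s / hind, phi_max = phi0 / (1 - c_star / d0),
       v_settle = v_s, si_inf = c_star / d0, rss = fit$value)
}
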