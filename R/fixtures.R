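# Seeded scenario generators: every detector in the package is testable
# against these ground-truthed traces without any recorded data.

# Run code with a temporary RNG state seeded from `seed` (NULL = leave RNG
# alone), restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a droplet pass over the aperture array
#'
#' Composes [droplet_trajectory()] with [li_signal()]: a droplet released
#' at the channel inner end is driven outward by the centrifugal force,
#' crosses the array, and modulates each sensor through the occlusion /
#' mixed-transmittance model. Additive Gaussian LI noise is applied and
#' clipped. The defaults reproduce the printed characterization
#' experiment: a 1 mm transparent water droplet in blue-dyed 75 cP mineral
#' oil, with the effective radius calibrated to the 64 rpm / 0.9 mm/s
#' observation; the rpm presets {64, 95, 170, 240} mirror that grid.
#'
#' @param rpm Rotation rate, rev/min.
#' @param drop A [droplet_spec()].
#' @param phase A [phase_spec()]; its `medium` must attenuate more than the
#'   droplet's for the pass to register as peaks.
#' @param array A [waveguide_array()].
#' @param noise_sigma Additive Gaussian LI noise s.d. (default 0.005;
#'   0.0125 is the stress tier matching the device's 5% repeat deviation).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param frame A [rotor_frame()]; default calibrated via
#'   [fit_effective_radius()] at (64 rpm, 0.9 mm/s).
#' @param sample_rate Samples per second.
#' @param channel_depth Optical path depth, mm.
#' @param led,ldr Source and detector models.
#' @return List with `trace` (a [sensor_trace()]) and `truth`: aperture
#'   `crossing_times` (s), `mean_velocity` (mm/s, pitch over mean crossing
#'   interval), the full `trajectory`, and the scenario parameters.
#' @export
make_droplet_pass <- function(rpm = 64, drop = droplet_spec(),
                              phase = phase_spec(
                                medium = optical_medium("blue oil", 0.1265)),
                              array = waveguide_array(),
                              noise_sigma = 0.005, seed = NULL,
                              frame = rotor_frame(
                                fit_effective_radius(64, 0.9, drop, phase)),
                              sample_rate = 100, channel_depth = 2,
                              led = led_source(), ldr = ldr_model()) {
  stopifnot(rpm > 0, noise_sigma >= 0)
  spin <- spin_protocol(rpm)
  pos <- aperture_positions(array)
  x_target <- max(pos) + array$aperture_diameter_D1 / 2 +
    drop$diameter_d / 2 + 1
  v_floor <- abs(terminal_velocity(drop, phase, spin$omega(0), frame$r0))
  if (v_floor <= 0) stop("droplet does not move: zero density contrast")
  t_end <- max(1.15 * x_target / v_floor, 5)
  traj <- droplet_trajectory(drop, phase, spin, frame,
                             t_span = c(0, t_end), dt = 1 / sample_rate)
  trace <- li_signal(shadow_trajectory(traj, drop$diameter_d), array,
                     led = led, ldr = ldr,
                     continuous = phase$medium, dispersed = drop$medium,
                     channel_depth = channel_depth,
                     t_span = c(0, t_end), sample_rate = sample_rate,
                     meta = list(rpm = rpm, seed = seed,
                                 noise_sigma = noise_sigma,
                                 scenario = "droplet_pass"))
  if (noise_sigma > 0) {
    noisy <- with_seed(seed, trace$li +
                         matrix(stats::rnorm(length(trace$li), 0, noise_sigma),
                                nrow(trace$li)))
    trace$li[] <- pmin(1, pmax(0, noisy))
  }
  crossing <- stats::approx(traj$x_mm, traj$time_s, xout = pos, ties = "ordered")$y
  pitch <- aperture_pitch(array)
  truth <- list(crossing_times = crossing,
                mean_velocity = pitch / mean(diff(crossing)),
                trajectory = traj, rpm = rpm, pitch = pitch,
                positions = pos, r_eff = frame$r0)
  list(trace = trace, truth = truth)
}

#' Simulate a sedimentation run over virtual sensors
#'
#' Composes [settle()] with [virtual_sensor_occupancy()] and the two
#' plateau light levels of the separated fractions (plasma/PBS 0.9,
#' packed RBC 0.72): each sensor reads the RBC level while inside the
#' sedimentation column and the plasma level once the column has receded
#' past it. Additive Gaussian LI noise is applied and clipped.
#'
#' @param label Suspension class: `"normal"`, `"GA_0.01"`, `"GA_0.02"` or
#'   `"patient"` (see [suspension_preset()]).
#' @param channel A [channel_geometry()].
#' @param positions_outer Aperture centers, mm from the channel outer end;
#'   defaults to the read-out protocol matching the label
#'   ([deformability_protocol()]).
#' @param noise_sigma Additive Gaussian LI noise s.d.
#' @param seed Integer seed.
#' @param spin A [spin_protocol()].
#' @param t_span,dt Simulation span and step, s.
#' @param li_plasma,li_rbc Plateau LI of the clear and RBC fractions.
#' @param phi0,v_ref Suspension parameters passed to [suspension_preset()].
#' @return List with `trace` and `truth` (`states` over time, `d1_mm`,
#'   `SI`, `enabled_counts`, `si_inf`, `label`, the settle series).
#' @export
make_sedimentation <- function(label = "normal",
                               channel = channel_geometry(),
                               positions_outer = NULL,
                               noise_sigma = 0.005, seed = NULL,
                               spin = spin_protocol(1600),
                               t_span = c(0, 1200), dt = 1,
                               li_plasma = 0.9, li_rbc = 0.72,
                               phi0 = 0.30, v_ref = 0.23) {
  spec <- suspension_preset(label, phi0 = phi0, v_ref = v_ref)
  if (is.null(positions_outer))
    positions_outer <- deformability_protocol(
      if (label == "patient") "sickle_screen" else "ga_grading")$positions_outer
  sed <- settle(spec, channel, spin, t_span = t_span, dt = dt)
  covered <- virtual_sensor_occupancy(sed$d1_mm, positions_outer,
                                      d0 = channel$length_d0)
  li <- ifelse(covered, li_rbc, li_plasma)
  if (noise_sigma > 0)
    li <- with_seed(seed, li + matrix(stats::rnorm(length(li), 0, noise_sigma),
                                      nrow(li)))
  li[] <- pmin(1, pmax(0, li))
  trace <- sensor_trace(sed$time_s, li,
                        meta = list(label = label, seed = seed,
                                    noise_sigma = noise_sigma,
                                    rpm = 1600,
                                    positions_outer = positions_outer,
                                    scenario = "sedimentation"))
  truth <- list(states = covered, d1_mm = sed$d1_mm, SI = sed$SI,
                enabled_counts = rowSums(!covered),
                si_inf = attr(sed, "si_inf"), label = label,
                settle = sed, positions_outer = positions_outer)
  list(trace = trace, truth = truth)
}
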