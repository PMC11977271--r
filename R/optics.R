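#' Waveguide aperture array
#'
#' Geometry of a linear array of cone-shaped waveguide apertures positioned
#' along the radial axis of a microchannel, each guiding light onto one
#' light-dependent resistor (LDR). Apertures are indexed inner-to-outer
#' (increasing axial coordinate, 0 at the channel's rotation-center-proximal
#' end).
#'
#' @param n_apertures Number of apertures (typically 2-6).
#' @param aperture_diameter_D1 Top aperture diameter, mm (typical 0.2-1.0).
#' @param base_diameter_D2 Cone base diameter matching the LDR face, mm.
#' @param gap Edge-to-edge gap between adjacent cones, mm (fabrication
#'   minimum 0.3 mm).
#' @param first_center Axial position of the first (innermost) aperture
#'   center, mm from the channel inner end.
#' @param tilt_efficiency Per-aperture static light-collection efficiency in
#'   (0, 1]; oblique cones collect slightly less light than the vertical
#'   center cone. Recycled to `n_apertures`.
#' @return An object of class `waveguide_array`.
#' @examples
#' wa <- waveguide_array(n_apertures = 3, aperture_diameter_D1 = 1, gap = 0.3)
#' aperture_positions(wa)
#' @export
waveguide_array <- function(n_apertures = 3L, aperture_diameter_D1 = 1,
                            base_diameter_D2 = 5, gap = 0.3,
                            first_center = 14,
                            tilt_efficiency = c(1, 0.95, 0.95)[seq_len(n_apertures)]) {
  n_apertures <- as.integer(n_apertures)
  stopifnot(n_apertures >= 1L, aperture_diameter_D1 > 0, gap >= 0,
            aperture_diameter_D1 + gap > 0, base_diameter_D2 > 0)
  tilt_efficiency <- rep_len(tilt_efficiency, n_apertures)
  if (any(!is.finite(tilt_efficiency)) || any(tilt_efficiency <= 0) ||
      any(tilt_efficiency > 1))
    stop("tilt_efficiency must lie in (0, 1]")
  structure(list(n_apertures = n_apertures,
                 aperture_diameter_D1 = aperture_diameter_D1,
                 base_diameter_D2 = base_diameter_D2,
                 gap = gap, first_center = first_center,
                 tilt_efficiency = tilt_efficiency),
            class = "waveguide_array")
}

#' Aperture center positions
#'
#' Axial center positions of the apertures, mm from the channel inner end.
#' Centers form an arithmetic progression with pitch `D1 + gap`.
#'
#' @param array A [waveguide_array()].
#' @return Numeric vector of length `n_apertures`, inner-to-outer.
#' @export
aperture_positions <- function(array) {
  stopifnot(inherits(array, "waveguide_array"))
  pitch <- array$aperture_diameter_D1 + array$gap
  array$first_center + (seq_len(array$n_apertures) - 1) * pitch
}

#' Aperture pitch (center-to-center spacing)
#'
#' @param array A [waveguide_array()].
#' @return Pitch in mm, `D1 + gap`.
#' @export
aperture_pitch <- function(array) {
  stopifnot(inherits(array, "waveguide_array"))
  array$aperture_diameter_D1 + array$gap
}

#' Optical medium with decadic attenuation
#'
#' A fluid characterized by a decadic (base-10) attenuation coefficient, so
#' that transmittance through depth h is `10^(-k h)` (Beer-Lambert; dye
#' concentration and path length are interchangeable).
#'
#' @param name Label.
#' @param decadic_attenuation_k Attenuation coefficient, per mm, >= 0.
#' @return An object of class `optical_medium`.
#' @export
optical_medium <- function(name = "medium", decadic_attenuation_k = 0) {
  stopifnot(is.numeric(decadic_attenuation_k),
            length(decadic_attenuation_k) == 1,
            is.finite(decadic_attenuation_k), decadic_attenuation_k >= 0)
  structure(list(name = name, decadic_attenuation_k = decadic_attenuation_k),
            class = "optical_medium")
}

#' Transmittance of a medium at a path depth
#'
#' @param medium An [optical_medium()].
#' @param depth Path length, mm (vectorized, >= 0).
#' @return Fraction(s) in (0, 1]: `10^(-k * depth)`.
#' @export
transmittance <- function(medium, depth) {
  stopifnot(inherits(medium, "optical_medium"))
  if (any(!is.finite(depth)) || any(depth < 0))
    stop("depth must be finite and >= 0")
  10^(-medium$decadic_attenuation_k * depth)
}

#' Fit an attenuation coefficient from two depth/intensity observations
#'
#' Solves the 2x2 Beer-Lambert system `B * 10^(-k h1) = li1`,
#' `B * 10^(-k h2) = li2` for the attenuation coefficient k and the
#' zero-depth baseline B. Used to calibrate dyed fluids from two channel
#' depths (e.g. a blue dye reading LI 0.74 at 0.08 mm and 0.60 at 0.80 mm).
#'
#' @param li1,li2 Observed light-intensity values in (0, 1].
#' @param h1,h2 Corresponding path depths, mm (`h1 != h2`).
#' @return List with `k` (per mm) and `baseline` (zero-depth LI).
#' @export
fit_attenuation <- function(li1, h1, li2, h2) {
  stopifnot(li1 > 0, li2 > 0, h1 >= 0, h2 >= 0, h1 != h2)
  k <- log10(li1 / li2) / (h2 - h1)
  list(k = k, baseline = li1 * 10^(k * h1))
}

#' Fraction of an aperture occluded by a circular shadow
#'
#' Area of intersection of two coplanar discs (the projected shadow of a
#' droplet or fluid column, and the waveguide aperture) divided by the
#' aperture area, via the standard circular-lens area formula. Both discs
#' lie on the channel axis; only the axial center offset matters.
#'
#' @param shadow_center Shadow center position along the axis, mm (vectorized).
#' @param shadow_diameter Shadow disc diameter, mm.
#' @param aperture_center Aperture center position, mm.
#' @param aperture_diameter Aperture diameter, mm.
#' @return Covered fraction(s) in \[0, 1\]; 1 iff the aperture disc is
#'   contained in the shadow disc, 0 iff the discs are disjoint.
#' @export
occlusion_fraction <- function(shadow_center, shadow_diameter,
                               aperture_center, aperture_diameter) {
  stopifnot(shadow_diameter > 0, aperture_diameter > 0)
  r1 <- shadow_diameter / 2
  r2 <- aperture_diameter / 2
  d <- abs(shadow_center - aperture_center)
  area <- circle_overlap_area(r1, r2, d)
  pmin(1, pmax(0, area / (pi * r2^2)))
}

# Lens area of two circles radius r1, r2 at center distance d (vectorized in d)
circle_overlap_area <- function(r1, r2, d) {
  out <- numeric(length(d))
  disjoint <- d >= r1 + r2
  contained <- d <= abs(r1 - r2)
  out[contained] <- pi * min(r1, r2)^2
  mid <- !disjoint & !contained
  if (any(mid)) {
    dm <- d[mid]
    a1 <- r1^2 * acos(pmin(1, pmax(-1, (dm^2 + r1^2 - r2^2) / (2 * dm * r1))))
    a2 <- r2^2 * acos(pmin(1, pmax(-1, (dm^2 + r2^2 - r1^2) / (2 * dm * r2))))
    s <- (-dm + r1 + r2) * (dm + r1 - r2) * (dm - r1 + r2) * (dm + r1 + r2)
    out[mid] <- a1 + a2 - 0.5 * sqrt(pmax(0, s))
  }
  out
}

#' LED light source with a voltage-to-baseline calibration
#'
#' The LED drive voltage sets the maximum (unoccluded, unattenuated) light
#' intensity a sensor can register. The calibration is a monotone piecewise
#' linear map through user-supplied anchors; the defaults pass through the
#' dark level (0 V, LI 0.02) and full power (3.5 V, LI 0.95).
#'
#' @param voltage Drive voltage, V.
#' @param anchors Two-column matrix or data.frame `(voltage, li)` of
#'   calibration anchors; must be non-decreasing in both columns.
#' @return An object of class `led_source`.
#' @export
led_source <- function(voltage = 3.5,
                       anchors = cbind(voltage = c(0, 3.5),
                                       li = c(0.02, 0.95))) {
  anchors <- as.matrix(anchors)
  stopifnot(ncol(anchors) == 2, nrow(anchors) >= 2,
            !is.unsorted(anchors[, 1], strictly = TRUE),
            !is.unsorted(anchors[, 2]),
            all(anchors[, 2] >= 0), all(anchors[, 2] <= 1),
            voltage >= 0)
  structure(list(voltage = voltage, anchors = anchors), class = "led_source")
}

#' Baseline light intensity of an LED source
#'
#' Evaluates the monotone piecewise-linear voltage calibration at the
#' source's drive voltage (clamped to the anchor range).
#'
#' @param led A [led_source()].
#' @param voltage Optional voltage override, V.
#' @return Baseline LI in \[0, 1\].
#' @export
led_baseline <- function(led, voltage = led$voltage) {
  stopifnot(inherits(led, "led_source"))
  stats::approx(led$anchors[, 1], led$anchors[, 2], xout = voltage,
                rule = 2)$y
}

#' Light-dependent resistor model
#'
#' First-order detector: resistance spans `r_dark` (absolute darkness) to
#' `r_bright` (maximum illumination), with a single-pole response lag. The
#' printed device class responds in 8-12 ms; the default time constant is
#' the 10 ms midpoint.
#'
#' @param response_time_tau Response time constant, s.
#' @param r_dark Resistance in darkness (arbitrary units), > `r_bright`.
#' @param r_bright Resistance at maximum illumination, > 0.
#' @return An object of class `ldr_model`.
#' @export
ldr_model <- function(response_time_tau = 0.010, r_dark = 1e4, r_bright = 100) {
  stopifnot(response_time_tau > 0, r_bright > 0, r_dark > r_bright)
  structure(list(response_time_tau = response_time_tau,
                 r_dark = r_dark, r_bright = r_bright),
            class = "ldr_model")
}

#' Normalize raw LDR resistance to the 0-1 light-intensity scale
#'
#' `LI = (r_dark - r) / (r_dark - r_bright)`, clipped to \[0, 1\]: 0 at
#' absolute darkness, 1 at the maximum illumination achievable at the given
#' LED power. Out-of-range readings are clipped rather than rejected.
#'
#' @param raw_resistance Resistance series (same units as the model's).
#' @param ldr An [ldr_model()].
#' @return LI series in \[0, 1\].
#' @export
normalize_li <- function(raw_resistance, ldr) {
  stopifnot(inherits(ldr, "ldr_model"))
  span <- ldr$r_dark - ldr$r_bright
  if (span <= 0) stop("degenerate calibration: r_dark must exceed r_bright")
  pmin(1, pmax(0, (ldr$r_dark - raw_resistance) / span))
}

#' Sensor trace container
#'
#' Time-stamped per-sensor normalized light-intensity series: the
#' interchange format between the forward simulator and the detectors.
#' Columns align with aperture indices, inner-to-outer.
#'
#' @param time Strictly increasing time vector, s.
#' @param li Numeric matrix `[n_samples x n_sensors]` of LI values in
#'   \[0, 1\] (values beyond by < 1e-6 are clipped).
#' @param meta Named list of scenario metadata (rpm, geometry, seed, ...).
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(time, li, meta = list()) {
  li <- as.matrix(li)
  stopifnot(is.numeric(time), length(time) == nrow(li), length(time) >= 1)
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(!is.finite(li))) stop("li must be finite")
  if (any(li < -1e-6) || any(li > 1 + 1e-6))
    stop("li values outside [0, 1]")
  li[] <- pmin(1, pmax(0, li))
  if (is.null(colnames(li))) colnames(li) <- paste0("li_", seq_len(ncol(li)))
  structure(list(time = as.numeric(time), li = li, meta = meta),
            class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %d samples x %d sensors, t = [%.3g, %.3g] s\n",
              nrow(x$li), ncol(x$li), x$time[1], x$time[length(x$time)]))
  if (length(x$meta)) {
    flat <- vapply(x$meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta:", paste(names(flat), flat, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Forward optical signal of a moving shadow over the aperture array
#'
#' Per sensor, the instantaneous light intensity is
#' `baseline * tilt * ((1 - f) * T_cont + f * T_disp)` where `f` is the
#' occlusion fraction of the aperture by the projected shadow and `T` are
#' the Beer-Lambert transmittances of continuous and dispersed media at the
#' channel depth (area-weighted mixed-pixel rule for partially covered
#' apertures). The result is passed through the LDR's first-order lag and
#' clipped to \[0, 1\].
#'
#' @param trajectory Function of time returning `list(center = , diameter = )`
#'   (mm, vectorized over time): the projected shadow disc. See
#'   [shadow_trajectory()]. A diameter of 0 means no shadow.
#' @param array A [waveguide_array()].
#' @param led A [led_source()].
#' @param ldr An [ldr_model()] (supplies the lag time constant).
#' @param continuous,dispersed [optical_medium()]s of the continuous phase
#'   and the shadow-casting dispersed phase.
#' @param channel_depth Optical path depth of the channel, mm.
#' @param t_span Length-2 time span, s.
#' @param sample_rate Samples per second (default 100; should exceed
#'   `2 / tau`).
#' @param dark_level Additive dark floor LI (default 0).
#' @param meta Extra metadata stored on the trace.
#' @return A [sensor_trace()].
#' @export
li_signal <- function(trajectory, array, led = led_source(),
                      ldr = ldr_model(), continuous = optical_medium(),
                      dispersed = optical_medium("dispersed"),
                      channel_depth = 2, t_span = c(0, 1),
                      sample_rate = 100, dark_level = 0, meta = list()) {
  stopifnot(inherits(array, "waveguide_array"), length(t_span) == 2,
            t_span[2] > t_span[1], sample_rate > 0, channel_depth >= 0,
            dark_level >= 0, dark_level < 1)
  time <- seq(t_span[1], t_span[2], by = 1 / sample_rate)
  if (is.unsorted(time, strictly = TRUE)) stop("time grid must be strictly increasing")
  sh <- trajectory(time)
  center <- rep_len(sh$center, length(time))
  diam <- rep_len(sh$diameter, length(time))
  baseline <- led_baseline(led)
  t_cont <- transmittance(continuous, channel_depth)
  t_disp <- transmittance(dispersed, channel_depth)
  pos <- aperture_positions(array)
  d1 <- array$aperture_diameter_D1
  li <- matrix(0, length(time), array$n_apertures)
  for (j in seq_len(array$n_apertures)) {
    f <- numeric(length(time))
    has <- diam > 0
    if (any(has))
      f[has] <- occlusion_fraction(center[has], diam[has][1], pos[j], d1)
    inst <- dark_level + (baseline - dark_level) * array$tilt_efficiency[j] *
      ((1 - f) * t_cont + f * t_disp)
    li[, j] <- first_order_lag(inst, time, ldr$response_time_tau)
  }
  li[] <- pmin(1, pmax(0, li))
  meta <- utils::modifyList(
    list(sample_rate = sample_rate, channel_depth_mm = channel_depth,
         n_sensors = array$n_apertures), meta)
  sensor_trace(time, li, meta)
}

# Discrete single-pole low-pass: exact exponential update on the sample grid
first_order_lag <- function(x, time, tau) {
  n <- length(x)
  if (n <= 1 || tau <= 0) return(x)
  y <- numeric(n)
  y[1] <- x[1]
  a <- 1 - exp(-diff(time) / tau)
  for (i in 2:n) y[i] <- y[i - 1] + a[i - 1] * (x[i] - y[i - 1])
  y
}

#' Shadow trajectory from a droplet path
#'
#' Builds the `trajectory` argument of [li_signal()] from a time/position
#' table (e.g. a [droplet_trajectory()] result) and a fixed shadow diameter.
#' Positions are interpolated linearly and clamped at the table ends.
#'
#' @param traj Data frame with columns `time_s` and `x_mm`.
#' @param diameter Shadow (droplet) diameter, mm.
#' @param offset Axial offset added to `x_mm` (mm), e.g. the position of the
#'   droplet release point relative to the channel inner end.
#' @return Function of time returning `list(center, diameter)`.
#' @export
shadow_trajectory <- function(traj, diameter, offset = 0) {
  stopifnot(all(c("time_s", "x_mm") %in% names(traj)), diameter >= 0)
  f <- stats::approxfun(traj$time_s, traj$x_mm + offset, rule = 2)
  function(t) list(center = f(t), diameter = rep_len(diameter, length(t)))
}
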