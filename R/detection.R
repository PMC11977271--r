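#' Enabled/disabled state of a sensor under the 5% absorbance rule
#'
#' A sensor is disabled (shadowed) when its light intensity falls at least
#' `threshold` below the baseline. To suppress chatter at the boundary the
#' state is released with hysteresis: a disabled sensor re-enables only
#' when the deficit drops below `threshold / 2`. Applied sequentially along
#' the input, carrying state.
#'
#' @param li LI value(s) in \[0, 1\].
#' @param baseline Baseline LI in \[0, 1\] (clear-sensor reference).
#' @param threshold Detection threshold as an LI difference (default 0.05,
#'   the minimum difference used for detection; must be > 0).
#' @param prev Optional previous state (`"enabled"`/`"disabled"`) to carry
#'   hysteresis across calls.
#' @return Character vector of `"enabled"` / `"disabled"`, one per input.
#' @export
sensor_state <- function(li, baseline, threshold = 0.05, prev = "enabled") {
  if (threshold <= 0) stop("threshold must be positive")
  stopifnot(all(li >= 0), all(li <= 1), baseline >= 0, baseline <= 1,
            prev %in% c("enabled", "disabled"))
  out <- character(length(li))
  state <- prev
  deficit <- baseline - li
  for (i in seq_along(li)) {
    state <- if (state == "enabled") {
      if (deficit[i] >= threshold) "disabled" else "enabled"
    } else {
      if (deficit[i] < threshold / 2) "enabled" else "disabled"
    }
    out[i] <- state
  }
  out
}

#' Detect droplet-passage events in a sensor trace
#'
#' Per sensor, deviations from a rolling-median baseline are thresholded
#' and grouped into excursions; each excursion yields one event (no double
#' counting within a refractory window). Event polarity is auto-selected
#' from the dominant excursion sign (transparent droplets in dyed oil give
#' peaks; dyed droplets in clear oil give troughs). Event time is the
#' amplitude-weighted centroid of the above-threshold samples, which is
#' sub-sample accurate for the symmetric triangular passages this geometry
#' produces.
#'
#' @param trace A [sensor_trace()].
#' @param threshold Minimum |LI deviation| for detection (default 0.05).
#' @param polarity `"auto"`, `"peak"` or `"trough"`.
#' @param baseline_window Rolling-median window, s (default 2). The trace
#'   must be at least this long.
#' @param refractory Minimum separation between events, s (default 0.05);
#'   excursions closer than this are merged.
#' @return Data frame `sensor, time, polarity, amplitude` (0 rows if no
#'   events), ordered by sensor then time.
#' @export
detect_events <- function(trace, threshold = 0.05,
                          polarity = c("auto", "peak", "trough"),
                          baseline_window = 2, refractory = 0.05) {
  stopifnot(inherits(trace, "sensor_trace"), threshold > 0,
            baseline_window > 0, refractory >= 0)
  polarity <- match.arg(polarity)
  time <- trace$time
  dt <- stats::median(diff(time))
  if (time[length(time)] - time[1] < baseline_window)
    stop("trace shorter than the baseline smoothing window")
  k <- max(3L, as.integer(baseline_window / dt) %/% 2L * 2L + 1L)
  k <- min(k, (length(time) - 1L) %/% 2L * 2L + 1L)
  res <- list()
  for (j in seq_len(ncol(trace$li))) {
    x <- trace$li[, j]
    base <- stats::runmed(x, k, endrule = "median")
    dev <- x - base
    pol_j <- if (polarity == "auto") {
      if (max(dev) >= -min(dev)) "peak" else "trough"
    } else polarity
    signed <- if (pol_j == "peak") dev else -dev
    above <- signed >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    # merge excursions separated by less than the refractory window
    if (nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- time[runs[i, 1]] - time[merged[nrow(merged), 2]]
        if (gap < refractory) merged[nrow(merged), 2] <- runs[i, 2]
        else merged <- rbind(merged, runs[i, ])
      }
      runs <- merged
    }
    for (i in seq_len(nrow(runs))) {
      idx <- runs[i, 1]:runs[i, 2]
      w <- signed[idx]
      res[[length(res) + 1]] <- data.frame(
        sensor = j, time = sum(time[idx] * w) / sum(w),
        polarity = pol_j, amplitude = max(w))
    }
  }
  if (!length(res))
    return(data.frame(sensor = integer(), time = numeric(),
                      polarity = character(), amplitude = numeric()))
  out <- do.call(rbind, res)
  out[order(out$sensor, out$time), , drop = FALSE]
}

#' Droplet velocity from inter-aperture event timing
#'
#' Matches events between adjacent sensors greedily in time order (each
#' event on sensor i pairs with the earliest unused later event on sensor
#' i+1) and converts each matched pair to a velocity, distance over elapsed
#' time: `v = pitch / dt`. The summary velocity is the mean over all pairs;
#' unmatched events are reported and excluded.
#'
#' @param events Event table from [detect_events()] (columns `sensor`,
#'   `time`).
#' @param pitch Center-to-center aperture spacing, mm.
#' @return List of class `velocity_estimate`: `velocity` (mean, mm/s),
#'   `pairs` (per-pair table), `n_unmatched`.
#' @export
estimate_velocity <- function(events, pitch) {
  stopifnot(is.data.frame(events), all(c("sensor", "time") %in% names(events)),
            pitch > 0)
  sensors <- sort(unique(events$sensor))
  if (length(sensors) < 2)
    stop("need matched events on at least two sensors")
  pairs <- list()
  unmatched <- 0L
  for (s in sensors[-length(sensors)]) {
    t_from <- sort(events$time[events$sensor == s])
    t_to <- sort(events$time[events$sensor == s + 1])
    used <- logical(length(t_to))
    for (tf in t_from) {
      cand <- which(!used & t_to > tf)
      if (!length(cand)) { unmatched <- unmatched + 1L; next }
      i <- cand[1]
      used[i] <- TRUE
      dt <- t_to[i] - tf
      if (dt == 0) stop("zero inter-sensor interval")
      pairs[[length(pairs) + 1]] <- data.frame(
        sensor_from = s, sensor_to = s + 1L, t_from = tf, t_to = t_to[i],
        dt = dt, velocity = pitch / dt)
    }
    unmatched <- unmatched + sum(!used)
  }
  if (!length(pairs)) stop("no matched event pairs across adjacent sensors")
  pairs <- do.call(rbind, pairs)
  structure(list(velocity = mean(pairs$velocity), pairs = pairs,
                 n_unmatched = unmatched),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("<velocity_estimate> %.4g mm/s (mean of %d pairs, %d unmatched)\n",
              x$velocity, nrow(x$pairs), x$n_unmatched))
  invisible(x)
}

#' Locate a two-phase interface from sensor states
#'
#' With the light-absorbing phase entering from the channel inner end, a
#' monotone state pattern (disabled sensors, then enabled) brackets the
#' interface between the last disabled and first enabled aperture, with
#' half-aperture margins. The sample volume follows from the interface
#' position and the channel cross-section. Non-monotone patterns raise a
#' warning and return the widest consistent bracket.
#'
#' @param states Character vector of `"enabled"` / `"disabled"`, one per
#'   sensor, ordered inner-to-outer.
#' @param positions Aperture center positions, mm from the channel inner
#'   end.
#' @param channel A [channel_geometry()].
#' @param aperture_diameter Aperture diameter D1, mm (half of it is the
#'   bracket margin).
#' @param timestamp Optional time stamp, s.
#' @return List of class `interface_estimate`: `lower_bound`, `upper_bound`
#'   (mm), `position` (point estimate, mm; channel end for an all-disabled
#'   pattern, 0 for all-enabled, bracket midpoint otherwise),
#'   `volume_estimate`, `volume_lower`, `volume_upper` (uL), `timestamp`.
#' @export
locate_interface <- function(states, positions, channel = channel_geometry(),
                             aperture_diameter = 1, timestamp = NA_real_) {
  stopifnot(length(states) == length(positions), length(states) >= 1,
            all(states %in% c("enabled", "disabled")),
            inherits(channel, "channel_geometry"),
            all(positions >= 0), all(positions <= channel$length_d0))
  ord <- order(positions)
  states <- states[ord]; positions <- positions[ord]
  d0 <- channel$length_d0
  half <- aperture_diameter / 2
  dis <- states == "disabled"
  monotone <- !is.unsorted(rev(dis))  # disabled block first, then enabled
  if (all(!dis)) {                    # all enabled: interface below the array
    lower <- 0; upper <- max(0, positions[1] - half); est <- 0
  } else if (all(dis)) {              # all disabled: filled past the array
    lower <- min(d0, positions[length(positions)] + half); upper <- d0
    est <- d0
  } else if (monotone) {
    lower <- positions[max(which(dis))] + half
    upper <- positions[min(which(!dis))] - half
    est <- (lower + upper) / 2
  } else {
    warning("ambiguous interface: non-monotone sensor state pattern")
    lower <- max(0, positions[min(which(!dis))] - half)
    upper <- min(d0, positions[max(which(dis))] + half)
    est <- (lower + upper) / 2
  }
  area <- channel$width * channel$depth  # mm^2; mm^3 == uL
  structure(list(lower_bound = lower, upper_bound = upper, position = est,
                 volume_estimate = est * area, volume_lower = lower * area,
                 volume_upper = upper * area, timestamp = timestamp),
            class = "interface_estimate")
}

#' Deformability read-out protocol presets
#'
#' Two calibrated protocols for grading RBC deformability from enabled-
#' sensor counts during centrifugal sedimentation:
#' \describe{
#'   \item{`ga_grading`}{15-min read; three-level map 2 -> normal,
#'     1 -> GA_0.01, 0 -> GA_0.02 (glutaraldehyde-stiffened grades).}
#'   \item{`sickle_screen`}{10-min read; binary map 1 -> normal (healthy),
#'     0 -> patient_like (sickle-cell-like rigidity).}
#' }
#' Aperture positions are measured from the channel's outer end and differ
#' between protocols (the array mounting is a free design parameter).
#'
#' @param preset `"ga_grading"` or `"sickle_screen"`.
#' @return List with `read_time` (s), `threshold`, `baseline`,
#'   `positions_outer` (mm), `d0` (mm), `map` (named count -> label).
#' @export
deformability_protocol <- function(preset = c("ga_grading", "sickle_screen")) {
  preset <- match.arg(preset)
  if (preset == "ga_grading")
    list(name = preset, read_time = 900, threshold = 0.05, baseline = 0.9,
         positions_outer = c(13.0, 14.3, 15.6), d0 = 41,
         map = c(`2` = "normal", `1` = "GA_0.01", `0` = "GA_0.02"))
  else
    list(name = preset, read_time = 600, threshold = 0.05, baseline = 0.9,
         positions_outer = c(12.3, 13.6, 14.9), d0 = 41,
         map = c(`1` = "normal", `0` = "patient_like"))
}

#' Classify RBC deformability from a sedimentation trace
#'
#' Applies the 5% absorbance rule per sensor against a fixed pre-run
#' baseline, counts enabled sensors at the protocol's read time (averaging
#' LI over a short window around it), and maps the count to a class label
#' through the protocol's calibration. Counts outside the map give
#' `"indeterminate"`. When the read-time state pattern localizes the
#' bed/plasma interface between two apertures, a sedimentation-index
#' estimate is attached.
#'
#' @param trace A [sensor_trace()] whose sensor columns correspond,
#'   in order, to `protocol$positions_outer`.
#' @param protocol A [deformability_protocol()] (or a like-shaped list).
#' @param calibration Optional count -> label map overriding the
#'   protocol's.
#' @param read_window Averaging half-window around the read time, s.
#' @return List of class `deformability_call`: `label`, `enabled_count`,
#'   `enabled_counts` (data frame over time), `si_estimate` (or NA),
#'   `states` at read time, `read_time`.
#' @export
classify_deformability <- function(trace, protocol = deformability_protocol(),
                                   calibration = protocol$map,
                                   read_window = 2) {
  stopifnot(inherits(trace, "sensor_trace"),
            ncol(trace$li) == length(protocol$positions_outer))
  rt <- protocol$read_time
  if (rt < trace$time[1] || rt > trace$time[length(trace$time)])
    stop("read_time outside the trace time span")
  thr <- protocol$threshold
  base <- protocol$baseline
  # per-sample states (no hysteresis needed against a fixed baseline)
  deficit <- base - trace$li
  enabled <- deficit < thr
  counts <- data.frame(time_s = trace$time, enabled = rowSums(enabled))
  sel <- abs(trace$time - rt) <= read_window
  li_rt <- colMeans(trace$li[sel, , drop = FALSE])
  states <- ifelse(base - li_rt >= thr, "disabled", "enabled")
  n_enabled <- sum(states == "enabled")
  label <- if (as.character(n_enabled) %in% names(calibration))
    unname(calibration[[as.character(n_enabled)]]) else "indeterminate"
  # SI estimate: covered (disabled) sensors sit inside the RBC column,
  # so the column height d1 lies between the outermost covered and the
  # innermost clear aperture (positions measured from the outer end).
  pos <- protocol$positions_outer
  covered <- states == "disabled"
  si_est <- NA_real_
  if (any(covered) && any(!covered)) {
    hi <- max(pos[covered]); lo <- min(pos[!covered])
    if (hi < lo) {
      d1_est <- (hi + lo) / 2
      si_est <- sedimentation_index(protocol$d0, d1_est)
    }
  }
  structure(list(label = label, enabled_count = n_enabled,
                 enabled_counts = counts, si_estimate = si_est,
                 states = states, read_time = rt),
            class = "deformability_call")
}

#' @export
print.deformability_call <- function(x, ...) {
  cat(sprintf("<deformability_call> label=%s  enabled=%d at t=%g s  SI~%s\n",
              x$label, x$enabled_count, x$read_time,
              if (is.na(x$si_estimate)) "n/a" else sprintf("%.3f", x$si_estimate)))
  invisible(x)
}
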