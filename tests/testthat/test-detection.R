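test_that("the 5% rule flags shadowed sensors, with hysteresis on release", {
  expect_equal(sensor_state(0.9, 0.9), "enabled")
  expect_equal(sensor_state(0.72, 0.90), "disabled")   # plasma vs RBC contrast
  expect_equal(sensor_state(0.9 - 0.049, 0.9), "enabled")  # below threshold
  expect_error(sensor_state(0.5, 0.9, threshold = 0), "threshold")
  # release requires the deficit to fall below threshold/2
  seqs <- sensor_state(c(0.84, 0.865, 0.88), baseline = 0.9)
  expect_equal(seqs, c("disabled", "disabled", "enabled"))
  # without a prior excursion 0.865 stays enabled
  expect_equal(sensor_state(0.865, 0.9), "enabled")
})

test_that("no events are detected on a flat trace", {
  tr <- sensor_trace(seq(0, 10, 0.01), matrix(0.6, 1001, 3))
  expect_equal(nrow(detect_events(tr)), 0)
  short <- sensor_trace(seq(0, 0.5, 0.01), matrix(0.6, 51, 2))
  expect_error(detect_events(short), "window")
})

test_that("a single droplet pass yields one ordered event per sensor", {
  sim <- make_droplet_pass(rpm = 95, noise_sigma = 0.005, seed = 11)
  ev <- detect_events(sim$trace)
  expect_equal(ev$sensor, 1:3)
  expect_true(all(ev$polarity == "peak"))
  expect_true(all(diff(ev$time) > 0))  # inner to outer
  expect_true(all(ev$amplitude >= 0.05))
})

test_that("well-separated droplets are counted once each", {
  # two synthetic passes rendered as LI dips on three sensors
  t <- seq(0, 30, 0.01)
  li <- matrix(0.8, length(t), 3)
  for (j in 1:3) for (t0 in c(8, 20) + 0.65 * (j - 1))
    li[, j] <- li[, j] - 0.3 * exp(-(t - t0)^2 / (2 * 0.2^2))
  tr <- sensor_trace(t, pmax(li, 0))
  ev <- detect_events(tr)
  expect_equal(as.vector(table(ev$sensor)), rep(2L, 3))
  expect_true(all(ev$polarity == "trough"))
  v <- estimate_velocity(ev, pitch = 1.3)
  expect_equal(v$velocity, 1.3 / 0.65, tolerance = 0.02)
  expect_equal(v$n_unmatched, 0)
})

test_that("raising the threshold never increases the event count", {
  sim <- make_droplet_pass(rpm = 170, noise_sigma = 0.0125, seed = 5)
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.35),
                   function(th) nrow(detect_events(sim$trace, threshold = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("velocity is pitch over elapsed time, averaged across matched pairs", {
  ev <- data.frame(sensor = c(1, 2, 3), time = c(0, 0.1, 0.2),
                   polarity = "peak", amplitude = 0.3)
  expect_equal(estimate_velocity(ev, 1.3)$velocity, 13)
  ev2 <- data.frame(sensor = c(1, 2), time = c(0, 1.3))
  expect_equal(estimate_velocity(ev2, 1.3)$velocity, 1)
  # an extra unmatched event is reported and excluded
  ev3 <- rbind(ev, data.frame(sensor = 3, time = 0.4, polarity = "peak",
                              amplitude = 0.3))
  est <- estimate_velocity(ev3, 1.3)
  expect_equal(est$velocity, 13)
  expect_equal(est$n_unmatched, 1)
  expect_error(estimate_velocity(ev[1, ], 1.3), "two sensors")
})

test_that("interface brackets follow the sensor state pattern", {
  ch <- channel_geometry(40, 2, 1)
  pos <- c(14, 15.3, 16.6)
  all_en <- locate_interface(rep("enabled", 3), pos, ch)
  expect_equal(c(all_en$lower_bound, all_en$upper_bound), c(0, 13.5))
  two_dis <- locate_interface(c("disabled", "disabled", "enabled"), pos, ch)
  expect_equal(c(two_dis$lower_bound, two_dis$upper_bound), c(15.8, 16.1))
  expect_true(two_dis$lower_bound > pos[2] && two_dis$upper_bound < pos[3])
  expect_warning(locate_interface(c("disabled", "enabled", "disabled"), pos, ch),
                 "ambiguous")
})

test_that("a full channel reads as its geometric capacity", {
  ch <- channel_geometry(40, 1, 2)
  full <- locate_interface(rep("disabled", 3), c(14, 15.3, 16.6), ch)
  expect_equal(full$volume_estimate, 80)
  empty <- locate_interface(rep("enabled", 3), c(14, 15.3, 16.6), ch)
  expect_equal(empty$volume_estimate, 0)
})

test_that("interface bracket contains the simulated true interface", {
  ch <- channel_geometry(40, 1, 2)
  pos <- c(10, 14, 18, 22)
  for (truth in c(2, 11, 16, 20.5, 30)) {
    states <- ifelse(pos < truth, "disabled", "enabled")
    est <- locate_interface(states, pos, ch)
    expect_true(est$lower_bound <= truth + 0.5 &&
                  truth - 0.5 <= est$upper_bound,
                label = paste("interface", truth, "in bracket"))
  }
})

test_that("deformability calls recover their own class labels", {
  ga <- deformability_protocol("ga_grading")
  for (lab in c("normal", "GA_0.01", "GA_0.02")) {
    sim <- make_sedimentation(lab, seed = 3)
    call <- classify_deformability(sim$trace, ga)
    expect_equal(call$label, lab)
  }
  sc <- deformability_protocol("sickle_screen")
  pat <- make_sedimentation("patient", seed = 3)
  expect_equal(classify_deformability(pat$trace, sc)$label, "patient_like")
  hea <- make_sedimentation("normal", seed = 3,
                            positions_outer = sc$positions_outer)
  expect_equal(classify_deformability(hea$trace, sc)$label, "normal")
})

test_that("deformability calls attach an SI estimate when the interface is bracketed", {
  sim <- make_sedimentation("GA_0.01", seed = 9)
  call <- classify_deformability(sim$trace, deformability_protocol("ga_grading"))
  expect_equal(call$si_estimate, 0.64, tolerance = 0.02)
  # counts bounded by the sensor count, non-negative
  expect_true(all(call$enabled_counts$enabled %in% 0:3))
})

test_that("out-of-map counts and out-of-span read times are handled", {
  sim <- make_sedimentation("normal", seed = 2)
  proto <- deformability_protocol("ga_grading")
  proto$map <- c(`0` = "GA_0.02")
  expect_equal(classify_deformability(sim$trace, proto)$label, "indeterminate")
  proto2 <- deformability_protocol("ga_grading")
  proto2$read_time <- 1e6
  expect_error(classify_deformability(sim$trace, proto2), "read_time")
})
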