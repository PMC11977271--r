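test_that("aperture centers form an arithmetic progression with pitch D1 + gap", {
  wa <- waveguide_array(3, aperture_diameter_D1 = 1, gap = 0.3, first_center = 0)
  expect_equal(aperture_positions(wa), c(0, 1.3, 2.6))
  expect_equal(aperture_pitch(wa), 1.3)
  expect_equal(aperture_positions(waveguide_array(1, first_center = 7)), 7)
  wa6 <- waveguide_array(6, aperture_diameter_D1 = 0.2, gap = 0.3,
                         first_center = 0, tilt_efficiency = 1)
  expect_equal(aperture_positions(wa6), seq(0, 2.5, by = 0.5))
})

test_that("transmittance follows the decadic exponential law", {
  m <- optical_medium("dye", 0.2)
  expect_identical(transmittance(m, 0), 1)
  expect_error(transmittance(m, -0.1), "depth")
  # multiplicativity over a grid
  g <- expand.grid(a = c(0, 0.05, 0.4, 1, 3), b = c(0, 0.1, 0.8, 2))
  err <- abs(transmittance(m, g$a + g$b) -
               transmittance(m, g$a) * transmittance(m, g$b))
  expect_lt(max(err), 1e-12)
})

test_that("two-depth attenuation fit reproduces its anchors and the dye calibration", {
  fit <- fit_attenuation(0.74, 0.08, 0.60, 0.80)
  m <- optical_medium("blue", fit$k)
  # round trip: the fitted model must pass through both observations
  expect_equal(fit$baseline * transmittance(m, 0.08), 0.74, tolerance = 1e-12)
  expect_equal(fit$baseline * transmittance(m, 0.80), 0.60, tolerance = 1e-12)
  expect_equal(fit$k, 0.1265, tolerance = 1e-3)
  expect_equal(fit$baseline, 0.757, tolerance = 1e-3)
})

test_that("occlusion fraction matches geometry limits and the MC oracle", {
  expect_equal(occlusion_fraction(0, 1, 0, 1), 1)          # concentric, equal
  expect_equal(occlusion_fraction(2, 1, 0, 1), 0)          # disjoint
  expect_equal(occlusion_fraction(0.1, 3, 0, 1), 1)        # aperture inside shadow
  # equal 1 mm discs at 0.5 mm separation (value frozen from the MC oracle)
  expect_equal(occlusion_fraction(0.5, 1, 0, 1), 0.391, tolerance = 1e-3)
  # 20-case grid vs Monte-Carlo
  set.seed(42)
  grid <- expand.grid(shadow_d = c(0.4, 0.7, 1.0, 1.6),
                      sep_frac = c(0.05, 0.3, 0.55, 0.8, 0.98))
  for (i in seq_len(nrow(grid))) {
    sd_ <- grid$shadow_d[i]
    sep <- grid$sep_frac[i] * (sd_ + 1) / 2
    expect_lt(abs(occlusion_fraction(sep, sd_, 0, 1) -
                    mc_occlusion(sep, sd_, 0, 1)), 1e-3)
  }
  # continuity in separation
  seps <- seq(0, 1.2, by = 1e-3)
  f <- occlusion_fraction(seps, 1, 0, 1)
  expect_lt(max(abs(diff(f))), 0.01)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("forward LI signal obeys its closed-form limits", {
  wa <- waveguide_array(3, first_center = 2, gap = 0.3,
                        tilt_efficiency = c(1, 0.95, 0.9))
  clear <- optical_medium("clear", 0)
  led <- led_source(3.5)
  base <- led_baseline(led)
  still <- function(center, diam) function(t)
    list(center = rep_len(center, length(t)), diameter = rep_len(diam, length(t)))
  # no shadow, zero attenuation: LI = baseline * tilt exactly
  tr <- li_signal(still(0, 0), wa, led = led, continuous = clear,
                  dispersed = clear, t_span = c(0, 1))
  expect_equal(unname(tr$li[nrow(tr$li), ]), base * wa$tilt_efficiency,
               tolerance = 1e-12)
  # opaque stationary shadow fully covering sensor 1: steady LI -> 0 there only
  opaque <- optical_medium("opaque", 1e6)
  tr2 <- li_signal(still(2, 1.5), wa, led = led, continuous = clear,
                   dispersed = opaque, t_span = c(0, 1))
  last <- tr2$li[nrow(tr2$li), ]
  expect_equal(unname(last[1]), 0, tolerance = 1e-9)
  expect_gt(last[2], 0.5)
  # always within [0, 1]
  expect_true(all(tr2$li >= 0 & tr2$li <= 1))
})

test_that("LI is non-increasing in channel depth for an absorbing medium", {
  wa <- waveguide_array(1, first_center = 5)
  dye <- optical_medium("dye", 0.13)
  still0 <- function(t) list(center = rep(0, length(t)),
                             diameter = rep(0, length(t)))
  li_at <- vapply(c(0.08, 0.26, 0.46, 0.62, 0.8, 2), function(h) {
    tr <- li_signal(still0, wa, continuous = dye, dispersed = dye,
                    channel_depth = h, t_span = c(0, 0.5))
    tr$li[nrow(tr$li), 1]
  }, numeric(1))
  expect_true(all(diff(li_at) < 0))
})

test_that("first-order detector lag reaches 63.2% of a step after one tau", {
  tau <- 0.01
  time <- seq(0, 0.1, by = 1e-4)
  x <- ifelse(time >= 0.02, 1, 0)
  y <- discsense:::first_order_lag(x, time, tau)
  expect_equal(y[which.min(abs(time - (0.02 + tau)))], 1 - exp(-1),
               tolerance = 1e-2)
})

test_that("resistance normalization is linear, clipped, and rejects degenerate calibration", {
  ldr <- ldr_model(r_dark = 1000, r_bright = 200)
  expect_equal(normalize_li(1000, ldr), 0)
  expect_equal(normalize_li(200, ldr), 1)
  expect_equal(normalize_li(600, ldr), 0.5)
  expect_equal(normalize_li(c(1200, 100), ldr), c(0, 1))  # clipped
  expect_error(ldr_model(r_dark = 5, r_bright = 5), "r_dark")
})

test_that("sensor traces enforce their invariants", {
  expect_error(sensor_trace(c(0, 1, 1), matrix(0.5, 3, 2)), "increasing")
  expect_error(sensor_trace(c(0, 1), matrix(c(0.5, 1.2), 2, 1)), "outside")
  tr <- sensor_trace(c(0, 1), matrix(c(0.5, 1 + 1e-8), 2, 1))
  expect_true(all(tr$li <= 1))
})

test_that("LED calibration is monotone and clamps to the anchor range", {
  led <- led_source(3.5)
  v <- seq(0, 5, by = 0.25)
  b <- led_baseline(led, v)
  expect_true(all(diff(b) >= 0))
  expect_equal(led_baseline(led, 0), 0.02)
  expect_equal(led_baseline(led, 3.5), 0.95)
  expect_equal(led_baseline(led, 5), 0.95)  # clamped
})
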