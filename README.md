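# discsense

Signal models and detectors for optical sensing on centrifugal
microfluidic ("lab-on-a-disc") devices that read the channel through an
array of light-dependent resistors (LDRs) behind sub-millimeter
cone-shaped waveguide apertures. Such devices replace stroboscopes and
high-speed cameras for monitoring droplets, two-phase interfaces and
blood-plasma separation during rotation; their raw output is a per-sensor
normalized light-intensity (LI) time series in [0, 1].

discsense is for engineers and researchers building or analyzing these
sensor arrays. It provides:

* **Forward models** — Beer–Lambert attenuation `T(h) = 10^(-k h)`,
  circle-overlap occlusion of an aperture by a projected droplet shadow,
  LED/LDR calibration with first-order detector lag (`li_signal()`); a
  reduced-order droplet force balance in the rotating frame,
  `m dv/dt = Δρ V ω² r − 18 µ V v / (d² H(κ))` with Hadamard–Rybczynski
  mobility `H` (`droplet_trajectory()`, `terminal_velocity()`); and
  two-front Kynch sedimentation kinematics with Richardson–Zaki hindrance
  for red-blood-cell (RBC) suspensions (`settle()`), where the
  sedimentation index `SI = (d0 − d1)/d0` rises to the mass-conservation
  ceiling `1 − φ0/φmax`.
* **Inverse procedures** — event detection and droplet counting on LI
  traces, velocimetry from inter-aperture timing (`v = pitch / Δt`),
  interface localization and sample-volume monitoring under the 5%
  absorbance rule, and RBC deformability grading from enabled-sensor
  counts (`detect_events()`, `estimate_velocity()`, `locate_interface()`,
  `classify_deformability()`).
* **Seeded synthetic scenarios** with ground truth
  (`make_droplet_pass()`, `make_sedimentation()`), trace CSV/JSON I/O and
  a config-driven pipeline (`run_pipeline()`), plus a thin command-line
  wrapper in `inst/cli/discsense`.

## Worked example

Simulate a 1 mm transparent water droplet crossing a three-aperture array
(D1 = 1 mm, 0.3 mm gaps) in blue-dyed 75 cP oil at 240 rpm, then recover
its velocity from the trace alone:

```r
library(discsense)

sim <- make_droplet_pass(rpm = 240, noise_sigma = 0.005, seed = 42)
ev  <- detect_events(sim$trace)
ev
#>  sensor     time polarity amplitude
#>       1 1.079754     peak 0.3684118
#>       2 1.175874     peak 0.3541142
#>       3 1.271911     peak 0.3517714

estimate_velocity(ev, pitch = aperture_pitch(waveguide_array()))
#> <velocity_estimate> 13.53 mm/s (mean of 2 pairs, 0 unmatched)

sim$truth$mean_velocity
#> [1] 13.509
```

Each sensor fires exactly once as the droplet passes (a transparent
droplet in dyed oil *brightens* the sensor, hence `peak` polarity), the
~0.096 s spacing between adjacent events is the aperture pitch (1.3 mm)
divided by the droplet speed, and the recovered 13.53 mm/s matches the
simulated ground truth within 0.2%.

Grading RBC deformability from a sedimentation run:

```r
sed <- make_sedimentation("GA_0.01", seed = 42)   # mildly stiffened cells
classify_deformability(sed$trace, deformability_protocol("ga_grading"))
#> <deformability_call> label=GA_0.01  enabled=1 at t=900 s  SI~0.635
```

One enabled sensor at the 15-minute read maps to the 0.01%
glutaraldehyde grade, and the bracketed column height yields an SI
estimate of 0.635 against the class's calibrated endpoint of 0.64.

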