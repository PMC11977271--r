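---
title: "Models and methods behind discsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind discsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discsense)
```

discsense models an optical sensing scheme for centrifugal microfluidics:
an array of light-dependent resistors (LDRs), each looking at the channel
through a sub-millimeter cone-shaped waveguide aperture, reads the light
transmitted through the fluid column above it. Anything that darkens the
column over an aperture — a dyed droplet, a two-phase interface, a packed
red-blood-cell (RBC) bed — lowers that sensor's normalized light intensity
(LI, on a 0–1 min/max-resistance scale). The package provides the forward
models that generate such LI traces and the inverse procedures that read
droplet velocities, interface positions, sample volumes and RBC
deformability grades back out of them.

## Forward optical model

Each aperture reports

$$\mathrm{LI} = B \,\eta \left[(1-f)\,T_\mathrm{cont} + f\,T_\mathrm{disp}\right],$$

then passes through a single-pole low-pass with the LDR time constant and
is clipped to [0, 1]. The pieces:

* **Baseline $B$** — the LED voltage-to-LI calibration, a monotone
  piecewise-linear map through anchors (0 V, 0.02) and (3.5 V, 0.95);
  intermediate anchors are user-supplied. `led_baseline()`.
* **Tilt efficiency $\eta$** — a static per-aperture factor in (0, 1]
  (default {1, 0.95, 0.95} for a vertical center cone flanked by two
  oblique ones). Tilting is treated as a calibration constant, not ray
  optics.
* **Transmittances $T$** — decadic Beer–Lambert, $T(h) = 10^{-kh}$ at the
  channel depth $h$. `fit_attenuation()` calibrates $k$ and the zero-depth
  baseline from two depth/LI observations (the bundled blue-dye constant
  $k \approx 0.1265\ \mathrm{mm^{-1}}$ comes from LI 0.74 at 0.08 mm and
  0.60 at 0.80 mm).
* **Occlusion fraction $f$** — the droplet or fluid column is projected as
  a disc of its own diameter onto the aperture plane, offset only along
  the channel axis (the channel width is comparable to the aperture, and
  no lateral information is available), and $f$ is the circle–circle
  intersection area over the aperture area (`occlusion_fraction()`,
  standard circular-lens formula, cross-checked against Monte-Carlo
  integration in the tests).
* **Mixed-pixel rule** — a partially covered aperture mixes the two
  media's transmittances by area weight. This is a modeling choice; real
  edge refraction is not represented.
* **Detector lag** — first-order, $\tau = 10$ ms by default (midpoint of
  the 8–12 ms class of CdS LDRs). Because both sensors of a timing pair
  lag identically, inter-aperture intervals are unaffected.

Default sampling is 100 Hz. Normalization (`normalize_li()`) clips
out-of-range readings instead of erroring, matching how a deployed device
treats sensor jitter at the rails.

## Droplet dynamics

A reduced-order force balance stands in for full two-phase CFD:

$$m \frac{dv}{dt} = \Delta\rho\, V \,\omega^2 r(t) \;-\;
  \frac{18\,\mu\, V}{d^2 H(\kappa)}\, v,$$

with $H(\kappa) = (1+\kappa)/(2/3+\kappa)$ the Hadamard–Rybczynski
mobility for drop/phase viscosity ratio $\kappa$. Added-mass and history
forces are neglected (creeping flow; the velocity relaxation time is
$\sim$1 ms at these parameters). The centrifugal radius advances with the
droplet, $r(t) = r_0 + x(t)$; a fixed-radius mode is a flag. Integration
is adaptive (`deSolve::lsoda`, rtol $10^{-6}$); the steady state matches
the closed-form terminal velocity to well under 0.5%.

Wall retardation in a channel whose width is comparable to the droplet is
substantial but unprinted, so it is absorbed — together with the unknown
mounting radius — into a single effective radius $r_\mathrm{eff}$
calibrated by `fit_effective_radius()` from one observed (rpm, velocity)
pair. Predictions at other rotation rates then follow pure $\omega^2$
scaling. Calibrating to the 64 rpm / 0.9 mm/s observation for a 1 mm
water droplet in 75 cP oil predicts 12.66 mm/s at 240 rpm and 1.98 mm/s
at 95 rpm, within 3% and 1% of the measured 13 and 2 mm/s. The measured
4.8 mm/s at 170 rpm deviates about 30% from $\omega^2$ scaling and is
documented as out-of-model: one lumped constant cannot absorb whatever
(likely transient or geometric) effect produced it. The resulting
$r_\mathrm{eff} \approx 227$ mm exceeds any plausible disc radius
precisely because it also soaks up the strong wall hindrance; it is a
calibration constant, not a geometric claim.

Lateral Coriolis deflection is reduced to a dimensionless index
$2\rho\omega w^2/\mu$ (Coriolis vs viscous stress scale; the mean velocity
cancels), with a configurable "deflecting" threshold at 1 — enough to
rank a 4 cP phase as deflecting where a 34 cP one is not, without any 3-D
field computation.

## Sedimentation kinematics

No mechanistic sedimentation model accompanies the device's RBC
experiments — only endpoint sedimentation indices and photographs — so the
package uses the simplest kinematics consistent with them: a Kynch-style
two-front model. The clear (plasma) front advances from the channel inner
end at the hindered settling speed

$$v_s = v_\mathrm{ref}\,(\omega/\omega_\mathrm{ref})^2 (1-\phi_0)^n,$$

(Richardson–Zaki, $n = 4.65$ default, $\omega_\mathrm{ref} = 1600$ rpm),
while the packed bed grows from the outer end under cell mass
conservation; the fronts merge and the state is constant thereafter. The
sedimentation height $d_1$ is the full RBC-containing column (suspension
plus bed) measured from the outer end, so the sedimentation index
$\mathrm{SI} = (d_0 - d_1)/d_0$ rises monotonically to the
mass-conservation ceiling $1 - \phi_0/\phi_\mathrm{max}$. (Defining $d_1$
as the packed bed alone would make SI fall over time, contradicting both
the measured SI curves and the ceiling; the two definitions coincide at
merge, where the endpoints are read.)

Deformability enters solely through the bed packing fraction
$\phi_\mathrm{max}$: deformable cells pack denser, giving a shorter
column and higher SI. Presets are calibrated to the measured endpoints —
normal 0.68, glutaraldehyde (GA) 0.01% 0.64, GA 0.02% 0.50, sickle-cell
patient 0.63. A nominal 40% hematocrit with $d_0 = 41$ mm and SI 0.68
would require $\phi_\mathrm{max} = 1.25$, which is impossible; the
effective in-channel volume fraction must have been lower (plasma
trapping, filling losses). The default is therefore $\phi_0 = 0.30$,
which keeps every calibrated $\phi_\mathrm{max} \le 0.94$, and $\phi_0$
stays configurable.

$v_\mathrm{ref} = 0.23$ mm/s was fixed once so that, at 1600 rpm, all
four classes plateau within the 60-min experiment, the three GA grades
are already distinguishable at the 15-min read, and the patient curve has
plateaued while the healthy one has not at the 10-min read. The measured
time-lapse photographs are not digitized, so this time scale is a package
choice, not a fit.

## Detection and classification

* **5% rule** (`sensor_state()`): a sensor is disabled when its LI falls
  at least 0.05 below baseline — the plasma (0.9) vs packed-RBC (0.72)
  contrast clears this easily. Release uses threshold/2 hysteresis to
  suppress chatter; the baseline is a rolling median (default 2 s window)
  for dynamic scenarios and a fixed pre-run value for sedimentation
  protocols.
* **Event detection** (`detect_events()`): threshold excursions of the
  deviation from baseline, one event per excursion with a 0.05 s
  refractory merge (half the minimum expected inter-sensor interval);
  polarity auto-selected from the dominant sign. Event time is the
  amplitude-weighted centroid of the above-threshold samples —
  sub-sample accurate on the symmetric triangular passages this geometry
  produces, and robust to additive noise.
* **Velocimetry** (`estimate_velocity()`): greedy time-ordered matching
  of events between adjacent sensors; each pair contributes
  pitch/interval; the mean is reported, unmatched events are excluded and
  counted.
* **Interface and volume** (`locate_interface()`): monotone state
  patterns bracket the interface between the last disabled and first
  enabled aperture with half-aperture margins; volume is position times
  cross-section. Degenerate patterns snap the point estimate to the
  consistent channel end (a fully disabled array reads as a full
  channel). Non-monotone patterns warn and return the widest consistent
  bracket.
* **Deformability** (`classify_deformability()`): enabled-sensor count at
  the protocol read time, mapped through a calibration: `ga_grading`
  (15 min; 2 → normal, 1 → GA 0.01%, 0 → GA 0.02%) and `sickle_screen`
  (10 min; 1 → healthy, 0 → patient-like). Counts outside the map return
  `indeterminate`. Because the hindered settling speed is
  class-independent in this model, pre-plateau columns are identical
  across classes; discrimination relies on plateau order and timing, and
  the two protocols therefore use different array positions
  ({13.0, 14.3, 15.6} and {12.3, 13.6, 14.9} mm from the outer end) —
  consistent with treating the array mounting as a free design parameter,
  which the hardware allows. When the read-time pattern brackets the
  column top between two apertures, an SI estimate is attached.

## Synthetic scenarios and what they do not show

`make_droplet_pass()` and `make_sedimentation()` compose the forward
models, add seeded additive Gaussian LI noise (default $\sigma = 0.005$;
$\sigma = 0.0125$ is the stress tier corresponding to the device's ~5%
repeat deviation) and return ground truth alongside the trace. They
emulate clean single-droplet passes and sharp two-level sedimentation
plateaus. They do not emulate: LDR 1/f noise or temperature drift, motor
vibration, droplet deformation or wall pinning, rouleaux aggregation
kinetics, compressible-bed rheology, or diffuse RBC/plasma interfaces.
Passing round-trip tests therefore demonstrates internal consistency of
the inverse procedures under the stated noise model — not field
performance on real blood.

## Numerical choices

* Problem sizes: traces are sampled at 100 Hz over the natural pass
  duration (about 5–25 s depending on rpm); sedimentation runs use 1 s
  steps over 20 min; parameter-recovery tests use 100 seeded trials.
* Occlusion inverse-cosine arguments are clamped to [−1, 1] and the
  Heron radicand floored at 0 against roundoff at tangency.
* The sedimentation fit (`fit_sedimentation()`) optimizes the
  two-parameter piecewise-linear SI model in log space with Nelder–Mead,
  initialized from the early-time slope and late-time plateau; the model
  is piecewise linear, so a derivative-free search is appropriate.
* Trace CSV I/O keeps 6 decimals (round-trip lossless at LI resolution);
  LI values marginally outside [0, 1] (≤ 0.01) are clipped with a
  warning, larger excursions are errors.
* All randomness flows from a single explicit seed; fixed seed means
  byte-identical traces and reports.

## Known limitations

Single effective wavelength (no RGB/spectral unmixing); no cone-interior
ray tracing (aperture and tilt effects are calibration constants); 1-D
axial occlusion geometry; velocimetry assumes one dominant droplet per
pass window (greedy matching only); the sedimentation model has sharp
fronts and no early-time acceleration; the 170 rpm velocity observation
is outside the one-constant $\omega^2$ model.
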