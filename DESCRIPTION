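Package: discsense
Title: Optical Droplet, Interface and Sedimentation Sensing for
    Lab-on-a-Disc Photodetector Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse signal models for centrifugal microfluidic
    (lab-on-a-disc) devices instrumented with arrays of light-dependent
    resistors behind cone-shaped waveguide apertures. The forward model maps
    droplets, two-phase interfaces and sedimenting red-blood-cell columns in
    a rotating microchannel to per-sensor normalized light-intensity traces
    (Beer-Lambert attenuation, circle-overlap occlusion, first-order detector
    lag). Inverse procedures recover droplet counts and velocities from
    inter-aperture timing, localize fluid interfaces and sample volumes, and
    grade red-blood-cell deformability from sedimentation-index endpoints and
    enabled-sensor counts. A seeded synthetic-scenario generator makes every
    detector testable without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
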