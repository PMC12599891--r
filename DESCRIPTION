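Package: gaitica
Title: Substance-Impairment Classification from Smartphone Gait via
    Gramian Angular Fields and a TICA-Pooled Tiled CNN
Version: 0.1.0
Authors@R: person("gaitica", "developers", role = c("aut", "cre"),
    email = "gaitica@example.org")
Description: Tools to discriminate alcohol- from marijuana-induced gait
    impairment using smartphone inertial sensor recordings.  Raw triaxial
    accelerometer signals are low-pass filtered, cleaned with a Hampel
    outlier filter, segmented into gait cycles at salient minima of the
    signal vector magnitude, validated by normalized cross-correlation
    against a per-recording template, and encoded as Gramian Angular
    Summation Field images.  The images are classified by a tiled
    convolutional network with topographic ICA (TICA) pooling whose
    first-layer filter banks can be pretrained, unsupervised, on abundant
    sober gait samples by a projected line-search descent that maintains
    locality, tile weight tying, and local orthonormality.  A synthetic
    gait generator with class-dependent cadence, sway, and stride-time
    variability makes the full pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
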