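Package: pamffr
Title: Myogenic Artifact Contamination of the Frequency-Following Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying contamination of the
    auditory frequency-following response (FFR) by the postauricular-muscle
    (PAM) startle reflex. Provides click and periodic click-train stimulus
    construction, a synthetic evoked-potential cohort generator with planted
    gaze-dependent PAM artifact and music-training correlation structure,
    epoch preprocessing (zero-phase band-pass and notch filtering,
    amplitude-threshold sweep rejection, ensemble averaging, channel
    subtraction), amplitude/latency/spectral metrics, a convolution model
    that derives FFRs by iterating transient onset responses at the stimulus
    fundamental frequency, and the inferential pipeline (polynomial gaze
    contrasts, partial correlations, regression with variance inflation
    factors, and bootstrap Sobel mediation analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
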