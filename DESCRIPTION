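Package: tremorkit
Title: Quantification of Pathological Tremor from Consumer Accelerometers
Version: 0.1.0
Authors@R: person("Analysis", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying pathological tremor (Parkinson's disease,
    essential tremor) from acceleration time series recorded with consumer
    devices such as smartphones. Implements the standard preprocessing chain
    (demeaning, analysis-window extraction, moving-average downsampling,
    band-limited acceleration-to-displacement conversion), eight time- and
    frequency-domain tremor metrics (RMS amplitude, regularity, 3-7 Hz power
    distribution, median and peak power frequency, two power dispersions,
    harmonic index), method-agreement statistics (Pearson, Bland-Altman,
    Lin's concordance, ICC(2,1), Holm-adjusted contiguous-score t-tests with
    post-hoc power), a 0-5 amplitude-anchored clinical rating scale, and a
    seeded synthetic tremor simulator that renders the same simulated tremor
    through a coarse low-rate "phone" channel and a fine high-rate
    "laboratory" channel for validation studies without hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
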