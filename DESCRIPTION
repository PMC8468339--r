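Package: mrisim
Title: Educational MRI Acquisition Simulation and Learning-Outcome Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A teaching-oriented magnetic resonance imaging (MRI) acquisition
    simulator together with the statistical toolkit needed to evaluate its
    educational impact. The simulator builds synthetic tissue-property
    phantoms (proton density, T1, T2, optional B0 inhomogeneity), reslices
    them onto an arbitrary oblique acquisition grid, evaluates closed-form
    steady-state signal equations for spin-echo, fast spin-echo, spoiled
    gradient-echo and inversion-recovery sequences, and injects classic
    acquisition artifacts in k-space (thermal noise, spikes, periodic-motion
    ghosting, echo-train attenuation, partial-Fourier reconstruction and
    phase wrap-around) before reconstructing magnitude images. The
    evaluation toolkit scores multiple-choice knowledge questionnaires under
    hits and null-expectation ratings, computes KR-20 and Cronbach's alpha
    reliability, selects high-reliability item subsets, and runs pre/post
    two-group inference with normality-gated tests and Cohen's d effect
    sizes, including a calibrated synthetic response generator.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
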