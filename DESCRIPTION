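Package: shearFocus
Title: Shearlet-Based Sharpness Evaluation for Microscope Autofocus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Passive-autofocus sharpness evaluation for medical microscope
    images. Decomposes an image with a non-subsampled shearlet transform
    (a shift-invariant multiscale, multidirectional filter bank), measures
    each sub-band's energy as its coefficient variance, and scores sharpness
    as a weighted ratio of high- to low-frequency energy. Includes the
    classical focus measures used for comparison (Tenengrad, Roberts,
    Laplacian, energy of gradient, DCT, Canny, plain variance), focus-curve
    statistics (min-max normalisation, narrow width at the 40 and 80 percent
    levels, unimodality diagnostics), a noise-immunity test protocol
    (Gaussian, salt-and-pepper and Poisson corruption with optional bilateral
    or guided pre-filtering), and a synthetic focal-stack generator emulating
    sparse cell-like objects under a parametric defocus sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, EBImage, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
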