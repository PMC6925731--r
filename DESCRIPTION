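Package: carostab
Title: Suppression of Probe and Breathing Disturbances for Carotid Wall
    Motion Estimation in B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Preprocessing toolchain for speckle tracking of the common
    carotid artery wall in B-mode ultrasound sequences. Global rigid
    disturbances caused by probe jitter and subject breathing are estimated
    by registering far-from-wall subimages on local phase/orientation
    feature images derived from the monogenic signal, after speckle-reducing
    anisotropic diffusion (SRAD) with an optional longitudinally weighted
    scheme. Frames are aligned by the inverse disturbance and the wall
    motion is recovered by normalized cross-correlation block matching.
    Includes a convolutional speckle simulator with a pulsating
    two-interface vessel wall and known ground-truth motion/disturbance,
    plus evaluation statistics (normalized RMSE, linear regression and
    correlation, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
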