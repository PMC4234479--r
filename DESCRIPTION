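Package: dcamix
Title: Dynamic Color Analysis of Mixing in Opaque pH-Indicating Suspensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the state and time evolution of mixing in stirred
    vessels containing opaque, pH-indicating suspensions (such as blue maize
    flour suspensions, whose native anthocyanins act as a wide-spectrum pH
    indicator) by Dynamic Color Analysis: color readings from images or a
    colorimeter are mapped into a three-dimensional color space (CIELab, HSB
    or RGB) and the Euclidean distance of every sampling location to a final
    mixed-state reference color is tracked over time. Provides grid sampling
    of vessel images, mean and standard-deviation mixedness trajectories,
    polynomial trend fits, an indicator-validity (monotone-decrease) check,
    piecewise Ostwald-de Waele power-law rheology fitting and classification,
    stirred-tank shear-rate estimates, and a fully seeded synthetic
    experiment generator (relaxing pH fields, pH-to-color calibration,
    rendered image sequences with illumination noise, rheometry curves) so
    the entire pipeline can be exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
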