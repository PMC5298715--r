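Package: nirfuse
Title: Nonlinear Wavelet Fusion of RGB and Near-Infrared Images for Fruit
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments orange fruit from leafy backgrounds in registered
    colour/near-infrared image pairs. Both images are decomposed with a
    Daubechies length-4 discrete wavelet transform, detail subbands are
    zeroed to suppress unstructured fruit-coloured background noise, and the
    colour approximation coefficients are enhanced by adding the NIR
    approximation gated by a local-entropy homogeneity weight. The fused
    coefficients are clustered with a seeded C-means algorithm and the fruit
    cluster is reconstructed to full resolution. Includes linear baselines
    (R-B and 2R-G-B vegetation indices, PCA projections, Fisher linear
    discriminant), Otsu thresholding, a pair-counting weighted F-measure,
    fruit identification rates, and a seeded synthetic citrus-scene
    generator with ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
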