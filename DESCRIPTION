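Package: wavefuse
Title: Multiscale Wavelet-Domain Fusion of Multimodal Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-level fusion of co-registered multimodal medical image
    pairs (for example CT with MRI) in the wavelet domain. Implements a
    from-scratch separable 2-D multilevel discrete wavelet transform on
    orthogonal Daubechies filter banks with periodic or symmetric boundary
    handling, the maximum-absolute-coefficient selection fusion rule swept
    over a range of decomposition levels, seven non-reference fusion quality
    metrics (Xydeas-Petrovic edge strength Q, fusion mutual information,
    entropy, standard deviation, blind structural similarity, spatial
    frequency, average gradient), classic comparison methods (averaging,
    PCA-weighted, gradient/contrast/ratio pyramid, shift-invariant Haar
    wavelet fusion), a deterministic synthetic two-modality phantom
    generator, and grayscale PNG/TIFF/PGM input/output with a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
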