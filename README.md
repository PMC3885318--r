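# wavefuse

Pixel-level fusion of co-registered multimodal medical images in the
wavelet domain, for researchers who need to merge complementary
acquisitions — a CT scan showing bone and sharp structure with an MRI
showing soft tissue, an MRA with a T1-weighted MR — into one image that
carries both kinds of information, together with the standard
non-reference metrics used to judge how well a fusion method did.

## The method

Both sources `I1(x, y)` and `I2(x, y)` are decomposed with a separable
2-D discrete wavelet transform (orthogonal Daubechies db3 bank by
default) to level `l`:

    W1^l = DWT[I1],   W2^l = DWT[I2]

Fused coefficients follow the maximum-selection rule — large wavelet
coefficients mark salient structure (edges, boundaries, contours), so at
each position the coefficient of larger absolute value wins, ties going
to the first source:

    WF^l(x,y) = W1^l(x,y)  if |W1^l(x,y)| >= |W2^l(x,y)|
                W2^l(x,y)  otherwise

and the fused image is the inverse transform `F^l = IDWT[WF^l]`. The
decomposition level is a genuine degree of freedom: the sweep runs from
level 2 up to the dyadic capacity `floor(log2(min(H, W)))` — level 8 for
256 × 256 images — and returns one fused image per scale.

The package also implements, from their standard constructions, the
classic comparison methods (pixel averaging, PCA-weighted averaging,
gradient/contrast/ratio pyramid fusion, shift-invariant undecimated Haar
fusion) and seven non-reference quality metrics: Xydeas–Petrovic edge
strength Q, fusion mutual information MI, entropy E, standard deviation
SD, blind structural similarity BSSIM, spatial frequency SF and average
gradient AG. A deterministic phantom generator produces co-registered
two-modality test pairs with known complementary content and the ideal
composite reference, so fusion quality can be measured against ground
truth.

## Worked example

```r
library(wavefuse)

ph <- phantom_pair(size = 128, seed = 1, n_features = 3)
f3 <- fuse_images(ph$modality_a, ph$modality_b, level = 3)
f3$fused_image
#> <image2d> 128 x 128, value_range [0, 255]
#>   intensity min 10.18, max 234.8, mean 59.36

rmse(ph$modality_a, ph$composite_reference)   # 10.78
rmse(ph$modality_b, ph$composite_reference)   # 11.47
rmse(f3$fused_image, ph$composite_reference)  #  1.76
```

Modality A carries thin bright line features, modality B smooth blobs;
each alone misses the other's content (RMSE ≈ 11 against the composite
holding both), while the level-3 fused image recovers nearly everything
(RMSE 1.76).

A full method comparison, one row per method and level:

```r
run_comparison(ph$modality_a, ph$modality_b, level_min = 2, level_max = 5)
#> # A tibble: 9 × 9
#>   method           level     Q    MI     E    SD BSSIM    SF    AG
#>   <chr>            <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 proposed level 2     2 0.917  2.93  2.31  45.6 0.946  27.3  4.54
#> 2 proposed level 3     3 0.909  2.86  3.12  45.7 0.945  27.4  4.64
#> 3 proposed level 4     4 0.883  2.80  4.13  45.9 0.938  27.5  4.77
#> 4 proposed level 5     5 0.916  2.77  5.02  45.8 0.929  27.5  4.88
#> 5 gp                  NA 0.941  2.87  3.48  44.8 0.950  27.3  4.46
#> 6 cp                  NA 0.920  2.82  3.42  45.1 0.950  27.5  4.48
#> 7 rp                  NA 0.905  2.83  3.39  47.0 0.939  25.6  4.40
#> 8 pca                 NA 0.910  2.96  1.74  42.5 0.950  23.7  3.69
#> 9 sidwt-haar          NA 0.938  2.85  3.03  44.1 0.949  27.4  4.47
```

Q and BSSIM score structural transfer from the sources (1 = perfect); MI
is the intensity information shared with both sources in bits; E, SD, SF
and AG describe the richness, contrast and sharpness of the fused image
itself — higher is better throughout. Note how entropy rises with the
decomposition level: deeper scales move more coarse information through
the max rule.

## Command line

```sh
Rscript inst/cli/wavefuse.R phantom --size 256 --seed 7 --out phantoms/
Rscript inst/cli/wavefuse.R fuse --in-a phantoms/modality_a.png \
    --in-b phantoms/modality_b.png --levels 2:8 \
    --methods proposed,gp,cp,rp,pca,sidwt-haar \
    --report report.csv --out fused/
Rscript inst/cli/wavefuse.R metrics --in-a A.png --in-b B.png --fused F.png
```

`fuse` writes every fused image as PNG plus a CSV/JSON report whose rows
and columns mirror the standard fusion benchmark tables (method, Q, MI,
E, SD, BSSIM, SF, AG). Inputs may be 8/16-bit grayscale PNG, TIFF or PGM;
color images are converted to Rec.601 luminance.

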