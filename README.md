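# otoshape

Outline morphometrics of fish otoliths for stock discrimination.

Otoliths (the calcium-carbonate "ear stones" of fish) carry population-
specific outline shapes, so photographs of otoliths can be used to tell which
stock a fish belongs to. `otoshape` turns a folder of calibrated otolith
photographs (bright otolith on a dark background) into independent shape
coefficients and population-level statistics, end to end:

1. **Outline extraction** — each JPEG is converted to grayscale, binarized at
   an intensity threshold, and the otolith's closed boundary is traced with
   Moore-neighbour contour tracing (8-connected, consistently oriented).
   Red-outline overlay images are written for quality control.
2. **Smoothing** — pixel noise is removed by iterating the weighted moving
   average p\_i ← (p\_{i−1} + 2p\_i + p\_{i+1})/4 around the closed contour.
3. **Normalization** — every outline is centred on its centroid, rotated so
   the longest (maximum Feret) axis is horizontal, and scaled to unit area.
4. **Shape coefficients** — two alternative descriptor sets per otolith:
   * *Wavelet*: the radius r(θ) is sampled at 2^10 = 1024 equidistant angles
     counter-clockwise from the 0° radial and decomposed with a periodized
     discrete wavelet transform (Daubechies least-asymmetric filter, 8
     vanishing moments). The scaling coefficient plus detail levels 0–5 give
     **64 coefficients**, each localized in angle along the outline.
   * *Fourier*: normalized elliptic Fourier descriptors of the closed curve
     (x(t), y(t)) with 12 harmonics; dropping the three coefficients fixed by
     the size/rotation/starting-point normalization (a₁, b₁, c₁) leaves
     **45 coefficients** (4·12 − 3).
5. **Allometry** — `std_coefs()` removes the fish-length effect from every
   coefficient by common-slope centring, after omitting coefficients whose
   length slope differs among groups (length × group interaction, P < 0.05,
   optionally Bonferroni-corrected).
6. **Statistics** — constrained ordination of the coefficient matrix by
   population (CAP; with Euclidean distances this is redundancy analysis,
   via `vegan::capscale`), a distance-based permutation ANOVA (pseudo-F,
   add-one p-value convention), cluster plots (group means ± 1 SE on the CAP
   axes), and LDA classification error by cross-validation or bootstrap.

Calibrated size descriptors (Feret length, width, perimeter, area in mm via
the `cal` pixels-per-mm column), per-group mean shapes reconstructed from the
wavelet coefficients, per-angle variance partition (intraclass correlation),
and reconstruction-quality curves are included. A synthetic-fixture module
(`make_project()`, `render_blob()`, `make_coefficient_dataset()`) renders
otolith-like images with planted group and allometry structure so the entire
pipeline can be exercised and validated without any real data.

## Project layout

```
ShapeAnalysis/
├── FISH.csv            # folder, picname (mandatory), length_cm, cal, pop, ...
├── Original/IC/403_1.jpg ...
└── Fixed/IC/403_1.jpg ...     # contrast-fixed copies used for detection
```

`folder`/`picname` link each CSV row to `Fixed/<folder>/<picname>.jpg`.

## Worked example

Fully synthetic, so it runs anywhere:

```r
library(otoshape)

make_project("demo", n_per_group = c(IC = 30, NO = 30, SC = 30),
             seed = 42, width = 500, height = 400,
             length_model = list(mean = 30, sd = 2.5, radius_per_cm = 3.6,
                                 elong_per_cm = 0.004))

shape <- load_project("demo", "FISH.csv")
shape <- detect_outline(shape, threshold = 0.2)   # 90 outlines detected
shape <- smooth_outlines(shape, 100)
shape <- generate_shape_coefficients(shape)       # 90 x 64 and 90 x 45
shape <- enrich_master_list(shape)
shape <- std_coefs(shape, classes = "pop")

group_means(shape, "pop")
#>   group otolith.length otolith.width otolith.perimeter otolith.area
#> 1    IC       2.416480      2.019521          6.938608     3.706294
#> 2    NO       2.468274      2.087528          7.116936     3.860676
#> 3    SC       2.382218      2.030381          6.933311     3.612722

pop <- get_masterlist(shape)$pop
permutation_anova(get_std_wavelet(shape), pop, permutations = 1000, seed = 1)
#> Permutation ANOVA on Euclidean distances (1000 permutations)
#>          Df    Var       F     P
#> Model     2 0.0826 11.7235 0.001
#> Residual 87 0.3066      NA    NA

cap(get_std_wavelet(shape), pop)
#> CAP (Euclidean) with 2 constrained axes
#>   eigenvalues: 6.147 1.206
#>   % of among-group variation: 83.6% 16.4%

lda_error(get_std_wavelet(shape), pop, estimator = "cv", seed = 1)
#> LDA cv misclassification rate: 0.3667 (10 resamples)
```

The mean lengths/areas differ because otolith size is planted proportional to
fish length; the permutation ANOVA recovers the planted third-harmonic group
differences at the smallest attainable p (1/1001, reported as 0.001); CAP
axis 1 carries most of the among-group variation; and the LDA error reflects
the moderate planted effect with three overlapping groups. Reconstruction
quality: `estimate_outline_reconstruction(shape)` reports that wavelet level
3 and 4 Fourier harmonics already reach 98.5 % mean reconstruction accuracy
on these smooth synthetic otoliths.

The whole pipeline can also be driven in one call (`run_workflow()`, with a
YAML config recorded next to the outputs) or from a shell via
`inst/scripts/otoshape.R` (`synth`, `run`, `extract`, `measure`, `analyze`
subcommands).

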