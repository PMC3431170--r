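# lesionsnake

Computerized segmentation and characterization of mass-like breast MRI
lesions, for researchers building or evaluating computer-aided diagnosis
pipelines on 2-D post-contrast images.

The package implements a two-step segmentation:

1. **Fuzzy c-means initialization.** Within a user-drawn rectangular ROI,
   intensities are clustered into lesion and background (c = 2, fuzzifier
   m = 2, stop criterion 5·10⁻⁴ on the membership change, ≤ 100
   iterations). The bright-cluster membership map is thresholded at
   T = 0.5 and cleaned up by hole filling, morphological opening and
   largest-8-connected-component selection.
2. **Gradient vector flow (GVF) snake refinement.** From the edge map
   f(x, y) = |∇I|², the external force field **v** = (u, v) minimizes

   ∬ μ(u_x² + u_y² + v_x² + v_y²) + |∇f|² |**v** − ∇f|² dx dy,  μ = 0.1,

   and a closed snake **x**(s) initialized on the initial-mask boundary
   evolves under F_int = α**x**″(s) − β**x**⁗(s) (α = 0.01, β = 0) and
   F_ext = **v** until force balance.

Each segmented lesion is then characterized by 13 gray-level co-occurrence
(Haralick) texture measures (distance 1, averaged over 0°/45°/90°/135°)
and 8 morphological descriptors built on the radial-length series r_i
(compactness P²/4πS, spiculation (1/N)Σ|r_i − r_{i+1}|, extent,
elongation, solidity, circularity, radial-length entropy, eccentricity).
Benign and malignant lesions are classified by Fisher stepwise
discriminant analysis (Wilks' lambda partial-F entry/removal at
p = 0.10 / 0.15) under leave-one-out cross-validation, with ROC/AUC
analysis and the DeLong paired AUC test. Segmentations are scored against
reference masks with the area overlap ratios AOR₁ = |A_C∩A_R|/|A_R| and
AOR₂ = |A_C∩A_R|/|A_C∪A_R|.

Because clinical images cannot ship with the package, a first-class
synthetic phantom generator (`make_phantom()`, `make_cohort()`) emulates
the study material: star-polygon lesions r(θ) = R(1 + A·cos kθ) with
exact ground-truth masks, rim-enhancement falloff, textural
heterogeneity, boundary blur and noise, in smooth/homogeneous "benign"
vs spiculated/heterogeneous "malignant" classes.

## Worked example

```r
library(lesionsnake)

ph  <- make_phantom(phantom_spec(lesion_class = "malignant", n_spicules = 8L,
                                 spicule_amplitude = 0.1,
                                 texture_heterogeneity = 16,
                                 noise_sigma = 25, seed = 7))
res <- run_lesion(ph$image, phantom_roi(ph$mask))

overlap(res$initial_mask, ph$mask)   # fuzzy c-means initialization
#>   area_c area_r intersection union  aor1  aor2
#> 1    964   1024          951  1037 0.929 0.917
overlap(res$refined_mask, ph$mask)   # after GVF-snake refinement
#>   area_c area_r intersection union  aor1  aor2
#> 1    958   1024          958  1024 0.936 0.936
```

The initialization captures 91.7% of the lesion by Jaccard overlap
(AOR₂); the snake pulls the contour onto the margin and raises it to
93.6%. The feature vector of the refined mask feeds the classifier:

```r
res$features[, c("entropy", "contrast", "p1_compactness",
                 "p2_spiculation", "p5_solidity")]
#>   entropy contrast p1_compactness p2_spiculation p5_solidity
#> 1   6.768  158.104          1.229          0.496       0.903
```

High co-occurrence entropy (heterogeneous enhancement), compactness above
1 and solidity below 1 (irregular, spiculated outline) are the signature
of the malignant class. A full cohort study — segmentation evaluation
against ground truth plus cross-validated classification from both the
computer-segmented and the reference masks — is one call:

```r
study <- run_study(make_cohort(22, 38, seed = 1))
study$evaluation$summary
glance(study$classification$roc_refined)
autoplot(study$classification$roc_refined)
```

A thin command-line front end over the same functions lives in
`inst/cli/lesionsnake.R` (subcommands `phantom`, `segment-init`,
`segment`, `features`, `classify`).

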