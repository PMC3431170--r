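---
title: "Two-step lesion segmentation and characterization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step lesion segmentation and characterization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionsnake)
```

This vignette documents the models behind `lesionsnake`, the parameters
that matter, the numerical decisions taken where the methods leave them
open, what the synthetic phantoms do and do not emulate, and the known
limitations. It states no empirical result that the package's test suite
and acceptance script do not themselves compute.

## The segmentation model

Mass-like lesions on post-contrast breast MRI enhance strongly against
their background, but their margins are blurred by acquisition and
partial-volume effects, and their enhancement is heterogeneous. The
package segments such a lesion in two steps inside a user-supplied
rectangular ROI.

**Step 1 — fuzzy c-means (FCM) initialization.** Pixel intensities in the
ROI are clustered into two fuzzy classes. With memberships $u_{ik}$ and
centers $c_k$, the alternating updates

$$c_k = \frac{\sum_i u_{ik}^m x_i}{\sum_i u_{ik}^m},\qquad
  u_{ik} = \Big(\sum_j (|x_i - c_k| / |x_i - c_j|)^{2/(m-1)}\Big)^{-1}$$

minimize the fuzzified within-cluster distance $J_m=\sum_{k,i} u_{ik}^m
(x_i-c_k)^2$. The lesion is always the cluster with the **higher center**
(contrast enhancement), never a cluster index, so relabeling cannot flip
the result. The bright membership map is thresholded at $T$ with a strict
inequality, holes are filled (4-connected background components not
touching the border), a morphological opening with a radius-1 disk (3×3
cross) removes pixel-scale bridges and protrusions, and the largest
8-connected component is kept. The feature space is scalar intensity
only — deliberately: the initialization is cheap and robust, and its
known failure mode (a slightly undersized region wherever rim
enhancement falls below the membership threshold) is exactly what the
second step corrects.

**Step 2 — GVF snake refinement.** From the edge map
$f = |\nabla I|^2$ (intensities first normalized to $[0,1]$ so that the
weights below are scale-meaningful for any 8-bit input), the gradient
vector flow field $\mathbf v = (u, v)$ minimizes

$$\varepsilon = \iint \mu\,(u_x^2+u_y^2+v_x^2+v_y^2)
  + |\nabla f|^2\,|\mathbf v - \nabla f|^2\,dx\,dy ,$$

i.e. it equals $\nabla f$ where edges are strong and diffuses smoothly
elsewhere, extending the capture range and carrying force into boundary
concavities. A closed curve $\mathbf x(s)$ initialized on the
initial-mask boundary then evolves under the internal force
$\alpha \mathbf x''(s) - \beta \mathbf x''''(s)$ and external force
$\mathbf v$ until the mean point displacement per iteration falls below a
tolerance.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_clusters`, `weighting_exponent` | 2, 2 | FCM classes and fuzzifier |
| `stop_criterion` | 5e-4 | max membership change per FCM iteration |
| `max_iterations` (FCM) | 100 | iteration cap |
| `threshold` T | 0.5 | membership binarization threshold |
| `mu` | 0.1 | GVF regularization (smoothness vs data fidelity) |
| `gvf n_iterations`, `time_step` | 80, 1 | explicit diffusion steps |
| `alpha`, `beta` | 0.01, 0 | snake tension and rigidity |
| `gamma` | 1 | semi-implicit snake step (viscosity) |
| `snake max_iterations`, `convergence_tol` | 400, 0.01 px | balance criterion |
| `presmooth_sigma` | 1 px | Gaussian presmoothing before gradients |
| GLCM `levels` | 64 | gray-level quantization of the co-occurrence matrix |
| `p_enter`, `p_remove` | 0.10, 0.15 | stepwise partial-F thresholds |

The first block (clusters, fuzzifier, stop criterion, iteration cap,
threshold, $\mu$, $\alpha$, $\beta$, the stepwise probabilities) is the
published operating point of the method; the defaults are kept verbatim.
The remaining numerics are this package's choices, discussed next.

## Numerical decisions

**FCM initialization and stop metric.** The method's description leaves
initialization and the convergence metric open. Centers start at the
25th and 75th intensity percentiles of the ROI — deterministic, so runs
are exactly reproducible; a seed is consulted only in the degenerate case
that both percentiles coincide. The stop criterion is interpreted as the
maximum absolute membership change between iterations, the common
convention. Because the feature is scalar intensity, updates are computed
once per distinct gray level and broadcast — algebraically identical to
the per-pixel iteration, and verified against a per-pixel textbook oracle
to 1e-6 in the tests.

**GVF numerics.** The Euler–Lagrange equations are solved by explicit
diffusion from $(u,v)=\nabla f$ with replicated borders. The diffusion
term obeys the stability bound $\Delta t \le 1/(4\mu)$, enforced at
construction; the reaction (data) term is advanced semi-implicitly,
$u \leftarrow (u + \Delta t(\mu\nabla^2u + b\,f_x))/(1+\Delta t\,b)$ with
$b=|\nabla f|^2$, so arbitrarily strong edge maps remain stable. In the
refinement pipeline the edge map is rescaled to unit maximum before
diffusion: the functional weighs the data term by $|\nabla f|^2$, so its
absolute scale decides how strongly edges anchor the field, and without
the rescaling a low-contrast 8-bit image anchors almost nothing.

**Snake discretization.** The classic semi-implicit update
$\mathbf x_{t+1} = (A + \gamma I)^{-1}(\gamma \mathbf x_t +
F_{ext}(\mathbf x_t))$ with the periodic pentadiagonal stiffness matrix
$A$ built from $\alpha,\beta$; it is unconditionally stable in the
internal term. Points are resampled to 1-px arc-length spacing every 10
iterations; self-intersection loops are excised at resampling time (the
shorter arc between two crossing edges is removed), the standard snake
reparameterization. The external force is the **saturated-normalized**
field $\mathbf v / \max(|\mathbf v|, s)$ with floor $s = 0.1$: unit
vectors where the field is strong — bounded, fast steps through the weak
far field between the initialization and the margin — and linear below
the floor, so the zero-crossing at the edge ridge remains a stable
equilibrium. The raw field (`normalize_force = FALSE`) is available; with
it, far-field magnitudes after diffusion are often below 0.05 px per
step, and the snake can stall against the convergence tolerance before
reaching the margin.

**Digital-boundary geometry.** A boundary traced through the centers of
boundary pixels lies half a pixel inside the region under the
pixel-as-square model, so the snake is initialized with a 0.5-px outward
normal offset. Rasterization marks pixels whose centers fall inside the
polygon (even-odd rule), counting centers exactly on the boundary as
inside, which makes mask → contour → mask a near-identity on digital
shapes.

**Texture features.** The co-occurrence matrix is symmetric (both pair
orders counted — direction averaging over 0°/45°/90°/135° presupposes
it), restricted to pixel pairs **both inside the lesion mask**, and
quantized to 64 equal-width bins over the in-mask min–max range. The
quantization level changes feature values and is exposed prominently.
Entropies use the natural log with $0\log 0 := 0$; the inner expression
of the second information measure of correlation is clamped at 0 before
the square root. Sum variance is the variance of the gray-sum
distribution about the sum average, and difference variance the variance
of the gray-difference distribution — the ambiguity in the original
definitions resolved to the common modern reading.

**Shape features.** The perimeter is the chain-code length of the traced
boundary (1 per axial step, $\sqrt2$ per diagonal), which keeps
compactness near 1 for disks at any size but carries an intrinsic
discretization floor: consecutive-radius differences of a perfect digital
disk average about 0.3 px, which is the noise floor of the spiculation
measure, and block-upscaling a mask inflates any chain-code perimeter by
up to $\sqrt2$ on diagonal runs. The circularity descriptor as printed in
its source, $\frac1N\sum (r_i - \mu_r)$, is identically zero; it is
implemented as the mean **absolute** deviation, the only reading that
measures contour irregularity. The radial-length entropy histogram bins
$r_i/\max r_i$ into 10 equal-width bins on $[0,1]$: binning the observed
range instead (e.g. with a $\sqrt N$ rule) makes the entropy *maximal*
for a perfect disk, because pixelation spreads the near-equal radii
uniformly over a sliver-wide range — inverting the intended meaning.
The convex hull for solidity is taken over the four corners of each
boundary pixel, so convex digital shapes (e.g. rectangles) attain
solidity exactly 1. Eccentricity comes from the second-moment-equivalent
ellipse with the standard 1/12 per-pixel variance correction.

**Classifier.** Stepwise selection uses Wilks' lambda partial-F tests
with the two-group formula $F = (n-2-q)(\Lambda_q/\Lambda_{q+1}-1)$ on
$(1, n-2-q)$ degrees of freedom; ties break by column order, making
selection deterministic and row-order invariant. Feature selection runs
**inside every leave-one-out fold** by default — selecting once on all
data and cross-validating only the discriminant fit leaks the held-out
label into selection; that mode (`selection = "full_data"`) is kept for
comparison, and the full-data subset is reported alongside, as study
reports conventionally do. The discriminant is the two-class Fisher rule
$w = \Sigma_{pooled}^{-1}(\mu_{mal} - \mu_{ben})$ with equal priors; the
operating point on the ROC sweep is Youden's J. AUC is trapezoidal over
the threshold sweep, which equals the Mann–Whitney pair-count statistic
with ties counted one half (asserted as an identity in the tests). The
DeLong comparison uses placement-value covariances and a two-sided
z-test; with identical score vectors both the difference and its variance
vanish and p = 1 is returned by convention.

## What the phantoms emulate — and what they do not

`make_phantom()` draws a star polygon $r(\theta) = R(1 + A\cos k\theta)$
— the minimal shape family spanning smooth to spiculated with analytic
control over every morphological descriptor — rasterizes it exactly
(the stored ground-truth mask is never touched by later corruption), and
then builds the image: a darker background; a brighter lesion whose
enhancement fades quadratically toward the rim (`rim_falloff`, default
0.4 — mass enhancement is strongest in the core, and this fade is what
makes an intensity-only clustering cut slightly inside the margin);
multiplicative texture heterogeneity from a smoothed Gaussian field
(correlation length 4 px, the scale of enhancement patchiness rather
than pixel noise); optional patchy background enhancement
(`parenchyma_sd`) with a 4-px peritumoral clearance ramp; Gaussian
boundary blur; additive Gaussian noise; clipping and rounding to 8-bit.

The default cohort conditions (`cohort_params()`) are fixed once:
benign lesions are smooth ($A \le 0.04$) and homogeneous (heterogeneity
2–6 gray levels, enhancement 160–180), malignant lesions carry 6–9
spicules of moderate amplitude 0.07–0.12 with stronger heterogeneity
(12–22) and enhancement (185–210); both classes share radius 14–22 px,
rim falloff 0.3–0.5, blur 1.2 px and noise 25 gray levels. The spicule
amplitudes are deliberately moderate: these are *mass-like* lesions
whose margins undulate, not stellate distortions, and thin high-curvature
spicules are in any case destroyed by the acquisition blur before any
segmenter sees them. All randomness descends from one seed through a
deterministic per-phantom split, so cohorts are bit-reproducible and any
single phantom can be regenerated in isolation.

What passing tests on phantoms do **not** show: the phantoms have a
single lesion per image, stationary Gaussian noise, no bias field or coil
inhomogeneity, no dynamic contrast time dimension, no adjacent enhancing
structures under the default cohort (the `parenchyma_sd` field exists
precisely because confluent parenchymal enhancement is the regime where
both stages degrade together), and pixel units throughout (no physical
calibration — all reported features except area are unit-free ratios).
Performance numbers on phantoms therefore bound the method's behavior
under controlled conditions; they are not clinical performance claims.

## Problem sizes

The test suite and acceptance script are sized for a single CPU: oracle
equivalences run on fixtures up to 64×64; the segmentation batch property
uses a 30-phantom cohort (11 benign / 19 malignant, fixed seed); the
classification experiment uses the full 22/38 cohort layout on 128×128
images; the permutation null uses 15 relabelings of a 28-lesion cohort
and the family-recovery check 8 seeds per signal family; the DeLong
variance check bootstraps a 20-case fixture 2000 times. These sizes are
the package's reporting choices and are stated here so that users scaling
them up know what was actually verified.

## Known limitations

- **Pooled leave-one-out scores are pessimistic under the null.** Holding
  a case out shifts its own class mean away from it, so on label-permuted
  data the LOOCV AUC distribution centers somewhat *below* 0.5 (a known
  property of pooled cross-validated scores). The null check in the tests
  asserts closeness to chance with a band wide enough for this bias; the
  procedure cannot manufacture spurious discrimination, which is the
  scientifically relevant direction.
- **Spicule rounding.** Tension plus curve resampling low-pass the
  contour, so very thin spicules are rounded; past an amplitude of
  roughly 0.15·R (at the default blur) refinement can lose overlap on
  spiculated shapes even as it gains on smooth ones. The snake improves
  the cohort *mean* overlap and the improvement is concentrated where the
  initialization undershoots; it is not a per-lesion guarantee.
- **Chain-code perimeter bias.** Compactness of a digital disk is ~1.1,
  not 1.0; comparisons should be within a fixed rasterization, not across
  resampling schemes.
- **Single closed contour.** No topology changes, balloon forces or GVF
  variants; multi-focal lesions need one ROI per focus.
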