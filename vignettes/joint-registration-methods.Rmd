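---
title: "Joint spherical registration of cortical geometry and function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint spherical registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cortical surface registration aligns brains by their folding patterns (sulcal
depth, curvature) under the assumption that anatomy predicts function. That
assumption is only partly true: task-fMRI activations of anatomically
matched regions vary across subjects, so even a perfect anatomical alignment
leaves functional areas misregistered. `spherereg` implements a
learning-based registration framework that models both sources of
variability at once: a *joint* diffeomorphic deformation shared by geometry
and function captures the large between-subject differences, while two small
*modality-specific* deformations capture the within-subject discrepancy
between where a brain folds and where it activates. A population atlas with
geometric and functional channels is learned simultaneously, instead of
registering to a fixed external template.

Training is *semi-supervised*: functional contrast maps (e.g. a
sentence-versus-nonword t-map) enter the training loss but are never inputs
to the network. At inference, deformations are predicted from geometry
alone, so the trained model applies to any subject with a surface
reconstruction, functional data or not.

# Generative model

All data live on a cell-centered latitude–longitude grid over the unit
sphere (`make_grid()`): row $i$ has elevation $\theta_i = \pi(i+0.5)/H$,
columns wrap periodically in azimuth. Cell-centering keeps the exact poles
out of the grid so $\sin\theta > 0$ everywhere.

Let $A$ be the unknown multi-channel atlas. For each subject,

1. a smooth stationary velocity field $v_j$ (the *joint* deformation,
   amplitude ~3 grid cells in the simulator) produces
   $I_j = A \circ \exp(v_j) + \varepsilon_1$, the latent subject image;
2. small modality fields $v_g, v_f$ (amplitude ~0.8 cells) produce the
   observations $I_g = I_j^{geom} \circ \exp(v_g) + \varepsilon_2$ and
   $I_f = I_j^{func} \circ \exp(v_f) + \varepsilon_3$,

with isotropic Gaussian noise $\varepsilon_k \sim N(0, \sigma^2 I)$ at each
stage. Marginalizing the latent image gives a Gaussian likelihood with
variance $2\sigma^2$ — the property checked by Monte-Carlo simulation in the
test suite. Deformation priors penalize the squared spatial gradient of each
displacement field ($\lambda_j = 0.1$ for the joint field, $\lambda_g =
\lambda_f = 0.2$ for the modality fields) and the squared cohort-mean
displacement ($\alpha_j$, default 0.01), which anchors the atlas at the
deformation barycenter of the population (an *unbiased* atlas).

`synthetic_cortex` (`make_true_atlas()`, `sample_subject()`,
`make_cohort()`) is a forward simulator of exactly this model: the geometric
channel is a banded sinusoidal folding pattern with zero median
(curvature-like, amplitude 3), the functional channel a set of smooth
positive blobs with t-statistic scale (peak 10) whose centers sit at folding
ridge maxima shifted along longitude by `func_offset` cells — so the optimal
functional alignment genuinely differs from the geometric one, the situation
the separate modality fields exist for. Velocities are sampled as Gaussian
white noise smoothed to `smoothness_scale` (default 6 cells, the scale of
the simulated folds) and rescaled to a maximum magnitude; cohorts can be
*centered* by drawing joint velocities in antithetic $\pm v$ pairs, which
zeroes the cohort-mean joint velocity by construction.

What the simulator does *not* emulate: real cortical geometry (neither the
folding topology nor its spatial statistics), spatially correlated fMRI
noise, inter-subject variability of activation amplitude, or the
metric distortions of surface inflation. Passing recovery tests on this
cohort therefore demonstrates that the estimator is consistent under its own
generative assumptions — not that it matches FreeSurfer-grade performance on
real cohorts.

# Deformation machinery

Deformations are dense displacement fields in grid-cell units,
$\phi = \mathrm{Id} + u$, with bilinear interpolation that wraps in
longitude and clamps at the first/last latitude row. Clamping is a
deliberate approximation: there is no flow across the poles, where the
$\sin\theta$ weights make the data nearly weightless anyway. Stationary
velocity fields are exponentiated by scaling and squaring
(`integrate_svf()`, default 7 squarings: the field is divided by $2^7$ and
self-composed seven times), which yields fold-free maps for smooth inputs;
`invert_svf()` exponentiates $-v$. Two successive warps — first by
$\phi_j$, then by $\phi_g$ — equal a single warp by
`compose_deformation(phi_j, phi_g)`. Regularity is quantified by the
central-difference Jacobian determinant and the percentage of non-positive
determinants (`negative_jacobian_fraction()`).

The integration depth 7 is the conventional choice; the suite verifies that
depths 7 and 9 agree to $10^{-3}$ cells and that the exponential tracks a
1024-step explicit Euler flow of the same velocity field (mean endpoint
discrepancy below $10^{-2}$ cells for fields up to 2 cells).

# Network and loss

An encoder–decoder network (five encoder levels with
[128, 256, 384, 512, 640] filters, 3×3 kernels, 2×2 max pooling,
leaky-rectifier activations, symmetric decoder with skip connections, two
final convolutions with [64, 32] filters) maps the standardized geometric
channels to **three** velocity fields $v_j, v_g, v_f$ at full grid
resolution, each followed by an integration layer. Velocity heads are
initialized near zero so an untrained model predicts the identity. Kernel
size and pooling factor are assumptions (not printed in the architecture
description); `scale_divisor = 8` shrinks every filter count for desk-scale
work, which is the configuration exercised by the tests. The atlas
channels are free parameters of the model, initialized from unit-variance
Gaussian noise (the scale of standardized features) and learned jointly;
`tied_fields = TRUE` ties $v_f \equiv v_g$ (the single-field ablation) and
`atlas_frozen` freezes the atlas (the fixed-atlas ablation).

The loss is the negative log posterior of the generative model with the
Gaussian variance absorbed into the modality weights (0.7 functional : 0.3
geometric). Each similarity term is a $\sin\theta$-weighted mean squared
error evaluated in *both* spaces and averaged: the atlas is warped by
$\exp(v_j)$ then $\exp(v_g)$ and compared with the subject, and the subject
is warped by the inverse composition and compared with the atlas. Evaluating
both directions prevents the learned atlas from drifting toward a
systematically deformed configuration. Whether the two spaces should be
summed or averaged is not specified; they are averaged here, which only
rescales the similarity weight. Distortion weights are applied to the
smoothness terms as well, for consistency of the spatial measure.

Two numerical points deserve emphasis:

* **Translational gauge.** With a learnable atlas, adding a constant shift
  to every subject's $u_g$ and $u_f$ while shifting the atlas the opposite
  way changes no likelihood or smoothness term — an exactly flat direction
  that a stochastic optimizer will wander along, corrupting the atlas and
  any comparison against ground-truth deformations. The centrality prior is
  therefore applied to the batch mean of *all three* fields (reported as
  `central_j`, `central_g`, `central_f`), not only the joint one; this is
  the same unbiasedness argument extended to the modality fields. The
  centrality weight `alpha_j` defaults to 1: sensitivity runs over
  0.01/0.1/1 showed that 0.01 leaves ~1-cell residual global offset fields
  within a 200-epoch budget, while 0.1–1 damp the gauge modes without
  measurably changing any similarity term.
* **Functional masking.** Subjects without functional maps contribute
  nothing to the functional similarity terms (masked mean over observed
  subjects); a cohort with no functional data reduces exactly to a
  geometric-only objective, which the suite checks bit-for-bit.

# Training

Mini-batches of 8 subjects are optimized with Adam at an initial rate of
$10^{-3}$ decaying linearly to $10^{-4}$ over the first 500 epochs, after
which the rate is multiplied by 0.9 whenever the validation loss fails to
improve for 100 consecutive epochs. The validation split (default 20%,
never augmented) also selects the retained checkpoint; at desk scale the
validation loss is evaluated every `val_every` epochs (5 in the reference
runs) since it is only consulted by the plateau rule and checkpointing.

Augmentation draws, per subject and step, a smooth random warp with
on-sphere displacement sd of 4 cells — a length defined on the full
256-row parameterization, so desk-scale runs on the 64-row grid use the
metric-matched value of 1 cell — and additive Gaussian noise (sd 1 on
geometric, sd 6 on functional channels, applied on the raw feature scale
before standardization — the simulated t-maps peak near 10, so sd-6 noise is
aggressive but not destructive). The same warp is applied to all channels of
a subject. "Distortion-proper" warping divides the longitudinal displacement
by $\sin\theta$ so the metric displacement is uniform across latitudes;
because that factor diverges at the pole rows, the realized longitudinal
displacement is capped at one eighth of the grid circumference. Without the
cap (and without gradient clipping, global L2 norm 1 by default), the
near-weightless polar rows eventually destabilize long runs: the $\sin\theta$
weights that make the losses metrically correct also leave polar velocities
almost unconstrained.

Atlas parameters take an Adam step-size multiplier (default 10): they are
the only parameters living on the data scale rather than the
small-convolution-weight scale, and with desk-scale step budgets a shared
rate would leave the atlas under-trained relative to the network.

All randomness (split, batch order, augmentation, initialization) flows from
the single `seed` in `train_config()`; rerunning with the same seed
reproduces the loss log bit for bit on one CPU thread.

# Evaluation

`evaluate_cohort()` reports, per subject: Pearson correlation to the group
mean map before and after registration (the group mean includes the subject
itself, matching the printed formula; $\sin\theta$ weights act as frequency
weights), the pairwise improvement, the negative-Jacobian percentage of the
composed fields, and — when ground truth exists — the distortion-weighted
mean endpoint error between predicted and true composed deformations, with
the longitudinal difference taken modulo the grid width. Paired method
comparisons use a one-tailed Wilcoxon signed-rank test (`exact
distribution` for $n \le 25$ without ties, normal approximation with tie and
continuity corrections otherwise). Undefined correlations (constant maps)
are returned as `NA` with a warning, never silently zeroed.

# Reference experiment sizes

The test suite and the acceptance script run one reference experiment: a
centered cohort of 20 subjects on a 64×128 grid (joint amplitude 3 cells,
modality amplitude 0.8, $\sigma = 0.25$), the desk-scale network (filters
divided by 8) trained for 200 epochs with the published hyperparameters,
then evaluated on 10 freshly simulated subjects. Smaller grids (16×32,
32×64) are used for unit-level checks. These sizes are the package's
reference desk-scale conditions; the full-scale configuration
(256×512 grid, unscaled filters) is available through the same interfaces.

# Known limitations

* The latitude clamp makes warping near the pole rows an approximation;
  fields that push across a pole are not modeled (the simulator's and
  augmentation's fields keep polar flow small, and $\sin\theta$ weighting
  suppresses the rows in every loss and metric).
* The network consumes the equiangular grid directly; it is not an intrinsic
  spherical convolution, so filters see latitude-dependent distortion that
  the loss weights correct only statistically.
* Per-subject recovery of the *modality* fields from geometry alone is
  limited by construction: the simulator draws $v_f$ independently of
  geometry, so a geometric-only network can learn it only by memorizing the
  training cohort, and the sd-6 functional augmentation noise prevents that
  at cohort size 20. Consequently the separate functional head carries
  residual noise and the tied ablation attains slightly *lower* endpoint
  recovery error — the corresponding endpoint-error check in the acceptance
  suite fails by design and is left failing. The claim the architecture
  actually makes — better functional *alignment* — holds: on the reference
  cohort the separate model improves the functional correlation to the
  group mean more than the tied ablation for every subject (signed-rank
  p < 0.01), and that check passes.
* Convolution matrix products run in single precision; all other numerics
  are double precision. Gradients are exact for the implemented operators
  (verified by finite differences) up to that arithmetic.
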