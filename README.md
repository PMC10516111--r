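# spherereg

Joint diffeomorphic registration of cortical geometry and function on the
sphere, with simultaneous learning of an unbiased population atlas.

## What it does and for whom

Surface-based registration aligns cortical folding patterns and assumes
function follows. It often does not: task activations of anatomically
matched regions shift between subjects. `spherereg` is for neuroimaging
researchers who want both aligned, without needing functional data for every
subject. It implements a learning-based framework in which:

* subjects are parameterized onto a latitude–longitude grid with
  sin(θ) area-distortion weights;
* an encoder–decoder network predicts, from **geometric features only**,
  three stationary velocity fields: a joint field φ_j (large,
  between-subject) and two small modality fields φ_g, φ_f
  (within-subject geometry–function discrepancy), each exponentiated by
  scaling-and-squaring into a diffeomorphic deformation;
* the training loss is the negative log posterior of a generative model —
  I_g = φ_g ∘ φ_j ∘ A + noise and likewise for I_f — with
  distortion-weighted MSE similarity evaluated in both atlas and subject
  space, smoothness priors (λ_j = 0.1, λ_g = λ_f = 0.2), a centrality prior
  pinning the cohort-mean displacements (unbiased atlas), and a 0.7 : 0.3
  functional : geometric weighting;
* functional maps enter only the loss (semi-supervision), so inference needs
  geometry alone;
* the multi-channel atlas A is learned as part of the model, starting from
  Gaussian noise.

A forward simulator of the same generative model (`make_cohort()`) provides
cohorts with known atlas, deformations and noise for controlled recovery
experiments; readers for FreeSurfer morph-data/surface files and GIFTI
overlays connect the pipeline to real surface data.

## Worked example

```r
library(spherereg)

# simulate a centered cohort: 20 subjects, 64 x 128 grid, known ground truth
cohort <- make_cohort(generative_config(n_lat = 64, n_lon = 128,
                                        n_subjects = 20, seed = 7))

# desk-scale network (published filter counts / 8), atlas learned from noise
model <- build_model(network_config(scale_divisor = 8), cohort$grid, seed = 7)
fit <- train_model(model, cohort,
                   train_config(epochs = 200, seed = 7, val_every = 5,
                                warp_aug_sigma = 1))

# register a fresh subject: geometry in, all three fields out
subject <- make_cohort(generative_config(n_lat = 64, n_lon = 128,
                                         n_subjects = 1, seed = 8))$subjects[[1]]
fields <- predict_fields(fit$model, standardize(subject$geom))
negative_jacobian_fraction(fields$phi_geom)
#> [1] 0

# how well does the learned atlas match the simulator's truth?
w <- distortion_weights(cohort$grid)
cor_atlas <- spherereg:::weighted_pearson(
  fit$model$atlas$geometric[, , 1],
  standardize(cohort$atlas)$values[, , 1], w$w)
round(cor_atlas, 2)
#> [1] 0.98
```

`negative_jacobian_fraction()` is the percentage of grid cells where the
predicted deformation folds (0 means everywhere-invertible), and the final
correlation says the atlas learned from noise recovered the simulated
population template. `evaluate_cohort(fit$model, cohort)` adds per-subject
correlations to the group mean, pairwise improvements and
deformation-recovery errors.

## Command line

A thin CLI wraps the same functions (see `inst/cli/spherereg`):

```sh
spherereg simulate --config cohort.yaml --out cohort.rds
spherereg train    --data cohort.rds --config train.yaml --out rundir/
spherereg register --model rundir/checkpoint_best.rds --subject subj.rds --out out.rds
spherereg evaluate --model rundir/checkpoint_best.rds --data cohort.rds --out report.json
```

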