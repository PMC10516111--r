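# Reference study conditions shared by the acceptance checks: a centered
# synthetic cohort of 20 subjects on a 64 x 128 grid, and the desk-scale
# network (published filter counts divided by 8) trained for 200 epochs with
# the published hyperparameters. Training runs once per session and is
# cached.

.ref_cache <- new.env(parent = emptyenv())

reference_generative_config <- function(n_subjects = 20L, seed = 7L) {
  generative_config(n_lat = 64L, n_lon = 128L, n_subjects = n_subjects,
                    joint_amplitude = 3.0, modality_amplitude = 0.8,
                    sigma_noise = 0.25, seed = seed)
}

reference_run <- function() {
  if (is.null(.ref_cache$fit)) {
    cohort <- make_cohort(reference_generative_config())
    model <- build_model(network_config(scale_divisor = 8), cohort$grid,
                         n_geom_channels = 1, n_func_channels = 1, seed = 7)
    tc <- reference_train_config()
    .ref_cache$cohort <- cohort
    .ref_cache$fit <- train_model(model, cohort, tc)
  }
  list(fit = .ref_cache$fit, cohort = .ref_cache$cohort)
}

# Single-field ablation (v_f tied to v_g) on the same cohort; cached like
# the reference run.
tied_run <- function() {
  if (is.null(.ref_cache$tied_fit)) {
    ref <- reference_run()
    tied_model <- build_model(network_config(scale_divisor = 8,
                                             tied_fields = TRUE),
                              ref$cohort$grid, 1, 1, seed = 7)
    .ref_cache$tied_fit <- train_model(tied_model, ref$cohort,
                                       reference_train_config(epochs = 100L))
  }
  .ref_cache$tied_fit
}

heldout_cohort <- function(n = 10L) {
  make_cohort(reference_generative_config(n_subjects = n, seed = 8L))
}

# Desk-scale training conditions: published hyperparameters, with the
# augmentation warp sd converted to this grid's resolution (the printed
# 4-cell sd lives on the full 256-row parameterization; 64/256 * 4 = 1).
reference_train_config <- function(epochs = 200L, seed = 7L, ...) {
  train_config(epochs = epochs, batch_size = 8L, seed = seed,
               val_every = 5L, warp_aug_sigma = 1, ...)
}
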