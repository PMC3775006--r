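# Shared small fixtures, built once per test session.

.fx <- new.env(parent = emptyenv())

fx_head <- function() {
  if (is.null(.fx$head)) .fx$head <- head_model()
  .fx$head
}

fx_grid <- function(spacing = 14) {
  key <- paste0("grid", spacing)
  if (is.null(.fx[[key]])) .fx[[key]] <- build_source_grid(fx_head(), spacing)
  .fx[[key]]
}

fx_montage <- function(n = 32) {
  key <- paste0("mon", n)
  if (is.null(.fx[[key]])) .fx[[key]] <- default_montage(n, fx_head())
  .fx[[key]]
}

fx_leadfield <- function(spacing = 14, n = 32) {
  key <- paste0("lf", spacing, "_", n)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- lead_field(fx_head(), fx_montage(n), fx_grid(spacing))
  .fx[[key]]
}

fx_laura <- function(spacing = 14, n = 32, alpha = 3e-4) {
  key <- paste0("op", spacing, "_", n, "_", alpha)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- laura_inverse_operator(fx_leadfield(spacing, n),
                                         laura_config(alpha = alpha))
  .fx[[key]]
}

# single-voxel grid at an arbitrary position (mm)
point_grid <- function(pos) {
  structure(list(pos = matrix(pos, 1, 3), spacing = NA_real_,
                 radius = min(fx_head()$radii), center = c(0, 0, 0),
                 n = 1L),
            class = "source_grid")
}

# small zero-noise simulated dataset, cached
fx_dataset_clean <- function() {
  if (is.null(.fx$ds_clean)) {
    cfg <- sim_config(n_subjects = 4, n_channels = 32, sampling_rate = 250,
                      n_trials_per_condition = 2, noise_sd = 0, brain_noise_sd = 0,
                      blink_rate = 0, latency_jitter_sd = 0,
                      amplitude_lognorm_sd = 0, seed = 42)
    .fx$ds_clean <- simulate_dataset(cfg)
  }
  .fx$ds_clean
}
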