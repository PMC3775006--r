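#' Analysis configuration
#'
#' Presets for the two analysis families. `lep` analyses the laser
#' evoked potential proper: epochs -300..800 ms around laser onset,
#' 2-35 Hz zero-phase band-pass, baseline -300..0 ms, source volumes
#' over -100..600 ms, statistics in 100..450 ms. `peristim` analyses
#' the interval around laser onset: epochs -800..700 ms, 0.1-30 Hz,
#' baseline -800..-500 ms, statistics in -500..100 ms, group-map
#' threshold T = 50.
#'
#' The default profile is desk-scale (8 subjects, 64 channels, 500 Hz,
#' 10-mm grid, ~20 trials per condition); `paper_scale = TRUE` restores
#' 16 subjects, 128 channels, 1000 Hz and a 7-mm grid.
#'
#' @param mode `"lep"` or `"peristim"`.
#' @param paper_scale Use the full-scale profile.
#' @param n_subjects,n_channels,sampling_rate,n_trials Simulation sizes
#'   (override the profile).
#' @param grid_spacing Source-grid spacing in mm.
#' @param alpha_reg LAURA regularization fraction (0.03% = 3e-4).
#' @param n_pc Principal components before ICA.
#' @param icasso_runs ICASSO repetitions.
#' @param K Fixed component count (`NULL`: ICASSO selection).
#' @param K_candidates Candidate orders when selecting.
#' @param z_threshold Z-map threshold.
#' @param t_threshold Group T-map threshold.
#' @param n_perm Permutations for the family-wise correction.
#' @param alpha_level Significance level.
#' @param noise_sd Sensor noise SD (uV).
#' @param seed Seed.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("lep", "peristim"),
                            paper_scale = FALSE,
                            n_subjects = if (paper_scale) 16 else 8,
                            n_channels = if (paper_scale) 128 else 64,
                            sampling_rate = if (paper_scale) 1000 else 500,
                            n_trials = if (paper_scale) 40 else 20,
                            grid_spacing = if (paper_scale) 7 else 10,
                            alpha_reg = 3e-4, n_pc = 30,
                            icasso_runs = 15, K = NULL,
                            K_candidates = 2:8,
                            z_threshold = 3.1,
                            t_threshold = if (match.arg(mode) == "lep") 70 else 50,
                            n_perm = 2000, alpha_level = 0.05,
                            noise_sd = 1.5, brain_noise_sd = 15,
                            seed = 1L) {
  mode <- match.arg(mode)
  preset <- if (mode == "lep") {
    list(epoch_window = c(-0.3, 0.8), band = c(2, 35),
         baseline = c(-0.3, 0), series_window = c(-0.1, 0.6),
         stat_window = c(0.1, 0.45))
  } else {
    list(epoch_window = c(-0.8, 0.7), band = c(0.1, 30),
         baseline = c(-0.8, -0.5), series_window = c(-0.8, 0.7),
         stat_window = c(-0.5, 0.1))
  }
  structure(c(list(mode = mode, paper_scale = paper_scale,
                   n_subjects = n_subjects, n_channels = n_channels,
                   sampling_rate = sampling_rate, n_trials = n_trials,
                   grid_spacing = grid_spacing, alpha_reg = alpha_reg,
                   n_pc = n_pc, icasso_runs = icasso_runs, K = K,
                   K_candidates = K_candidates,
                   z_threshold = z_threshold, t_threshold = t_threshold,
                   n_perm = n_perm, alpha_level = alpha_level,
                   noise_sd = noise_sd, brain_noise_sd = brain_noise_sd,
                   seed = seed),
              preset),
            class = "analysis_config")
}

#' Preprocess a simulated dataset into condition evoked responses
#'
#' Applies the fixed pipeline order per subject and condition: common
#' average reference, PCA eyeblink removal (on the concatenated trials,
#' using the ground-truth or detected blink onsets), epoch windowing,
#' peak-to-peak rejection, averaging, zero-phase band-pass, baseline
#' correction.
#'
#' @param dataset A `lep_dataset` from [simulate_dataset()].
#' @param config An [analysis_config()].
#' @param reject_threshold Peak-to-peak rejection threshold (uV).
#' @return Nested list `[[subject]][[condition]]` of `lep_evoked`.
#' @export
preprocess_dataset <- function(dataset, config,
                               reject_threshold = 300) {
  out <- list()
  for (s in names(dataset$epochs)) {
    out[[s]] <- list()
    for (co in names(dataset$epochs[[s]])) {
      ep <- dataset$epochs[[s]][[co]]
      ep <- common_average_reference(ep)
      ep <- remove_blinks_epochs(ep, dataset)
      ep <- crop_epochs(ep, config$epoch_window)
      ep <- reject_artifact_epochs(ep, reject_threshold)
      ev <- average_epochs(ep)
      ev <- bandpass_filter(ev, config$band[1], config$band[2])
      ev <- baseline_correct(ev, config$baseline)
      out[[s]][[co]] <- ev
    }
  }
  out
}

# PCA blink removal applied trial-wise using the dataset's blink log
remove_blinks_epochs <- function(ep, dataset) {
  log <- dataset$ground_truth$blinks
  if (is.null(log)) return(ep)
  sel <- log[log$subject == ep$subject & log$condition == ep$condition, ]
  if (!nrow(sel)) return(ep)
  d <- dim(ep$data)
  # concatenate trials, remove, split back
  flat <- matrix(aperm(ep$data, c(2, 3, 1)), d[2], d[3] * d[1])
  onsets <- (sel$trial - 1L) * d[3] + sel$onset_sample
  cleaned <- pca_artifact_removal(flat, onsets, ep$rate)
  arr <- array(cleaned, dim = c(d[2], d[3], d[1]))
  ep$data <- aperm(arr, c(3, 1, 2))
  ep
}

# crop an epoch set to a sub-window (half-open)
crop_epochs <- function(ep, window) {
  idx <- baseline_index(ep$window, ep$rate, window)
  ep$data <- ep$data[, , idx, drop = FALSE]
  ep$window <- window
  ep
}

#' Run one analysis family end to end
#'
#' Simulation (or supplied dataset) -> preprocessing -> forward model ->
#' LAURA inverse per subject and condition -> group ICA with ICASSO ->
#' pointwise repeated-measures ANOVA on the component time courses with
#' max-statistic permutation correction -> significant-interval and
#' peak tables, plus a provenance manifest.
#'
#' @param config An [analysis_config()].
#' @param dataset Optional `lep_dataset` (default: simulated from the
#'   config sizes and seed).
#' @param out_dir Optional directory; when given, peak tables, time
#'   courses, interval tables and the manifest are written as TSV/YAML.
#' @return List of class `lep_analysis`: `gica` fit, `anova_by_component`,
#'   `permtest`, `intervals`, `evoked`, `dataset`, `config`, `manifest`.
#' @export
run_analysis <- function(config, dataset = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(dataset)) {
    cfg <- sim_config(n_subjects = config$n_subjects,
                      n_channels = config$n_channels,
                      sampling_rate = config$sampling_rate,
                      n_trials_per_condition = config$n_trials,
                      noise_sd = config$noise_sd,
                      brain_noise_sd = config$brain_noise_sd,
                      seed = config$seed)
    dataset <- simulate_dataset(cfg)
  }
  evoked <- preprocess_dataset(dataset, config)
  hm <- dataset$config$head_model %||% head_model()
  grid <- build_source_grid(hm, config$grid_spacing)
  lf <- lead_field(hm, dataset$montage, grid)
  op <- laura_inverse_operator(lf, laura_config(alpha = config$alpha_reg))
  series <- list()
  for (s in names(evoked)) for (co in names(evoked[[s]])) {
    ev <- crop_evoked(evoked[[s]][[co]], config$series_window)
    series[[length(series) + 1L]] <- apply_inverse(op, ev)
  }
  fit <- group_ica(series, n_pc = min(config$n_pc, length(series) *
                                        nrow(series[[1]]$magnitudes) - 1),
                   K = config$K, K_candidates = config$K_candidates,
                   n_runs = config$icasso_runs, seed = config$seed)
  stats_res <- component_stats(fit, config)
  manifest <- list(
    mode = config$mode, seed = config$seed,
    n_subjects = config$n_subjects, n_channels = config$n_channels,
    sampling_rate = config$sampling_rate,
    band = config$band, baseline = config$baseline,
    epoch_window = config$epoch_window,
    series_window = config$series_window,
    stat_window = config$stat_window,
    grid_spacing = config$grid_spacing, n_voxels = grid$n,
    alpha_reg = config$alpha_reg, n_pc = fit$reduction$n_pc,
    K = fit$K, icasso_runs = config$icasso_runs,
    z_threshold = config$z_threshold, t_threshold = config$t_threshold,
    n_perm = config$n_perm, alpha_level = config$alpha_level,
    config_hash = config_hash(config),
    r_version = as.character(getRversion()))
  res <- structure(list(gica = fit, anova = stats_res$anova,
                        permtest = stats_res$permtest,
                        intervals = stats_res$intervals,
                        tc_array = stats_res$tc_array,
                        stat_time = stats_res$stat_time,
                        evoked = evoked, dataset = dataset,
                        operator = op, leadfield = lf,
                        config = config, manifest = manifest),
                   class = "lep_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(unclass(config)))],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  # small deterministic polynomial hash (no external digest dependency)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", h)
}

# component x time RM-ANOVA + permutation correction on the stat window
component_stats <- function(fit, config) {
  tc <- fit$tc
  subjects <- sort(unique(tc$subject))
  conds <- conditions_lep()
  times <- sort(unique(tc$time))
  sel_t <- times[times >= config$stat_window[1] - 1e-9 &
                   times < config$stat_window[2] - 1e-9]
  K <- fit$K
  n <- length(subjects); Tn <- length(sel_t)
  y <- array(0, dim = c(n, 3, K * Tn))
  for (si in seq_len(n)) for (ci in 1:3) {
    sub <- tc[tc$subject == subjects[si] & tc$condition == conds[ci] &
                tc$time %in% sel_t, ]
    sub <- sub[order(sub$component, sub$time), ]
    y[si, ci, ] <- sub$value
  }
  pt <- permutation_correct(y, n_perm = config$n_perm,
                            alpha = config$alpha_level,
                            seed = config$seed)
  anova_by_comp <- vector("list", K)
  intervals <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- (k - 1) * Tn + seq_len(Tn)
    anova_by_comp[[k]] <- rm_anova_pointwise(
      y[, , idx, drop = FALSE], conditions = conds)
    iv <- significant_intervals(pt$mask[idx], sel_t)
    if (nrow(iv)) iv$component <- k
    intervals[[k]] <- iv
  }
  intervals <- do.call(rbind, intervals[vapply(intervals, nrow,
                                               integer(1)) > 0])
  if (is.null(intervals))
    intervals <- tibble::tibble(start_ms = numeric(0),
                                end_ms = numeric(0),
                                n_points = integer(0),
                                component = integer(0))
  list(anova = anova_by_comp, permtest = pt, intervals = intervals,
       tc_array = y, stat_time = sel_t)
}

#' @export
print.lep_analysis <- function(x, ...) {
  cat(sprintf("LEP source-ICA analysis (%s mode): K = %d components, %d significant interval(s)\n",
              x$config$mode, x$gica$K, nrow(x$intervals)))
  invisible(x)
}

#' Write analysis outputs as TSV + manifest
#'
#' @param res A `lep_analysis`.
#' @param dir Output directory.
#' @export
write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(res$gica$tc),
                     file.path(dir, "component_timecourses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$intervals),
                     file.path(dir, "significant_intervals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  smaps <- subject_component_maps(res$gica, analysis_series(res))
  peaks <- list()
  for (k in seq_len(res$gica$K)) {
    gm <- group_tmap(smaps[, k, ], res$gica$grid,
                     t_threshold = res$config$t_threshold)
    if (nrow(gm$peaks)) {
      gm$peaks$component <- k
      peaks[[length(peaks) + 1L]] <- gm$peaks
    }
  }
  if (length(peaks))
    utils::write.table(as.data.frame(do.call(rbind, peaks)),
                       file.path(dir, "group_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(res$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

# rebuild the source_series list of an analysis (for subject maps)
analysis_series <- function(res) {
  series <- list()
  for (s in names(res$evoked)) for (co in names(res$evoked[[s]])) {
    ev <- crop_evoked(res$evoked[[s]][[co]], res$config$series_window)
    series[[length(series) + 1L]] <- apply_inverse(res$operator, ev)
  }
  series
}
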