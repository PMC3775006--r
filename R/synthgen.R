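#' Gaussian dipole-moment pulse
#'
#' Smooth unimodal time course used as the ground-truth source waveform:
#' a Gaussian pulse peaking at `latency` with temporal SD `width`. Beyond
#' 3 widths from the peak the pulse has decayed below 1% of its maximum.
#'
#' @param latency Peak time in s (must lie inside `window`).
#' @param width Temporal standard deviation in s (> 0).
#' @param amplitude Peak dipole moment in nA.m.
#' @param window Length-2 numeric, time interval (t_min, t_max) in s;
#'   samples follow the half-open convention `[t_min, t_max)`.
#' @param rate Sampling rate in Hz (> 0).
#' @return Numeric vector of dipole moments, one per sample, with the
#'   time axis in attribute `"time"`.
#' @export
#' @examples
#' w <- source_waveform(0.19, 0.03, 10, c(-0.1, 0.6), 1000)
#' which.max(w)   # sample 291 -> t = 0.19 s
source_waveform <- function(latency, width, amplitude, window, rate) {
  if (!is.numeric(width) || width <= 0) stop("`width` must be > 0")
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be > 0")
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (latency < window[1] || latency >= window[2])
    stop("`window` must contain `latency`")
  t <- time_axis(window, rate)
  out <- amplitude * exp(-(t - latency)^2 / (2 * width^2))
  attr(out, "time") <- t
  out
}

# half-open sample grid [t_min, t_max)
time_axis <- function(window, rate) {
  n <- round((window[2] - window[1]) * rate)
  window[1] + seq_len(n - 1 + 1) / rate - 1 / rate
}

#' Ground-truth dipole source
#'
#' @param position Length-3, head-frame coordinates in mm (must be inside
#'   the brain shell of the head model used for simulation).
#' @param orientation Length-3 dipole orientation; normalized to unit norm.
#' @param latency Peak latency in s relative to laser onset.
#' @param width Temporal SD of the pulse in s (> 0).
#' @param base_amplitude Peak moment in nA.m.
#' @param condition_gains Length-3 positive multiplicative gains for the
#'   (positive, neutral, negative) picture conditions.
#' @return An object of class `gt_source`.
#' @export
ground_truth_source <- function(position, orientation, latency, width,
                                base_amplitude,
                                condition_gains = c(1, 1, 1)) {
  stopifnot(length(position) == 3L, length(orientation) == 3L,
            length(condition_gains) == 3L)
  if (width <= 0) stop("`width` must be > 0")
  if (any(condition_gains <= 0)) stop("`condition_gains` must be > 0")
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("`orientation` must be non-zero")
  structure(list(position = as.numeric(position),
                 orientation = as.numeric(orientation) / nrm,
                 latency = latency, width = width,
                 base_amplitude = base_amplitude,
                 condition_gains = as.numeric(condition_gains)),
            class = "gt_source")
}

#' Default ground-truth source set
#'
#' Three spatially compact dipoles emulating the qualitative effect
#' pattern of emotional modulation of LEPs: an insula-like right
#' anterior source enhanced under negative pictures, a posterior
#' cingulate/precuneus-like source enhanced under positive pictures,
#' and an unmodulated midline premotor source. In the spherical head
#' model the positions are nominal: each is placed within the sensor
#' cap's sensitivity so that every simulated cluster is recoverable in
#' principle, and the peak latencies are separated by more than two
#' pulse widths, as successive LEP component peaks are.
#'
#' @return List of three [ground_truth_source()] objects.
#' @export
default_sources <- function() {
  list(
    insula = ground_truth_source(
      position = c(45, 20, 15), orientation = c(45, 20, 15),
      latency = 0.15, width = 0.02, base_amplitude = 25,
      condition_gains = c(1, 1, 1.3)),
    pcc = ground_truth_source(
      position = c(4, -55, 30), orientation = c(4, -55, 30),
      latency = 0.21, width = 0.022, base_amplitude = 22,
      condition_gains = c(1.3, 1, 1)),
    premotor = ground_truth_source(
      position = c(-18, 4, 46), orientation = c(-18, 4, 46),
      latency = 0.30, width = 0.03, base_amplitude = 20,
      condition_gains = c(1, 1, 1))
  )
}

#' Simulation configuration
#'
#' Defaults follow the study design being emulated: 16 subjects,
#' 128 channels at 1000 Hz, 40 trials per emotional condition, laser
#' onset 1.1 s after picture onset. Inter-subject spread (latency jitter
#' SD 10 ms, log-normal amplitude SD 0.2) and sensor noise are stand-ins
#' chosen to keep group decomposition valid.
#'
#' @param n_subjects Number of subjects.
#' @param n_channels Number of electrodes.
#' @param sampling_rate Hz.
#' @param n_trials_per_condition Trials per emotional condition (>= 1).
#' @param laser_onset_offset Picture-to-laser delay in s.
#' @param window Per-trial epoch window in s relative to laser onset.
#' @param sources List of [ground_truth_source()] objects.
#' @param noise_sd Instrumental (spatially white) sensor-noise SD in uV.
#' @param brain_noise_sd Per-dipole moment SD (nA.m) of the ongoing
#'   background brain activity: `n_noise_dipoles` randomly placed
#'   dipoles with white time courses, projected through the head model,
#'   giving the spatially correlated part of single-trial EEG noise.
#' @param n_noise_dipoles Number of background-noise dipoles.
#' @param blink_rate Eyeblink rate, events per minute.
#' @param blink_amplitude Peak blink amplitude in uV at the most frontal channel.
#' @param latency_jitter_sd Between-subject latency jitter SD in s.
#' @param amplitude_lognorm_sd Between-subject log-normal amplitude SD.
#' @param behavior_means 3 x 3 matrix of condition means, rows pain (1-7),
#'   valence (1-9), arousal (1-9), columns positive/neutral/negative.
#' @param behavior_subject_sd Between-subject SD of rating means.
#' @param behavior_trial_sd Within-subject trial-to-trial rating SD.
#' @param head_model A [head_model()].
#' @param seed Integer seed; together with the other fields it fully
#'   determines the simulated output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16, n_channels = 128,
                       sampling_rate = 1000, n_trials_per_condition = 40,
                       laser_onset_offset = 1.1, window = c(-0.9, 0.9),
                       sources = default_sources(), noise_sd = 1.5,
                       brain_noise_sd = 15, n_noise_dipoles = 50,
                       blink_rate = 3, blink_amplitude = 120,
                       latency_jitter_sd = 0.010,
                       amplitude_lognorm_sd = 0.2,
                       behavior_means = rbind(pain = c(2.78, 2.83, 3.34),
                                              valence = c(7.35, 5.31, 2.40),
                                              arousal = c(4.27, 2.94, 6.07)),
                       behavior_subject_sd = 0.5,
                       behavior_trial_sd = 1.0,
                       head_model = lepsica_head_default(), seed = 1L) {
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0")
  if (n_trials_per_condition < 1) stop("`n_trials_per_condition` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (brain_noise_sd < 0) stop("`brain_noise_sd` must be >= 0")
  if (blink_rate < 0) stop("`blink_rate` must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

conditions_lep <- function() c("positive", "neutral", "negative")

# default head model for sim_config (avoids forcing the argument at build time)
lepsica_head_default <- function() head_model()

# lead field at arbitrary point-dipole positions (mm): ad-hoc one-off grid
point_lead_field <- function(head_model, montage, positions) {
  pos <- matrix(positions, ncol = 3)
  r <- sqrt(rowSums(sweep(pos, 2, head_model$center)^2))
  if (any(r >= min(head_model$radii)))
    stop("invalid geometry: source outside the head-model brain volume")
  g <- structure(list(pos = pos, spacing = NA_real_,
                      radius = min(head_model$radii),
                      center = head_model$center, n = nrow(pos)),
                 class = "source_grid")
  lead_field(head_model, montage, g)
}

#' Stereotyped frontal blink topography
#'
#' Smooth frontal-positive spatial gradient over channels: weight decays
#' with angular distance from the most anterior-inferior scalp position,
#' the conventional EOG pattern.
#'
#' @param montage A `lep_montage`.
#' @return Unit-norm numeric vector of channel weights.
#' @export
blink_topography <- function(montage) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  u <- pos / sqrt(rowSums(pos^2))
  front <- c(0, cos(pi / 6), -sin(pi / 6))   # anterior, slightly below equator
  w <- exp(-(acos(pmin(1, pmax(-1, u %*% front)))^2) / (2 * 0.5^2))
  w <- as.vector(w - mean(w))                # average-referenced pattern
  w / sqrt(sum(w^2))
}

blink_profile <- function(rate) {
  # stereotyped ~300 ms smooth bump
  n <- max(3L, round(0.3 * rate))
  sin(pi * seq_len(n) / (n + 1))^2
}

#' Inject eyeblink artifacts into a recording
#'
#' Adds blinks at Poisson-distributed times: each event contributes a
#' fixed spatial template times a stereotyped ~300 ms temporal bump.
#'
#' @param recording Channels x samples matrix (uV).
#' @param rate Blink rate in events per minute (>= 0).
#' @param template_topography Channel-weight vector (fixed spatial pattern).
#' @param sampling_rate Hz.
#' @param amplitude Peak amplitude in uV (scales the template).
#' @return The recording with blinks added; event onset samples in
#'   attribute `"blink_onsets"`.
#' @export
inject_blinks <- function(recording, rate, template_topography,
                          sampling_rate, amplitude = 120) {
  if (rate < 0) stop("`rate` must be >= 0")
  n_samp <- ncol(recording)
  onsets <- integer(0)
  if (rate > 0) {
    dur_min <- n_samp / sampling_rate / 60
    n_ev <- stats::rpois(1, rate * dur_min)
    if (n_ev > 0) onsets <- sort(sample.int(n_samp, n_ev, replace = TRUE))
  }
  prof <- blink_profile(sampling_rate) * amplitude
  topo <- template_topography / max(abs(template_topography))
  for (on in onsets) {
    idx <- on:min(n_samp, on + length(prof) - 1L)
    recording[, idx] <- recording[, idx] +
      outer(topo, prof[seq_along(idx)])
  }
  attr(recording, "blink_onsets") <- onsets
  recording
}

new_lep_epochs <- function(data, rate, window, subject, condition,
                           events = NULL) {
  structure(list(data = data, rate = rate, window = window,
                 subject = subject, condition = condition,
                 events = events),
            class = "lep_epochs")
}

#' @export
print.lep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("lep_epochs: %d trials x %d channels x %d samples, %g Hz, [%g, %g) s, subject %s, %s\n",
              d[1], d[2], d[3], x$rate, x$window[1], x$window[2],
              x$subject, x$condition))
  invisible(x)
}

#' Simulate a multi-subject laser-evoked EEG dataset
#'
#' Generates, for every subject and emotional condition, an epoch set
#' whose clean part is the lead-field projection of the summed
#' ground-truth source waveforms scaled by that condition's gain, plus
#' white sensor noise and eyeblink artifacts, together with a behavioral
#' rating table and a full ground-truth record. Identical configurations
#' (including `seed`) give identical output.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `lep_dataset`:
#' \describe{
#'   \item{epochs}{nested list `[[subject]][[condition]]` of `lep_epochs`}
#'   \item{behavior}{tibble with per subject x condition rating means}
#'   \item{montage}{the electrode montage used}
#'   \item{ground_truth}{sources, per-subject jitters, clean evoked
#'     responses, blink events and the source-to-channel gains}
#' }
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_exists()
  set.seed(cfg$seed)
  on.exit(.restore_seed(old), add = TRUE)

  conds <- conditions_lep()
  mon <- default_montage(cfg$n_channels, cfg$head_model)
  src_pos <- t(vapply(cfg$sources, `[[`, numeric(3), "position"))
  lf <- point_lead_field(cfg$head_model, mon, src_pos)
  # channel gain pattern per source for its fixed orientation
  gains <- vapply(seq_along(cfg$sources), function(s) {
    ori <- cfg$sources[[s]]$orientation
    as.vector(lf$gain[, (3 * (s - 1) + 1):(3 * s)] %*% ori)
  }, numeric(cfg$n_channels))                       # channels x sources

  t_ax <- time_axis(cfg$window, cfg$sampling_rate)
  n_samp <- length(t_ax)
  topo <- blink_topography(mon)

  # background brain activity: random interior dipoles with fixed random
  # orientations, projected through the same head model
  noise_gain <- NULL
  if (cfg$brain_noise_sd > 0 && cfg$n_noise_dipoles > 0) {
    r_brain <- min(cfg$head_model$radii)
    npos <- matrix(stats::rnorm(cfg$n_noise_dipoles * 3), ncol = 3)
    npos <- npos / sqrt(rowSums(npos^2)) *
      (r_brain * 0.95 * stats::runif(cfg$n_noise_dipoles)^(1 / 3))
    npos <- sweep(npos, 2, cfg$head_model$center, `+`)
    nlf <- point_lead_field(cfg$head_model, mon, npos)
    nori <- matrix(stats::rnorm(cfg$n_noise_dipoles * 3), ncol = 3)
    nori <- nori / sqrt(rowSums(nori^2))
    noise_gain <- vapply(seq_len(cfg$n_noise_dipoles), function(s)
      as.vector(nlf$gain[, (3 * (s - 1) + 1):(3 * s)] %*% nori[s, ]),
      numeric(cfg$n_channels))                    # channels x dipoles
  }

  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  epochs <- vector("list", cfg$n_subjects); names(epochs) <- subjects
  clean <- vector("list", cfg$n_subjects); names(clean) <- subjects
  jit <- vector("list", cfg$n_subjects); names(jit) <- subjects
  blink_log <- list()

  for (i in seq_len(cfg$n_subjects)) {
    lat_jit <- stats::rnorm(length(cfg$sources), 0, cfg$latency_jitter_sd)
    amp_fac <- exp(stats::rnorm(length(cfg$sources), 0,
                                cfg$amplitude_lognorm_sd))
    jit[[i]] <- list(latency = lat_jit, amplitude = amp_fac)
    epochs[[i]] <- vector("list", 3L); names(epochs[[i]]) <- conds
    clean[[i]] <- vector("list", 3L); names(clean[[i]]) <- conds
    for (ci in 1:3) {
      wf <- vapply(seq_along(cfg$sources), function(s) {
        so <- cfg$sources[[s]]
        so$base_amplitude * amp_fac[s] * so$condition_gains[ci] *
          exp(-(t_ax - (so$latency + lat_jit[s]))^2 / (2 * so$width^2))
      }, numeric(n_samp))                           # samples x sources
      ev <- gains %*% t(wf)                         # channels x samples
      clean[[i]][[ci]] <- ev
      dat <- array(0, dim = c(cfg$n_trials_per_condition,
                              cfg$n_channels, n_samp))
      for (tr in seq_len(cfg$n_trials_per_condition)) {
        x <- ev + matrix(stats::rnorm(cfg$n_channels * n_samp,
                                      0, cfg$noise_sd),
                         cfg$n_channels, n_samp)
        if (!is.null(noise_gain))
          x <- x + noise_gain %*%
            matrix(stats::rnorm(cfg$n_noise_dipoles * n_samp,
                                0, cfg$brain_noise_sd),
                   cfg$n_noise_dipoles, n_samp)
        x <- inject_blinks(x, cfg$blink_rate, topo, cfg$sampling_rate,
                           cfg$blink_amplitude)
        ons <- attr(x, "blink_onsets")
        if (length(ons))
          blink_log[[length(blink_log) + 1L]] <-
            tibble::tibble(subject = subjects[i], condition = conds[ci],
                           trial = tr, onset_sample = ons)
        dat[tr, , ] <- x
      }
      epochs[[i]][[ci]] <- new_lep_epochs(dat, cfg$sampling_rate,
                                          cfg$window, subjects[i],
                                          conds[ci])
    }
  }

  behavior <- simulate_behavior(cfg, subjects)
  gt <- list(sources = cfg$sources, source_gains = gains,
             subject_jitter = jit, clean_evoked = clean,
             blinks = if (length(blink_log))
               do.call(rbind, blink_log) else NULL,
             blink_topography = topo, time = t_ax)
  structure(list(epochs = epochs, behavior = behavior, montage = mon,
                 ground_truth = gt, config = cfg),
            class = "lep_dataset")
}

# behavioral ratings: per-trial truncated normals around subject means
simulate_behavior <- function(cfg, subjects) {
  conds <- conditions_lep()
  scales <- list(pain = c(1, 7), valence = c(1, 9), arousal = c(1, 9))
  rows <- list()
  for (i in seq_along(subjects)) for (ci in 1:3) {
    vals <- vapply(1:3, function(m) {
      mu_i <- cfg$behavior_means[m, ci] +
        stats::rnorm(1, 0, cfg$behavior_subject_sd)
      tr <- mu_i + stats::rnorm(cfg$n_trials_per_condition, 0,
                                cfg$behavior_trial_sd)
      sc <- scales[[m]]
      mean(pmin(sc[2], pmax(sc[1], tr)))
    }, numeric(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject = subjects[i], condition = conds[ci],
      pain = vals[1], valence = vals[2], arousal = vals[3])
  }
  do.call(rbind, rows)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.lep_dataset <- function(x, ...) {
  cat(sprintf("lep_dataset: %d subjects x 3 conditions, %d channels, %g Hz, %d trials/condition\n",
              x$config$n_subjects, x$config$n_channels,
              x$config$sampling_rate, x$config$n_trials_per_condition))
  invisible(x)
}

#' Write / read a simulated dataset as the plain-text fixture container
#'
#' The container is a directory holding `meta.yaml` (sampling rate,
#' window, subjects, conditions), `montage.txt` (whitespace `label x y z`
#' in mm), `behavior.tsv`, and one gzipped TSV per subject x condition
#' with one row per (trial, channel) and one column per sample.
#'
#' @param dataset A `lep_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- dataset$config
  meta <- list(sampling_rate = cfg$sampling_rate, window = cfg$window,
               subjects = names(dataset$epochs),
               conditions = conditions_lep(),
               n_trials = cfg$n_trials_per_condition)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  write_montage(dataset$montage, file.path(dir, "montage.txt"))
  utils::write.table(as.data.frame(dataset$behavior),
                     file.path(dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(dataset$epochs)) for (co in conditions_lep()) {
    ep <- dataset$epochs[[s]][[co]]
    d <- dim(ep$data)
    m <- do.call(rbind, lapply(seq_len(d[1]),
                               function(tr) ep$data[tr, , , drop = FALSE][1, , ]))
    f <- gzfile(file.path(dir, sprintf("%s_%s.tsv.gz", s, co)), "w")
    utils::write.table(cbind(trial = rep(seq_len(d[1]), each = d[2]),
                             channel = rep(seq_len(d[2]), d[1]),
                             round(m, 4)),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    close(f)
  }
  invisible(dir)
}

#' @param dir Directory written by [write_dataset()].
#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  mon <- read_montage(file.path(dir, "montage.txt"))
  behavior <- tibble::as_tibble(
    utils::read.table(file.path(dir, "behavior.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE))
  epochs <- list()
  for (s in meta$subjects) {
    epochs[[s]] <- list()
    for (co in meta$conditions) {
      df <- utils::read.table(
        file.path(dir, sprintf("%s_%s.tsv.gz", s, co)),
        header = TRUE, sep = "\t")
      n_tr <- max(df$trial); n_ch <- max(df$channel)
      n_sa <- ncol(df) - 2L
      arr <- array(0, dim = c(n_tr, n_ch, n_sa))
      m <- as.matrix(df[, -(1:2)])
      for (tr in seq_len(n_tr))
        arr[tr, , ] <- m[df$trial == tr, ][order(df$channel[df$trial == tr]), ]
      epochs[[s]][[co]] <- new_lep_epochs(arr, meta$sampling_rate,
                                          unlist(meta$window), s, co)
    }
  }
  structure(list(epochs = epochs, behavior = behavior, montage = mon,
                 ground_truth = NULL, config = NULL),
            class = "lep_dataset")
}
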