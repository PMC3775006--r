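#' Cut epochs from a continuous recording
#'
#' Extracts fixed-length windows around event times under the half-open
#' convention `[t_min, t_max)`: the epoch holds
#' `round((t_max - t_min) * rate)` samples and sample `k` (0-based)
#' corresponds to time `t_min + k / rate` relative to its event.
#'
#' @param recording Channels x samples matrix (uV); sample 1 is time 0.
#' @param rate Sampling rate in Hz.
#' @param event_times Event times in s.
#' @param t_min,t_max Epoch window in s relative to each event.
#' @param subject,condition Metadata carried on the result.
#' @return A `lep_epochs` object (trials x channels x samples).
#' @export
#' @examples
#' rec <- matrix(rnorm(2 * 3000), 2)
#' ep <- epoch_data(rec, 1000, c(1, 2), -0.3, 0.8)
#' dim(ep$data)  # 2 x 2 x 1100
epoch_data <- function(recording, rate, event_times, t_min, t_max,
                       subject = "S01", condition = "neutral") {
  stopifnot(t_min < t_max, rate > 0)
  n_samp <- round((t_max - t_min) * rate)
  n_rec <- ncol(recording)
  dat <- array(0, dim = c(length(event_times), nrow(recording), n_samp))
  for (i in seq_along(event_times)) {
    start <- round(event_times[i] * rate) + round(t_min * rate) + 1L
    idx <- start:(start + n_samp - 1L)
    if (idx[1] < 1L || idx[length(idx)] > n_rec)
      stop(sprintf("epoch window for trial %d exceeds recording bounds", i))
    dat[i, , ] <- recording[, idx]
  }
  new_lep_epochs(dat, rate, c(t_min, t_max), subject, condition)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over channels. Idempotent and
#' invariant to any spatially uniform offset.
#'
#' @param x Channels x samples matrix, or a `lep_epochs` object.
#' @return Same type as the input, average-referenced.
#' @export
common_average_reference <- function(x) {
  if (inherits(x, "lep_epochs")) {
    for (tr in seq_len(dim(x$data)[1]))
      x$data[tr, , ] <- common_average_reference(x$data[tr, , ])
    return(x)
  }
  if (nrow(x) < 2) stop("common average reference needs >= 2 channels")
  sweep(x, 2, colMeans(x))
}

#' PCA-based artifact removal
#'
#' Averages the recording around the supplied artifact event onsets,
#' extracts the leading spatial principal component(s) of that
#' artifact-locked average, and projects them out of the whole
#' recording (rank reduction by the number of removed components).
#'
#' @param recording Channels x samples matrix (uV).
#' @param artifact_onsets Event onset samples (1-based).
#' @param sampling_rate Hz.
#' @param n_components Number of spatial components to remove per
#'   artifact class (default 1).
#' @param span Averaging window length in s following each onset.
#' @return The cleaned recording; removed topographies (channels x
#'   n_components, unit columns) in attribute `"removed_topography"`.
#' @export
pca_artifact_removal <- function(recording, artifact_onsets, sampling_rate,
                                 n_components = 1, span = 0.3) {
  n_samp <- ncol(recording)
  len <- max(2L, round(span * sampling_rate))
  ok <- artifact_onsets[artifact_onsets + len - 1L <= n_samp]
  if (length(ok) < 3L) {
    warning("fewer than 3 artifact events; recording passed through")
    attr(recording, "removed_topography") <- NULL
    return(recording)
  }
  avg <- matrix(0, nrow(recording), len)
  for (on in ok) avg <- avg + recording[, on:(on + len - 1L)]
  avg <- avg / length(ok)
  sv <- svd(avg, nu = n_components, nv = 0)
  U <- sv$u                                    # channels x n_components
  cleaned <- recording - U %*% (t(U) %*% recording)
  attr(cleaned, "removed_topography") <- U
  cleaned
}

#' Reject epochs on a peak-to-peak amplitude criterion
#'
#' @param epochs A `lep_epochs` object.
#' @param threshold Peak-to-peak rejection threshold in uV (> 0); a trial
#'   is rejected when any channel exceeds it.
#' @return The retained epochs; rejection log (tibble with trial index and
#'   offending channels) in attribute `"rejection_log"`.
#' @export
reject_artifact_epochs <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "lep_epochs"))
  if (threshold <= 0) stop("`threshold` must be > 0")
  d <- dim(epochs$data)
  ptp <- apply(epochs$data, c(1, 2), function(v) diff(range(v)))
  bad <- ptp > threshold
  rejected <- which(rowSums(bad) > 0)
  if (length(rejected) == d[1])
    stop("all trials rejected at this threshold")
  log <- if (length(rejected)) {
    tibble::tibble(
      trial = rejected,
      channels = vapply(rejected, function(tr)
        paste(which(bad[tr, ]), collapse = ","), character(1)),
      max_ptp = vapply(rejected, function(tr) max(ptp[tr, ]), numeric(1)))
  } else {
    tibble::tibble(trial = integer(0), channels = character(0),
                   max_ptp = numeric(0))
  }
  keep <- setdiff(seq_len(d[1]), rejected)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  attr(epochs, "rejection_log") <- log
  epochs
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift; symmetric pulses keep
#' their latency. Data are edge-padded by reflection before filtering.
#' A `low` of 0 gives a pure low-pass.
#'
#' @param x Channels x samples matrix, `lep_epochs`, or `lep_evoked`.
#' @param low,high Band edges in Hz, `0 <= low < high < rate/2`.
#' @param rate Sampling rate in Hz (taken from the object if present).
#' @param order Filter order (per pass).
#' @return Same type as the input, filtered.
#' @export
bandpass_filter <- function(x, low, high, rate = NULL, order = 4) {
  if (inherits(x, "lep_epochs")) {
    for (tr in seq_len(dim(x$data)[1]))
      x$data[tr, , ] <- bandpass_filter(x$data[tr, , ], low, high, x$rate,
                                        order)
    x$band <- c(low, high)
    return(x)
  }
  if (inherits(x, "lep_evoked")) {
    x$data <- bandpass_filter(x$data, low, high, x$rate, order)
    x$band <- c(low, high)
    return(x)
  }
  if (is.null(rate)) stop("`rate` required for matrix input")
  if (low < 0 || low >= high || high >= rate / 2)
    stop("invalid band: need 0 <= low < high < rate/2")
  flt <- if (low == 0)
    signal::butter(order, high / (rate / 2), type = "low")
  else
    signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  n <- ncol(x)
  pad <- min(n - 1L, max(16L, round(rate)))   # reflect up to 1 s at each end
  t(apply(x, 1, function(v) {
    vp <- c(2 * v[1] - rev(v[2:(pad + 1)]), v,
            2 * v[n] - rev(v[(n - pad):(n - 1)]))
    signal::filtfilt(flt, vp)[(pad + 1):(pad + n)]
  }))
}

#' Baseline correction
#'
#' Subtracts from every channel its mean over the baseline window.
#'
#' @param x A `lep_epochs` or `lep_evoked` object.
#' @param window Length-2 baseline interval in s (must lie inside the
#'   epoch window; half-open sample selection).
#' @return Same type, baseline-corrected; the window is recorded in the
#'   `baseline` field.
#' @export
baseline_correct <- function(x, window) {
  idx <- baseline_index(x$window, x$rate, window)
  if (inherits(x, "lep_epochs")) {
    for (tr in seq_len(dim(x$data)[1])) {
      m <- matrix(x$data[tr, , idx], nrow = dim(x$data)[2])
      x$data[tr, , ] <- x$data[tr, , ] - rowMeans(m)
    }
  } else if (inherits(x, "lep_evoked")) {
    x$data <- x$data - rowMeans(x$data[, idx, drop = FALSE])
  } else stop("unsupported input")
  x$baseline <- window
  x
}

baseline_index <- function(epoch_window, rate, baseline_window) {
  t_ax <- time_axis(epoch_window, rate)
  idx <- which(t_ax >= baseline_window[1] - 1e-9 &
                 t_ax < baseline_window[2] - 1e-9)
  if (!length(idx)) stop("baseline window outside the epoch")
  idx
}

#' Average epochs into an evoked response
#'
#' @param epochs A `lep_epochs` object.
#' @return A `lep_evoked` object: `data` (channels x samples, uV),
#'   `rate`, `window`, `n_epochs`, plus any `band`/`baseline` metadata.
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "lep_epochs"))
  d <- dim(epochs$data)
  ev <- apply(epochs$data, c(2, 3), mean)
  structure(list(data = ev, rate = epochs$rate, window = epochs$window,
                 subject = epochs$subject, condition = epochs$condition,
                 n_epochs = d[1], band = epochs$band,
                 baseline = epochs$baseline),
            class = "lep_evoked")
}

#' @export
print.lep_evoked <- function(x, ...) {
  cat(sprintf("lep_evoked: %d channels x %d samples, %g Hz, [%g, %g) s, n = %d\n",
              nrow(x$data), ncol(x$data), x$rate, x$window[1], x$window[2],
              x$n_epochs))
  invisible(x)
}

#' Crop an evoked response to a sub-window
#'
#' @param evoked A `lep_evoked` object.
#' @param window Length-2 target interval in s (half-open).
#' @return The cropped `lep_evoked`.
#' @export
crop_evoked <- function(evoked, window) {
  idx <- baseline_index(evoked$window, evoked$rate, window)
  evoked$data <- evoked$data[, idx, drop = FALSE]
  evoked$window <- window
  evoked
}

#' Global field power
#'
#' Per-sample spatial standard deviation of the average-referenced
#' potentials (equivalently the RMS about the spatial mean).
#'
#' @param evoked A `lep_evoked` object or channels x samples matrix.
#' @return Numeric vector, one value per sample (uV).
#' @export
global_field_power <- function(evoked) {
  m <- if (inherits(evoked, "lep_evoked")) evoked$data else evoked
  m <- sweep(m, 2, colMeans(m))
  sqrt(colMeans(m^2))
}

#' Butterfly plot of an evoked response with global field power
#'
#' @param object A `lep_evoked` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lep_evoked <- function(object, ...) {
  t_ax <- time_axis(object$window, object$rate) * 1000
  df <- data.frame(
    time = rep(t_ax, each = nrow(object$data)),
    channel = factor(rep(seq_len(nrow(object$data)), ncol(object$data))),
    uV = as.vector(object$data))
  gfp <- data.frame(time = t_ax, uV = global_field_power(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$uV)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$channel),
                       linewidth = 0.2, alpha = 0.4) +
    ggplot2::geom_line(data = gfp, colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "potential (uV)",
                  title = "Evoked potential (red: global field power)")
}
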