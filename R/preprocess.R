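# Signal processing: zero-phase Butterworth filtering, EMG envelope
# extraction and submaximal normalization, cross-correlation stream
# synchronization, and resampling of all streams onto a shared 25 Hz grid.

TARGET_FS <- 25 # Hz, shared rate of inputs and SJRF targets

#' Butterworth filter specification
#'
#' @param kind `"low"` or `"high"` pass.
#' @param order Filter order (default 4, the convention used throughout the
#'   processing chain).
#' @param cutoff_hz Cut-off frequency in Hz; must be below the Nyquist
#'   frequency of the signal the spec is applied to.
#' @param zero_phase Apply forward-backward (zero-phase) filtering. The
#'   effective magnitude response is then the squared single-pass response
#'   (a sine exactly at the cut-off is attenuated to amplitude 0.5, not
#'   `1/sqrt(2)`).
#' @return An object of class `sjrf_filter_spec`.
#' @export
filter_spec <- function(kind = c("low", "high"), order = 4, cutoff_hz,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  stopifnot_scalar_num(order, "order", min = 1)
  stopifnot_scalar_num(cutoff_hz, "cutoff_hz", min = 1e-9)
  structure(list(kind = kind, order = as.integer(order),
                 cutoff_hz = cutoff_hz, zero_phase = isTRUE(zero_phase)),
            class = "sjrf_filter_spec")
}

# default filter chain (printed cut-offs of the processing protocol)
default_filters <- function() {
  list(imu = filter_spec("low", 4, 10),
       emg_highpass = filter_spec("high", 4, 20),
       emg_envelope = filter_spec("low", 4, 3),
       sjrf = filter_spec("low", 4, 4))
}

# steady-state initial filter state for a unit step input, so that constant
# signals pass without warm-up transients (direct form II transposed)
lfilter_zi <- function(b, a) {
  b <- b / a[1]
  a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  A <- rbind(-a[2:n], cbind(diag(n - 2), rep(0, n - 2)))
  B <- b[2:n] - b[1] * a[2:n]
  solve(diag(n - 1) - t(A), B)
}

#' Apply a Butterworth filter
#'
#' Designs the filter with [signal::butter()] and applies it either causally
#' or zero-phase (forward-backward with odd-reflection edge padding of
#' `3 * order` samples and steady-state initial conditions, so DC passes a
#' low-pass exactly).
#'
#' @param x Uniformly sampled numeric vector.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @param channel Optional channel name used in error messages.
#' @return Filtered vector of the same length.
#' @export
butterworth_filter <- function(x, fs, spec, channel = "signal") {
  if (spec$cutoff_hz >= fs / 2) {
    stop(sprintf(
      "cut-off %.3g Hz is not below the Nyquist frequency %.3g Hz for %s",
      spec$cutoff_hz, fs / 2, channel), call. = FALSE)
  }
  bt <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2),
                       type = spec$kind)
  b <- as.numeric(bt$b)
  a <- as.numeric(bt$a)
  n <- length(x)
  pad <- 3L * spec$order
  if (n <= pad + 1L) {
    stop(sprintf("%s too short (%d samples) for filter warm-up (%d)",
                 channel, n, pad + 1L), call. = FALSE)
  }
  zi <- lfilter_zi(b, a)
  if (!spec$zero_phase) {
    return(as.numeric(.iir_filter_cpp(b, a, x, zi * x[1])))
  }
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(.iir_filter_cpp(b, a, ext, zi * ext[1]))
  y <- rev(as.numeric(.iir_filter_cpp(b, a, rev(y), zi * y[length(y)])))
  y[(pad + 1):(pad + n)]
}

# linear interpolation of a (time x channel) matrix onto a new time grid;
# clamped at the edges
resample_linear <- function(time, data, grid) {
  data <- as.matrix(data)
  out <- vapply(seq_len(ncol(data)), function(j) {
    stats::approx(time, data[, j], xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  out <- matrix(out, nrow = length(grid))
  colnames(out) <- colnames(data)
  out
}

#' EMG envelope (pre-normalization)
#'
#' The envelope chain applied to raw EMG at its native rate, in the stated
#' order: 4th-order high-pass at 20 Hz, offset correction (subtraction of the
#' full-trial mean), full-wave rectification, 4th-order low-pass at 3 Hz.
#' Ringing undershoot of the final low-pass is clipped at zero.
#'
#' @param x Raw EMG vector.
#' @param fs Sampling rate (Hz), typically 1024.
#' @param filters Filter chain as in `default_filters()`.
#' @return Non-negative envelope at the native rate.
#' @export
emg_envelope <- function(x, fs = EMG_FS, filters = default_filters()) {
  y <- butterworth_filter(x, fs, filters$emg_highpass, "emg")
  y <- y - mean(y)
  y <- abs(y)
  y <- butterworth_filter(y, fs, filters$emg_envelope, "emg envelope")
  pmax(y, 0)
}

#' Compute an EMG normalization reference
#'
#' Mean of the pre-normalization envelope over a window of a static
#' submaximal-contraction recording. The default window is the central 60%
#' of the recording, which skips the fiducial burst and any clock-offset
#' margin.
#'
#' @param x Raw EMG vector of the static posture recording.
#' @param fs Sampling rate in Hz.
#' @param window_s Numeric `(start, end)` in seconds; `NULL` for the default.
#' @param muscle Optional muscle label carried through.
#' @return List with `muscle`, `reference_value` (> 0) and `source_window_s`.
#' @export
compute_emg_reference <- function(x, fs = EMG_FS, window_s = NULL,
                                  muscle = NA_character_) {
  total <- (length(x) - 1) / fs
  if (is.null(window_s)) window_s <- c(0.2, 0.8) * total
  if (window_s[2] <= window_s[1] || window_s[1] < 0 || window_s[2] > total) {
    stop(sprintf("window [%.2f, %.2f] s outside recording of %.2f s",
                 window_s[1], window_s[2], total), call. = FALSE)
  }
  env <- emg_envelope(x, fs)
  idx <- which(seq_along(x) >= window_s[1] * fs + 1 &
                 seq_along(x) <= window_s[2] * fs + 1)
  if (length(idx) == 0) stop("empty reference window", call. = FALSE)
  ref <- mean(env[idx])
  if (!is.finite(ref) || ref <= 0) {
    stop("non-positive EMG reference value", call. = FALSE)
  }
  list(muscle = muscle, reference_value = ref, source_window_s = window_s)
}

#' Process one EMG channel to the shared 25 Hz grid
#'
#' Envelope extraction ([emg_envelope()]), division by the submaximal
#' reference value, then linear resampling onto `grid` and clipping at 0.
#'
#' @param x Raw EMG vector.
#' @param fs Native sampling rate (Hz).
#' @param reference_value Positive normalization constant.
#' @param grid Target time grid (seconds, same clock as `time`).
#' @param time Sample times of `x`; defaults to `0, 1/fs, ...`.
#' @return Dimensionless non-negative envelope on `grid`.
#' @export
process_emg <- function(x, fs = EMG_FS, reference_value, grid,
                        time = (seq_along(x) - 1) / fs) {
  if (!is.finite(reference_value) || reference_value <= 0) {
    stop("reference_value must be positive", call. = FALSE)
  }
  env <- emg_envelope(x, fs) / reference_value
  pmax(as.numeric(resample_linear(time, matrix(env), grid)), 0)
}

#' Process one IMU stream to the shared 25 Hz grid
#'
#' Zero-phase 4th-order low-pass at 10 Hz per channel, then linear resampling
#' onto the shared grid. The prior band-limiting keeps the 12.5 Hz Nyquist of
#' the target rate alias-safe.
#'
#' @param data Matrix (samples x 6 channels).
#' @param fs Native sampling rate (128 Hz).
#' @param grid Target time grid in seconds.
#' @param time Sample times; defaults to `0, 1/fs, ...`.
#' @param filters Filter chain list.
#' @return Matrix on `grid` with the input's column names.
#' @export
process_imu <- function(data, fs = IMU_FS, grid,
                        time = (seq_len(nrow(data)) - 1) / fs,
                        filters = default_filters()) {
  data <- as.matrix(data)
  filt <- apply(data, 2, butterworth_filter, fs = fs, spec = filters$imu)
  resample_linear(time, filt, grid)
}

#' Process the ground-truth SJRF series to the shared 25 Hz grid
#'
#' Zero-phase 4th-order low-pass at 4 Hz per force component, then linear
#' resampling onto the shared grid.
#'
#' @param data Matrix (samples x 3), columns Fx, Fy, Fz in N.
#' @param fs Native sampling rate (100 Hz).
#' @param grid Target time grid in seconds.
#' @param time Sample times; defaults to `0, 1/fs, ...`.
#' @param filters Filter chain list.
#' @return N x 3 matrix on `grid`.
#' @export
process_sjrf <- function(data, fs = SJRF_FS, grid,
                         time = (seq_len(nrow(data)) - 1) / fs,
                         filters = default_filters()) {
  data <- as.matrix(data)
  filt <- apply(data, 2, butterworth_filter, fs = fs, spec = filters$sjrf)
  resample_linear(time, filt, grid)
}

# one comparable synchronization signal per stream: mean of standardized
# channels (the fiducial burst is common to all channels, so averaging
# boosts it relative to stream-specific content)
sync_signal <- function(stream) {
  X <- as.matrix(stream$data)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) return(rep(0, nrow(X)))
  Z <- scale(X[, keep, drop = FALSE])
  rowMeans(Z)
}

#' Estimate inter-stream clock offsets by cross-correlation
#'
#' Each stream is compared to the reference stream (the upper-arm IMU) via
#' normalized cross-correlation over a lag window, after resampling both to a
#' common 128 Hz grid. The sharp fiducial burst at the start of each stream
#' anchors the correlation peak. Streams whose peak correlation falls below
#' `min_peak` are left at offset 0 with a warning.
#'
#' @param recording An `sjrf_recording`.
#' @param lag_window_s Search window half-width in seconds (default 2).
#' @param min_peak Minimum normalized correlation peak (default 0.2).
#' @param reference Name of the reference IMU stream.
#' @return Named numeric vector of estimated offsets in seconds (positive =
#'   stream lags the reference), one per IMU and EMG stream; the reference
#'   itself is 0.
#' @export
synchronize_streams <- function(recording, lag_window_s = 2, min_peak = 0.2,
                                reference = "upper_arm") {
  fs <- IMU_FS
  ref_stream <- recording$imu[[reference]]
  t_end <- min(vapply(c(recording$imu, recording$emg),
                      function(s) max(s$time), 0))
  # correlate over the early window containing the fiducial burst (activity
  # content is still quasi-static there); content later in the trial would
  # otherwise bias the peak
  t_end <- min(t_end, TRIAL_LEAD_S + 0.5)
  grid <- seq(0, t_end, by = 1 / fs)
  # low-pass at 10 Hz: the fiducial burst lives below ~5 Hz, while the EMG
  # carrier is broadband; filtering sharpens the correlation peak
  lp <- filter_spec("low", 4, 10)
  ref <- stats::approx(ref_stream$time, sync_signal(ref_stream),
                       xout = grid, rule = 2)$y
  ref <- butterworth_filter(ref - mean(ref), fs, lp)

  est_one <- function(stream, name) {
    s <- stats::approx(stream$time, sync_signal(stream), xout = grid,
                       rule = 2)$y
    s <- butterworth_filter(s - mean(s), fs, lp)
    L <- min(round(lag_window_s * fs), length(grid) - 2L)
    lags <- -L:L
    n <- length(grid)
    # global energy normalization: short-overlap lags cannot produce
    # spuriously high correlations
    den <- sqrt(sum(ref^2) * sum(s^2))
    r <- vapply(lags, function(k) {
      if (k >= 0) {
        a <- ref[1:(n - k)]
        b2 <- s[(1 + k):n]
      } else {
        a <- ref[(1 - k):n]
        b2 <- s[1:(n + k)]
      }
      if (den == 0) 0 else sum(a * b2) / den
    }, 0)
    peak <- max(r)
    if (!is.finite(peak) || peak < min_peak) {
      warning(sprintf(
        "no reliable correlation peak for stream '%s' (peak %.2f); offset 0",
        name, peak), call. = FALSE)
      return(0)
    }
    k <- which.max(r)
    # parabolic interpolation of the peak for sub-sample resolution
    frac <- 0
    if (k > 1 && k < length(r)) {
      denom <- r[k - 1] - 2 * r[k] + r[k + 1]
      if (denom < 0) frac <- 0.5 * (r[k - 1] - r[k + 1]) / denom
      frac <- max(min(frac, 0.5), -0.5)
    }
    (lags[k] + frac) / fs
  }

  streams <- c(recording$imu, recording$emg)
  out <- stats::setNames(numeric(length(streams)), names(streams))
  for (nm in names(streams)) {
    out[nm] <- if (nm == reference) 0 else est_one(streams[[nm]], nm)
  }
  out
}

#' Align one recording onto the shared 25 Hz grid
#'
#' The full preprocessing chain for one subtrial: estimate inter-stream
#' offsets ([synchronize_streams()]), shift each stream's time base, filter
#' and resample every stream onto one 25 Hz grid, and crop to the activity
#' window (the fiducial burst and the offset margins at both ends are
#' dropped).
#'
#' @param recording An `sjrf_recording`.
#' @param emg_refs Named list (per muscle) of reference lists from
#'   [compute_emg_reference()].
#' @param filters Filter chain list.
#' @param offsets Optional externally estimated offsets (named vector);
#'   `NULL` to estimate via cross-correlation.
#' @param fs_out Output rate in Hz (25).
#' @return A data frame of class `sjrf_aligned`: `time_s`, 30 IMU columns
#'   (`<stream>_<channel>`), 2 EMG columns, `Fx`, `Fy`, `Fz`; keys attached
#'   as attributes `participant_id`, `activity`, `subtrial`.
#' @export
align_trial <- function(recording, emg_refs, filters = default_filters(),
                        offsets = NULL, fs_out = TARGET_FS) {
  if (is.null(offsets)) offsets <- synchronize_streams(recording)

  shifted <- function(stream, nm) stream$time - offsets[[nm]]
  starts <- c(vapply(names(recording$imu),
                     function(nm) min(shifted(recording$imu[[nm]], nm)), 0),
              vapply(names(recording$emg),
                     function(nm) min(shifted(recording$emg[[nm]], nm)), 0),
              min(recording$sjrf$time))
  ends <- c(vapply(names(recording$imu),
                   function(nm) max(shifted(recording$imu[[nm]], nm)), 0),
            vapply(names(recording$emg),
                   function(nm) max(shifted(recording$emg[[nm]], nm)), 0),
            max(recording$sjrf$time))
  crop0 <- max(max(starts), TRIAL_LEAD_S)
  crop1 <- min(min(ends), TRIAL_LEAD_S + recording$duration_s)
  # anchor the grid at integer multiples of the output period so every
  # subtrial lands on the identical absolute grid
  g0 <- ceiling(crop0 * fs_out) / fs_out
  grid <- seq(g0, crop1, by = 1 / fs_out)
  if (length(grid) < 13) stop("aligned window too short", call. = FALSE)

  cols <- list()
  for (s in names(recording$imu)) {
    st <- recording$imu[[s]]
    X <- process_imu(st$data, st$fs, grid, time = shifted(st, s),
                     filters = filters)
    colnames(X) <- paste(s, colnames(st$data), sep = "_")
    cols[[s]] <- X
  }
  for (m in names(recording$emg)) {
    st <- recording$emg[[m]]
    e <- process_emg(st$data[, 1], st$fs,
                     reference_value = emg_refs[[m]]$reference_value,
                     grid = grid, time = shifted(st, m))
    cols[[m]] <- matrix(e, ncol = 1, dimnames = list(NULL, paste0("emg_", m)))
  }
  Y <- process_sjrf(recording$sjrf$data, recording$sjrf$fs, grid,
                    time = recording$sjrf$time, filters = filters)
  colnames(Y) <- c("Fx", "Fy", "Fz")

  out <- data.frame(time_s = grid - grid[1], do.call(cbind, cols), Y,
                    check.names = FALSE)
  attr(out, "participant_id") <- recording$participant_id
  attr(out, "activity") <- recording$activity
  attr(out, "subtrial") <- recording$subtrial
  attr(out, "offsets") <- offsets
  class(out) <- c("sjrf_aligned", "data.frame")
  out
}

#' Preprocess a whole cohort
#'
#' Computes per-participant EMG normalization references from the static
#' posture recordings, then aligns every subtrial (valid and excluded) onto
#' the shared 25 Hz grid.
#'
#' @param cohort An `sjrf_cohort`.
#' @param filters Filter chain list.
#' @return List with `aligned` (named list of `sjrf_aligned` data frames,
#'   keyed like the manifest) and `emg_refs` (per participant, per muscle).
#' @export
align_cohort <- function(cohort, filters = default_filters()) {
  participants <- sort(unique(cohort$manifest$participant_id))
  emg_refs <- lapply(participants, function(p) {
    rec <- cohort$static[[p]]
    refs <- lapply(names(rec$emg), function(m) {
      compute_emg_reference(rec$emg[[m]]$data[, 1], rec$emg[[m]]$fs,
                            muscle = m)
    })
    stats::setNames(refs, names(rec$emg))
  })
  names(emg_refs) <- as.character(participants)
  aligned <- lapply(stats::setNames(cohort$manifest$key, cohort$manifest$key),
                    function(key) {
      rec <- cohort$recordings[[key]]
      align_trial(rec, emg_refs[[as.character(rec$participant_id)]],
                  filters = filters)
    })
  list(aligned = aligned, emg_refs = emg_refs)
}
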