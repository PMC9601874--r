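#' Construct a raw single-lead ECG signal
#'
#' @param samples numeric vector (millivolts, arbitrary offset).
#' @param fs sampling rate in Hz, finite and positive.
#' @return an object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("signal must have at least 2 samples", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be finite and positive", call. = FALSE)
  structure(list(samples = samples, fs = fs), class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("ECG signal: %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' A fixed-length single heartbeat
#'
#' @param samples numeric vector of length `length`.
#' @param r_index 1-based position of the R peak within the beat.
#' @param label optional class tag (one of `N`, `L.B.B.B.`, `R.B.B.B.`,
#'   `A.P.`, `P.V.C.`, `F.V.N.`, `V.F.`).
#' @param length required beat length (default 300).
#' @return an object of class `ecg_beat`.
#' @export
ecg_beat <- function(samples, r_index, label = NA_character_, length = 300) {
  samples <- as.numeric(samples)
  if (base::length(samples) != length) {
    stop(sprintf("beat must have exactly %d samples, got %d", length,
                 base::length(samples)), call. = FALSE)
  }
  if (r_index < 1 || r_index > length) {
    stop("'r_index' must lie inside the beat", call. = FALSE)
  }
  structure(list(samples = samples, r_index = as.integer(r_index),
                 label = label),
            class = "ecg_beat")
}

#' @export
print.ecg_beat <- function(x, ...) {
  cat(sprintf("ECG beat: %d samples, R peak at %d%s\n", length(x$samples),
              x$r_index,
              if (is.na(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Attenuates spectral content above `cutoff_hz` (default 50 Hz, above which
#' ECG content is dominated by noise) with an order-`order` Butterworth filter
#' applied forward and backward ([signal::filtfilt]), so R-peak positions are
#' not shifted.
#'
#' @param signal an [ecg_signal()].
#' @param cutoff_hz cutoff frequency; must lie strictly below the Nyquist
#'   frequency `fs/2`.
#' @param order filter order (default 4; the effective attenuation is doubled
#'   by the forward-backward pass).
#' @return an [ecg_signal()] of identical length.
#' @export
lowpass_filter <- function(signal, cutoff_hz = 50, order = 4) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (cutoff_hz <= 0 || cutoff_hz >= signal$fs / 2) {
    stop(sprintf("'cutoff_hz' must lie in (0, fs/2) = (0, %g)", signal$fs / 2),
         call. = FALSE)
  }
  if (length(signal$samples) <= 3 * (order + 1)) {
    stop("signal shorter than the filter warm-up length", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (signal$fs / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward edge transients
  x <- signal$samples
  n <- length(x)
  pad <- min(n - 1L, 12L * order)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, ext)
  ecg_signal(y[(pad + 1):(pad + n)], signal$fs)
}

#' Detect R peaks by adaptive-threshold local search
#'
#' A sample is reported as an R peak when it is a strict local maximum, rises
#' above an adaptive amplitude threshold (a fraction of the rolling maximum
#' over a 2-second window), and lies at least one refractory interval after
#' the previous accepted peak. Returns an empty vector (not an error) when no
#' candidate clears the threshold, e.g. on a flat signal.
#'
#' @param signal a filtered [ecg_signal()].
#' @param refractory_s minimum R-R separation in seconds (default 0.2).
#' @param threshold_frac fraction of the rolling 2-s maximum used as the
#'   amplitude threshold (default 0.6).
#' @return an integer vector of strictly increasing 1-based peak indices.
#' @export
detect_r_peaks <- function(signal, refractory_s = 0.2, threshold_frac = 0.6) {
  stopifnot(inherits(signal, "ecg_signal"))
  x <- signal$samples
  n <- length(x)
  refractory <- max(1L, as.integer(round(refractory_s * signal$fs)))
  if (n < refractory + 2L) return(integer(0))
  win <- min(n, as.integer(round(2 * signal$fs)))
  roll_max <- zoo::rollapply(zoo::zoo(x), width = win, FUN = max,
                             partial = TRUE, align = "center")
  thr <- threshold_frac * as.numeric(roll_max)
  # strict local maxima (plateaus take their first sample)
  i <- 2:(n - 1)
  is_peak <- x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > thr[i] & x[i] > 0
  cand <- i[is_peak]
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  last <- -Inf
  for (p in cand) {
    if (p - last >= refractory) {
      keep <- c(keep, p)
      last <- p
    } else if (x[p] > x[keep[length(keep)]]) {
      keep[length(keep)] <- p            # taller peak within the refractory window wins
      last <- p
    }
  }
  keep
}

#' Slice fixed-length beats around detected R peaks
#'
#' Each peak yields the contiguous window
#' `[peak - pre_samples, peak - pre_samples + beat_length)`; peaks whose
#' window would cross a record boundary are dropped and counted. The default
#' alignment places the R peak 100 samples into a 300-sample beat
#' (about 0.28 s of pre-R context at 360 Hz), leaving room for both the P and
#' the T wave.
#'
#' @param signal an [ecg_signal()].
#' @param peaks integer vector of R-peak indices (1-based).
#' @param pre_samples samples kept before each R peak (default 100).
#' @param beat_length beat length in samples (default 300).
#' @return a list with `beats` (list of [ecg_beat()]) and `n_dropped`
#'   (boundary peaks skipped).
#' @export
segment_beats <- function(signal, peaks, pre_samples = 100, beat_length = 300) {
  stopifnot(inherits(signal, "ecg_signal"))
  n <- length(signal$samples)
  beats <- list()
  dropped <- 0L
  for (p in peaks) {
    start <- p - pre_samples
    if (start < 1 || start + beat_length - 1 > n) {
      dropped <- dropped + 1L
      next
    }
    beats[[length(beats) + 1L]] <-
      ecg_beat(signal$samples[start:(start + beat_length - 1)],
               r_index = pre_samples + 1L, length = beat_length)
  }
  if (dropped > 0) {
    message(sprintf("segment_beats: dropped %d peak(s) too close to record boundaries",
                    dropped))
  }
  list(beats = beats, n_dropped = dropped)
}

#' Resample a signal to a target rate by linear interpolation
#'
#' Fixed 300-sample beats presuppose a fixed rate; records not sampled at
#' 360 Hz are linearly resampled before segmentation.
#'
#' @param signal an [ecg_signal()].
#' @param fs_out target sampling rate (default 360).
#' @return an [ecg_signal()] at `fs_out`.
#' @export
resample_signal <- function(signal, fs_out = 360) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (signal$fs == fs_out) return(signal)
  n <- length(signal$samples)
  t_old <- (seq_len(n) - 1) / signal$fs
  t_new <- seq(0, t_old[n], by = 1 / fs_out)
  ecg_signal(stats::approx(t_old, signal$samples, xout = t_new)$y, fs_out)
}

#' Full preprocessing: filter, detect, segment
#'
#' Resamples to 360 Hz if needed, applies the zero-phase low-pass, detects R
#' peaks and slices 300-sample beats.
#'
#' @param signal an [ecg_signal()].
#' @param cutoff_hz low-pass cutoff (default 50).
#' @param pre_samples,beat_length see [segment_beats()].
#' @return a list with `beats`, `peaks`, `n_dropped`, and the filtered signal.
#' @export
preprocess_signal <- function(signal, cutoff_hz = 50, pre_samples = 100,
                              beat_length = 300) {
  signal <- resample_signal(signal, 360)
  filt <- lowpass_filter(signal, cutoff_hz)
  peaks <- detect_r_peaks(filt)
  seg <- segment_beats(filt, peaks, pre_samples, beat_length)
  list(beats = seg$beats, peaks = peaks, n_dropped = seg$n_dropped,
       filtered = filt)
}

#' Stack beats into a matrix (one beat per row)
#'
#' @param beats a list of [ecg_beat()] objects.
#' @return a numeric matrix with `beat_length` columns.
#' @export
beats_matrix <- function(beats) {
  do.call(rbind, lapply(beats, function(b) b$samples))
}
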