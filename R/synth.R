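#' Rhythm classes recognised by the synthetic generator
#' @export
wscec_classes <- c("N", "L.B.B.B.", "R.B.B.B.", "A.P.", "P.V.C.", "F.V.N.", "V.F.")

# Reference normal PQRST morphology at 360 Hz: Gaussian bumps, times in
# seconds relative to the R apex, amplitudes in millivolt-like units.
.pqrst_template <- data.frame(
  wave   = c("P", "Q", "R", "S", "T"),
  center = c(-0.170, -0.030, 0.000, 0.030, 0.190),
  sigma  = c(0.022, 0.009, 0.011, 0.009, 0.045),
  amp    = c(0.15, -0.12, 1.00, -0.20, 0.35),
  stringsAsFactors = FALSE
)

# Class-specific morphology deltas applied to the reference template.
# BBB classes widen the QRS by 2.5x and add a second R bump (pronounced for
# right, shallow for left); atrial premature beats shift the P wave 40 ms
# earlier; PVC enlarges (x1.8) and widens the QRS and suppresses the P wave;
# ventricular flutter is a 5 Hz sinusoid; FVN averages normal and flutter.
.class_template <- function(class_tag) {
  tpl <- .pqrst_template
  qrs <- tpl$wave %in% c("Q", "R", "S")
  # widening is a time dilation of the whole complex about the R apex:
  # both the bump widths and the Q/S offsets scale
  widen_qrs <- function(tpl, factor) {
    tpl$sigma[qrs] <- tpl$sigma[qrs] * factor
    tpl$center[qrs] <- tpl$center[qrs] * factor
    tpl
  }
  second_r <- NULL
  switch(class_tag,
    "N" = NULL,
    "L.B.B.B." = {
      tpl <- widen_qrs(tpl, 2.5)
      second_r <- data.frame(wave = "R2", center = 0.070, sigma = 0.020,
                             amp = 0.30)
    },
    "R.B.B.B." = {
      tpl <- widen_qrs(tpl, 2.5)
      second_r <- data.frame(wave = "R2", center = 0.070, sigma = 0.020,
                             amp = 0.80)
    },
    "A.P." = {
      tpl$center[tpl$wave == "P"] <- tpl$center[tpl$wave == "P"] - 0.040
    },
    "P.V.C." = {
      tpl <- widen_qrs(tpl, 2.0)
      tpl$amp[qrs] <- tpl$amp[qrs] * 1.8
      tpl$amp[tpl$wave == "P"] <- 0
    },
    "F.V.N." = NULL,   # handled as a template average in generate_beat
    "V.F."   = NULL,   # pure sinusoid, no bumps
    stop(sprintf("unknown class '%s'", class_tag), call. = FALSE)
  )
  rbind(tpl, second_r)
}

#' Specification of one synthetic beat
#'
#' @param class_tag one of [wscec_classes].
#' @param fs sampling rate (default 360 Hz).
#' @param length beat length in samples (default 300).
#' @param r_offset samples before the R apex (default 100, matching
#'   [segment_beats()] alignment).
#' @param amplitude_jitter multiplicative s.d. applied per wave (default 0.05).
#' @param timing_jitter s.d. of per-wave centre shifts in seconds
#'   (default 0.004).
#' @param noise_sd additive white-noise s.d. (default 0.02).
#' @param seed integer seed; identical spec + seed reproduces the beat exactly.
#' @return a list of class `beat_spec`.
#' @export
beat_spec <- function(class_tag = "N", fs = 360, length = 300, r_offset = 100,
                      amplitude_jitter = 0.05, timing_jitter = 0.004,
                      noise_sd = 0.02, seed = 1) {
  if (!class_tag %in% wscec_classes) {
    stop(sprintf("unknown class '%s'; expected one of %s", class_tag,
                 paste(wscec_classes, collapse = ", ")), call. = FALSE)
  }
  stopifnot(fs > 0, length > 1, r_offset >= 0, r_offset < length,
            amplitude_jitter >= 0, timing_jitter >= 0, noise_sd >= 0)
  structure(list(class_tag = class_tag, fs = fs, length = as.integer(length),
                 r_offset = as.integer(r_offset),
                 amplitude_jitter = amplitude_jitter,
                 timing_jitter = timing_jitter, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "beat_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.render_bumps <- function(tpl, t, amp_jit, time_jit) {
  y <- numeric(length(t))
  for (w in seq_len(nrow(tpl))) {
    a <- tpl$amp[w] * (1 + stats::rnorm(1, 0, amp_jit))
    c0 <- tpl$center[w] + stats::rnorm(1, 0, time_jit)
    y <- y + a * exp(-(t - c0)^2 / (2 * tpl$sigma[w]^2))
  }
  y
}

#' Generate one synthetic beat
#'
#' Sums class-specific Gaussian bumps for the P, Q, R, S and T waves (plus a
#' second R bump for bundle-branch-block classes), then adds white noise.
#' Ventricular flutter is rendered as a 5 Hz sinusoid with the R amplitude;
#' the fusion class averages the normal and flutter waveforms.
#'
#' @param spec a [beat_spec()].
#' @return an [ecg_beat()] carrying the class label.
#' @export
#' @examples
#' b <- generate_beat(beat_spec("N", seed = 1))
#' which.max(b$samples)   # the planted R apex, near sample 101
generate_beat <- function(spec) {
  stopifnot(inherits(spec, "beat_spec"))
  .with_seed(spec$seed, {
    t <- (seq_len(spec$length) - 1 - spec$r_offset) / spec$fs   # seconds from R
    flutter <- function() {
      a <- 1.0 * (1 + stats::rnorm(1, 0, spec$amplitude_jitter))
      ph <- stats::rnorm(1, 0, spec$timing_jitter) * 2 * pi * 5
      a * cos(2 * pi * 5 * t + ph)
    }
    clean <- switch(spec$class_tag,
      "V.F."   = flutter(),
      "F.V.N." = {
        normal <- .render_bumps(.class_template("N"), t,
                                spec$amplitude_jitter, spec$timing_jitter)
        (normal + flutter()) / 2
      },
      .render_bumps(.class_template(spec$class_tag), t,
                    spec$amplitude_jitter, spec$timing_jitter)
    )
    samples <- clean + stats::rnorm(spec$length, 0, spec$noise_sd)
    ecg_beat(samples, r_index = spec$r_offset + 1L, label = spec$class_tag,
             length = spec$length)
  })
}

#' Generate a continuous synthetic record with ground truth
#'
#' Concatenates seeded beats back-to-back (one beat per 300 samples at
#' 360 Hz, i.e. 72 bpm), adds a 0.3 Hz low-amplitude baseline-wander
#' sinusoid, and pads both ends so the boundary beats survive filtering and
#' segmentation.
#'
#' @param class_counts named integer vector, e.g. `c("N" = 3, "V.F." = 2)`;
#'   beats are emitted class by class in the given order.
#' @param seed integer master seed; per-beat seeds are derived from it.
#' @param fs,beat_length,r_offset,amplitude_jitter,timing_jitter,noise_sd
#'   forwarded to [beat_spec()].
#' @param wander_amp baseline-wander amplitude (default 0.05).
#' @param pad samples of quiet baseline at each end (default 36, i.e. 0.1 s).
#' @return a list with `signal` (an [ecg_signal()]) and `annotations`
#'   (data frame: `class`, `r_index` 1-based global R positions).
#' @export
generate_record <- function(class_counts, seed = 1, fs = 360, beat_length = 300,
                            r_offset = 100, amplitude_jitter = 0.05,
                            timing_jitter = 0.004, noise_sd = 0.02,
                            wander_amp = 0.05, pad = 36) {
  class_counts <- class_counts[class_counts > 0]
  classes <- rep(names(class_counts), times = class_counts)
  n_beats <- length(classes)
  total <- if (n_beats > 0) n_beats * beat_length + 2 * pad else 0L
  samples <- numeric(total)
  r_index <- integer(n_beats)
  for (i in seq_len(n_beats)) {
    spec <- beat_spec(classes[i], fs = fs, length = beat_length,
                      r_offset = r_offset,
                      amplitude_jitter = amplitude_jitter,
                      timing_jitter = timing_jitter, noise_sd = noise_sd,
                      seed = (seed * 1000L + i) %% .Machine$integer.max)
    start <- pad + (i - 1) * beat_length
    samples[start + seq_len(beat_length)] <- generate_beat(spec)$samples
    r_index[i] <- start + r_offset + 1L
  }
  if (total > 0) {
    tt <- (seq_len(total) - 1) / fs
    samples <- samples + wander_amp * sin(2 * pi * 0.3 * tt)
  }
  sig <- if (total >= 2) ecg_signal(samples, fs) else
    structure(list(samples = numeric(0), fs = fs), class = "ecg_signal")
  list(signal = sig,
       annotations = data.frame(class = classes, r_index = r_index,
                                stringsAsFactors = FALSE))
}

#' Write a synthetic record to CSV with JSON annotations
#'
#' @param record the result of [generate_record()].
#' @param path CSV output path (single `sample` column); annotations land at
#'   `<path>.json` together with the sampling rate.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(data.frame(sample = record$signal$samples), path,
                   row.names = FALSE)
  jsonlite::write_json(list(fs = record$signal$fs,
                            annotations = record$annotations),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single-column CSV signal
#'
#' @param path CSV with one numeric column.
#' @param fs sampling rate of the stored signal.
#' @return an [ecg_signal()].
#' @export
read_signal_csv <- function(path, fs) {
  df <- utils::read.csv(path)
  ecg_signal(df[[1]], fs)
}
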