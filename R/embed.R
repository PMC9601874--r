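#' Embedding configuration for the sliding-window FFT
#'
#' Parameters of the short-time FFT embedding that maps a beat to an ordered
#' point cloud in \eqn{R^d}. Window length `l` is chosen near the sample
#' length of the sharp part of a normal QRS complex (about 10 samples at
#' 360 Hz) so the embedding emphasises QRS changes.
#'
#' @param l window length in samples (default 10).
#' @param tau sliding step in samples (default 1).
#' @param d embedding dimension; must be odd and at most `l` (default 3).
#' @param scale multiplier applied to the coefficient vector (default `2/l`,
#'   under which the first-harmonic coordinates of a window-commensurate
#'   sinusoid equal its amplitude).
#' @return an object of class `embed_config`.
#' @export
embed_config <- function(l = 10, tau = 1, d = 3, scale = 2 / l) {
  if (l < 2) stop("window length 'l' must be at least 2", call. = FALSE)
  if (tau < 1) stop("sliding step 'tau' must be at least 1", call. = FALSE)
  if (d %% 2 != 1) stop("embedding dimension 'd' must be odd", call. = FALSE)
  if (d > l) stop("'d' must not exceed the window length 'l'", call. = FALSE)
  structure(list(l = as.integer(l), tau = as.integer(tau), d = as.integer(d),
                 scale = scale),
            class = "embed_config")
}

#' @export
print.embed_config <- function(x, ...) {
  cat(sprintf("STFFT embedding: l = %d, tau = %d, d = %d, scale = %g\n",
              x$l, x$tau, x$d, x$scale))
  invisible(x)
}

#' Sliding windows of a beat
#'
#' Splits a length-n signal into \eqn{\hat n - 1} contiguous windows of
#' length `l`, where \eqn{\hat n = \lfloor(n - l)/\tau\rfloor}; window k
#' (k = 1, ..., \eqn{\hat n - 1}) starts at zero-based offset \eqn{k\tau}.
#' Note the indexing starts at k = 1, so the window at offset 0 is not used.
#'
#' @param samples numeric vector (one beat).
#' @param l window length.
#' @param tau sliding step.
#' @return a matrix with one window per row (`nhat - 1` rows, `l` columns).
#' @export
sliding_windows <- function(samples, l = 10, tau = 1) {
  n <- length(samples)
  nhat <- floor((n - l) / tau)
  if (nhat < 2) {
    stop(sprintf("signal of length %d too short for l = %d, tau = %d (needs at least one window)",
                 n, l, tau), call. = FALSE)
  }
  k <- seq_len(nhat - 1)
  starts <- k * tau               # zero-based offsets
  idx <- outer(starts, seq_len(l) - 1L, "+") + 1L
  matrix(samples[idx], nrow = nhat - 1L, ncol = l)
}

#' Leading real FFT coefficients of one window
#'
#' Computes the DFT \eqn{C_k = \sum_i t_i e^{-2\pi j k i / l}} and returns
#' the first `d` real coordinates \eqn{(a_0, a_1, b_1, \ldots)} where
#' \eqn{a_k, b_k} are the real and imaginary parts of \eqn{C_k}, multiplied
#' by `scale`.
#'
#' @param window numeric vector of length `l`.
#' @param d odd number of coordinates to keep, `d <= l`.
#' @param scale multiplier.
#' @return a numeric vector of length `d`.
#' @export
#' @examples
#' fft_coeffs(rep(1, 10), d = 3, scale = 1)  # (10, 0, 0)
fft_coeffs <- function(window, d = 3, scale = 1) {
  if (d %% 2 != 1 || d > length(window)) {
    stop("'d' must be odd and at most the window length", call. = FALSE)
  }
  C <- stats::fft(window)
  nh <- (d - 1) / 2
  out <- numeric(d)
  out[1] <- Re(C[1])
  if (nh > 0) {
    k <- seq_len(nh)
    out[2 * k]     <- Re(C[k + 1])
    out[2 * k + 1] <- Im(C[k + 1])
  }
  scale * out
}

#' Embed one beat as a point cloud in R^d
#'
#' Composes [sliding_windows()] and [fft_coeffs()]: each window becomes one
#' point whose coordinates are the scaled leading FFT coefficients.
#'
#' @param beat an [ecg_beat] or numeric vector.
#' @param config an [embed_config()].
#' @return an object of class `embedded_cloud`: list with `points`
#'   (matrix, one point per row, `d` columns) and `config`.
#' @export
embed_beat <- function(beat, config = embed_config()) {
  samples <- if (inherits(beat, "ecg_beat")) beat$samples else as.numeric(beat)
  W <- sliding_windows(samples, config$l, config$tau)
  C <- stats::mvfft(t(W))            # DFT of each window (columns)
  nh <- (config$d - 1) / 2
  pts <- matrix(0, nrow = nrow(W), ncol = config$d)
  pts[, 1] <- Re(C[1, ])
  if (nh > 0) {
    for (k in seq_len(nh)) {
      pts[, 2 * k]     <- Re(C[k + 1, ])
      pts[, 2 * k + 1] <- Im(C[k + 1, ])
    }
  }
  structure(list(points = config$scale * pts, config = config),
            class = "embedded_cloud")
}

#' @export
print.embedded_cloud <- function(x, ...) {
  cat(sprintf("STFFT point cloud: %d points in R^%d (l = %d, tau = %d)\n",
              nrow(x$points), ncol(x$points), x$config$l, x$config$tau))
  invisible(x)
}

#' Write an embedded cloud to CSV with a sidecar config JSON
#'
#' @param cloud an `embedded_cloud`.
#' @param path CSV output path; the config is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  df <- as.data.frame(cloud$points)
  names(df) <- paste0("x", seq_len(ncol(cloud$points)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(unclass(cloud$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
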