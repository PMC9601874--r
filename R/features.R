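#' Wasserstein scalar curvature sequence of an SPD cloud
#'
#' Evaluates [scalar_curvature()] at every matrix of the cloud, producing the
#' per-beat curvature sequence \eqn{W = \{w_i\}}; every value is positive and
#' below [curvature_upper_bound()] of its matrix.
#'
#' @param cloud an `spd_cloud` or a list of SPD matrices.
#' @return a numeric vector of positive curvatures, one per matrix.
#' @export
wsc_sequence <- function(cloud) {
  mats <- if (inherits(cloud, "spd_cloud")) cloud$matrices else cloud
  vapply(mats, scalar_curvature, numeric(1))
}

#' Histogram ceiling from the standard beat
#'
#' The histogram ceiling is the minimum of the standard (reference normal)
#' beat's maximum scalar curvature and the analytic cap
#' \eqn{3 d (d - 1) / \epsilon}, where \eqn{\epsilon} is the assumed lower
#' bound on the second-smallest eigenvalue of the local scatter matrices.
#'
#' @param standard_curvatures curvature sequence of the standard beat.
#' @param epsilon positive eigenvalue scale (default 0.09).
#' @param d embedding dimension (default 3).
#' @return the ceiling `b`.
#' @export
#' @examples
#' choose_b(c(10, 500), epsilon = 0.09, d = 3)  # analytic cap: 200
choose_b <- function(standard_curvatures, epsilon = 0.09, d = 3) {
  if (length(standard_curvatures) == 0) {
    stop("empty curvature sequence", call. = FALSE)
  }
  if (epsilon <= 0) stop("'epsilon' must be positive", call. = FALSE)
  min(max(standard_curvatures), 3 * d * (d - 1) / epsilon)
}

#' Curvature histogram with bin width m and ceiling b
#'
#' Bins the curvature sequence into half-open intervals
#' \eqn{[mj, m(j+1))} for \eqn{j = 0, \ldots, \lfloor b/m \rfloor}. Values at
#' or above the upper edge of the last bin are excluded and counted
#' separately, so `sum(counts) + excluded == length(values)`.
#'
#' @param values positive curvature sequence.
#' @param m bin width (> 0, default 1).
#' @param b ceiling (> 0).
#' @return an object of class `curvature_histogram`: list with `m`, `b`,
#'   `counts` (length `floor(b/m) + 1`, named by bin index starting at 0) and
#'   `excluded`.
#' @export
curvature_histogram <- function(values, m = 1, b) {
  if (m <= 0 || b <= 0) stop("'m' and 'b' must be positive", call. = FALSE)
  jmax <- floor(b / m)
  j <- floor(values / m)
  inside <- j <= jmax & values >= 0
  counts <- tabulate(j[inside] + 1L, nbins = jmax + 1L)
  structure(list(m = m, b = b, counts = counts,
                 excluded = sum(!inside)),
            class = "curvature_histogram")
}

#' @export
print.curvature_histogram <- function(x, ...) {
  cat(sprintf("Curvature histogram: %d bins of width %g up to %g, %d values excluded\n",
              length(x$counts), x$m, x$b, x$excluded))
  invisible(x)
}

#' Write a curvature histogram to CSV
#'
#' @param hist a `curvature_histogram`.
#' @param path output path; columns `bin_low`, `bin_high`, `count`.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  j <- seq_along(hist$counts) - 1L
  utils::write.csv(data.frame(bin_low = hist$m * j, bin_high = hist$m * (j + 1),
                              count = hist$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Curvature dispersion of one beat
#'
#' Summarises the curvature sequence and its histogram as a point in the
#' dispersion plane:
#' \itemize{
#'   \item `cur1` (transverse dispersion): the median of
#'     \eqn{U_1 = \{w \in W : ms \le w \le b\}} (mean of the middle two for
#'     even cardinality).
#'   \item `cur2` (longitudinal dispersion):
#'     \eqn{\sqrt{\frac{1}{|U_2|-s-1} \sum_{j \ge s+1} (y_j - \bar y)^2}}
#'     with \eqn{\bar y = (\sum_{j \in U_2} y_j)/\lfloor b/m\rfloor} and
#'     \eqn{U_2 = \{j \ge s+1 : y_j \ne 0\}}.
#' }
#' With `s = 0` and every column \eqn{j \ge 1} nonzero, `cur2` reduces to the
#' sample standard deviation of the columns; zeroed columns both enter the
#' deviation sum at height 0 and shrink the \eqn{|U_2|-s-1} denominator, so
#' emptying a bin amplifies the dispersion. Evenly filled histograms give
#' points near \eqn{((b+ms)/2, 0)}: healthy beats, whose curvature spreads
#' regularly, land to the right and low.
#'
#' When \eqn{U_1} is empty or \eqn{|U_2|-s-1 \le 0}, the corresponding
#' component is `NA` and the beat is flagged unclassifiable rather than
#' producing `NaN`.
#'
#' @param values positive curvature sequence `W`.
#' @param hist a `curvature_histogram` of `values` (bin width `m`, ceiling `b`).
#' @param s nonnegative integer truncation index, `s <= floor(b/m)` (default 0).
#' @return an object of class `dispersion_point`: list with `cur1`, `cur2`,
#'   `ok` (logical) and `reason` (`NA` or a string explaining the flag).
#' @export
dispersion <- function(values, hist, s = 0) {
  m <- hist$m; b <- hist$b
  jmax <- floor(b / m)
  if (s < 0 || s > jmax) stop("'s' must lie in [0, floor(b/m)]", call. = FALSE)
  u1 <- values[values >= m * s & values <= b]
  cur1 <- if (length(u1)) stats::median(u1) else NA_real_
  y <- hist$counts                       # y[j + 1] is column j
  # deviation sum runs over all j >= s+1 (zero columns included)
  j_all <- if (s + 1 <= jmax) seq.int(s + 1, jmax) else integer(0)
  u2 <- j_all[y[j_all + 1L] != 0]
  denom <- length(u2) - s - 1
  cur2 <- if (denom >= 1) {
    ybar <- sum(y[u2 + 1L]) / jmax
    sqrt(sum((y[j_all + 1L] - ybar)^2) / denom)
  } else NA_real_
  reason <- if (is.na(cur1)) {
    "no curvature values inside [m*s, b]"
  } else if (is.na(cur2)) {
    "fewer than s + 2 nonzero histogram columns above index s"
  } else NA_character_
  structure(list(cur1 = cur1, cur2 = cur2,
                 ok = !is.na(cur1) && !is.na(cur2), reason = reason),
            class = "dispersion_point")
}

#' @export
print.dispersion_point <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("Dispersion point: cur1 = %.4g, cur2 = %.4g\n", x$cur1, x$cur2))
  } else {
    cat(sprintf("Dispersion point: unclassifiable (%s)\n", x$reason))
  }
  invisible(x)
}
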