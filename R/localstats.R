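#' k-nearest-neighbour indices within a point cloud
#'
#' Exact Euclidean kNN of point `i` among the other points of the cloud; the
#' centre point is not its own neighbour unless `include_self = TRUE`.
#' Distance ties are broken by smaller index, so the result is deterministic.
#'
#' @param cloud an `embedded_cloud` or a numeric matrix (points in rows).
#' @param i index of the centre point (1-based).
#' @param k neighbourhood size; must be smaller than the number of points.
#' @param include_self count the centre point itself as one of the k
#'   neighbours (default `FALSE`).
#' @return an integer vector of `k` indices ordered by increasing distance.
#' @export
knn_indices <- function(cloud, i, k, include_self = FALSE) {
  pts <- if (inherits(cloud, "embedded_cloud")) cloud$points else as.matrix(cloud)
  n <- nrow(pts)
  if (k >= n) stop(sprintf("k = %d must be smaller than the cloud size %d", k, n),
                   call. = FALSE)
  d2 <- colSums((t(pts) - pts[i, ])^2)
  cand <- if (include_self) seq_len(n) else setdiff(seq_len(n), i)
  ord <- cand[order(d2[cand], cand)]
  ord[seq_len(k)]
}

#' Local Gaussian statistics of one neighbourhood
#'
#' Mean and scatter of the k nearest neighbours of point `i`:
#' \eqn{\mu_i = \frac{1}{k}\sum_j N_{ij}} and the unnormalised scatter
#' \eqn{\Sigma_i = \sum_j (N_{ij}-\mu_i)^T (N_{ij}-\mu_i)} (outer products of
#' row-vector deviations, no \eqn{1/k} factor). The neighbourhood is modelled
#' as a sample from a local Gaussian whose covariance carries the fine
#' structure of the cloud.
#'
#' @inheritParams knn_indices
#' @return a list of class `neighborhood` with `center_index`,
#'   `member_indices`, `mu` (d-vector) and `sigma` (d x d symmetric PSD matrix).
#' @export
local_gaussian <- function(cloud, i, k, include_self = FALSE) {
  pts <- if (inherits(cloud, "embedded_cloud")) cloud$points else as.matrix(cloud)
  idx <- knn_indices(pts, i, k, include_self)
  nb <- pts[idx, , drop = FALSE]
  mu <- colMeans(nb)
  dev <- sweep(nb, 2, mu)
  sigma <- crossprod(dev)            # sum of outer products, unnormalised
  structure(list(center_index = i, member_indices = idx,
                 mu = mu, sigma = .symmetrize(sigma)),
            class = "neighborhood")
}

#' SPD point cloud of local scatter matrices
#'
#' Converts every point of a Euclidean cloud into the scatter matrix of its
#' k-nearest-neighbour neighbourhood. Scatter matrices whose smallest
#' eigenvalue falls below `eig_floor` are regularised by adding
#' `eig_floor * I`; the number of regularised matrices is recorded (rank
#' deficiency signals a locally degenerate embedding, where the curvature
#' bound is uninformative).
#'
#' @param cloud an `embedded_cloud` or numeric matrix.
#' @param k neighbourhood size (default 20).
#' @param eig_floor eigenvalue floor; `NULL` (default) uses
#'   `1e-8 *` the mean trace of the cloud's scatter matrices, falling back to
#'   `1e-8` when that mean is zero (all-degenerate cloud).
#' @param include_self passed to [knn_indices()].
#' @return an object of class `spd_cloud`: list with `matrices` (list of d x d
#'   SPD matrices, one per source point), `k`, `eig_floor`, `n_regularized`.
#' @export
spd_cloud <- function(cloud, k = 20, eig_floor = NULL, include_self = FALSE) {
  pts <- if (inherits(cloud, "embedded_cloud")) cloud$points else as.matrix(cloud)
  n <- nrow(pts)
  mats <- vector("list", n)
  for (i in seq_len(n)) {
    mats[[i]] <- local_gaussian(pts, i, k, include_self)$sigma
  }
  if (is.null(eig_floor)) {
    mean_tr <- mean(vapply(mats, function(m) sum(diag(m)), numeric(1)))
    eig_floor <- if (mean_tr > 0) 1e-8 * mean_tr else 1e-8
  }
  n_reg <- 0L
  d <- ncol(pts)
  for (i in seq_len(n)) {
    ev <- eigen(mats[[i]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < eig_floor) {
      mats[[i]] <- mats[[i]] + diag(eig_floor, d)
      n_reg <- n_reg + 1L
    }
  }
  structure(list(matrices = mats, k = as.integer(k), eig_floor = eig_floor,
                 n_regularized = n_reg),
            class = "spd_cloud")
}

#' @export
print.spd_cloud <- function(x, ...) {
  d <- if (length(x$matrices)) nrow(x$matrices[[1]]) else 0L
  cat(sprintf("SPD point cloud: %d matrices of size %dx%d (k = %d, %d regularized)\n",
              length(x$matrices), d, d, x$k, x$n_regularized))
  invisible(x)
}

#' @export
length.spd_cloud <- function(x) length(x$matrices)

#' Write an SPD cloud to CSV (row-major upper triangles) with sidecar JSON
#'
#' @param cloud an `spd_cloud`.
#' @param path CSV output path; `k` and the regularisation count are written
#'   next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spd_csv <- function(cloud, path) {
  # column-major lower triangle of a symmetric matrix == row-major upper triangle
  rows <- t(vapply(cloud$matrices, function(m) m[lower.tri(m, diag = TRUE)],
                   numeric(sum(lower.tri(cloud$matrices[[1]], diag = TRUE)))))
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  jsonlite::write_json(list(k = cloud$k, eig_floor = cloud$eig_floor,
                            n_regularized = cloud$n_regularized),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
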