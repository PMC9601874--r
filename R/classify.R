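#' The default symptom-description-domain partition of the dispersion plane
#'
#' Rectangles in the (cur1, cur2) plane associated with cardiac conditions.
#' Interval endpoints carry open/closed flags; unbounded sides are `Inf`.
#' The coarse domains are disjoint in cur1:
#' \itemize{
#'   \item `D0` = (25, 200] x \[0, 25\]: normal (fine label `N`).
#'   \item `D1` = (25, 90] x (25, Inf): atrial abnormal (`A.P.`).
#'   \item `D2` = (10, 25] x \[0, Inf): ventricular abnormal, with subdomains
#'     `D21` = (10, 25] x \[0, 50\] (`V.F.`), `D22` = (10, 25] x \[40, 70\]
#'     (`F.V.N.`), `D23` = (10, 25] x \[60, Inf) (`P.V.C.`); subdomain
#'     overlaps are deliberate and yield the coarse label only.
#'   \item `D3` = \[0, 10) x \[0, Inf): bundle branch block, with `D31` =
#'     \[0, 10) x \[0, 140\] (`L.B.B.B.`) and `D32` = \[0, 10) x \[100, Inf)
#'     (`R.B.B.B.`), again overlapping.
#'   \item `D4`: the complement — unclassified.
#' }
#' The boxes reflect a clinical-recording calibration under the default
#' embedding scale; [read_partition()] loads alternative boxes from JSON for
#' recalibrated pipelines.
#'
#' @return a list of class `domain_partition`. Each rectangle is a list with
#'   elements `cur1` and `cur2`, each `c(lo, hi)` with attributes dropped, and
#'   `cur1_open`/`cur2_open` logical pairs (`TRUE` = open endpoint).
#' @export
default_partition <- function() {
  rect <- function(c1, c1o, c2, c2o) {
    list(cur1 = c1, cur1_open = c1o, cur2 = c2, cur2_open = c2o)
  }
  structure(list(
    D0  = rect(c(25, 200), c(TRUE, FALSE), c(0, 25),    c(FALSE, FALSE)),
    D1  = rect(c(25, 90),  c(TRUE, FALSE), c(25, Inf),  c(TRUE, TRUE)),
    D2  = rect(c(10, 25),  c(TRUE, FALSE), c(0, Inf),   c(FALSE, TRUE)),
    D21 = rect(c(10, 25),  c(TRUE, FALSE), c(0, 50),    c(FALSE, FALSE)),
    D22 = rect(c(10, 25),  c(TRUE, FALSE), c(40, 70),   c(FALSE, FALSE)),
    D23 = rect(c(10, 25),  c(TRUE, FALSE), c(60, Inf),  c(FALSE, TRUE)),
    D3  = rect(c(0, 10),   c(FALSE, TRUE), c(0, Inf),   c(FALSE, TRUE)),
    D31 = rect(c(0, 10),   c(FALSE, TRUE), c(0, 140),   c(FALSE, FALSE)),
    D32 = rect(c(0, 10),   c(FALSE, TRUE), c(100, Inf), c(FALSE, TRUE))
  ), class = "domain_partition")
}

#' Load a domain partition from JSON
#'
#' Schema: `{"D0": {"cur1": [lo, hi, lo_open, hi_open], "cur2": [...]}, ...}`
#' with `lo_open`/`hi_open` encoded as 0/1. All nine rectangle names of
#' [default_partition()] must be present.
#'
#' @param path JSON file path.
#' @return a `domain_partition`.
#' @export
read_partition <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- names(default_partition())
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("partition file lacks domains: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(raw[need], function(r) {
    list(cur1 = as.numeric(r$cur1[1:2]), cur1_open = as.logical(r$cur1[3:4]),
         cur2 = as.numeric(r$cur2[1:2]), cur2_open = as.logical(r$cur2[3:4]))
  })
  structure(out, class = "domain_partition")
}

#' Write a domain partition to JSON
#'
#' @param partition a `domain_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  enc <- lapply(unclass(partition), function(r) {
    list(cur1 = c(r$cur1, as.integer(r$cur1_open)),
         cur2 = c(r$cur2, as.integer(r$cur2_open)))
  })
  jsonlite::write_json(enc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

.in_interval <- function(x, lim, open) {
  lo_ok <- if (open[1]) x > lim[1] else x >= lim[1]
  hi_ok <- if (open[2]) x < lim[2] else x <= lim[2]
  lo_ok && hi_ok
}

.in_rect <- function(p, r) {
  .in_interval(p[1], r$cur1, r$cur1_open) && .in_interval(p[2], r$cur2, r$cur2_open)
}

#' Classify a dispersion point against the symptom-domain partition
#'
#' Evaluates rectangle membership with the exact open/closed endpoint flags.
#' Inside the ventricular (`D2`) and bundle-branch-block (`D3`) domains a
#' point falling in the overlap of two subdomains receives only the coarse
#' label (fine = `"none"`); outside all domains the point is unclassified.
#' Non-finite coordinates (flagged beats) are unclassified.
#'
#' @param p a `dispersion_point` or numeric `c(cur1, cur2)`.
#' @param partition a `domain_partition` (default [default_partition()]).
#' @return a list of class `diagnosis` with `coarse` (one of `normal`,
#'   `atrial_abnormal`, `ventricular_abnormal`, `bundle_branch_block`,
#'   `unclassified`) and `fine` (one of `N`, `A.P.`, `V.F.`, `F.V.N.`,
#'   `P.V.C.`, `L.B.B.B.`, `R.B.B.B.`, `none`).
#' @export
#' @examples
#' classify_point(c(50, 10))   # normal / N
#' classify_point(c(15, 65))   # ventricular overlap -> coarse only
classify_point <- function(p, partition = default_partition()) {
  if (inherits(p, "dispersion_point")) p <- c(p$cur1, p$cur2)
  p <- as.numeric(p)
  diag_out <- function(coarse, fine) {
    structure(list(coarse = coarse, fine = fine), class = "diagnosis")
  }
  if (any(!is.finite(p))) return(diag_out("unclassified", "none"))
  if (.in_rect(p, partition$D0)) return(diag_out("normal", "N"))
  if (.in_rect(p, partition$D1)) return(diag_out("atrial_abnormal", "A.P."))
  if (.in_rect(p, partition$D2)) {
    sub <- c(D21 = .in_rect(p, partition$D21),
             D22 = .in_rect(p, partition$D22),
             D23 = .in_rect(p, partition$D23))
    fine <- if (sum(sub) == 1) {
      switch(names(which(sub)), D21 = "V.F.", D22 = "F.V.N.", D23 = "P.V.C.")
    } else "none"
    return(diag_out("ventricular_abnormal", fine))
  }
  if (.in_rect(p, partition$D3)) {
    sub <- c(D31 = .in_rect(p, partition$D31),
             D32 = .in_rect(p, partition$D32))
    fine <- if (sum(sub) == 1) {
      switch(names(which(sub)), D31 = "L.B.B.B.", D32 = "R.B.B.B.")
    } else "none"
    return(diag_out("bundle_branch_block", fine))
  }
  diag_out("unclassified", "none")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf("Diagnosis: %s (fine: %s)\n", x$coarse, x$fine))
  invisible(x)
}

#' Coarse classes in reporting order
#' @keywords internal
.coarse_classes <- c("normal", "atrial_abnormal", "ventricular_abnormal",
                     "bundle_branch_block", "unclassified")

#' Per-class classification metrics
#'
#' For every coarse class j with truth set \eqn{Q_j} and predicted set
#' \eqn{\tilde Q_j}:
#' \deqn{TPR_j = \frac{|\tilde Q_j \cap Q_j|}{|Q_j|}, \quad
#'   NRR_j = 1 - \frac{|\tilde Q_j \cap \bigcup_{k \ne j} Q_k|}{|\bigcup_{k \ne j} Q_k|}, \quad
#'   PPV_j = \frac{|\tilde Q_j \cap Q_j|}{|\tilde Q_j|}, \quad
#'   F1_j = \frac{2 |\tilde Q_j \cap Q_j|}{|Q_j| + |\tilde Q_j|}.}
#' All reported as percentages; metrics of empty classes are `NA`
#' (undefined), not 0.
#'
#' @param truth character vector of true coarse classes.
#' @param predicted character vector of predicted coarse classes, or a list
#'   of `diagnosis` objects.
#' @return a list of class `metrics_report` with a `metrics` data frame
#'   (class, original_size, classified_size, intersection, tpr, nrr, ppv, f1,
#'   percentages) and a `confusion` table (truth in rows).
#' @export
evaluate_classification <- function(truth, predicted) {
  if (is.list(predicted)) {
    predicted <- vapply(predicted, function(d) d$coarse, character(1))
  }
  stopifnot(length(truth) == length(predicted))
  classes <- union(.coarse_classes, union(unique(truth), unique(predicted)))
  n <- length(truth)
  rows <- lapply(classes, function(cl) {
    Q <- truth == cl
    Qh <- predicted == cl
    inter <- sum(Q & Qh)
    nQ <- sum(Q); nQh <- sum(Qh); n_other <- n - nQ
    data.frame(
      class = cl,
      original_size = nQ,
      classified_size = nQh,
      intersection = inter,
      tpr = if (nQ > 0) 100 * inter / nQ else NA_real_,
      nrr = if (n_other > 0) 100 * (1 - sum(Qh & !Q) / n_other) else NA_real_,
      ppv = if (nQh > 0) 100 * inter / nQh else NA_real_,
      f1  = if (nQ + nQh > 0) 100 * 2 * inter / (nQ + nQh) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  metrics <- do.call(rbind, rows)
  confusion <- table(truth = factor(truth, levels = classes),
                     predicted = factor(predicted, levels = classes))
  structure(list(metrics = metrics, confusion = confusion, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$metrics
  keep <- m$original_size > 0 | m$classified_size > 0
  m <- m[keep, , drop = FALSE]
  m[c("tpr", "nrr", "ppv", "f1")] <- round(m[c("tpr", "nrr", "ppv", "f1")], 2)
  cat(sprintf("Classification metrics over %d beats:\n", x$n))
  print(m, row.names = FALSE)
  invisible(x)
}
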