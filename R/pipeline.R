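#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end classifier with the defaults of
#' the reference study conditions: window length `l = 10`, sliding step
#' `tau = 1`, embedding dimension `d = 3`, neighbourhood size `k = 20`,
#' bin width `m = 1`, truncation `s = 0`, eigenvalue scale `epsilon = 0.09`.
#'
#' @param l,tau,d,embed_scale see [embed_config()].
#' @param k neighbourhood size for the local scatter matrices.
#' @param m histogram bin width.
#' @param s histogram truncation index.
#' @param epsilon eigenvalue scale in the analytic curvature cap
#'   `3 d (d-1) / epsilon`.
#' @param eig_floor scatter eigenvalue floor (`NULL` = automatic, see
#'   [spd_cloud()]).
#' @param include_self include each point in its own neighbourhood.
#' @param partition a `domain_partition` (default [default_partition()]).
#' @param pre_samples,beat_length,fs,lowpass_hz preprocessing settings.
#' @return a list of class `wscec_config`.
#' @export
wscec_config <- function(l = 10, tau = 1, d = 3, embed_scale = 2 / l, k = 20,
                         m = 1, s = 0, epsilon = 0.09, eig_floor = NULL,
                         include_self = FALSE,
                         partition = default_partition(),
                         pre_samples = 100, beat_length = 300, fs = 360,
                         lowpass_hz = 50) {
  embed <- embed_config(l = l, tau = tau, d = d, scale = embed_scale)
  structure(list(embed = embed, k = k, m = m, s = s, epsilon = epsilon,
                 eig_floor = eig_floor, include_self = include_self,
                 partition = partition, pre_samples = pre_samples,
                 beat_length = beat_length, fs = fs, lowpass_hz = lowpass_hz),
            class = "wscec_config")
}

#' @export
print.wscec_config <- function(x, ...) {
  cat(sprintf(paste0("Pipeline config: l = %d, tau = %d, d = %d, k = %d, ",
                     "m = %g, s = %d, epsilon = %g\n"),
              x$embed$l, x$embed$tau, x$embed$d, x$k, x$m, x$s, x$epsilon))
  invisible(x)
}

#' Map fine rhythm labels to coarse symptom classes
#'
#' @param labels character vector of fine labels ([wscec_classes]).
#' @return character vector of coarse classes.
#' @export
label_to_coarse <- function(labels) {
  map <- c("N" = "normal", "A.P." = "atrial_abnormal",
           "P.V.C." = "ventricular_abnormal", "F.V.N." = "ventricular_abnormal",
           "V.F." = "ventricular_abnormal",
           "L.B.B.B." = "bundle_branch_block", "R.B.B.B." = "bundle_branch_block")
  out <- unname(map[labels])
  out[is.na(out) & !is.na(labels)] <- "unclassified"
  out
}

#' Dispersion features of a single beat
#'
#' One beat through the feature chain: STFFT embedding, kNN scatter cloud,
#' scalar-curvature sequence, histogram at the supplied ceiling, dispersion.
#'
#' @param beat an [ecg_beat()] or numeric vector.
#' @param b histogram ceiling (from [choose_b()] on the standard beat).
#' @param config a [wscec_config()].
#' @return a list with `dispersion`, `histogram`, `curvatures`, `spd`
#'   (the SPD cloud), and `cloud`.
#' @export
beat_features <- function(beat, b, config = wscec_config()) {
  cloud <- embed_beat(beat, config$embed)
  spd <- spd_cloud(cloud, k = config$k, eig_floor = config$eig_floor,
                   include_self = config$include_self)
  w <- wsc_sequence(spd)
  h <- curvature_histogram(w, m = config$m, b = b)
  dp <- dispersion(w, h, s = config$s)
  list(dispersion = dp, histogram = h, curvatures = w, spd = spd, cloud = cloud)
}

#' Run the full curvature-dispersion classifier over a set of beats
#'
#' Executes the end-to-end procedure: (1) embed the standard normal beat,
#' (2) compute its curvature sequence and fix the histogram ceiling
#' `b = min(max standard curvature, 3 d (d-1) / epsilon)` once, then for
#' every input beat (3) embed, (4) build the SPD scatter cloud, (5) compute
#' the curvature sequence and histogram, (6) extract the dispersion point and
#' (7) classify it against the symptom-domain partition. A failure in any
#' stage flags that beat unclassified-with-reason; it never aborts the batch.
#'
#' @param beats a list of [ecg_beat()] objects, or a numeric matrix with one
#'   beat per row.
#' @param standard_beat the reference normal beat used to fix the ceiling;
#'   `NULL` (default) uses the noise-free synthetic normal template with
#'   seed 0.
#' @param config a [wscec_config()].
#' @param labels optional character vector of fine truth labels; defaults to
#'   the `label` fields of `beats` when present. When any label is known, a
#'   [evaluate_classification()] report against the coarse truth is included.
#' @return an object of class `wscec_result`: list with `features` (data
#'   frame: beat_id, label, cur1, cur2, n_points, n_regularized, n_excluded,
#'   coarse, fine, ok, reason), `diagnoses` (list), `metrics`
#'   (a `metrics_report` or `NULL`), `b`, and `config`.
#' @export
run_wscec <- function(beats, standard_beat = NULL, config = wscec_config(),
                      labels = NULL) {
  if (is.matrix(beats)) {
    beats <- apply(beats, 1, function(r) {
      ecg_beat(r, r_index = config$pre_samples + 1, length = length(r))
    }, simplify = FALSE)
  }
  if (is.null(labels)) {
    labels <- vapply(beats, function(b) {
      if (inherits(b, "ecg_beat")) b$label else NA_character_
    }, character(1))
  }
  if (is.null(standard_beat)) {
    standard_beat <- generate_beat(beat_spec("N", seed = 0, noise_sd = 0,
                                             amplitude_jitter = 0,
                                             timing_jitter = 0,
                                             length = config$beat_length))
  }
  std_spd <- spd_cloud(embed_beat(standard_beat, config$embed), k = config$k,
                       eig_floor = config$eig_floor,
                       include_self = config$include_self)
  b <- choose_b(wsc_sequence(std_spd), epsilon = config$epsilon,
                d = config$embed$d)

  n <- length(beats)
  diagnoses <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      f <- beat_features(beats[[i]], b, config)
      dg <- if (f$dispersion$ok) {
        classify_point(f$dispersion, config$partition)
      } else {
        structure(list(coarse = "unclassified", fine = "none"),
                  class = "diagnosis")
      }
      list(f = f, dg = dg, err = NA_character_)
    }, error = function(e) list(f = NULL, dg = structure(
      list(coarse = "unclassified", fine = "none"), class = "diagnosis"),
      err = conditionMessage(e)))
    diagnoses[[i]] <- res$dg
    rows[[i]] <- data.frame(
      beat_id = i,
      label = labels[i],
      cur1 = if (is.null(res$f)) NA_real_ else res$f$dispersion$cur1,
      cur2 = if (is.null(res$f)) NA_real_ else res$f$dispersion$cur2,
      n_points = if (is.null(res$f)) NA_integer_ else length(res$f$curvatures),
      n_regularized = if (is.null(res$f)) NA_integer_ else res$f$spd$n_regularized,
      n_excluded = if (is.null(res$f)) NA_integer_ else res$f$histogram$excluded,
      coarse = res$dg$coarse,
      fine = res$dg$fine,
      ok = !is.null(res$f) && res$f$dispersion$ok,
      reason = if (!is.na(res$err)) res$err else
        if (!is.null(res$f) && !res$f$dispersion$ok) res$f$dispersion$reason else
          NA_character_,
      stringsAsFactors = FALSE
    )
  }
  features <- do.call(rbind, rows)
  metrics <- if (any(!is.na(labels))) {
    truth <- label_to_coarse(labels)
    truth[is.na(truth)] <- "unclassified"
    evaluate_classification(truth,
                            vapply(diagnoses, function(d) d$coarse, character(1)))
  } else NULL
  structure(list(features = features, diagnoses = diagnoses, metrics = metrics,
                 b = b, config = config),
            class = "wscec_result")
}

#' @export
print.wscec_result <- function(x, ...) {
  cat(sprintf("Curvature-dispersion classification of %d beats (b = %g):\n",
              nrow(x$features), x$b))
  print(table(x$features$coarse))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Write the result tables of a pipeline run
#'
#' Emits `features.csv`, `diagnoses.csv` and, when metrics exist,
#' `metrics.json` (which also embeds a config snapshot) into `dir`.
#'
#' @param result a `wscec_result`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(beat_id = result$features$beat_id,
               coarse = result$features$coarse, fine = result$features$fine),
    file.path(dir, "diagnoses.csv"), row.names = FALSE)
  cfg <- result$config
  snapshot <- list(l = cfg$embed$l, tau = cfg$embed$tau, d = cfg$embed$d,
                   scale = cfg$embed$scale, k = cfg$k, m = cfg$m, s = cfg$s,
                   epsilon = cfg$epsilon, b = result$b)
  out <- list(config = snapshot)
  if (!is.null(result$metrics)) {
    out$metrics <- result$metrics$metrics
    out$confusion <- as.data.frame(result$metrics$confusion)
  }
  jsonlite::write_json(out, file.path(dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
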