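#' Binning scheme specification
#'
#' A small validated container naming one of the three bucket-building
#' strategies and exactly the parameters that strategy needs:
#' * `"adaptive"` - a `resolution_curve` (bucket width `mz / R(mz)`);
#' * `"ppm"` - a tolerance `tol_ppm` (bucket half-width `tol * 1e-6 * mz`);
#' * `"constant"` - a grid `width_da` over `[mz_min, mz_max]`.
#'
#' @param method One of `"adaptive"`, `"ppm"`, `"constant"`.
#' @param curve `resolution_curve` (adaptive only).
#' @param tol_ppm Tolerance in ppm (ppm only).
#' @param width_da Grid width in Da (constant only).
#' @param mz_min,mz_max Grid range (constant only).
#' @return A `bin_scheme`.
#' @export
#' @examples
#' bin_scheme("adaptive", curve = orbitrap_curve(70000))
#' bin_scheme("ppm", tol_ppm = 5)
#' bin_scheme("constant", width_da = 0.1, mz_min = 70, mz_max = 434)
bin_scheme <- function(method = c("adaptive", "ppm", "constant"),
                       curve = NULL, tol_ppm = NULL, width_da = NULL,
                       mz_min = NULL, mz_max = NULL) {
  method <- match.arg(method)
  if (method == "adaptive") {
    if (!inherits(curve, "resolution_curve")) {
      stop_validation("Adaptive scheme requires `curve` (a resolution_curve).")
    }
    if (!is.null(tol_ppm) || !is.null(width_da)) {
      stop_validation("Adaptive scheme takes only `curve`.")
    }
  } else if (method == "ppm") {
    if (is.null(tol_ppm)) stop_validation("ppm scheme requires `tol_ppm`.")
    check_number(tol_ppm, "tol_ppm")
    if (!is.null(curve) || !is.null(width_da)) stop_validation("ppm scheme takes only `tol_ppm`.")
  } else {
    if (is.null(width_da) || is.null(mz_min) || is.null(mz_max)) {
      stop_validation("Constant scheme requires `width_da`, `mz_min`, `mz_max`.")
    }
    check_number(width_da, "width_da")
    if (!is.null(curve) || !is.null(tol_ppm)) {
      stop_validation("Constant scheme takes only `width_da`, `mz_min`, `mz_max`.")
    }
  }
  structure(list(method = method, curve = curve, tol_ppm = tol_ppm,
                 width_da = width_da, mz_min = mz_min, mz_max = mz_max),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  desc <- switch(x$method,
    adaptive = sprintf("adaptive, R(200) = %.0f, k = %.3f",
                       predict_resolution(x$curve, 200), x$curve$index),
    ppm = sprintf("dynamic, +/-%g ppm", x$tol_ppm),
    constant = sprintf("constant, %g Da over [%g, %g]", x$width_da, x$mz_min, x$mz_max))
  cat(sprintf("<bin_scheme> %s\n", desc))
  invisible(x)
}

#' Build a bucket set for one batch of spectra under a scheme
#'
#' For adaptive and ppm schemes, candidates are pooled from the batch's
#' peaks ([pool_candidates()]) and the matching builder is applied; the
#' constant scheme ignores the peaks and returns its fixed grid.
#'
#' @param peaks Long peak table for one batch.
#' @param scheme A [bin_scheme()].
#' @param min_scan_frac Candidate support threshold (see [pool_candidates()]).
#' @return Disjoint, sorted bucket tibble.
#' @export
build_buckets <- function(peaks, scheme, min_scan_frac = 0.5) {
  stopifnot(inherits(scheme, "bin_scheme"))
  switch(scheme$method,
    adaptive = build_adaptive_buckets(
      pool_candidates(peaks, curve = scheme$curve, min_scan_frac = min_scan_frac),
      scheme$curve),
    ppm = build_ppm_buckets(
      pool_candidates(peaks, tol_ppm = scheme$tol_ppm, min_scan_frac = min_scan_frac),
      scheme$tol_ppm),
    constant = build_constant_grid(scheme$width_da, scheme$mz_min, scheme$mz_max))
}

#' Full binning-and-integration pipeline
#'
#' Denoises spectra, builds one bucket set per batch under the scheme,
#' unifies the bucket sets across batches, and bins every spectrum against
#' the unified feature space.
#'
#' @param peaks Long peak table (`observation_id`, `batch_id`, `mz`,
#'   `intensity`, optional `label`).
#' @param scheme A [bin_scheme()].
#' @param denoise_frac Per-spectrum base-peak fraction below which peaks are
#'   dropped before pooling and binning (default 0.001; 0 disables).
#' @param min_scan_frac Candidate support threshold per batch.
#' @param normalize Row normalization mode passed to [normalize_rows()]
#'   (default `"none"`).
#' @return A `feature_matrix` over the unified buckets.
#' @export
integrate_spectra <- function(peaks, scheme, denoise_frac = 0.001,
                              min_scan_frac = 0.5, normalize = "none") {
  check_columns(peaks, c("observation_id", "batch_id", "mz", "intensity"), "peaks")
  clean <- denoise_spectra(peaks, denoise_frac)
  sets <- lapply(split(clean, clean$batch_id), build_buckets,
                 scheme = scheme, min_scan_frac = min_scan_frac)
  fm <- integrate_batches(clean, sets)
  normalize_rows(fm, normalize)
}

#' Benchmark ground-truth recovery of a binning scheme
#'
#' Runs the full pipeline (denoise, per-batch bucket building, cross-batch
#' unification) and scores the unified bucket set against a ground-truth
#' feature list with [recovery_analysis()].
#'
#' @inheritParams integrate_spectra
#' @param truth Ground-truth feature table (`name`, `mz`).
#' @param match_tol_ppm Recovery matching tolerance in ppm (default 5).
#' @return A `recovery_report`.
#' @export
#' @examples
#' cfg <- sim_config(n_features = 20, n_scans_per_batch = 5,
#'                   noise_density = 2, seed = 1)
#' truth <- simulate_ground_truth(cfg)
#' peaks <- simulate_scans(truth, cfg)
#' rep <- benchmark_recovery(peaks, truth,
#'                           bin_scheme("adaptive", curve = cfg$curve))
#' glance(rep)
benchmark_recovery <- function(peaks, truth, scheme, match_tol_ppm = 5,
                               denoise_frac = 0.001, min_scan_frac = 0.5) {
  check_columns(peaks, c("observation_id", "batch_id", "mz", "intensity"), "peaks")
  clean <- denoise_spectra(peaks, denoise_frac)
  sets <- lapply(split(clean, clean$batch_id), build_buckets,
                 scheme = scheme, min_scan_frac = min_scan_frac)
  unified <- unify_bucket_sets(sets)
  recovery_analysis(unified, clean, truth, match_tol_ppm = match_tol_ppm)
}
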