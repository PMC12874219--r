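#' Read centroid spectra from long-form CSV
#'
#' Expected columns: `scan_id` (or `observation_id`), `mz`, `intensity`;
#' optional `batch_id`, `label`, `x`, `y` (MSI pixel coordinates). Peaks are
#' returned sorted by m/z within each scan.
#'
#' @param path CSV file path.
#' @return Long peak tibble with columns `observation_id`, `batch_id`,
#'   `label`, `mz`, `intensity` (plus `x`, `y` when present). An empty file
#'   yields an empty tibble with a warning.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("File not found: %s", path))
  df <- tryCatch(
    suppressWarnings(readr::read_csv(path, show_col_types = FALSE, progress = FALSE)),
    error = function(e) stop_io(sprintf("Could not parse %s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0L) {
    warn(sprintf("%s contains no peaks.", path))
    return(tibble(observation_id = character(), batch_id = character(),
                  label = character(), mz = numeric(), intensity = numeric()))
  }
  if ("scan_id" %in% names(df) && !"observation_id" %in% names(df)) {
    df <- dplyr::rename(df, observation_id = "scan_id")
  }
  check_columns(df, c("observation_id", "mz", "intensity"), path)
  bad <- which(!is.finite(df$intensity) | df$intensity < 0)
  if (length(bad)) {
    stop_validation(sprintf("%s: negative or non-finite intensity at data row %d.",
                            path, bad[1]))
  }
  if (any(!is.finite(df$mz) | df$mz <= 0)) {
    stop_validation(sprintf("%s: non-positive m/z value present.", path))
  }
  df$observation_id <- as.character(df$observation_id)
  if (!"batch_id" %in% names(df)) df$batch_id <- "batch1"
  if (!"label" %in% names(df)) df$label <- NA_character_
  keep <- c("observation_id", "batch_id", "label", "mz", "intensity",
            intersect(c("x", "y"), names(df)))
  df <- df[order(df$batch_id, df$observation_id, df$mz), keep]
  as_tibble(df)
}

#' Write centroid spectra to long-form CSV
#'
#' @param peaks Long peak tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(peaks, path) {
  check_columns(peaks, c("observation_id", "mz", "intensity"), "peaks")
  readr::write_csv(peaks, path, progress = FALSE)
  invisible(path)
}

mzml_header_template <- function(n) {
  data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L, polarity = 0L,
    peaksCount = 0L, totIonCurrent = 0, retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = 0, basePeakIntensity = 0, collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = 0, highMZ = 0, precursorScanNum = 0L, precursorMZ = 0,
    precursorCharge = 0L, precursorIntensity = 0, mergedScan = 0L,
    mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
}

require_mzr <- function() {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop_io("mzML support requires the Bioconductor package `mzR`.")
  }
}

#' Write centroid spectra to mzML
#'
#' One MS1 spectrum per `observation_id`, in (batch, observation) order.
#' Batch ids, labels and pixel coordinates are not representable in plain
#' mzML; supply them again on read via [read_spectra_mzml()] or use the CSV
#' format to round-trip them.
#'
#' @param peaks Long peak tibble.
#' @param path Output `.mzML` path.
#' @return `path`, invisibly.
#' @export
write_spectra_mzml <- function(peaks, path) {
  require_mzr()
  check_columns(peaks, c("observation_id", "mz", "intensity"), "peaks")
  if (!"batch_id" %in% names(peaks)) peaks$batch_id <- "batch1"
  obs <- dplyr::arrange(dplyr::distinct(peaks, .data$observation_id, .data$batch_id),
                        .data$batch_id, .data$observation_id)
  split_peaks <- split(peaks[, c("mz", "intensity")], peaks$observation_id)
  pk <- lapply(obs$observation_id, function(id) {
    p <- split_peaks[[id]]
    p <- p[order(p$mz), ]
    cbind(mz = p$mz, intensity = p$intensity)
  })
  hdr <- mzml_header_template(length(pk))
  hdr$peaksCount <- vapply(pk, nrow, integer(1))
  hdr$totIonCurrent <- vapply(pk, function(m) sum(m[, 2]), numeric(1))
  nonempty <- hdr$peaksCount > 0
  hdr$lowMZ[nonempty] <- vapply(pk[nonempty], function(m) min(m[, 1]), numeric(1))
  hdr$highMZ[nonempty] <- vapply(pk[nonempty], function(m) max(m[, 1]), numeric(1))
  hdr$basePeakMZ[nonempty] <- vapply(pk[nonempty],
                                     function(m) m[which.max(m[, 2]), 1], numeric(1))
  hdr$basePeakIntensity[nonempty] <- vapply(pk[nonempty], function(m) max(m[, 2]), numeric(1))
  hdr$spectrumId <- obs$observation_id
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read centroid spectra from mzML
#'
#' @param path `.mzML` file path.
#' @param batch_id Batch id to assign to all spectra (mzML does not carry
#'   one).
#' @param label Class label to assign (default `NA`).
#' @param mode `"centroid"` (reject profile-mode data), `"profile"` (reject
#'   centroid data) or `"any"`.
#' @return Long peak tibble (`observation_id`, `batch_id`, `label`, `mz`,
#'   `intensity`).
#' @export
read_spectra_mzml <- function(path, batch_id = "batch1", label = NA_character_,
                              mode = c("centroid", "any", "profile")) {
  require_mzr()
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_io(sprintf("File not found: %s", path))
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop_io(sprintf("Could not open %s: %s",
                                                         path, conditionMessage(e))))
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) {
    warn(sprintf("%s contains no spectra.", path))
    return(tibble(observation_id = character(), batch_id = character(),
                  label = character(), mz = numeric(), intensity = numeric()))
  }
  centroided <- hdr$centroided
  if (mode == "centroid" && isTRUE(any(!centroided))) {
    stop_validation(sprintf("%s contains profile-mode spectra but centroid data were expected.", path))
  }
  if (mode == "profile" && isTRUE(all(centroided))) {
    stop_validation(sprintf("%s contains centroid spectra but profile-mode data were expected.", path))
  }
  ids <- if (!is.null(hdr$spectrumId) && !anyDuplicated(hdr$spectrumId)) {
    as.character(hdr$spectrumId)
  } else {
    sprintf("scan=%d", hdr$acquisitionNum)
  }
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  rows <- purrr::map2(pk, ids, function(m, id) {
    tibble(observation_id = id, mz = m[, 1], intensity = m[, 2])
  })
  out <- dplyr::bind_rows(rows)
  out$batch_id <- batch_id
  out$label <- label
  out <- out[order(out$observation_id, out$mz), ]
  out[, c("observation_id", "batch_id", "label", "mz", "intensity")]
}

#' Read spectra from any supported format
#'
#' Dispatches on the file extension: `.mzML` via \pkg{mzR}, `.csv` via
#' [read_spectra_csv()].
#'
#' @inheritParams read_spectra_mzml
#' @return Long peak tibble.
#' @export
read_centroid_spectra <- function(path, batch_id = "batch1", label = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mzml = read_spectra_mzml(path, batch_id = batch_id, label = label),
    csv = {
      out <- read_spectra_csv(path)
      if (nrow(out) && all(out$batch_id == "batch1")) out$batch_id <- batch_id
      out
    },
    imzml = stop_io("imzML is not supported; convert MSI pixels to mzML or long CSV."),
    stop_io(sprintf("Unsupported spectra format: .%s (use .mzML or .csv).", ext)))
}

#' Serialize a resolution curve to JSON
#'
#' Keys: `coefficient`, `index`, `n_points`, `r_squared`.
#'
#' @param curve A `resolution_curve`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "resolution_curve"))
  jsonlite::write_json(
    list(coefficient = curve$coefficient, index = curve$index,
         n_points = curve$n_points, r_squared = curve$r_squared),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("File not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("coefficient", "index")) {
    if (is.null(x[[f]])) stop_io(sprintf("%s: missing field `%s`.", path, f))
  }
  resolution_curve(x$coefficient, x$index,
                   n_points = x$n_points %||% 0L,
                   r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a bucket set to JSON
#'
#' Layout: `{method, parameters, buckets: [{lower, upper, apex, n_members}]}`.
#'
#' @param buckets Bucket tibble.
#' @param path Output JSON path.
#' @param parameters Optional named list of scheme parameters to record.
#' @return `path`, invisibly.
#' @export
write_buckets_json <- function(buckets, path, parameters = list()) {
  validate_buckets(buckets)
  jsonlite::write_json(
    list(method = attr(buckets, "method") %||% "unknown",
         parameters = parameters,
         buckets = as.data.frame(buckets)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_buckets_json
#' @export
read_buckets_json <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("File not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- as_tibble(x$buckets)
  b$n_members <- as.integer(b$n_members)
  attr(b, "method") <- x$method
  validate_buckets(b, path)
  b
}

#' Write a feature matrix to CSV
#'
#' Identifier columns first (`observation_id`, `batch_id`, `label`), then
#' one column per bucket named by apex m/z to 4 decimals.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  if (!inherits(fm, "feature_matrix")) stop_validation("`fm` must be a feature_matrix.")
  readr::write_csv(as_tibble(fm), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param buckets Optional bucket tibble (e.g. from [read_buckets_json()])
#'   to reattach as column provenance.
#' @export
read_feature_matrix <- function(path, buckets = NULL) {
  if (!file.exists(path)) stop_io(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("observation_id", "batch_id", "label"), path)
  df$label <- as.character(df$label)
  if (!is.null(buckets)) validate_buckets(buckets)
  out <- as_tibble(df)
  attr(out, "buckets") <- buckets
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Read a ground-truth feature list from CSV
#'
#' Expected columns: `name`, `mz`.
#'
#' @param path CSV path.
#' @return Tibble with columns `name`, `mz`.
#' @export
read_truth_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("name", "mz"), path)
  if (any(df$mz <= 0)) stop_validation(sprintf("%s: non-positive m/z.", path))
  as_tibble(df[, c("name", "mz")])
}

#' Write a recovery report to JSON
#'
#' Summary rates plus the per-feature classification table.
#'
#' @param report A `recovery_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_recovery_json <- function(report, path) {
  stopifnot(inherits(report, "recovery_report"))
  feats <- report$features
  feats$status <- as.character(feats$status)
  jsonlite::write_json(
    list(recovery_rate = report$recovery_rate,
         counts = as.list(report$counts),
         n_features = report$n_features,
         match_tol_ppm = report$match_tol_ppm,
         features = as.data.frame(feats)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
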