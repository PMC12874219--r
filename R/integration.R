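#' Unify bucket sets across batches
#'
#' Concatenates per-batch bucket sets, sorts by lower bound, and fuses
#' overlapping intervals ([fuse_overlapping()]). Interval overlap is the only
#' cross-batch alignment mechanism: a feature measured with a small ppm mass
#' shift in a second batch produces a bucket overlapping the first batch's
#' bucket, and fusion collapses the pair into one column of the unified
#' feature space.
#'
#' @param bucket_sets Non-empty list of disjoint, sorted bucket tibbles.
#' @return One disjoint, sorted bucket tibble (the unified feature space).
#' @export
unify_bucket_sets <- function(bucket_sets) {
  if (!is.list(bucket_sets) || length(bucket_sets) == 0L || is.data.frame(bucket_sets)) {
    stop_validation("`bucket_sets` must be a non-empty list of bucket tibbles.")
  }
  purrr::iwalk(bucket_sets, function(b, i) validate_buckets(b, paste0("bucket_sets[[", i, "]]")))
  all <- dplyr::bind_rows(bucket_sets)
  all <- all[order(all$lower), , drop = FALSE]
  fuse_overlapping(all)
}

#' Remove low-intensity peaks per spectrum
#'
#' Drops peaks below a fraction of each spectrum's base-peak intensity.
#' This is the default light denoising applied before candidate pooling and
#' binning; set `frac = 0` to disable.
#'
#' @param peaks Long peak table with `observation_id`, `mz`, `intensity`.
#' @param frac Threshold as a fraction of the per-spectrum base peak
#'   (default 0.001, i.e. 0.1%).
#' @return Filtered peak table.
#' @export
denoise_spectra <- function(peaks, frac = 0.001) {
  check_columns(peaks, c("observation_id", "mz", "intensity"), "peaks")
  if (!is.numeric(frac) || frac < 0) stop_validation("`frac` must be >= 0.")
  if (frac == 0 || nrow(peaks) == 0L) return(peaks)
  dplyr::ungroup(dplyr::filter(
    dplyr::group_by(peaks, .data$observation_id),
    .data$intensity >= frac * max(.data$intensity)))
}

#' Integrate binned batches into one feature matrix
#'
#' Builds the unified cross-batch feature space with [unify_bucket_sets()]
#' and re-bins every spectrum of every batch against it. Rows are ordered by
#' (batch, observation); columns are the unified buckets, named by apex m/z
#' to 4 decimals. Absent features are true zeros - nothing is imputed.
#'
#' @param peaks Long peak table for all batches, with columns
#'   `observation_id`, `batch_id`, `mz`, `intensity` and optionally `label`.
#' @param bucket_sets List of per-batch bucket tibbles. If named, names must
#'   be batch ids present in `peaks`; every batch named in either argument
#'   must have at least one spectrum.
#' @return A `feature_matrix`: a tibble with identifier columns
#'   `observation_id`, `batch_id`, `label` followed by one intensity column
#'   per unified bucket; the bucket provenance tibble is attached as
#'   `attr(, "buckets")`.
#' @export
integrate_batches <- function(peaks, bucket_sets) {
  check_columns(peaks, c("observation_id", "batch_id", "mz", "intensity"), "peaks")
  if (nrow(peaks) == 0L) stop_validation("`peaks` contains no spectra.")
  if (!is.null(names(bucket_sets)) && all(nzchar(names(bucket_sets)))) {
    absent <- setdiff(names(bucket_sets), unique(peaks$batch_id))
    if (length(absent)) {
      stop_validation(sprintf("Batch(es) %s have a bucket set but no spectra.",
                              paste(absent, collapse = ", ")))
    }
  }
  unified <- unify_bucket_sets(bucket_sets)
  bin_spectra(peaks, unified)
}

#' Bin many spectra against one bucket set
#'
#' Vectorized multi-spectrum version of [bin_spectrum()]; the workhorse
#' behind [integrate_batches()].
#'
#' @inheritParams integrate_batches
#' @param buckets Disjoint, sorted bucket tibble.
#' @return A `feature_matrix` (see [integrate_batches()]).
#' @export
bin_spectra <- function(peaks, buckets) {
  check_columns(peaks, c("observation_id", "mz", "intensity"), "peaks")
  validate_buckets(buckets)
  if (!"batch_id" %in% names(peaks)) peaks$batch_id <- "batch1"
  if (!"label" %in% names(peaks)) peaks$label <- NA_character_

  obs <- dplyr::arrange(
    dplyr::distinct(peaks, .data$observation_id, .data$batch_id, .data$label),
    .data$batch_id, .data$observation_id)
  if (anyDuplicated(obs$observation_id)) {
    stop_validation("`observation_id` values must be unique across batches.")
  }

  col_names <- feature_column_names(buckets)
  values <- matrix(0, nrow = nrow(obs), ncol = nrow(buckets),
                   dimnames = list(NULL, col_names))
  if (nrow(peaks) > 0L && nrow(buckets) > 0L) {
    bidx <- assign_to_buckets(peaks$mz, buckets)
    keep <- !is.na(bidx)
    if (any(keep)) {
      ridx <- match(peaks$observation_id[keep], obs$observation_id)
      sums <- rowsum(as.numeric(peaks$intensity[keep]),
                     group = (bidx[keep] - 1) * nrow(obs) + ridx)
      pos <- as.integer(rownames(sums))
      values[cbind((pos - 1L) %% nrow(obs) + 1L, (pos - 1L) %/% nrow(obs) + 1L)] <- sums[, 1]
    }
  }
  new_feature_matrix(obs, values, buckets)
}

feature_column_names <- function(buckets) {
  make.unique(sprintf("%.4f", buckets$apex))
}

new_feature_matrix <- function(obs, values, buckets) {
  out <- dplyr::bind_cols(obs, as_tibble(values))
  attr(out, "buckets") <- buckets
  class(out) <- c("feature_matrix", class(out))
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  b <- attr(x, "buckets")
  cat(sprintf("<feature_matrix> %d observations x %d buckets (%d batch%s)\n",
              nrow(x), if (is.null(b)) ncol(x) - 3L else nrow(b),
              length(unique(x$batch_id)),
              if (length(unique(x$batch_id)) == 1L) "" else "es"))
  NextMethod()
}

#' Extract the numeric value block of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return Numeric matrix (observations x buckets).
#' @export
feature_values <- function(fm) {
  id_cols <- intersect(c("observation_id", "batch_id", "label"), names(fm))
  as.matrix(fm[, setdiff(names(fm), id_cols), drop = FALSE])
}

#' Normalize feature-matrix rows
#'
#' `mode = "tic"` divides each row by its total ion current (row sum);
#' all-zero rows are left untouched and reported through the `zero_rows`
#' attribute and a message. `mode = "none"` is the identity.
#'
#' @param fm A `feature_matrix`.
#' @param mode `"tic"` or `"none"`.
#' @return The normalized `feature_matrix`.
#' @export
normalize_rows <- function(fm, mode = c("tic", "none")) {
  if (!inherits(fm, "feature_matrix")) stop_validation("`fm` must be a feature_matrix.")
  if (!is.character(mode) || !mode[1] %in% c("tic", "none")) {
    stop_validation(sprintf("Unknown normalization mode %s.", deparse(mode[1])))
  }
  mode <- mode[1]
  if (mode == "none") return(fm)
  vals <- feature_values(fm)
  totals <- rowSums(vals)
  zero <- totals == 0
  scaled <- vals / ifelse(zero, 1, totals)
  out <- new_feature_matrix(
    fm[, intersect(c("observation_id", "batch_id", "label"), names(fm))],
    scaled, attr(fm, "buckets"))
  attr(out, "zero_rows") <- fm$observation_id[zero]
  if (any(zero)) {
    inform(sprintf("%d all-zero row(s) left unnormalized: %s",
                   sum(zero), paste(head(fm$observation_id[zero], 5), collapse = ", ")))
  }
  out
}

#' @export
tidy.feature_matrix <- function(x, ...) {
  id_cols <- intersect(c("observation_id", "batch_id", "label"), names(x))
  tidyr::pivot_longer(as_tibble(x), cols = -dplyr::all_of(id_cols),
                      names_to = "feature", values_to = "intensity")
}

#' @export
glance.feature_matrix <- function(x, ...) {
  b <- attr(x, "buckets")
  vals <- feature_values(x)
  tibble(
    n_observations = nrow(x),
    n_buckets = ncol(vals),
    n_batches = length(unique(x$batch_id)),
    total_intensity = sum(vals),
    sparsity = mean(vals == 0)
  )
}

#' Heatmap of a feature matrix
#'
#' Log-intensity tile plot, observations by features, faceted by batch.
#'
#' @param object A `feature_matrix`.
#' @param max_features Cap on the number of (highest total intensity)
#'   features drawn, to keep the plot legible.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_matrix <- function(object, max_features = 100, ...) {
  long <- tidy(object)
  totals <- dplyr::summarise(dplyr::group_by(long, .data$feature),
                             total = sum(.data$intensity), .groups = "drop")
  keep <- totals$feature[order(-totals$total)][seq_len(min(max_features, nrow(totals)))]
  long <- dplyr::filter(long, .data$feature %in% keep)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$observation_id,
                                     fill = log10(.data$intensity + 1))) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$batch_id),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(name = "log10(intensity + 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "feature (bucket apex m/z)", y = "observation")
}
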