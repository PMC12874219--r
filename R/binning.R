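#' Validate a bucket set
#'
#' Checks the bucket-set invariants: columns `lower`, `upper`, `apex`,
#' `n_members`; `lower < upper`; `lower <= apex < upper`; sorted by `lower`;
#' pairwise disjoint intervals.
#'
#' @param buckets Bucket tibble.
#' @param name Name used in error messages.
#' @return `buckets`, invisibly.
#' @export
validate_buckets <- function(buckets, name = "buckets") {
  check_columns(buckets, c("lower", "upper", "apex", "n_members"), name)
  if (nrow(buckets) == 0L) return(invisible(buckets))
  with(buckets, {
    if (any(lower >= upper)) stop_validation(sprintf("`%s`: lower must be < upper.", name))
    if (any(apex < lower | apex >= upper)) {
      stop_validation(sprintf("`%s`: apex must lie in [lower, upper).", name))
    }
    if (is.unsorted(lower)) stop_validation(sprintf("`%s` must be sorted by lower bound.", name))
    if (nrow(buckets) > 1L && any(head(upper, -1) > tail(lower, -1) + 1e-12)) {
      stop_validation(sprintf("`%s` contains overlapping intervals.", name))
    }
  })
  invisible(buckets)
}

new_buckets <- function(lower, upper, apex, n_members, method = NULL) {
  out <- tibble(lower = as.numeric(lower), upper = as.numeric(upper),
                apex = as.numeric(apex), n_members = as.integer(n_members))
  attr(out, "method") <- method
  out
}

candidate_mz <- function(candidates, name = "candidates") {
  mz <- if (is.data.frame(candidates)) {
    check_columns(candidates, "mz", name)
    as.numeric(candidates$mz)
  } else {
    as.numeric(candidates)
  }
  if (anyNA(mz) || any(mz <= 0)) {
    stop_validation(sprintf("`%s` must be positive and non-missing.", name))
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop_validation(sprintf("`%s` must be strictly increasing.", name))
  }
  mz
}

#' Pool centroid peaks into candidate feature m/z values
#'
#' Collapses centroid peaks from many scans into a list of candidate feature
#' apexes, the input to the bucket builders. Peaks are clustered by
#' intensity-ordered seeding: the most intense unclaimed peak seeds a
#' cluster and claims every pooled peak within half the local bin width of
#' it; each cluster yields one candidate at the intensity-weighted mean m/z.
#' Candidates supported by fewer than `min_scan_frac` of the scans are
#' dropped, so sporadic noise peaks do not enter the feature space (the
#' "minimum fraction" convention of density-based peak grouping).
#'
#' The claiming radius is `adaptive_bin_width(curve, mz) / 2` when a curve is
#' supplied, or `tol_ppm * 1e-6 * mz` when pooling for a ppm scheme.
#'
#' @param peaks Long peak table with columns `mz`, `intensity`, and
#'   (optionally) `observation_id` identifying the scan each peak came from;
#'   without it all peaks are treated as one scan.
#' @param curve A `resolution_curve` (adaptive pooling radius).
#' @param tol_ppm Tolerance in ppm (alternative pooling radius); exactly one
#'   of `curve`, `tol_ppm` must be given.
#' @param min_scan_frac Minimum fraction of scans that must contribute at
#'   least one peak to a cluster (default 0.5).
#' @return Tibble with columns `mz` (strictly increasing candidate apexes),
#'   `n_peaks`, `n_scans`, `intensity` (summed). Empty input gives an empty
#'   tibble.
#' @export
pool_candidates <- function(peaks, curve = NULL, tol_ppm = NULL, min_scan_frac = 0.5) {
  if (is.null(curve) == is.null(tol_ppm)) {
    stop_validation("Supply exactly one of `curve` or `tol_ppm`.")
  }
  if (!is.null(curve)) stopifnot(inherits(curve, "resolution_curve"))
  if (!is.null(tol_ppm)) check_number(tol_ppm, "tol_ppm")
  if (!is.numeric(min_scan_frac) || min_scan_frac < 0 || min_scan_frac > 1) {
    stop_validation("`min_scan_frac` must be in [0, 1].")
  }
  check_columns(peaks, c("mz", "intensity"), "peaks")
  empty <- tibble(mz = numeric(), n_peaks = integer(),
                  n_scans = integer(), intensity = numeric())
  if (nrow(peaks) == 0L) return(empty)

  scan <- if ("observation_id" %in% names(peaks)) {
    as.integer(factor(peaks$observation_id))
  } else {
    rep(1L, nrow(peaks))
  }
  n_scans_total <- max(scan)

  o <- order(peaks$mz)
  mz <- as.numeric(peaks$mz)[o]
  ity <- as.numeric(peaks$intensity)[o]
  sc <- scan[o]
  n <- length(mz)

  # claiming radius per peak, precomputed vectorized
  hw_all <- if (!is.null(curve)) {
    adaptive_bin_width(curve, mz) / 2
  } else {
    tol_ppm * 1e-6 * mz
  }

  claimed <- logical(n)
  seed_order <- order(ity, decreasing = TRUE)
  cap <- n
  c_mz <- numeric(cap); c_np <- integer(cap); c_ns <- integer(cap); c_int <- numeric(cap)
  k <- 0L
  for (j in seed_order) {
    if (claimed[j]) next
    lo_mz <- mz[j] - hw_all[j]
    hi_mz <- mz[j] + hw_all[j]
    # peaks are mz-sorted, so the claim window is contiguous around the seed;
    # walk outward rather than binary-searching (findInterval revalidates the
    # whole vector per call, which is O(n) and dominates at pooled-scan scale)
    lo <- j
    while (lo > 1L && mz[lo - 1L] >= lo_mz) lo <- lo - 1L
    hi <- j
    while (hi < n && mz[hi + 1L] <= hi_mz) hi <- hi + 1L
    idx <- lo:hi
    idx <- idx[!claimed[idx]]
    claimed[idx] <- TRUE
    k <- k + 1L
    w <- ity[idx]
    c_mz[k] <- sum(mz[idx] * w) / sum(w)
    c_np[k] <- length(idx)
    c_ns[k] <- length(unique(sc[idx]))
    c_int[k] <- sum(w)
  }
  out <- tibble(mz = c_mz[seq_len(k)], n_peaks = c_np[seq_len(k)],
                n_scans = c_ns[seq_len(k)], intensity = c_int[seq_len(k)])
  out <- out[out$n_scans >= min_scan_frac * n_scans_total, , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  # weighted means of neighbouring clusters can in principle coincide; merge exact ties
  if (nrow(out) > 1L && any(diff(out$mz) <= 0)) {
    out$..grp <- cumsum(c(TRUE, diff(out$mz) > 0))
    out <- dplyr::summarise(
      dplyr::group_by(out, .data$..grp),
      mz = weighted.mean(.data$mz, .data$intensity),
      n_peaks = sum(.data$n_peaks), n_scans = max(.data$n_scans),
      intensity = sum(.data$intensity), .groups = "drop")
    out$..grp <- NULL
  }
  out
}

#' Build resolution-adaptive buckets
#'
#' The three-stage adaptive protocol: (1) predict the resolving power at each
#' candidate apex from the fitted curve; (2) open a bucket of full width
#' `w = apex / R(apex)` centered on the apex, i.e. `[apex - w/2, apex + w/2)`;
#' (3) fuse overlapping buckets ([fuse_overlapping()]) to absorb mass shifts
#' and the analyzer's limited resolving power.
#'
#' @param candidates Strictly increasing candidate apex m/z values (numeric
#'   vector, or a data frame with an `mz` column such as the output of
#'   [pool_candidates()]).
#' @param curve A `resolution_curve`.
#' @param as_halfwidth If `TRUE`, treat `mz / R(mz)` as the bucket
#'   *half*-width instead of the full width (buckets `[apex - w, apex + w)`,
#'   twice as wide). Default `FALSE`.
#' @return Disjoint, sorted bucket tibble (`lower`, `upper`, `apex`,
#'   `n_members`).
#' @export
#' @examples
#' build_adaptive_buckets(c(200, 500.002, 500.004), orbitrap_curve(70000))
build_adaptive_buckets <- function(candidates, curve, as_halfwidth = FALSE) {
  stopifnot(inherits(curve, "resolution_curve"))
  mz <- candidate_mz(candidates)
  if (!length(mz)) return(new_buckets(numeric(), numeric(), numeric(), integer(), "adaptive"))
  half <- adaptive_bin_width(curve, mz) * (if (isTRUE(as_halfwidth)) 1 else 0.5)
  out <- fuse_overlapping(new_buckets(mz - half, mz + half, mz, 1L, "adaptive"))
  attr(out, "method") <- "adaptive"
  out
}

#' Build dynamic ppm buckets
#'
#' Each candidate apex opens a bucket of constant *relative* width:
#' `[apex * (1 - tol_ppm * 1e-6), apex * (1 + tol_ppm * 1e-6))`, then
#' overlapping buckets are fused.
#'
#' @inheritParams build_adaptive_buckets
#' @param tol_ppm Half-width tolerance in ppm (> 0).
#' @return Disjoint, sorted bucket tibble.
#' @export
build_ppm_buckets <- function(candidates, tol_ppm) {
  check_number(tol_ppm, "tol_ppm")
  mz <- candidate_mz(candidates)
  if (!length(mz)) return(new_buckets(numeric(), numeric(), numeric(), integer(), "ppm"))
  d <- tol_ppm * 1e-6 * mz
  out <- fuse_overlapping(new_buckets(mz - d, mz + d, mz, 1L, "ppm"))
  attr(out, "method") <- "ppm"
  out
}

#' Build a constant-Dalton bucket grid
#'
#' Fixed-width half-open bins `[i*w, (i+1)*w)` anchored at m/z 0 (boundaries
#' are integer multiples of the width), covering `[mz_min, mz_max]`. Anchoring
#' at zero rather than at the data minimum makes column identities
#' reproducible across batches, matching fixed-grid preprocessing software.
#'
#' @param width_da Bin width in Da (> 0).
#' @param mz_min,mz_max Range to cover, `mz_min < mz_max`.
#' @return Bucket tibble; `apex` is the bin midpoint, `n_members` 1.
#' @export
#' @examples
#' build_constant_grid(0.1, 100.0, 100.3)
build_constant_grid <- function(width_da, mz_min, mz_max) {
  check_number(width_da, "width_da")
  check_number(mz_min, "mz_min")
  check_number(mz_max, "mz_max")
  if (mz_min >= mz_max) stop_validation("`mz_min` must be < `mz_max`.")
  i0 <- floor(mz_min / width_da + 1e-9)
  i1 <- floor(mz_max / width_da + 1e-9)
  i <- i0:i1
  # snap grid boundaries to 12 significant digits so that e.g. 1001 * 0.1
  # compares equal to the literal 100.1 under the half-open convention
  lower <- signif(i * width_da, 12)
  upper <- signif((i + 1) * width_da, 12)
  out <- new_buckets(lower, upper, (lower + upper) / 2, 1L, "constant")
  attr(out, "width_da") <- width_da
  out
}

#' Fuse overlapping buckets
#'
#' Transitively merges intervals that overlap (`upper_i > lower_{i+1}`); the
#' merged bucket spans the union, its apex is the `n_members`-weighted mean
#' of the member apexes, and member counts are summed. Idempotent: fusing a
#' fused set is the identity. Buckets that merely touch at a shared boundary
#' are *not* merged (half-open convention).
#'
#' @param buckets Bucket tibble sorted by `lower` (possibly overlapping).
#' @return Disjoint, sorted bucket tibble.
#' @export
fuse_overlapping <- function(buckets) {
  check_columns(buckets, c("lower", "upper", "apex", "n_members"), "buckets")
  method <- attr(buckets, "method")
  if (nrow(buckets) <= 1L) return(buckets)
  if (is.unsorted(buckets$lower)) stop_validation("`buckets` must be sorted by lower bound.")
  grp <- cumsum(c(TRUE, buckets$lower[-1] >= cummax(head(buckets$upper, -1))))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::add_column(buckets, ..grp = grp), .data$..grp),
    lower = min(.data$lower),
    upper = max(.data$upper),
    apex = weighted.mean(.data$apex, .data$n_members),
    n_members = sum(.data$n_members),
    .groups = "drop"
  )
  out$..grp <- NULL
  attr(out, "method") <- method
  out
}

#' Assign peaks of one spectrum to buckets
#'
#' Each peak goes to the unique bucket whose half-open interval
#' `[lower, upper)` contains its m/z, found by binary search; peaks falling
#' outside every bucket are dropped. Per-bucket intensity is the sum of the
#' assigned peak intensities.
#'
#' @param spectrum Data frame with columns `mz` and `intensity` (one scan).
#' @param buckets Disjoint, sorted bucket tibble.
#' @return Numeric intensity vector aligned with the rows of `buckets`.
#' @export
bin_spectrum <- function(spectrum, buckets) {
  check_columns(spectrum, c("mz", "intensity"), "spectrum")
  validate_buckets(buckets)
  out <- numeric(nrow(buckets))
  if (nrow(spectrum) == 0L || nrow(buckets) == 0L) return(out)
  idx <- assign_to_buckets(spectrum$mz, buckets)
  keep <- !is.na(idx)
  if (any(keep)) {
    sums <- rowsum(as.numeric(spectrum$intensity[keep]), idx[keep])
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  out
}

# vectorized peak -> bucket index (NA when outside every bucket);
# assumes `buckets` already validated
assign_to_buckets <- function(mz, buckets) {
  i <- findInterval(mz, buckets$lower)
  ok <- i >= 1L & mz < buckets$upper[pmax(i, 1L)]
  ifelse(ok, i, NA_integer_)
}

#' Compare bucket widths of the three binning strategies
#'
#' Diagnostic plot of bucket width against m/z for a resolution-adaptive
#' curve, one or more ppm tolerances, and one or more constant-Da widths.
#'
#' @param curve A `resolution_curve`.
#' @param tol_ppm ppm tolerances to show (full width = `2 * tol * 1e-6 * mz`).
#' @param width_da Constant bin widths to show.
#' @param mz_range m/z range of the x axis.
#' @return A ggplot object (log-scaled y axis).
#' @export
plot_bucket_widths <- function(curve, tol_ppm = c(5, 10),
                               width_da = c(0.001, 0.01, 0.1),
                               mz_range = c(100, 1500)) {
  stopifnot(inherits(curve, "resolution_curve"))
  mz <- seq(mz_range[1], mz_range[2], length.out = 300)
  frames <- list(tibble(mz = mz, width = adaptive_bin_width(curve, mz),
                        scheme = "adaptive"))
  for (t in tol_ppm) {
    frames[[length(frames) + 1L]] <-
      tibble(mz = mz, width = 2 * t * 1e-6 * mz, scheme = sprintf("%g ppm", t))
  }
  for (w in width_da) {
    frames[[length(frames) + 1L]] <-
      tibble(mz = mz, width = rep(w, length(mz)), scheme = sprintf("%g Da", w))
  }
  df <- dplyr::bind_rows(frames)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$width,
                                   color = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "m/z", y = "bucket width (Da)", color = "scheme") +
    ggplot2::theme_minimal()
}
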