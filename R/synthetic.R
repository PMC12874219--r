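#' Simulation configuration for multi-batch centroided scans
#'
#' Bundles and validates the parameters of the synthetic shotgun-MS
#' generator. The defaults emulate a low-mass standard-mix experiment on a
#' 70,000 @ m/z 200 Orbitrap: 112 ground-truth features in 70-434 Th, two
#' batches whose second batch carries a +3 ppm systematic mass shift, 1 ppm
#' per-scan calibration jitter, and a dense uniform noise floor.
#'
#' Feature intensities are log-normal; `intensity_scale` multiplies the mean
#' feature intensity to emulate concentration tiers (1, 0.5, 0.25 for
#' 1000/500/250 ppb) while the noise floor stays fixed at
#' `noise_intensity_frac` of the *reference* (unscaled) mean feature
#' intensity - electronic and chemical background does not track analyte
#' concentration.
#'
#' @param n_features Number of ground-truth features.
#' @param mz_range Length-2 increasing m/z range (Th).
#' @param min_spacing Minimum pairwise feature spacing (Da).
#' @param curve Generating instrument model (`resolution_curve`).
#' @param batch_shifts_ppm Per-batch systematic mass shifts (ppm); one batch
#'   per element.
#' @param scan_jitter_ppm Standard deviation of the per-scan random mass
#'   shift (ppm), common to all peaks of a scan.
#' @param noise_density Expected noise peaks per Da per scan.
#' @param noise_intensity_frac Mean noise intensity as a fraction of the
#'   reference mean feature intensity.
#' @param n_scans_per_batch Scans (or pixels) per batch.
#' @param dropout_prob Per-scan probability that a feature is absent.
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of feature
#'   intensity (defaults `log(1e6)` and 0.5).
#' @param intensity_scale Concentration-tier multiplier of the mean feature
#'   intensity.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return A validated `sim_config`.
#' @export
sim_config <- function(n_features = 112,
                       mz_range = c(70, 434),
                       min_spacing = 0.05,
                       curve = orbitrap_curve(70000),
                       batch_shifts_ppm = c(0, 3),
                       scan_jitter_ppm = 1,
                       noise_density = 50,
                       noise_intensity_frac = 0.03,
                       n_scans_per_batch = 50,
                       dropout_prob = 0.05,
                       intensity_meanlog = log(1e6),
                       intensity_sdlog = 0.5,
                       intensity_scale = 1,
                       seed = NULL) {
  check_number(n_features, "n_features")
  if (length(mz_range) != 2L || mz_range[1] >= mz_range[2]) {
    stop_validation("`mz_range` must be an increasing length-2 vector.")
  }
  check_number(min_spacing, "min_spacing")
  stopifnot(inherits(curve, "resolution_curve"))
  if (!is.numeric(batch_shifts_ppm) || length(batch_shifts_ppm) < 1L) {
    stop_validation("`batch_shifts_ppm` must give at least one batch shift.")
  }
  for (nm in c("scan_jitter_ppm", "noise_density", "noise_intensity_frac")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop_validation(sprintf("`%s` must be a non-negative scalar.", nm))
    }
  }
  check_number(n_scans_per_batch, "n_scans_per_batch")
  if (!is.numeric(dropout_prob) || dropout_prob < 0 || dropout_prob >= 1) {
    stop_validation("`dropout_prob` must be in [0, 1).")
  }
  check_number(intensity_scale, "intensity_scale")
  structure(
    list(n_features = as.integer(n_features), mz_range = as.numeric(mz_range),
         min_spacing = min_spacing, curve = curve,
         batch_shifts_ppm = as.numeric(batch_shifts_ppm),
         scan_jitter_ppm = scan_jitter_ppm, noise_density = noise_density,
         noise_intensity_frac = noise_intensity_frac,
         n_scans_per_batch = as.integer(n_scans_per_batch),
         dropout_prob = dropout_prob,
         intensity_meanlog = intensity_meanlog, intensity_sdlog = intensity_sdlog,
         intensity_scale = intensity_scale, seed = seed),
    class = "sim_config"
  )
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate ground-truth feature m/z values
#'
#' Draws `n_features` m/z values uniformly over `mz_range` subject to a
#' minimum pairwise spacing, by rejection sampling of the whole sorted draw.
#' Reproducible for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns `name` (`F001`, ...) and `mz` (ascending).
#' @export
simulate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  width <- diff(cfg$mz_range)
  if (cfg$n_features * cfg$min_spacing >= width) {
    stop_validation(sprintf(
      "Infeasible packing: %d features with spacing %g do not fit in a %g Da range.",
      cfg$n_features, cfg$min_spacing, width))
  }
  mz <- with_seed_maybe(cfg$seed, {
    for (attempt in seq_len(5000L)) {
      x <- sort(runif(cfg$n_features, cfg$mz_range[1], cfg$mz_range[2]))
      if (cfg$n_features == 1L || all(diff(x) >= cfg$min_spacing)) break
      x <- NULL
    }
    x
  })
  if (is.null(mz)) {
    stop_validation("Could not place features at the requested spacing (packing too dense).")
  }
  tibble(name = sprintf("F%03d", seq_len(cfg$n_features)), mz = mz)
}

#' Simulate centroided multi-batch scans
#'
#' Generates one centroid peak list per scan per batch. Each retained
#' feature (retention is Bernoulli with probability `1 - dropout_prob`)
#' appears at `mz * (1 + (batch_shift + jitter) * 1e-6)` where the jitter is
#' a single per-scan draw, with log-normal intensity. Poisson-many uniform
#' noise peaks are added per scan at the configured noise floor. Peak lists
#' are sorted by m/z within each scan; the whole draw is reproducible for a
#' fixed `cfg$seed`.
#'
#' @param truth Output of [simulate_ground_truth()] (or any `name`/`mz`
#'   table).
#' @param cfg A [sim_config()].
#' @return Long peak tibble with columns `observation_id`, `batch_id`,
#'   `label` (`NA`), `mz`, `intensity`, ordered by batch, scan, m/z.
#' @export
simulate_scans <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  check_columns(truth, c("name", "mz"), "truth")
  n_batches <- length(cfg$batch_shifts_ppm)
  width <- diff(cfg$mz_range)

  with_seed_maybe(cfg$seed, {
    batches <- lapply(seq_len(n_batches), function(b) {
      batch_id <- sprintf("batch%d", b)
      shift <- cfg$batch_shifts_ppm[b]
      scans <- sprintf("%s_s%03d", batch_id, seq_len(cfg$n_scans_per_batch))
      jitter <- rnorm(cfg$n_scans_per_batch, 0, cfg$scan_jitter_ppm)

      # feature peaks: scan x feature grid, thinned by dropout
      nf <- nrow(truth)
      scan_idx <- rep(seq_len(cfg$n_scans_per_batch), each = nf)
      mz0 <- rep(truth$mz, times = cfg$n_scans_per_batch)
      keep <- runif(length(mz0)) >= cfg$dropout_prob
      feat <- tibble(
        observation_id = scans[scan_idx[keep]],
        mz = mz0[keep] * (1 + (shift + jitter[scan_idx[keep]]) * 1e-6),
        intensity = rlnorm(sum(keep),
                           cfg$intensity_meanlog + log(cfg$intensity_scale),
                           cfg$intensity_sdlog)
      )

      # noise floor: intensity does not scale with the concentration tier
      n_noise <- rpois(cfg$n_scans_per_batch, cfg$noise_density * width)
      noise_meanlog <- cfg$intensity_meanlog + log(cfg$noise_intensity_frac)
      noise <- tibble(
        observation_id = rep(scans, times = n_noise),
        mz = runif(sum(n_noise), cfg$mz_range[1], cfg$mz_range[2]),
        intensity = rlnorm(sum(n_noise), noise_meanlog, cfg$intensity_sdlog)
      )

      out <- dplyr::bind_rows(feat, noise)
      out$batch_id <- batch_id
      out
    })
    out <- dplyr::bind_rows(batches)
    out$label <- NA_character_
    out <- out[order(out$batch_id, out$observation_id, out$mz), ]
    out[, c("observation_id", "batch_id", "label", "mz", "intensity")]
  })
}

#' Simulate noisy resolution points from a curve
#'
#' Draws `n` m/z values uniformly over `mz_range` and perturbs the exact
#' resolving power multiplicatively: `R = C * mz^k * (1 + N(0, rel_noise))`.
#'
#' @param curve Generating `resolution_curve`.
#' @param n Number of points (>= 3).
#' @param rel_noise Relative Gaussian noise s.d. (>= 0).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param mz_range m/z range of the points (default 100-1500).
#' @return Tibble with columns `mz`, `resolution`.
#' @export
simulate_resolution_points <- function(curve, n, rel_noise = 0, seed = NULL,
                                       mz_range = c(100, 1500)) {
  stopifnot(inherits(curve, "resolution_curve"))
  if (!is.numeric(n) || length(n) != 1L || n < 3) {
    stop_validation("`n` must be at least 3 (two-parameter fit).")
  }
  if (!is.numeric(rel_noise) || rel_noise < 0) stop_validation("`rel_noise` must be >= 0.")
  with_seed_maybe(seed, {
    mz <- runif(n, mz_range[1], mz_range[2])
    res <- predict_resolution(curve, mz) * (1 + rnorm(n, 0, rel_noise))
    tibble(mz = mz, resolution = pmax(res, .Machine$double.eps))
  })
}

#' Simulate a single profile-mode Gaussian peak
#'
#' Utility for exercising [estimate_resolution_points()]: a Gaussian peak
#' shape sampled on a regular m/z grid, with the FWHM implied by a
#' resolution curve.
#'
#' @param mz Apex m/z.
#' @param curve `resolution_curve` giving the FWHM as `mz / R(mz)`.
#' @param height Apex intensity.
#' @param step Grid spacing in Da (default FWHM/20).
#' @param span Half-extent of the grid in FWHM units.
#' @return Profile tibble (`mz`, `intensity`).
#' @export
simulate_profile_peak <- function(mz, curve, height = 1e6, step = NULL, span = 4) {
  check_number(mz, "mz")
  fwhm <- adaptive_bin_width(curve, mz)
  if (is.null(step)) step <- fwhm / 20
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  grid <- seq(mz - span * fwhm, mz + span * fwhm, by = step)
  intensity <- height * exp(-(grid - mz)^2 / (2 * sd^2))
  tibble(mz = grid, intensity = intensity)
}
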