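# Independent brute-force oracles used by the property tests. These must stay
# independent of the package implementation paths they check.

qe_curve <- orbitrap_curve(70000)  # 70,000 @ m/z 200, k = -0.5

# reconstruct explicit label vectors from confusion counts
labels_from_counts <- function(tp, fp, tn, fn, pos = "P", neg = "N") {
  list(
    truth = c(rep(pos, tp), rep(neg, fp), rep(neg, tn), rep(pos, fn)),
    pred  = c(rep(pos, tp), rep(pos, fp), rep(neg, tn), rep(neg, fn))
  )
}

# MCC as the Pearson correlation of the 0/1 indicator vectors (an algebraically
# different route than the count formula); NA (zero variance) maps to 0
oracle_mcc <- function(truth, pred, pos) {
  r <- suppressWarnings(stats::cor(as.numeric(truth == pos), as.numeric(pred == pos)))
  if (is.na(r)) 0 else r
}

# F1 as the harmonic mean of precision and recall computed from scratch
oracle_f1 <- function(truth, pred, pos) {
  p <- if (sum(pred == pos) == 0) 0 else sum(truth == pos & pred == pos) / sum(pred == pos)
  r <- if (sum(truth == pos) == 0) 0 else sum(truth == pos & pred == pos) / sum(truth == pos)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

# O(n*m) peak-in-interval scan
brute_bin <- function(spectrum, buckets) {
  out <- numeric(nrow(buckets))
  for (i in seq_len(nrow(spectrum))) {
    for (b in seq_len(nrow(buckets))) {
      if (spectrum$mz[i] >= buckets$lower[b] && spectrum$mz[i] < buckets$upper[b]) {
        out[b] <- out[b] + spectrum$intensity[i]
        break
      }
    }
  }
  out
}

# all-pairs reimplementation of the recovery taxonomy (no sorting/searching)
brute_recovery <- function(buckets, peaks, truth, tol_ppm) {
  nb <- nrow(buckets)
  wap <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    inb <- peaks$mz >= buckets$lower[b] & peaks$mz < buckets$upper[b]
    if (any(inb)) wap[b] <- sum(peaks$mz[inb] * peaks$intensity[inb]) / sum(peaks$intensity[inb])
  }
  cand <- lapply(seq_len(nrow(truth)), function(i) {
    which(!is.na(wap) & abs(wap - truth$mz[i]) / truth$mz[i] * 1e6 <= tol_ppm)
  })
  shared <- tabulate(unlist(cand), nbins = nb)
  status <- character(nrow(truth))
  for (i in seq_along(cand)) {
    cb <- cand[[i]]
    if (length(cb)) {
      best <- cb[which.min(abs(wap[cb] - truth$mz[i]))]
      if (length(cb) == 1L && shared[best] == 1L) status[i] <- "recovered"
      else if (shared[best] > 1L) status[i] <- "aggregated"
      else status[i] <- "clipped"
    } else {
      contain <- which(truth$mz[i] >= buckets$lower & truth$mz[i] < buckets$upper)
      status[i] <- if (length(contain) && !is.na(wap[contain])) "aggregated" else "missed"
    }
  }
  status
}

# minimal peak-table constructor
peak_tbl <- function(mz, intensity = rep(1, length(mz)), obs = "s1", batch = "batch1") {
  tibble::tibble(observation_id = obs, batch_id = batch, label = NA_character_,
                 mz = mz, intensity = intensity)
}

# random disjoint sorted bucket set
random_buckets <- function(n, lo = 100, hi = 500) {
  edges <- sort(runif(2 * n, lo, hi))
  lower <- edges[seq(1, 2 * n, by = 2)]
  upper <- edges[seq(2, 2 * n, by = 2)]
  tibble::tibble(lower = lower, upper = upper,
                 apex = (lower + upper) / 2, n_members = 1L)
}
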