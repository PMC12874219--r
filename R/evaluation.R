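#' Ground-truth recovery analysis of a binned bucket set
#'
#' Classifies every ground-truth m/z feature by how faithfully the bucket
#' set represents it once real (noisy, shifted) centroid peaks have been
#' binned. For each bucket that received at least one peak, the
#' intensity-weighted mean m/z of its member centroids is computed (the
#' *measured apex*). A bucket is a *candidate* for a truth feature when its
#' measured apex lies within `match_tol_ppm` of the feature's m/z. Statuses:
#'
#' * `recovered` - exactly one candidate bucket, and that bucket is a
#'   candidate for no other truth feature (a clean one-to-one mapping);
#' * `aggregated` - the feature's best candidate also matches another truth
#'   feature, or no bucket matches but some bucket's interval contains the
#'   feature (its apex was dragged beyond tolerance by co-binned extraneous
#'   peaks);
#' * `clipped` - two or more candidate buckets match the feature (its
#'   centroids were split across a bucket boundary);
#' * `missed` - no candidate and no containing bucket.
#'
#' The recovery rate is `recovered / total`.
#'
#' @param buckets Disjoint, sorted bucket tibble.
#' @param peaks Long centroid peak table (`mz`, `intensity`, optionally
#'   `observation_id`) - the peaks that were binned.
#' @param truth Data frame with columns `name` and `mz` (one row per
#'   ground-truth feature; duplicated m/z entries are rejected).
#' @param match_tol_ppm Matching tolerance in ppm (default 5).
#' @return A `recovery_report`: per-feature statuses plus summary counts;
#'   see [tidy.recovery_report()] and [glance.recovery_report()].
#' @export
recovery_analysis <- function(buckets, peaks, truth, match_tol_ppm = 5) {
  validate_buckets(buckets)
  check_columns(peaks, c("mz", "intensity"), "peaks")
  check_columns(truth, c("name", "mz"), "truth")
  check_number(match_tol_ppm, "match_tol_ppm")
  if (nrow(truth) == 0L) stop_validation("`truth` must contain at least one feature.")
  if (any(truth$mz <= 0)) stop_validation("`truth$mz` must be positive.")
  if (anyDuplicated(truth$mz)) stop_validation("`truth` contains duplicated m/z entries.")

  # measured apex per bucket: intensity-weighted mean of the member centroids
  bidx <- assign_to_buckets(peaks$mz, buckets)
  keep <- !is.na(bidx)
  wsum <- rowsum(as.numeric(peaks$intensity[keep]), bidx[keep])
  msum <- rowsum(as.numeric(peaks$mz[keep] * peaks$intensity[keep]), bidx[keep])
  member_bucket <- as.integer(rownames(wsum))
  wapex <- (msum / wsum)[, 1]
  ord <- order(wapex)
  wapex_sorted <- wapex[ord]
  bucket_sorted <- member_bucket[ord]

  n_truth <- nrow(truth)
  cand <- vector("list", n_truth)      # candidate bucket indices per feature
  cand_ppm <- vector("list", n_truth)
  for (i in seq_len(n_truth)) {
    m <- truth$mz[i]
    tol <- match_tol_ppm * 1e-6 * m
    lo <- findInterval(m - tol, wapex_sorted) + 1L
    hi <- findInterval(m + tol, wapex_sorted)
    if (hi >= lo) {
      j <- lo:hi
      cand[[i]] <- bucket_sorted[j]
      cand_ppm[[i]] <- abs(wapex_sorted[j] - m) / m * 1e6
    } else {
      cand[[i]] <- integer()
      cand_ppm[[i]] <- numeric()
    }
  }

  # how many truth features each bucket is a candidate for
  shared <- table(unlist(cand))

  status <- character(n_truth)
  best_bucket <- integer(n_truth)
  best_ppm <- rep(NA_real_, n_truth)
  for (i in seq_len(n_truth)) {
    cb <- cand[[i]]
    if (length(cb)) {
      b <- cb[which.min(cand_ppm[[i]])]
      best_bucket[i] <- b
      best_ppm[i] <- min(cand_ppm[[i]])
      n_shared <- shared[[as.character(b)]]
      if (length(cb) == 1L && n_shared == 1L) {
        status[i] <- "recovered"
      } else if (n_shared > 1L) {
        status[i] <- "aggregated"
      } else {
        status[i] <- "clipped"
      }
    } else {
      # no bucket matches within tolerance; if some populated bucket's
      # interval contains the feature, its apex was displaced -> aggregated
      ci <- assign_to_buckets(truth$mz[i], buckets)
      if (!is.na(ci) && ci %in% member_bucket) {
        status[i] <- "aggregated"
        best_bucket[i] <- ci
      } else {
        status[i] <- "missed"
        best_bucket[i] <- NA_integer_
      }
    }
  }

  features <- tibble(
    name = as.character(truth$name), mz = as.numeric(truth$mz),
    status = factor(status, levels = c("recovered", "aggregated", "clipped", "missed")),
    bucket = best_bucket, ppm_error = best_ppm
  )
  counts <- table(features$status)
  structure(
    list(features = features,
         counts = stats::setNames(as.integer(counts), names(counts)),
         recovery_rate = unname(counts[["recovered"]]) / n_truth,
         n_features = n_truth,
         match_tol_ppm = match_tol_ppm),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  %d ground-truth features, matched at +/-%g ppm\n",
              x$n_features, x$match_tol_ppm))
  for (s in names(x$counts)) {
    cat(sprintf("  %-10s %4d  (%.1f%%)\n", s, x$counts[[s]],
                100 * x$counts[[s]] / x$n_features))
  }
  cat(sprintf("  recovery rate: %.1f%%\n", 100 * x$recovery_rate))
  invisible(x)
}

#' @rdname recovery_analysis
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @export
tidy.recovery_report <- function(x, ...) x$features

#' @rdname recovery_analysis
#' @export
glance.recovery_report <- function(x, ...) {
  tibble(
    recovery_rate = x$recovery_rate,
    recovered = x$counts[["recovered"]], aggregated = x$counts[["aggregated"]],
    clipped = x$counts[["clipped"]], missed = x$counts[["missed"]],
    n_features = x$n_features, match_tol_ppm = x$match_tol_ppm
  )
}

#' Plot a recovery report
#'
#' Per-feature status along the m/z axis plus marginal status counts.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  pal <- c(recovered = "#1b7837", aggregated = "#d95f02",
           clipped = "#7570b3", missed = "#b2182b")
  ggplot2::ggplot(object$features,
                  ggplot2::aes(x = .data$mz, y = .data$status, color = .data$status)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.8, size = 1.5) +
    ggplot2::scale_color_manual(values = pal, guide = "none") +
    ggplot2::labs(
      x = "ground-truth m/z", y = NULL,
      title = sprintf("Recovery %.1f%% (%d/%d features)",
                      100 * object$recovery_rate,
                      object$counts[["recovered"]], object$n_features)) +
    ggplot2::theme_minimal()
}

#' Confusion counts from binary label vectors
#'
#' @param truth,predicted Equal-length binary label vectors (factor,
#'   character or logical).
#' @param positive The label treated as the positive class; defaults to the
#'   first label in sort order and is recorded in the result.
#' @return A `confusion_counts` object with fields `tp`, `fp`, `tn`, `fn`,
#'   `positive`.
#' @export
confusion_from_labels <- function(truth, predicted, positive = NULL) {
  if (length(truth) != length(predicted)) {
    stop_validation("`truth` and `predicted` must have equal length.")
  }
  if (length(truth) == 0L) stop_validation("Label vectors must be non-empty.")
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  levels <- sort(unique(c(truth, predicted)))
  if (length(levels) > 2L) {
    stop_validation(sprintf("Labels must be binary; got %d distinct values.", length(levels)))
  }
  if (is.null(positive)) positive <- levels[1]
  if (!positive %in% levels) {
    stop_validation(sprintf("`positive` label %s does not occur in the data.", deparse(positive)))
  }
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  confusion_counts(tp, fp, tn, fn, positive = positive)
}

#' @rdname confusion_from_labels
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn, positive = "positive") {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || anyNA(counts)) {
    stop_validation("Confusion counts must be non-negative.")
  }
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn),
                 positive = positive),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> positive = %s\n", x$positive))
  cat(sprintf("  tp=%g fp=%g tn=%g fn=%g\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

as_confusion <- function(c) {
  if (!inherits(c, "confusion_counts")) stop_validation("Expected a `confusion_counts` object.")
  c
}

#' Binary classification metrics
#'
#' Standard confusion-matrix scores with explicit zero-denominator
#' conventions (each metric is 0 when its denominator vanishes, so
#' near-degenerate predictions yield well-defined values):
#' * `f1_score`: \eqn{TP / (TP + (FP + FN)/2)}
#' * `mcc`: \eqn{(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' * `recall`: \eqn{TP / (TP + FN)}
#' * `precision`: \eqn{TP / (TP + FP)}
#'
#' @param c A `confusion_counts` object.
#' @return A single numeric score: F1 and precision/recall in \[0, 1\],
#'   MCC in \[-1, 1\].
#' @export
#' @examples
#' f1_score(confusion_counts(tp = 1, fp = 1, tn = 0, fn = 1)) # 0.5
#' mcc(confusion_counts(tp = 5, fp = 0, tn = 5, fn = 0))      # 1
f1_score <- function(c) {
  c <- as_confusion(c)
  den <- c$tp + 0.5 * (c$fp + c$fn)
  if (den == 0) return(0)
  c$tp / den
}

#' @rdname f1_score
#' @export
mcc <- function(c) {
  c <- as_confusion(c)
  den2 <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  if (den2 == 0) return(0)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(den2)
}

#' @rdname f1_score
#' @export
recall <- function(c) {
  c <- as_confusion(c)
  if (c$tp + c$fn == 0) return(0)
  c$tp / (c$tp + c$fn)
}

#' @rdname f1_score
#' @export
precision <- function(c) {
  c <- as_confusion(c)
  if (c$tp + c$fp == 0) return(0)
  c$tp / (c$tp + c$fp)
}

#' Support-weighted mean F1 across classes
#'
#' @param counts List of `confusion_counts`, one per class (each with that
#'   class taken as positive).
#' @param support Non-negative class supports, same length as `counts`, not
#'   all zero.
#' @return Weighted mean of the per-class F1 scores.
#' @export
weighted_f1 <- function(counts, support) {
  if (!is.list(counts) || length(counts) != length(support)) {
    stop_validation("`counts` and `support` must have equal length.")
  }
  if (any(support < 0) || anyNA(support)) stop_validation("`support` must be non-negative.")
  if (sum(support) == 0) stop_validation("At least one class must have positive support.")
  f1s <- vapply(counts, f1_score, numeric(1))
  sum(f1s * support) / sum(support)
}

#' Thin linear-classifier harness for feature matrices
#'
#' Fits a regularized logistic regression (ridge, via \pkg{glmnet}) on a
#' labeled feature matrix and applies it to another, returning predicted
#' labels. Deliberately plain plumbing for running integration-benchmark
#' style experiments; it is not the subject of this package and carries no
#' tuned defaults beyond glmnet's.
#'
#' @param train,test `feature_matrix` objects with non-missing `label`;
#'   `test` must share the training columns.
#' @param positive Label treated as the positive class.
#' @param lambda Ridge penalty (default 1e-2).
#' @return Character vector of predicted labels for the rows of `test`.
#' @export
linear_classifier <- function(train, test, positive, lambda = 1e-2) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop_validation("The `glmnet` package is required for linear_classifier().")
  }
  for (fm in list(train, test)) {
    if (!inherits(fm, "feature_matrix")) stop_validation("Inputs must be feature_matrix objects.")
  }
  if (anyNA(train$label)) stop_validation("`train` has missing labels.")
  x <- feature_values(train)
  y <- factor(train$label == positive, levels = c(FALSE, TRUE))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  xt <- feature_values(test)
  common <- intersect(colnames(x), colnames(xt))
  if (length(common) < ncol(x)) {
    xt_full <- matrix(0, nrow(xt), ncol(x), dimnames = list(NULL, colnames(x)))
    xt_full[, common] <- xt[, common]
    xt <- xt_full
  } else {
    xt <- xt[, colnames(x), drop = FALSE]
  }
  prob <- as.numeric(stats::predict(fit, newx = xt, type = "response"))
  other <- setdiff(unique(as.character(train$label)), positive)[1]
  ifelse(prob >= 0.5, positive, other)
}
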