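# Top-3 correctness and the variable-size prediction-set policy: prediction
# scores are accumulated over the top-k conditions until a calibrated
# threshold is reached, with k constrained to [k_min, k_max] (default [3, 7]).
# Score ties break by lexicographic condition code after descending score.

order_scores <- function(scores) {
  conds <- names(scores) %||% colnames(scores)
  order(-as.numeric(scores), conds)
}

#' Top-3 correctness for one case
#'
#' 1 if the reference top-1 condition is among the 3 highest-scoring
#' conditions, else 0 (ties broken by condition code).
#'
#' @param ref_top1 Reference top-1 condition code (or a
#'   `reference_standard`).
#' @param scores Named probability vector over the full taxonomy.
#' @return 0 or 1.
#' @export
top3_correct <- function(ref_top1, scores) {
  if (inherits(ref_top1, "reference_standard")) ref_top1 <- ref_top1$top1
  ord <- order_scores(scores)
  as.integer(ref_top1 %in% names(scores)[ord[1:3]])
}

#' Variable-k policy
#'
#' @param threshold Cumulative-score stopping threshold in (0, 1].
#' @param k_min,k_max Prediction-set size bounds (defaults 3 and 7).
#' @param calibration_report Optional list of achieved dev metrics
#'   (overall/high-risk sensitivity, mean k, false-positive rate).
#' @return An object of class `variable_k_policy`.
#' @export
variable_k_policy <- function(threshold, k_min = 3, k_max = 7,
                              calibration_report = NULL) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must lie in (0, 1]")
  if (k_min > k_max) stopf("k_min must not exceed k_max")
  structure(list(threshold = threshold, k_min = as.integer(k_min),
                 k_max = as.integer(k_max),
                 calibration_report = calibration_report),
            class = "variable_k_policy")
}

#' @export
print.variable_k_policy <- function(x, ...) {
  cat(sprintf("<variable_k_policy> threshold = %.4f, k in [%d, %d]\n",
              x$threshold, x$k_min, x$k_max))
  if (!is.null(x$calibration_report)) {
    r <- x$calibration_report
    cat(sprintf("  dev: sensitivity %.3f (high-risk %.3f), mean k %.2f, FPR %.5f\n",
                r$sensitivity, r$hr_sensitivity, r$mean_k, r$fpr))
  }
  invisible(x)
}

#' Variable-k prediction set for one case
#'
#' Emits the smallest k >= `k_min` whose cumulative top-k score reaches the
#' policy threshold, capped at `k_max`; the set is the top-k conditions by
#' descending score.
#'
#' @param scores Named probability vector over the taxonomy (sums to 1).
#' @param policy A [variable_k_policy].
#' @return List with `conditions` (ordered, length k) and `k`.
#' @export
variable_k_predict <- function(scores, policy) {
  ord <- order_scores(scores)
  cum <- cumsum(as.numeric(scores)[ord])
  k <- policy$k_min
  while (k < policy$k_max && cum[k] < policy$threshold) k <- k + 1L
  list(conditions = names(scores)[ord[seq_len(k)]], k = as.integer(k))
}

# Per-case quantities the exact threshold search needs: the rank of the
# reference condition among sorted scores and the cumulative scores at
# k_min..k_max. O(n log C) once; every candidate threshold is then O(log n).
variable_k_profile <- function(scores, ref_top1, k_min = 3L, k_max = 7L) {
  n <- nrow(scores)
  conds <- colnames(scores)
  ranks <- integer(n)
  cums <- matrix(0, n, k_max)
  for (i in seq_len(n)) {
    ord <- order(-scores[i, ], conds)
    ranks[i] <- match(match(ref_top1[i], conds), ord)
    cums[i, ] <- cumsum(scores[i, ord[seq_len(k_max)]])
  }
  list(ranks = ranks, cums = cums, k_min = as.integer(k_min),
       k_max = as.integer(k_max))
}

# Sensitivity / mean-k / FPR as step functions of the threshold, evaluated
# at a vector of candidate thresholds. A case is contained at threshold t
# iff rank <= k_min, or k_min < rank <= k_max and its cumulative score at
# (rank - 1) is < t (the stopping rule has not yet fired).
profile_metrics <- function(prof, thresholds, C, subset = NULL) {
  idx <- subset %||% seq_along(prof$ranks)
  ranks <- prof$ranks[idx]
  cums <- prof$cums[idx, , drop = FALSE]
  n <- length(ranks)
  always <- sum(!is.na(ranks) & ranks <= prof$k_min)
  mid <- which(!is.na(ranks) & ranks > prof$k_min & ranks <= prof$k_max)
  gate <- sort(cums[cbind(mid, ranks[mid] - 1L)])
  # findInterval with left.open counts gate values strictly below t
  contained <- always + findInterval(thresholds, gate, left.open = TRUE)
  sens <- contained / n
  ksum <- rep(prof$k_min * n, length(thresholds))
  if (prof$k_max > prof$k_min) {
    for (k in prof$k_min:(prof$k_max - 1L)) {
      ck <- sort(cums[, k])
      ksum <- ksum + findInterval(thresholds, ck, left.open = TRUE)
    }
  }
  mean_k <- ksum / n
  fpr <- (mean_k - sens) / (C - 1)
  list(sensitivity = sens, mean_k = mean_k, fpr = fpr, n = n)
}

#' Calibrate the variable-k threshold
#'
#' Exact search over all distinct cumulative-score values observed on the
#' development set (plus 1.0): thresholds achieving overall sensitivity of
#' at least `sensitivity_target` are kept; among them, those maximising
#' sensitivity on high-risk conditions; among those, the threshold with the
#' smallest false-positive rate (mean number of non-reference conditions
#' emitted per case, divided by C - 1) is returned. Sensitivity of a set is
#' containment of the reference top-1 condition.
#'
#' @param dev_scores Score matrix (n x C) on the development set.
#' @param dev_refs Character vector of reference top-1 conditions.
#' @param tax A `cond_taxonomy` (supplies the high-risk subset).
#' @param sensitivity_target Overall sensitivity floor (default 0.95).
#' @param k_min,k_max Set-size bounds (defaults 3 and 7).
#' @return A [variable_k_policy] with a populated calibration report.
#' @export
calibrate_policy <- function(dev_scores, dev_refs, tax,
                             sensitivity_target = 0.95, k_min = 3, k_max = 7) {
  if (nrow(dev_scores) == 0L) stopf("development set is empty")
  if (!length(tax$high_risk)) stopf("taxonomy has no high-risk conditions")
  C <- ncol(dev_scores)
  prof <- variable_k_profile(dev_scores, dev_refs, k_min, k_max)
  cand <- sort(unique(c(as.numeric(prof$cums), 1)))
  cand <- cand[cand > 0 & cand <= 1]

  hr_cases <- which(dev_refs %in% tax$high_risk)
  overall <- profile_metrics(prof, cand, C)
  feasible <- overall$sensitivity >= sensitivity_target
  if (!any(feasible)) {
    best <- max(overall$sensitivity)
    stopf(paste0("no threshold attains overall sensitivity %.3f with k <= %d ",
                 "(best achievable %.4f)"), sensitivity_target, k_max, best)
  }
  if (length(hr_cases)) {
    hr <- profile_metrics(prof, cand, C, subset = hr_cases)$sensitivity
  } else {
    hr <- rep(NA_real_, length(cand))
  }
  pick <- which(feasible)
  if (length(hr_cases)) {
    pick <- pick[hr[pick] == max(hr[pick])]
  }
  pick <- pick[which.min(overall$fpr[pick])]
  thr <- cand[pick]

  report <- list(
    sensitivity = overall$sensitivity[pick],
    hr_sensitivity = if (length(hr_cases)) hr[pick] else NA_real_,
    mean_k = overall$mean_k[pick],
    fpr = overall$fpr[pick],
    n_dev = nrow(dev_scores),
    sensitivity_target = sensitivity_target
  )
  variable_k_policy(thr, k_min, k_max, calibration_report = report)
}

#' Variable-k containment for a score matrix
#'
#' Applies a calibrated policy row-wise and reports, per case, the emitted k
#' and whether the reference top-1 is contained.
#'
#' @param scores Score matrix (n x C).
#' @param ref_top1 Character vector of reference top-1 conditions.
#' @param policy A [variable_k_policy].
#' @return data.frame with columns `k` and `contained` (0/1).
#' @export
variable_k_eval <- function(scores, ref_top1, policy) {
  prof <- variable_k_profile(scores, ref_top1, policy$k_min, policy$k_max)
  t <- policy$threshold
  k <- rep(policy$k_min, nrow(scores))
  if (policy$k_max > policy$k_min) {
    for (kk in policy$k_min:(policy$k_max - 1L)) {
      k <- k + as.integer(prof$cums[, kk] < t)
    }
  }
  contained <- !is.na(prof$ranks) & prof$ranks <= k
  data.frame(k = as.integer(k), contained = as.integer(contained))
}

#' Top-3 correctness for a score matrix
#'
#' @param scores Score matrix (n x C).
#' @param ref_top1 Character vector of reference top-1 conditions.
#' @return Integer vector of 0/1 flags.
#' @export
top3_flags <- function(scores, ref_top1) {
  prof <- variable_k_profile(scores, ref_top1, 3L, 3L)
  as.integer(!is.na(prof$ranks) & prof$ranks <= 3L)
}
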