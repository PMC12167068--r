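# Multiclass Platt (temperature) recalibration toward a new setting's
# condition distribution. The temperature divides the logits before the
# softmax; it is fit by one-vs-rest binary log-loss over the condition
# categories, where a category's predicted probability is the sum of the
# temperature-scaled probabilities of its member conditions. Two variants:
# a single global T (rank-preserving within a case) and a per-category
# vector of K temperatures (which can reorder conditions across categories
# and therefore change top-3 decisions).

#' Temperature-scale logits
#'
#' Softmax of `logits / T`. With a per-category temperature vector, each
#' condition's logit is divided by its category's temperature before the
#' shared softmax normalisation.
#'
#' @param logits Numeric vector or matrix (rows = cases) of C logits.
#' @param T Positive scalar temperature, or a positive vector of length K
#'   (one per category; requires `tax`).
#' @param tax A `cond_taxonomy`, required when `T` is a vector.
#' @return Probability vector/matrix summing to 1 per case.
#' @export
temperature_scale <- function(logits, T, tax = NULL) {
  if (any(T <= 0)) stopf("temperature must be positive")
  vec <- is.null(dim(logits))
  z <- if (vec) matrix(logits, nrow = 1L, dimnames = list(NULL, names(logits)))
       else logits
  if (length(T) == 1L) {
    z <- z / T
  } else {
    if (is.null(tax)) stopf("per-category temperature requires a taxonomy")
    if (length(T) != length(tax$categories)) {
      stopf("temperature vector must have one entry per category")
    }
    cat_idx <- match(tax$category_of[colnames(z)], tax$categories)
    z <- sweep(z, 2L, T[cat_idx], "/")
  }
  p <- softmax_rows(z)
  dimnames(p) <- dimnames(z)
  if (vec) p[1L, ] else p
}

# One-vs-rest category negative log-loss of temperature-scaled scores.
category_nll <- function(logits, T, tax, cat_target) {
  p <- temperature_scale(logits, T, tax)
  cat_idx <- match(tax$category_of[colnames(logits)], tax$categories)
  q <- t(rowsum(t(p), cat_idx))  # n x K category probabilities
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  K <- length(tax$categories)
  nll <- 0
  for (k in seq_len(K)) {
    y <- as.numeric(cat_target == k)
    nll <- nll - sum(y * log(q[, k]) + (1 - y) * log(1 - q[, k]))
  }
  nll / nrow(logits)
}

# Expected calibration error of the top-1 condition probability, 15
# equal-mass bins.
ece_top1 <- function(p, labels, bins = 15L) {
  correct <- colnames(p)[max.col(p, ties.method = "first")] == labels
  conf <- apply(p, 1L, max)
  br <- stats::quantile(conf, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE)
  br[1L] <- -Inf; br[bins + 1L] <- Inf
  bin <- cut(conf, unique(br), labels = FALSE)
  tab <- tapply(seq_along(conf), bin, function(i) {
    c(mean(conf[i]), mean(correct[i]), length(i))
  })
  sum(vapply(tab, function(x) x[3] * abs(x[1] - x[2]), 0)) / length(conf)
}

#' Fit a recalibration temperature
#'
#' Minimises the summed one-vs-rest binary log-loss over the K condition
#' categories on a calibration split, where each category's probability is
#' the sum of its member conditions' temperature-scaled probabilities. The
#' global variant is a 1-D minimisation over log T (tolerance 1e-6, with
#' T = 1 included in the comparison so the post-fit loss never exceeds the
#' pre-fit loss); the per-category variant optimises K log-temperatures.
#'
#' @param logits Logit matrix (n x C) on the calibration split (the
#'   `"logits"` attribute of [predict_scores] output).
#' @param labels Character vector of reference conditions for those cases.
#' @param tax A `cond_taxonomy`.
#' @param per_category Fit one temperature per category (default `FALSE`).
#' @return An object of class `calibration_model`: list with `T`
#'   (scalar or length-K vector), `per_category`, and `fit_report`
#'   (pre/post category NLL and pre/post top-1 expected calibration error on
#'   the calibration split).
#' @export
fit_temperature <- function(logits, labels, tax, per_category = FALSE) {
  if (nrow(logits) == 0L) stopf("calibration split is empty")
  cats <- tax$category_of[labels]
  cat_target <- match(cats, tax$categories)
  if (length(unique(cat_target[!is.na(cat_target)])) < 2L) {
    stopf("degenerate fit: calibration split contains a single category")
  }
  K <- length(tax$categories)
  obj1 <- function(logT) category_nll(logits, exp(logT), tax, cat_target)
  pre_nll <- category_nll(logits, 1, tax, cat_target)
  pre_ece <- ece_top1(temperature_scale(logits, 1), labels)

  if (!per_category) {
    opt <- stats::optimize(obj1, interval = c(log(0.05), log(20)),
                           tol = 1e-6)
    T_hat <- exp(opt$minimum)
    if (opt$objective > pre_nll) T_hat <- 1
  } else {
    # mild ridge on log T stabilises the K-parameter fit on small
    # calibration splits without moving the optimum materially
    lambda <- 0.05
    objK <- function(logT) {
      category_nll(logits, exp(logT), tax, cat_target) +
        lambda * mean(logT^2)
    }
    opt <- stats::optim(rep(0, K), objK, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    T_hat <- exp(opt$par)
    names(T_hat) <- tax$categories
    if (category_nll(logits, T_hat, tax, cat_target) > pre_nll) {
      T_hat <- rep(1, K)
    }
  }
  post_nll <- category_nll(logits, T_hat, tax, cat_target)
  post_ece <- ece_top1(temperature_scale(logits, T_hat, tax), labels)
  structure(list(T = T_hat, per_category = per_category,
                 fit_report = list(pre_nll = pre_nll, post_nll = post_nll,
                                   pre_ece = pre_ece, post_ece = post_ece,
                                   n = nrow(logits))),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  if (x$per_category) {
    cat("<calibration_model> per-category T:",
        paste(sprintf("%.2f", x$T), collapse = " "), "\n")
  } else {
    cat(sprintf("<calibration_model> global T = %.4f\n", x$T))
  }
  r <- x$fit_report
  cat(sprintf("  category NLL %.4f -> %.4f; top-1 ECE %.4f -> %.4f (n = %d)\n",
              r$pre_nll, r$post_nll, r$pre_ece, r$post_ece, r$n))
  invisible(x)
}

#' Recalibrate a score matrix
#'
#' @param scores Score matrix from [predict_scores] (uses its `"logits"`
#'   attribute).
#' @param model A `calibration_model`.
#' @param tax A `cond_taxonomy` (needed for per-category temperatures).
#' @return Recalibrated probability matrix (with updated `"logits"`).
#' @export
recalibrate_scores <- function(scores, model, tax = NULL) {
  logits <- attr(scores, "logits")
  if (is.null(logits)) stopf("scores carry no logits attribute")
  p <- temperature_scale(logits, model$T, tax)
  if (length(model$T) == 1L) {
    attr(p, "logits") <- logits / model$T
  } else {
    cat_idx <- match(tax$category_of[colnames(logits)], tax$categories)
    attr(p, "logits") <- sweep(logits, 2L, model$T[cat_idx], "/")
  }
  p
}

#' Stratified calibration/evaluation split
#'
#' Allocates `fraction` of the cases to the calibration side with
#' per-stratum proportional quotas rounded by largest remainder (every
#' stratum's calibration share is within one case of `fraction`), sampling
#' within strata without replacement, deterministically per seed.
#'
#' @param cases A `case_set`.
#' @param fraction Calibration fraction in (0, 1) (default 0.2).
#' @param strata_keys Character vector of `cases$info` column names defining
#'   the strata (default condition and sex).
#' @param seed Integer seed.
#' @return List with `calibration_ids` and `evaluation_ids` (disjoint,
#'   exhaustive character vectors of case ids).
#' @export
make_split <- function(cases, fraction = 0.2,
                       strata_keys = c("true_condition", "sex"), seed = 1) {
  n <- n_cases(cases)
  if (n == 0L) stopf("target case set is empty")
  if (fraction <= 0 || fraction >= 1) stopf("fraction must lie in (0, 1)")
  missing_keys <- setdiff(strata_keys, names(cases$info))
  if (length(missing_keys)) {
    stopf("unknown strata keys: %s", paste(missing_keys, collapse = ", "))
  }
  strat <- interaction(cases$info[strata_keys], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(n), strat)
  quotas <- largest_remainder(lengths(groups), fraction)
  cal_idx <- local_seed(derive_seed(seed, "split"), {
    unlist(lapply(seq_along(groups), function(g) {
      if (quotas[g] == 0L) return(integer(0))
      g_idx <- groups[[g]]
      g_idx[sample.int(length(g_idx), quotas[g])]
    }))
  })
  ids <- cases$info$case_id
  list(calibration_ids = sort(ids[cal_idx]),
       evaluation_ids = sort(setdiff(ids, ids[cal_idx])))
}
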