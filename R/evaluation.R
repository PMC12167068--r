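# Accuracy metrics adjusted for the study's condition sub-sampling design,
# confidence intervals, subgroup reports and error-factor analyses.

#' Inverse-probability sampling weights
#'
#' Weight of each case = 1 / subsample_rate of its true condition (e.g. 5
#' for a condition retained at 20%), undoing the design's thinning.
#'
#' @param cases A `case_set`.
#' @param tax A `cond_taxonomy`.
#' @return Numeric vector of per-case weights (all >= 1).
#' @export
sampling_weights <- function(cases, tax) {
  1 / tax$subsample_rate[cases$info$true_condition]
}

#' Sampling-adjusted accuracy
#'
#' Weighted proportion `sum(w * flag) / sum(w)`; with all weights 1 this is
#' the plain mean.
#'
#' @param correct_flags 0/1 correctness flags.
#' @param weights Per-case positive weights ([sampling_weights]); default
#'   all 1.
#' @return Proportion in \[0, 1\].
#' @export
weighted_accuracy <- function(correct_flags, weights = NULL) {
  if (!length(correct_flags)) stopf("no cases supplied")
  if (is.null(weights)) weights <- rep(1, length(correct_flags))
  if (length(weights) != length(correct_flags)) {
    stopf("weights must align with flags")
  }
  sum(weights * correct_flags) / sum(weights)
}

#' Confidence interval for a proportion
#'
#' 95% interval by the configured method: `"bootstrap"` (default; seeded
#' nonparametric percentile bootstrap honouring sampling weights, 2000
#' replicates) or `"wilson"` (closed form, unweighted).
#'
#' @param correct_flags 0/1 flags (for Wilson, `k` successes of `n` may be
#'   passed as `c(rep(1, k), rep(0, n - k))`).
#' @param weights Optional sampling weights (bootstrap only).
#' @param method `"bootstrap"` or `"wilson"`.
#' @param reps Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(low, high)`.
#' @export
proportion_ci <- function(correct_flags, weights = NULL,
                          method = c("bootstrap", "wilson"),
                          reps = 2000, seed = 1, conf = 0.95) {
  method <- match.arg(method)
  n <- length(correct_flags)
  if (n == 0L) stopf("no cases supplied")
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- mean(correct_flags)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    return(c(low = max(0, centre - half), high = min(1, centre + half)))
  }
  if (is.null(weights)) weights <- rep(1, n)
  stat <- local_seed(derive_seed(seed, "bootci"), {
    vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      sum(weights[idx] * correct_flags[idx]) / sum(weights[idx])
    }, 0)
  })
  q <- stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  c(low = q[1], high = q[2])
}

#' Accuracy stratified by case covariates
#'
#' One weighted accuracy (with CI) per stratum value of each requested
#' stratifier; unknown values form their own stratum.
#'
#' @param correct_flags 0/1 flags aligned to `cases`.
#' @param cases A `case_set`.
#' @param tax A `cond_taxonomy` (for sampling weights).
#' @param strata Columns of `cases$info` to stratify by.
#' @param metric Label recorded in the output (default `"top3"`).
#' @param ci_method Passed to [proportion_ci].
#' @param seed Bootstrap seed.
#' @return data.frame with columns `metric`, `stratifier`, `stratum`,
#'   `value`, `ci_low`, `ci_high`, `n`.
#' @export
stratified_report <- function(correct_flags, cases, tax,
                              strata = c("domain", "ambiguity_class", "sex",
                                         "age_group", "efst", "true_category",
                                         "anatomic_location"),
                              metric = "top3",
                              ci_method = "bootstrap", seed = 1) {
  w <- sampling_weights(cases, tax)
  rows <- list()
  for (s in strata) {
    if (!s %in% names(cases$info)) next
    vals <- as.character(cases$info[[s]])
    vals[is.na(vals)] <- "unknown"
    for (v in sort(unique(vals))) {
      idx <- vals == v
      ci <- proportion_ci(correct_flags[idx], w[idx], method = ci_method,
                          seed = derive_seed(seed, paste0(s, v)))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, stratifier = s, stratum = v,
        value = weighted_accuracy(correct_flags[idx], w[idx]),
        ci_low = ci[["low"]], ci_high = ci[["high"]], n = sum(idx),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Error-factor analysis
#'
#' Multivariable logistic regression of per-case correctness on dummy-coded
#' covariates (log odds with 95% Wald CIs; a positive log odds means the
#' factor is associated with the model being correct), plus univariable
#' Mann-Whitney screens of correctness between each factor level and its
#' reference level, Bonferroni-corrected within each variable group (e.g.
#' multiplied by 3 for a 3-level age grouping). Perfect separation is
#' reported per factor with an unbounded CI rather than failing; aliased
#' (collinear) factors are flagged.
#'
#' @param correct_flags 0/1 flags.
#' @param covariates data.frame of categorical covariates (one column per
#'   variable group; first level after sorting is the reference unless the
#'   column is a factor).
#' @param alpha Significance level after correction (default 0.05).
#' @return An object of class `error_factor_report`: data.frame with one
#'   row per non-reference factor level: `variable`, `level`, `log_odds`,
#'   `ci_low`, `ci_high`, `p_univariable`, `p_adjusted`, `significant`,
#'   `aliased`, `separated`.
#' @export
error_factor_analysis <- function(correct_flags, covariates, alpha = 0.05) {
  stopifnot(is.data.frame(covariates))
  covariates <- as.data.frame(lapply(covariates, function(x) {
    if (!is.factor(x)) x <- factor(x)
    droplevels(x)
  }), stringsAsFactors = TRUE)
  few <- vapply(covariates, nlevels, 0L) < 2L
  if (any(few)) {
    stopf("factor(s) with fewer than 2 levels: %s",
          paste(names(covariates)[few], collapse = ", "))
  }
  dat <- cbind(.correct = as.numeric(correct_flags), covariates)
  fit <- suppressWarnings(
    stats::glm(.correct ~ ., data = dat, family = stats::binomial())
  )
  cf <- summary(fit)$coefficients
  all_coefs <- names(stats::coef(fit))
  aliased_terms <- all_coefs[is.na(stats::coef(fit))]

  rows <- list()
  for (v in names(covariates)) {
    lv <- levels(covariates[[v]])
    ref <- lv[1L]
    others <- lv[-1L]
    n_tests <- length(others)
    for (l in others) {
      term <- paste0(v, l)
      aliased <- term %in% aliased_terms
      if (!aliased && term %in% rownames(cf)) {
        est <- cf[term, "Estimate"]; se <- cf[term, "Std. Error"]
        separated <- abs(est) > 10 || se > 100
        lo <- if (separated) -Inf else est - 1.96 * se
        hi <- if (separated) Inf else est + 1.96 * se
      } else {
        est <- NA_real_; lo <- NA_real_; hi <- NA_real_; separated <- FALSE
      }
      x1 <- correct_flags[covariates[[v]] == l]
      x0 <- correct_flags[covariates[[v]] == ref]
      p_u <- if (length(unique(c(x1, x0))) < 2L) 1 else
        suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE)$p.value)
      p_adj <- min(1, p_u * n_tests)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = l, log_odds = est, ci_low = lo, ci_high = hi,
        p_univariable = p_u, p_adjusted = p_adj,
        significant = !is.na(p_adj) && p_adj < alpha,
        aliased = aliased, separated = separated,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- fit
  class(out) <- c("error_factor_report", class(out))
  out
}

#' CLIN-vs-PAT accuracy equality test
#'
#' One-way ANOVA of per-case correctness on the photo-source domain (the
#' study's own choice of test for this comparison; a proportion test would
#' be the textbook alternative).
#'
#' @param correct_flags 0/1 flags.
#' @param domain Character vector of domains per case.
#' @return List with `p_value` and the `aov` fit.
#' @export
domain_equality_test <- function(correct_flags, domain) {
  fit <- stats::aov(flags ~ domain,
                    data = data.frame(flags = as.numeric(correct_flags),
                                      domain = factor(domain)))
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(p_value = p, fit = fit)
}
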