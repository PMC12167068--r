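#' Default condition-category labels
#'
#' The eleven category labels used to partition the condition taxonomy:
#' infections, contact dermatitis, inflammatory conditions, other eruptions,
#' neoplasms, pigmentary disorders, vascular lesions, blisters and ulcers,
#' hair disorders, nail disorders, and a residual class.
#'
#' @export
condition_categories <- c(
  "Infections", "Contact dermatitis", "Inflammatory", "Other eruptions",
  "Neoplasms", "Pigmentary disorder", "Vascular", "Blisters and ulcers",
  "Hair disorders", "Nail disorders", "Others"
)

#' Generate a condition taxonomy
#'
#' Builds a taxonomy of `n_conditions` condition codes partitioned into
#' `n_categories` categories by round-robin assignment (so category sizes
#' differ by at most one), flags a high-risk subset (drawn preferentially
#' from the "Neoplasms" category when present, mirroring skin cancers), and
#' attaches per-condition study sub-sampling rates. Three conditions stand in
#' for the heavily sub-sampled diagnoses of the source cohort design: an
#' eczema-like condition retained at rate 0.2, a seborrhoeic-keratosis-like
#' condition at 0.5 and a rash-like condition at 0.5; all other conditions
#' carry rate 1.
#'
#' @param n_conditions Number of condition codes (default 419).
#' @param n_categories Number of categories (default 11).
#' @param n_high_risk Size of the high-risk subset (default 20).
#' @param seed Integer seed; the taxonomy is deterministic given it.
#' @param category_labels Labels for the categories; defaults to
#'   [condition_categories] when `n_categories == 11`, otherwise generic
#'   labels are generated.
#' @return An object of class `cond_taxonomy`: a list with elements
#'   `conditions`, `categories`, `category_of` (named character vector),
#'   `high_risk`, `subsample_rate` (named numeric vector), `seed`.
#' @export
generate_taxonomy <- function(n_conditions = 419, n_categories = 11,
                              n_high_risk = 20, seed = 1,
                              category_labels = NULL) {
  if (!is_count(n_conditions) || !is_count(n_categories)) {
    stopf("n_conditions and n_categories must be positive integers")
  }
  if (n_categories > n_conditions) {
    stopf("n_categories (%d) must not exceed n_conditions (%d)",
          n_categories, n_conditions)
  }
  if (!is.numeric(n_high_risk) || n_high_risk < 0 || n_high_risk > n_conditions) {
    stopf("n_high_risk must lie in [0, n_conditions]")
  }
  if (is.null(category_labels)) {
    category_labels <- if (n_categories == 11) condition_categories else
      sprintf("Category %02d", seq_len(n_categories))
  }
  if (length(category_labels) != n_categories) {
    stopf("category_labels must have length n_categories")
  }
  width <- max(3L, nchar(as.character(n_conditions)))
  conditions <- sprintf(paste0("C%0", width, "d"), seq_len(n_conditions))
  category_of <- category_labels[((seq_len(n_conditions) - 1L) %% n_categories) + 1L]
  names(category_of) <- conditions

  high_risk <- local_seed(derive_seed(seed, "high_risk"), {
    pool <- conditions[category_of == "Neoplasms"]
    if (length(pool) >= n_high_risk) {
      sort(sample(pool, n_high_risk))
    } else {
      extra <- sample(setdiff(conditions, pool), n_high_risk - length(pool))
      sort(c(pool, extra))
    }
  })

  subsample_rate <- rep(1, n_conditions)
  names(subsample_rate) <- conditions
  first_of <- function(lab) {
    idx <- which(category_of == lab)
    if (length(idx)) conditions[idx[1L]] else NA_character_
  }
  special <- c("Inflammatory" = 0.2,    # eczema-like
               "Neoplasms" = 0.5,       # seborrhoeic-keratosis-like
               "Other eruptions" = 0.5) # rash-like
  for (lab in names(special)) {
    cond <- first_of(lab)
    if (!is.na(cond)) subsample_rate[cond] <- special[[lab]]
  }

  structure(
    list(conditions = conditions, categories = category_labels,
         category_of = category_of, high_risk = high_risk,
         subsample_rate = subsample_rate, seed = as.integer(seed)),
    class = "cond_taxonomy"
  )
}

#' @export
print.cond_taxonomy <- function(x, ...) {
  cat(sprintf("<cond_taxonomy> %d conditions in %d categories; %d high-risk\n",
              length(x$conditions), length(x$categories), length(x$high_risk)))
  cat("  sub-sampled conditions:",
      paste(sprintf("%s (%.1f)", names(x$subsample_rate)[x$subsample_rate < 1],
                    x$subsample_rate[x$subsample_rate < 1]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Define a domain profile
#'
#' A domain profile fixes the condition distribution and ambiguity level of
#' one data-generating setting. Three settings are modelled: `DEV` (the
#' classifier's development distribution), `CLIN` (clinician-taken photos)
#' and `PAT` (patient-taken photos), distinguished chiefly by their priors
#' over the condition categories.
#'
#' @param name One of `"DEV"`, `"CLIN"`, `"PAT"`.
#' @param category_prior Probability vector over the taxonomy's categories
#'   (named or in category order); must sum to 1 within 1e-9.
#' @param n_cases Number of cases to generate for this domain.
#' @param noise_scale Nonnegative scalar controlling case ambiguity: it
#'   scales the embedding noise and drives simulated rater error.
#' @param condition_prior_within_category Optional list (one numeric vector
#'   per category) of within-category condition priors; `NULL` means uniform.
#' @return An object of class `domain_profile`.
#' @export
domain_profile <- function(name, category_prior, n_cases, noise_scale = 2,
                           condition_prior_within_category = NULL) {
  name <- match.arg(name, c("DEV", "CLIN", "PAT"))
  if (any(category_prior < 0) || abs(sum(category_prior) - 1) > 1e-9) {
    stopf("category_prior must be nonnegative and sum to 1 (tolerance 1e-9)")
  }
  if (!is.numeric(n_cases) || n_cases < 0 || n_cases != floor(n_cases)) {
    stopf("n_cases must be a nonnegative integer")
  }
  if (!is.numeric(noise_scale) || noise_scale < 0) {
    stopf("noise_scale must be nonnegative")
  }
  if (!is.null(condition_prior_within_category)) {
    ok <- vapply(condition_prior_within_category, function(p) {
      all(p >= 0) && abs(sum(p) - 1) < 1e-9
    }, logical(1))
    if (!all(ok)) stopf("each within-category prior must sum to 1")
  }
  structure(
    list(name = name, category_prior = category_prior,
         n_cases = as.integer(n_cases), noise_scale = noise_scale,
         condition_prior_within_category = condition_prior_within_category),
    class = "domain_profile"
  )
}

# Geometric-decay within-category prior covering the first `coverage`
# fraction of each category's conditions (the development set sees only part
# of the taxonomy's long tail).
decay_prior <- function(sizes, decay, coverage = 1) {
  lapply(sizes, function(m) {
    keep <- max(1L, ceiling(coverage * m))
    p <- c(decay^(seq_len(keep) - 1L), rep(0, m - keep))
    p / sum(p)
  })
}

#' Default domain profiles
#'
#' Returns the package's reference study conditions: a `DEV` profile whose
#' category prior over-represents contact dermatitis, inflammatory
#' conditions and neoplasms and under-represents infections, and `CLIN` /
#' `PAT` profiles whose priors follow the clinical-cohort category
#' frequencies (normalised), with `PAT` slightly lighter on neoplasms. `DEV`
#' additionally covers only the head (about 60%) of each category's
#' conditions, so the target settings contain conditions the development
#' distribution essentially never produces -- the structure that drives the
#' generalisation gap.
#'
#' @param tax A `cond_taxonomy`.
#' @param n_dev,n_clin,n_pat Cases per domain.
#' @param noise_scale Shared ambiguity scale (see [domain_profile]).
#' @param dev_coverage Fraction of each category's conditions with positive
#'   prior in DEV (default 0.6).
#' @return Named list of three `domain_profile` objects.
#' @export
default_profiles <- function(tax, n_dev = 4000, n_clin = 1719, n_pat = 628,
                             noise_scale = 2, dev_coverage = 0.6) {
  K <- length(tax$categories)
  sizes <- as.integer(table(factor(tax$category_of, levels = tax$categories)))
  if (K == 11) {
    dev_prior <- c(0.025, 0.27, 0.32, 0.05, 0.25, 0.02, 0.015, 0.01, 0.01,
                   0.01, 0.02)
    clin_prior <- c(14.3, 23.2, 24.0, 15.7, 28.6, 2.9, 2.5, 1.4, 0.9, 2.6, 4.2)
    pat_prior <- c(11.7, 21.0, 20.8, 12.1, 18.0, 3.0, 2.2, 0.9, 1.5, 3.2, 5.6)
  } else {
    # generic shifted priors for non-default K (testing at reduced scale)
    w <- seq_len(K)
    dev_prior <- rev(w) / sum(w)
    clin_prior <- w / sum(w)
    pat_prior <- w^1.2
  }
  norm <- function(p) p / sum(p)
  names(dev_prior) <- names(clin_prior) <- names(pat_prior) <- tax$categories

  list(
    DEV = domain_profile("DEV", norm(dev_prior), n_dev, noise_scale,
                         decay_prior(sizes, 1, dev_coverage)),
    CLIN = domain_profile("CLIN", norm(clin_prior), n_clin, noise_scale,
                          decay_prior(sizes, 1, 1)),
    PAT = domain_profile("PAT", norm(pat_prior), n_pat, noise_scale,
                         decay_prior(sizes, 1, 1))
  )
}
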