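# Distribution-matching resampling of the development set and
# condition-aware augmentation with target-setting examples.

#' Metropolis-Hastings resampling plan
#'
#' @param target_category_dist Probability vector over the taxonomy's
#'   categories (named or in category order), the distribution to match.
#' @param n_out Number of ids to emit.
#' @param seed Integer seed (the chain is run with a fixed seed).
#' @param burn_in Discarded initial chain steps (default 1000).
#' @param thin Keep every `thin`-th state after burn-in (default 5).
#' @param match_level `"category"` (default, matching is done at the
#'   category level) or `"condition"`.
#' @return A list of class `resample_plan`.
#' @export
resample_plan <- function(target_category_dist, n_out, seed = 1,
                          burn_in = 1000, thin = 5,
                          match_level = c("category", "condition")) {
  match_level <- match.arg(match_level)
  if (any(target_category_dist < 0) ||
      abs(sum(target_category_dist) - 1) > 1e-9) {
    stopf("target distribution must be nonnegative and sum to 1")
  }
  if (!is_count(n_out)) stopf("n_out must be a positive integer")
  structure(list(target = target_category_dist, n_out = as.integer(n_out),
                 seed = as.integer(seed), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), match_level = match_level),
            class = "resample_plan")
}

#' Metropolis-Hastings resampling of a source set
#'
#' Runs a Markov chain over source case indices with a uniform independence
#' proposal and acceptance ratio `w(proposed) / w(current)`, where
#' `w(case) = target[group] / empirical_source[group]` and the group is the
#' case's condition category (or condition, per the plan's match level). The
#' chain's stationary law is exactly the group-matched resampling law, so
#' after burn-in and thinning the emitted ids' histogram converges to the
#' target distribution.
#'
#' @param source_cases A `case_set` (typically the development set).
#' @param tax A `cond_taxonomy`.
#' @param plan A [resample_plan].
#' @return Character vector of `plan$n_out` case ids (with replacement).
#' @export
mh_resample <- function(source_cases, tax, plan) {
  info <- source_cases$info
  group <- if (plan$match_level == "category") {
    factor(tax$category_of[info$true_condition], levels = tax$categories)
  } else {
    factor(info$true_condition, levels = tax$conditions)
  }
  target <- plan$target
  if (is.null(names(target))) names(target) <- levels(group)
  emp <- as.numeric(table(group)) / length(group)
  names(emp) <- levels(group)
  missing <- names(target)[target > 1e-12 & emp[names(target)] == 0]
  if (length(missing)) {
    stopf("target places mass on source-unrepresented group(s): %s",
          paste(missing, collapse = ", "))
  }
  w_group <- ifelse(emp > 0, target[levels(group)] / emp, 0)
  w <- w_group[as.integer(group)]

  n <- nrow(info)
  total <- plan$burn_in + plan$n_out * plan$thin
  local_seed(plan$seed, {
    prop <- sample.int(n, total, replace = TRUE)
    unif <- stats::runif(total)
    state <- sample.int(n, 1L)
    # start from a positive-weight state so the chain is well-defined
    while (w[state] == 0) state <- sample.int(n, 1L)
    kept <- integer(plan$n_out)
    kth <- 0L
    for (s in seq_len(total)) {
      j <- prop[s]
      if (w[state] == 0 || unif[s] * w[state] <= w[j]) state <- j
      if (s > plan$burn_in && (s - plan$burn_in) %% plan$thin == 0L) {
        kth <- kth + 1L
        kept[kth] <- state
      }
    }
    info$case_id[kept]
  })
}

#' Direct weighted-sampling oracle for distribution matching
#'
#' Independent sampling of source ids with probability proportional to the
#' same importance weights the Metropolis-Hastings chain uses; serves as the
#' exact reference law the chain must match.
#'
#' @inheritParams mh_resample
#' @export
weighted_resample_oracle <- function(source_cases, tax, plan) {
  info <- source_cases$info
  group <- if (plan$match_level == "category") {
    factor(tax$category_of[info$true_condition], levels = tax$categories)
  } else {
    factor(info$true_condition, levels = tax$conditions)
  }
  target <- plan$target
  if (is.null(names(target))) names(target) <- levels(group)
  emp <- as.numeric(table(group)) / length(group)
  names(emp) <- levels(group)
  w_group <- ifelse(emp > 0, target[levels(group)] / emp, 0)
  w <- w_group[as.integer(group)]
  local_seed(derive_seed(plan$seed, "oracle"), {
    info$case_id[sample.int(nrow(info), plan$n_out, replace = TRUE, prob = w)]
  })
}

#' Identify rarer conditions relative to the development histogram
#'
#' A condition is "rare" (under-represented in development) iff its
#' relative frequency in the development histogram is strictly below its
#' relative frequency in the target histogram.
#'
#' @param dev_hist,target_hist Named counts or frequencies over the same
#'   taxonomy (conditions absent from a histogram count as 0).
#' @param tax A `cond_taxonomy`.
#' @return Character vector of rare condition codes.
#' @export
find_rare_conditions <- function(dev_hist, target_hist, tax) {
  rel <- function(h) {
    v <- rep(0, length(tax$conditions))
    names(v) <- tax$conditions
    h <- h[names(h) %in% tax$conditions]
    v[names(h)] <- as.numeric(h)
    if (sum(v) > 0) v / sum(v) else v
  }
  dev_rel <- rel(dev_hist)
  tgt_rel <- rel(target_hist)
  tax$conditions[dev_rel < tgt_rel]
}

#' Augmentation configuration
#'
#' @param aug_alpha Probability that an augmentation draw comes from the
#'   rare-condition stratum (default 0.7).
#' @param donor_fraction Fraction of the target set forming the donor pool
#'   (default 0.2; the complementary fraction is the frozen evaluation set).
#' @param strata_keys Stratification keys for the donor split (default
#'   condition and sex).
#' @param seed Integer seed.
#' @export
augmentation_config <- function(aug_alpha = 0.7, donor_fraction = 0.2,
                                strata_keys = c("true_condition", "sex"),
                                seed = 1) {
  if (aug_alpha < 0 || aug_alpha > 1) stopf("aug_alpha must lie in [0, 1]")
  structure(list(aug_alpha = aug_alpha, donor_fraction = donor_fraction,
                 strata_keys = strata_keys, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Stratified donor/evaluation split of the target set
#'
#' Splits the target cases into a donor pool (`fraction`, stratified by
#' condition and demographics with largest-remainder quotas) and the frozen
#' evaluation remainder that every experiment configuration must share and
#' never train on.
#'
#' @param target_cases A `case_set`.
#' @param fraction Donor fraction in (0, 1) (default 0.2).
#' @param strata_keys Stratification columns of `target_cases$info`.
#' @param seed Integer seed.
#' @return List with `donor` and `eval` (`case_set`s), the id vectors
#'   `donor_ids` / `eval_ids`, and `eval_hash` (hash of the frozen split).
#' @export
stratified_donor_split <- function(target_cases, fraction = 0.2,
                                   strata_keys = c("true_condition", "sex"),
                                   seed = 1) {
  sp <- make_split(target_cases, fraction, strata_keys, seed)
  ids <- target_cases$info$case_id
  donor <- subset_cases(target_cases, ids %in% sp$calibration_ids)
  eval_set <- subset_cases(target_cases, ids %in% sp$evaluation_ids)
  list(donor = donor, eval = eval_set,
       donor_ids = sp$calibration_ids, eval_ids = sp$evaluation_ids,
       eval_hash = hash_ids(sp$evaluation_ids))
}

#' Condition-aware augmentation of a training set
#'
#' Draws `n_add` donor cases with replacement: with probability `aug_alpha`
#' uniformly from the rare-condition stratum of the donor pool, otherwise
#' uniformly from the common stratum, and appends them to the development
#' cases. Only the donor pool is ever drawn from; the frozen evaluation
#' split is untouchable by construction.
#'
#' @param dev_cases Development `case_set`.
#' @param donor_pool Donor `case_set` (the stratified donor fraction of the
#'   target set).
#' @param rare Character vector of rare condition codes
#'   ([find_rare_conditions]).
#' @param cfg An [augmentation_config].
#' @param n_add Number of donor draws (0 returns the development set
#'   unchanged).
#' @param donor_labels Labels used to assign donors to strata (default the
#'   donor pool's reference top-1 when present, else true conditions).
#' @return List with `cases` (the augmented `case_set`), `labels`
#'   (training labels: development true conditions followed by donor
#'   labels), and `drawn_ids`.
#' @export
condition_aware_augment <- function(dev_cases, donor_pool, rare, cfg, n_add,
                                    donor_labels = NULL) {
  if (n_add == 0L) {
    return(list(cases = dev_cases, labels = dev_cases$info$true_condition,
                drawn_ids = character(0)))
  }
  if (is.null(donor_labels)) {
    donor_labels <- donor_pool$info$ref_top1 %||% donor_pool$info$true_condition
  }
  is_rare <- donor_labels %in% rare
  if (!any(is_rare) && cfg$aug_alpha > 0) {
    stopf("infeasible: rare stratum of the donor pool is empty with aug_alpha > 0")
  }
  rare_idx <- which(is_rare)
  common_idx <- which(!is_rare)
  draws <- local_seed(derive_seed(cfg$seed, "augment"), {
    from_rare <- stats::runif(n_add) < cfg$aug_alpha
    if (!length(common_idx)) from_rare[] <- TRUE
    idx <- integer(n_add)
    n_r <- sum(from_rare)
    if (n_r) idx[from_rare] <- rare_idx[sample.int(length(rare_idx), n_r,
                                                   replace = TRUE)]
    if (n_add - n_r) {
      idx[!from_rare] <- common_idx[sample.int(length(common_idx), n_add - n_r,
                                               replace = TRUE)]
    }
    idx
  })
  drawn <- subset_cases(donor_pool, draws)
  list(cases = bind_cases(dev_cases, drawn),
       labels = c(dev_cases$info$true_condition, donor_labels[draws]),
       drawn_ids = donor_pool$info$case_id[draws])
}
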