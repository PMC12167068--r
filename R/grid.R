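# The experiment grid: eight configurations spanning no adaptation, score
# recalibration, development-set distribution matching, random vs
# condition-aware augmentation, and head-only vs end-to-end fine-tuning,
# all evaluated on one frozen stratified evaluation split of the target
# domains.

GRID_CONFIGURATIONS <- c(
  "baseline", "score_recalibration", "train_matched", "random_split_20",
  "condition_aware_20", "condition_aware_20_plus_recal",
  "head_only_condition_aware", "head_only_plus_recal"
)

#' Experiment-grid configuration
#'
#' Desk-scale defaults for the synthetic study world: a reduced taxonomy
#' and sample sizes that preserve the structure of the full-scale setting
#' (11 categories, development coverage of only part of each category,
#' category-prior shift between development and the two target domains).
#'
#' @param n_conditions,n_categories,n_high_risk Taxonomy size (defaults
#'   110/11/8 at desk scale).
#' @param d,d_meta Embedding dimensions.
#' @param n_dev,n_clin,n_pat Cases per domain.
#' @param noise_scale Ambiguity scale shared by the domains.
#' @param rater_skill Panel rater skill.
#' @param dev_coverage Fraction of each category's conditions present in
#'   the development distribution.
#' @param dev_tune_fraction Fraction of the development set held out from
#'   model fitting and used to calibrate the variable-k threshold (default
#'   0.3).
#' @param donor_fraction,aug_alpha Augmentation design (defaults 0.2, 0.7).
#' @param n_add Donor draws per augmentation (default twice the donor-pool
#'   size).
#' @param sensitivity_target Variable-k overall sensitivity floor.
#' @param train_steps,learning_rate,focal_gamma Optimiser settings.
#' @param configurations Subset of configurations to run (default all 8).
#' @param no_shift If `TRUE`, the target domains reuse the development
#'   profile's priors (a no-shift control world in which no adaptation
#'   should move accuracy materially).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(n_conditions = 110, n_categories = 11, n_high_risk = 8,
                        d = 16, d_meta = 16, n_dev = 3000, n_clin = 1200,
                        n_pat = 400, noise_scale = 2, rater_skill = 0.95,
                        dev_coverage = 0.75, dev_tune_fraction = 0.3,
                        donor_fraction = 0.2,
                        aug_alpha = 0.7, n_add = NULL,
                        sensitivity_target = 0.95, train_steps = 300,
                        learning_rate = 0.1, focal_gamma = 2,
                        configurations = GRID_CONFIGURATIONS,
                        no_shift = FALSE, seed = 1) {
  configurations <- match.arg(configurations, GRID_CONFIGURATIONS,
                              several.ok = TRUE)
  structure(as.list(environment()), class = "grid_config")
}

# Per-domain top-3 and variable-k rows for one configuration.
grid_rows <- function(label, scores, eval_set, tax, policy, seed) {
  info <- eval_set$info
  refs <- info$ref_top1
  w <- sampling_weights(eval_set, tax)
  t3 <- top3_flags(scores, refs)
  vk <- variable_k_eval(scores, refs, policy)$contained
  rows <- list()
  for (dom in unique(info$domain)) {
    idx <- info$domain == dom
    for (metric in c("top3", "variable_k")) {
      fl <- if (metric == "top3") t3[idx] else vk[idx]
      ci <- proportion_ci(fl, w[idx], method = "bootstrap",
                          seed = derive_seed(seed, paste0(label, dom, metric)))
      rows[[length(rows) + 1L]] <- data.frame(
        configuration = label, domain = dom, metric = metric,
        value = weighted_accuracy(fl, w[idx]),
        ci_low = ci[["low"]], ci_high = ci[["high"]], n = sum(idx),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the adaptation experiment grid
#'
#' Generates the synthetic world (DEV, CLIN, PAT), builds the reference
#' standards, freezes the stratified 20%/80% donor/evaluation split of the
#' combined target set, then trains and evaluates the requested
#' configurations on the identical frozen 80% evaluation split:
#'
#' * `baseline` -- trained on the development set only;
#' * `score_recalibration` -- baseline plus per-category temperature
#'   recalibration fit on the 20% calibration (donor) split;
#' * `train_matched` -- retrained end-to-end on a Metropolis-Hastings
#'   resample of the development set matched to the combined target
#'   category distribution (no target images are used);
#' * `random_split_20` -- retrained with uniform donor draws added;
#' * `condition_aware_20` (`_plus_recal`) -- retrained with rare-condition
#'   weighted donor draws (probability `aug_alpha` from the rare stratum);
#' * `head_only_condition_aware` (`_plus_recal`) -- the same augmentation
#'   but fine-tuning only the final classification layer over the frozen
#'   baseline encoders.
#'
#' @param config A [grid_config].
#' @return data.frame with one row per (configuration, domain, metric):
#'   `value`, `ci_low`, `ci_high`, `n`, `eval_hash` (shared by every row),
#'   plus a `manifest` attribute (seeds, split hash, configuration list).
#' @export
run_grid <- function(config = grid_config()) {
  stopifnot(inherits(config, "grid_config"))
  seed <- config$seed
  tax <- generate_taxonomy(config$n_conditions, config$n_categories,
                           config$n_high_risk, seed = derive_seed(seed, "tax"))
  profiles <- default_profiles(tax, config$n_dev, config$n_clin, config$n_pat,
                               config$noise_scale, config$dev_coverage)
  if (isTRUE(config$no_shift)) {
    for (dom in c("CLIN", "PAT")) {
      profiles[[dom]]$category_prior <- profiles$DEV$category_prior
      profiles[[dom]]$condition_prior_within_category <-
        profiles$DEV$condition_prior_within_category
    }
  }
  dev <- generate_cases(tax, profiles$DEV, config$d,
                        seed = derive_seed(seed, "dev"))
  prep_target <- function(profile, salt) {
    x <- generate_cases(tax, profile, config$d, seed = derive_seed(seed, salt))
    x <- apply_subsampling(x, tax, seed = derive_seed(seed, paste0(salt, "ss")))
    x <- simulate_panels(x, tax, config$rater_skill,
                         seed = derive_seed(seed, paste0(salt, "panel")))
    drop_excluded(panel_reference(x))
  }
  clin <- prep_target(profiles$CLIN, "clin")
  pat <- prep_target(profiles$PAT, "pat")
  target <- bind_cases(clin, pat)

  # hold a tune split of the development set out of model fitting; the
  # variable-k threshold is calibrated on it rather than on training scores
  tune_sp <- make_split(dev, config$dev_tune_fraction,
                        strata_keys = "true_condition",
                        seed = derive_seed(seed, "devtune"))
  dev_tune <- subset_cases(dev, dev$info$case_id %in% tune_sp$calibration_ids)
  dev <- subset_cases(dev, dev$info$case_id %in% tune_sp$evaluation_ids)

  split <- stratified_donor_split(target, config$donor_fraction,
                                  seed = derive_seed(seed, "donor"))
  donor <- split$donor
  eval_set <- split$eval
  n_add <- config$n_add %||% (2L * n_cases(donor))

  train_cfg <- function(salt) {
    loss_config(focal_gamma = config$focal_gamma,
                train_steps = config$train_steps,
                learning_rate = config$learning_rate,
                seed = derive_seed(seed, salt))
  }
  fit_e2e <- function(cases, labels, salt) {
    train_classifier(cases, labels,
                     new_classifier(tax, config$d, config$d_meta,
                                    seed = derive_seed(seed, paste0(salt, "i"))),
                     train_cfg(salt), mode = "end_to_end")
  }

  m_base <- fit_e2e(dev, dev$info$true_condition, "base")

  # threshold policy per model, calibrated on the held-out development tune
  # split
  policy_for <- function(model, recal = NULL) {
    sc <- predict_scores(dev_tune, model, seed = derive_seed(seed, "devsc"))
    if (!is.null(recal)) sc <- recalibrate_scores(sc, recal, tax)
    tryCatch(
      calibrate_policy(sc, dev_tune$info$true_condition, tax,
                       config$sensitivity_target),
      error = function(e) variable_k_policy(1)  # infeasible target: widest sets
    )
  }
  recal_for <- function(model) {
    sc <- predict_scores(donor, model, seed = derive_seed(seed, "calsc"))
    fit_temperature(attr(sc, "logits"), donor$info$ref_top1, tax,
                    per_category = TRUE)
  }
  eval_scores <- function(model, recal = NULL) {
    sc <- predict_scores(eval_set, model, seed = derive_seed(seed, "evalsc"))
    if (!is.null(recal)) sc <- recalibrate_scores(sc, recal, tax)
    sc
  }

  # shared ingredients for the adaptation configurations
  target_cat_dist <- prop.table(table(factor(
    tax$category_of[target$info$ref_top1], levels = tax$categories)))
  dev_hist <- table(dev$info$true_condition)
  donor_hist <- table(donor$info$ref_top1)
  rare <- find_rare_conditions(dev_hist, donor_hist, tax)
  aug_cfg <- augmentation_config(config$aug_alpha, config$donor_fraction,
                                 seed = derive_seed(seed, "aug"))

  models <- list()
  recals <- list()
  need <- function(cfgs) any(cfgs %in% config$configurations)

  if (need(c("train_matched"))) {
    # draw 2x the development-set size so the resample retains most of the
    # distinct common-category cases alongside the up-weighted rare ones;
    # the model is fine-tuned from the baseline on the matched resample
    # (shorter schedule, lower rate), which keeps what was learned from the
    # full development set while absorbing the target category prior
    plan <- resample_plan(as.numeric(target_cat_dist), 2L * n_cases(dev),
                          seed = derive_seed(seed, "mh"))
    ids <- mh_resample(dev, tax, plan)
    matched <- subset_cases(dev, match(ids, dev$info$case_id))
    ft_cfg <- train_cfg("matched")
    ft_cfg$train_steps <- max(50L, config$train_steps %/% 2L)
    ft_cfg$learning_rate <- config$learning_rate / 4
    models$train_matched <- train_classifier(matched,
                                             matched$info$true_condition,
                                             m_base, ft_cfg,
                                             mode = "end_to_end")
  }
  if (need(c("random_split_20"))) {
    rnd_cfg <- augmentation_config(0, config$donor_fraction,
                                   seed = derive_seed(seed, "rnd"))
    aug <- condition_aware_augment(dev, donor, rare = tax$conditions,
                                   cfg = rnd_cfg, n_add = n_add)
    models$random_split_20 <- fit_e2e(aug$cases, aug$labels, "random")
  }
  if (need(c("condition_aware_20", "condition_aware_20_plus_recal"))) {
    aug <- condition_aware_augment(dev, donor, rare, aug_cfg, n_add)
    models$condition_aware_20 <- fit_e2e(aug$cases, aug$labels, "condaware")
  }
  if (need(c("head_only_condition_aware", "head_only_plus_recal"))) {
    aug <- condition_aware_augment(dev, donor, rare, aug_cfg, n_add)
    models$head_only <- train_classifier(aug$cases, aug$labels, m_base,
                                         train_cfg("head"), mode = "head_only")
  }

  model_of <- list(
    baseline = m_base, score_recalibration = m_base,
    train_matched = models$train_matched,
    random_split_20 = models$random_split_20,
    condition_aware_20 = models$condition_aware_20,
    condition_aware_20_plus_recal = models$condition_aware_20,
    head_only_condition_aware = models$head_only,
    head_only_plus_recal = models$head_only
  )
  # score recalibration is also applied to the matched retrain, as in the
  # source experiment design
  with_recal <- c("score_recalibration", "train_matched",
                  "condition_aware_20_plus_recal", "head_only_plus_recal")

  out <- list()
  for (label in config$configurations) {
    model <- model_of[[label]]
    recal <- if (label %in% with_recal) recal_for(model) else NULL
    policy <- policy_for(model, recal)
    sc <- eval_scores(model, recal)
    rows <- grid_rows(label, sc, eval_set, tax, policy,
                      derive_seed(seed, "rows"))
    rows$eval_hash <- split$eval_hash
    out[[label]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "manifest") <- list(
    seed = seed, eval_hash = split$eval_hash,
    configurations = config$configurations,
    n_dev = n_cases(dev), n_eval = n_cases(eval_set),
    n_donor = n_cases(donor), n_rare = length(rare)
  )
  res
}

#' Random-split augmentation note
#'
#' `random_split_20` reuses [condition_aware_augment] with the full
#' condition list marked rare and `aug_alpha = 0`, which reduces to uniform
#' draws from the donor pool; this keeps the frozen evaluation split shared
#' with every other configuration.
#'
#' @name random_split
#' @keywords internal
NULL
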