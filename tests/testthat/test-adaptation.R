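# Distribution matching and condition-aware augmentation.

two_cat_world <- function(n = 2000, seed = 3) {
  tax <- generate_taxonomy(8, 2, 1, seed = 17)
  prof <- domain_profile("DEV", c(0.8, 0.2), n, noise_scale = 1)
  generate_cases(tax, prof, d = 4, seed = seed)
}

cat_hist <- function(ids, cases, tax) {
  cond <- cases$info$true_condition[match(ids, cases$info$case_id)]
  prop.table(table(factor(tax$category_of[cond], levels = tax$categories)))
}

test_that("Metropolis-Hastings resampling matches the target category law", {
  tax <- generate_taxonomy(8, 2, 1, seed = 17)
  src <- two_cat_world()

  # identity target: acceptance ratios are all one, histogram stays put
  emp <- prop.table(table(factor(tax$category_of[src$info$true_condition],
                                 levels = tax$categories)))
  plan_id <- resample_plan(as.numeric(emp), 10000, seed = 4)
  ids <- mh_resample(src, tax, plan_id)
  tv <- 0.5 * sum(abs(cat_hist(ids, src, tax) - emp))
  expect_lt(tv, 0.02)

  # shifted target 0.8/0.2 -> 0.5/0.5
  plan <- resample_plan(c(0.5, 0.5), 10000, seed = 4)
  ids2 <- mh_resample(src, tax, plan)
  h2 <- cat_hist(ids2, src, tax)
  expect_lt(0.5 * sum(abs(h2 - c(0.5, 0.5))), 0.02)

  # indistinguishable from the direct weighted-sampling oracle
  ids_or <- weighted_resample_oracle(src, tax, plan)
  h_or <- table(factor(tax$category_of[
    src$info$true_condition[match(ids_or, src$info$case_id)]],
    levels = tax$categories))
  h_mh <- table(factor(tax$category_of[
    src$info$true_condition[match(ids2, src$info$case_id)]],
    levels = tax$categories))
  p <- stats::chisq.test(rbind(as.integer(h_mh), as.integer(h_or)))$p.value
  expect_gt(p, 0.01)

  # zero target mass excludes the category entirely
  plan0 <- resample_plan(c(1, 0), 2000, seed = 6)
  ids0 <- mh_resample(src, tax, plan0)
  expect_equal(as.numeric(cat_hist(ids0, src, tax))[2], 0)

  expect_identical(mh_resample(src, tax, plan), mh_resample(src, tax, plan))
})

test_that("targets on unrepresented categories are rejected", {
  tax <- generate_taxonomy(8, 2, 1, seed = 17)
  prof <- domain_profile("DEV", c(1, 0), 500, noise_scale = 1)
  src <- generate_cases(tax, prof, d = 4, seed = 1)
  plan <- resample_plan(c(0.5, 0.5), 100, seed = 2)
  expect_error(mh_resample(src, tax, plan), "unrepresented")
})

test_that("rare conditions are those relatively more frequent in the target", {
  tax3 <- generate_taxonomy(3, 3, 1, seed = 4)
  h <- function(x) stats::setNames(x, tax3$conditions)
  expect_length(find_rare_conditions(h(c(10, 5, 5)), h(c(10, 5, 5)), tax3), 0L)
  expect_equal(find_rare_conditions(h(c(10, 5, 0)), h(c(8, 4, 3)), tax3),
               tax3$conditions[3])
  expect_equal(find_rare_conditions(h(c(0.5, 0.3, 0.2)), h(c(0.2, 0.3, 0.5)),
                                    tax3),
               tax3$conditions[3])
})

test_that("condition-aware augmentation draws rare donors at the configured rate", {
  tax <- small_tax
  prof_dev <- uniform_profile(tax, 300, 1)
  dev <- generate_cases(tax, prof_dev, d = 6, seed = 2)
  prof_tgt <- uniform_profile(tax, 800, 1, name = "CLIN")
  donors <- generate_cases(tax, prof_tgt, d = 6, seed = 3)
  rare <- tax$conditions[1:10]

  cfg <- augmentation_config(aug_alpha = 0.7, seed = 5)
  aug <- condition_aware_augment(dev, donors, rare, cfg, n_add = 10000)
  added <- aug$labels[-seq_len(n_cases(dev))]
  frac_rare <- mean(added %in% rare)
  expect_lt(abs(frac_rare - 0.7), 0.012)
  expect_equal(n_cases(aug$cases), n_cases(dev) + 10000)

  all_rare <- condition_aware_augment(dev, donors, rare,
                                      augmentation_config(1, seed = 5), 500)
  expect_true(all(all_rare$labels[-seq_len(n_cases(dev))] %in% rare))

  none <- condition_aware_augment(dev, donors, rare, cfg, n_add = 0)
  expect_identical(none$cases, dev)

  expect_error(
    condition_aware_augment(dev, donors, "not-a-condition", cfg, 10),
    "infeasible")
})

test_that("the frozen evaluation split is never drawn from and splits reproduce", {
  tax <- small_tax
  prof <- uniform_profile(tax, 600, 1, name = "PAT")
  target <- generate_cases(tax, prof, d = 6, seed = 9)
  sp <- stratified_donor_split(target, 0.2, strata_keys = "sex", seed = 1)
  expect_equal(n_cases(sp$donor) + n_cases(sp$eval), 600)
  expect_length(intersect(sp$donor_ids, sp$eval_ids), 0L)

  dev <- generate_cases(tax, uniform_profile(tax, 200, 1), d = 6, seed = 10)
  aug <- condition_aware_augment(dev, sp$donor, tax$conditions[1:8],
                                 augmentation_config(0.7, seed = 2), 400)
  expect_length(intersect(aug$drawn_ids, sp$eval_ids), 0L)

  sp2 <- stratified_donor_split(target, 0.2, strata_keys = "sex", seed = 1)
  expect_identical(sp$donor_ids, sp2$donor_ids)
  expect_identical(sp$eval_hash, sp2$eval_hash)

  # donor proportion within one case of 20% per stratum
  tab_all <- table(target$info$sex)
  tab_donor <- table(factor(sp$donor$info$sex, levels = names(tab_all)))
  expect_true(all(abs(as.integer(tab_donor) - 0.2 * as.integer(tab_all)) <= 1))
})
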