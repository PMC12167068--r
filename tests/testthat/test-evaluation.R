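# Sampling-adjusted metrics, confidence intervals, subgroup reports and the
# error-factor regression.

test_that("weighted accuracy implements inverse-probability adjustment", {
  expect_equal(weighted_accuracy(c(1, 0, 1, 1)), 0.75)
  # two eczema-like cases (weight 5) and one ordinary case (weight 1)
  expect_equal(weighted_accuracy(c(1, 0, 1), c(5, 5, 1)), 6 / 11)
  expect_equal(round(weighted_accuracy(c(1, 0, 1), c(5, 5, 1)), 4), 0.5455)
  expect_error(weighted_accuracy(numeric(0)), "no cases")
  expect_error(weighted_accuracy(c(1, 0), weights = 1), "align")

  # a condition sub-sampled at 20% carries weight 5
  tax <- generate_taxonomy(22, 11, 2, seed = 1)
  eczema_like <- names(tax$subsample_rate)[tax$subsample_rate == 0.2]
  prof <- uniform_profile(tax, 50, 1)
  cases <- generate_cases(tax, prof, d = 4, seed = 1)
  cases$info$true_condition[1] <- eczema_like
  w <- sampling_weights(cases, tax)
  expect_equal(unname(w[1]), 5)
  expect_true(all(w >= 1))
  # with all rates 1 the adjustment is a no-op
  flags <- rep_len(c(1, 0), 50)
  expect_equal(weighted_accuracy(flags, rep(1, 50)),
               weighted_accuracy(flags))
})

test_that("proportion CIs cover the closed-form Wilson interval and edge cases", {
  flags <- c(rep(1, 50), rep(0, 50))
  ci <- proportion_ci(flags, method = "wilson")
  expect_equal(round(unname(ci), 3), c(0.404, 0.596))
  expect_equal(unname(proportion_ci(rep(1, 20), method = "wilson")[2]), 1)
  expect_equal(unname(proportion_ci(rep(0, 20), method = "wilson")[1]), 0)

  boot <- proportion_ci(flags, seed = 4)
  expect_true(boot[["low"]] < 0.5 && boot[["high"]] > 0.5)
  expect_identical(boot, proportion_ci(flags, seed = 4))
  # weights shift the bootstrap interval
  bw <- proportion_ci(flags, weights = c(rep(5, 50), rep(1, 50)), seed = 4)
  expect_gt(bw[["low"]], boot[["low"]])
  expect_error(proportion_ci(integer(0)), "no cases")
})

test_that("stratified reports partition the cases and match the pooled estimate", {
  tax <- tiny_tax
  prof <- uniform_profile(tax, 300, 1.5)
  cases <- generate_cases(tax, prof, d = 4, seed = 3)
  flags <- rbinom(300, 1, 0.7)
  rep1 <- stratified_report(flags, cases, tax, strata = "domain",
                            ci_method = "wilson")
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$value, weighted_accuracy(flags, sampling_weights(cases, tax)))
  expect_true(rep1$ci_low <= rep1$value && rep1$value <= rep1$ci_high)

  rep2 <- stratified_report(flags, cases, tax, strata = c("sex", "age_group"),
                            ci_method = "wilson")
  for (s in unique(rep2$stratifier)) {
    expect_equal(sum(rep2$n[rep2$stratifier == s]), 300)
  }
})

test_that("accuracy is higher for unanimous than for disagreement cases under shared noise", {
  tax <- small_tax
  prof <- uniform_profile(tax, 1500, noise_scale = 3)
  cases <- generate_cases(tax, prof, d = 10, seed = 21)
  cases <- simulate_panels(cases, tax, 0.9, seed = 22)
  cases <- drop_excluded(panel_reference(cases))
  tr <- subset_cases(cases, 1:1000)
  te <- subset_cases(cases, 1001:n_cases(cases))
  model <- train_classifier(tr, tr$info$true_condition,
                            new_classifier(tax, 10, 10, seed = 1),
                            loss_config(train_steps = 200, seed = 1))
  flags <- top3_flags(predict_scores(te, model), te$info$ref_top1)
  acc <- tapply(flags, te$info$ambiguity_class, mean)
  expect_gt(acc[["unanimous"]], acc[["disagreement"]])
})

test_that("error-factor analysis has nominal coverage and detects planted effects", {
  set.seed(99)
  # a covariate independent of correctness: CI covers 0 in >= 90% of fits
  covered <- vapply(1:100, function(i) {
    flags <- rbinom(250, 1, 0.7)
    covs <- data.frame(x = sample(c("a", "b"), 250, replace = TRUE),
                       y = sample(c("u", "v"), 250, replace = TRUE))
    r <- error_factor_analysis(flags, covs)
    row <- r[r$variable == "x", ]
    row$ci_low <= 0 && 0 <= row$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.9)

  # planted category effect at n = 2000 is flagged significant
  grp <- sample(c("bad", "good"), 2000, replace = TRUE)
  flags <- rbinom(2000, 1, ifelse(grp == "bad", 0.55, 0.8))
  covs <- data.frame(category = grp,
                     sex = sample(c("f", "m"), 2000, replace = TRUE))
  r <- error_factor_analysis(flags, covs)
  row <- r[r$variable == "category" & r$level == "good", ]
  expect_true(row$significant)
  expect_gt(row$log_odds, 0)
  expect_lt(row$p_adjusted, 0.05)

  # Bonferroni multiplies by the number of non-reference levels per variable
  covs3 <- data.frame(age_group = sample(c("<30", "30-59", ">=60"), 500,
                                         replace = TRUE))
  flags3 <- rbinom(500, 1, 0.7)
  r3 <- error_factor_analysis(flags3, covs3)
  expect_equal(r3$p_adjusted, pmin(1, r3$p_univariable * 2))
})

test_that("collinear factors are flagged instead of crashing", {
  x <- sample(c("a", "b"), 300, replace = TRUE)
  flags <- rbinom(300, 1, ifelse(x == "a", 0.6, 0.8))
  covs <- data.frame(x = x, x_copy = x)
  r <- error_factor_analysis(flags, covs)
  expect_true(any(r$aliased))
  expect_error(error_factor_analysis(flags, data.frame(k = rep("a", 300))),
               "fewer than 2")
})

test_that("the domain equality test returns an ANOVA p-value", {
  flags <- rbinom(400, 1, 0.7)
  dom <- rep(c("CLIN", "PAT"), each = 200)
  out <- domain_equality_test(flags, dom)
  expect_true(out$p_value > 0 && out$p_value <= 1)
  # a planted domain gap is detected
  flags2 <- rbinom(400, 1, ifelse(dom == "CLIN", 0.85, 0.55))
  expect_lt(domain_equality_test(flags2, dom)$p_value, 0.01)
})
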