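# Temperature recalibration: scaling identities, the one-vs-rest category
# fit, and the stratified calibration split.

test_that("temperature scaling matches the softmax closed forms", {
  z <- c(a = 2, b = 0)
  expect_equal(temperature_scale(z, 1), c(a = exp(2), b = 1) / (exp(2) + 1))
  p2 <- temperature_scale(z, 2)
  expect_equal(as.numeric(p2), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(round(as.numeric(p2), 4), c(0.7311, 0.2689))
  # large T flattens to uniform
  pu <- temperature_scale(c(5, -3, 1), 1e6)
  expect_true(all(abs(pu - 1 / 3) < 1e-4))
  expect_error(temperature_scale(z, 0), "positive")
  expect_error(temperature_scale(z, -1), "positive")
  # matrix rows sum to one
  m <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("c", 1:4)))
  expect_true(all(abs(rowSums(temperature_scale(m, 2.5)) - 1) < 1e-12))
})

test_that("a single global temperature never reorders conditions within a case", {
  set.seed(5)
  z <- matrix(rnorm(10 * 22), 10, 22,
              dimnames = list(NULL, tiny_tax$conditions))
  for (T in c(0.3, 1, 4)) {
    p <- temperature_scale(z, T)
    for (i in 1:10) expect_equal(order(-p[i, ]), order(-z[i, ]))
  }
  # hence top-3 accuracy is invariant under any global T
  refs <- sample(tiny_tax$conditions, 10, replace = TRUE)
  expect_equal(top3_flags(temperature_scale(z, 3), refs),
               top3_flags(temperature_scale(z, 0.5), refs))
})

# Well-calibrated synthetic logits: labels drawn from the softmax itself.
calibrated_logits <- function(n, tax, seed, spread = 2) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * length(tax$conditions), sd = spread), n,
                length(tax$conditions),
                dimnames = list(NULL, tax$conditions))
    p <- exp(z - apply(z, 1, max))
    p <- p / rowSums(p)
    labels <- vapply(seq_len(n), function(i) {
      sample(tax$conditions, 1, prob = p[i, ])
    }, "")
    list(logits = z, labels = labels)
  })
}

test_that("fitting recovers a known temperature distortion within 10%", {
  sim <- calibrated_logits(5000, tiny_tax, seed = 21)
  distorted <- sim$logits / 2.5   # overconfident by T* = 2.5
  fit <- fit_temperature(distorted, sim$labels, tiny_tax)
  expect_lt(abs(fit$T - 1 / 2.5) / (1 / 2.5), 0.10)

  # grid-search oracle over T agrees with the 1-D optimiser
  grid <- seq(0.2, 1.2, by = 0.005)
  nll <- vapply(grid, function(T) {
    dermshift:::category_nll(distorted, T, tiny_tax,
                             match(tiny_tax$category_of[sim$labels],
                                   tiny_tax$categories))
  }, 0)
  expect_lt(abs(grid[which.min(nll)] - fit$T), 0.02)

  # optimisation guarantee: post-fit category NLL never exceeds pre-fit
  expect_lte(fit$fit_report$post_nll, fit$fit_report$pre_nll)
  # well-calibrated input keeps T near 1
  fit1 <- fit_temperature(sim$logits, sim$labels, tiny_tax)
  expect_true(fit1$T > 0.9 && fit1$T < 1.1)
})

test_that("expected calibration error falls after fitting a miscalibrated model", {
  sim <- calibrated_logits(4000, tiny_tax, seed = 8)
  distorted <- sim$logits / 2
  fit <- fit_temperature(distorted, sim$labels, tiny_tax)
  expect_lt(fit$fit_report$post_ece, fit$fit_report$pre_ece)
})

test_that("per-category temperatures are positive and can reorder across categories", {
  sim <- calibrated_logits(1500, tiny_tax, seed = 13)
  fit <- fit_temperature(sim$logits, sim$labels, tiny_tax,
                         per_category = TRUE)
  expect_length(fit$T, 11L)
  expect_true(all(fit$T > 0))
  expect_lte(fit$fit_report$post_nll, fit$fit_report$pre_nll + 1e-9)

  # single-category calibration split is degenerate
  one_cat <- tiny_tax$conditions[tiny_tax$category_of == tiny_tax$categories[1]]
  idx <- sim$labels %in% one_cat
  expect_error(
    fit_temperature(sim$logits[rep(which(idx)[1], 5), ],
                    rep(sim$labels[which(idx)[1]], 5), tiny_tax),
    "single category")
})

test_that("stratified splits allocate largest-remainder quotas deterministically", {
  prof <- uniform_profile(tiny_tax, 100, 1)
  cases <- generate_cases(tiny_tax, prof, d = 4, seed = 2)
  cases$info$one <- "all"
  sp <- make_split(cases, 0.2, strata_keys = "one", seed = 3)
  expect_length(sp$calibration_ids, 20L)
  expect_length(sp$evaluation_ids, 80L)
  expect_length(intersect(sp$calibration_ids, sp$evaluation_ids), 0L)
  expect_setequal(c(sp$calibration_ids, sp$evaluation_ids),
                  cases$info$case_id)

  # 50/50 strata yield a 10/10 calibration allocation
  cases$info$half <- rep(c("a", "b"), each = 50)
  sp2 <- make_split(cases, 0.2, strata_keys = "half", seed = 3)
  tab <- table(cases$info$half[cases$info$case_id %in% sp2$calibration_ids])
  expect_equal(as.integer(tab), c(10L, 10L))

  expect_identical(make_split(cases, 0.2, "half", seed = 5),
                   make_split(cases, 0.2, "half", seed = 5))
  # per-stratum share within one case of the target fraction
  sp3 <- make_split(cases, 0.2, strata_keys = "true_condition", seed = 9)
  sizes <- table(cases$info$true_condition)
  cal <- table(factor(
    cases$info$true_condition[cases$info$case_id %in% sp3$calibration_ids],
    levels = names(sizes)))
  expect_true(all(abs(as.integer(cal) - 0.2 * as.integer(sizes)) <= 1))
  expect_error(make_split(cases, 1.2), "\\(0, 1\\)")
})
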