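# Generator contracts: taxonomy structure, distributional convergence,
# determinism, and the rater-panel simulator.

test_that("round-robin category assignment balances category sizes", {
  tax <- generate_taxonomy(419, 11, 20, seed = 1)
  sizes <- table(tax$category_of)
  expect_setequal(as.integer(sizes), c(38L, 39L))
  expect_equal(sum(sizes), 419)
  # every condition has exactly one category; high-risk is a subset
  expect_equal(sort(names(tax$category_of)), sort(tax$conditions))
  expect_true(all(tax$high_risk %in% tax$conditions))
  expect_true(all(tax$subsample_rate > 0 & tax$subsample_rate <= 1))
  expect_setequal(sort(unique(tax$subsample_rate)), c(0.2, 0.5, 1))

  bij <- generate_taxonomy(11, 11, 2, seed = 1)
  expect_true(all(table(bij$category_of) == 1L))
})

test_that("taxonomy generation is deterministic and validates arguments", {
  expect_identical(generate_taxonomy(50, 5, 3, seed = 9),
                   generate_taxonomy(50, 5, 3, seed = 9))
  expect_error(generate_taxonomy(5, 11, 1), "exceed")
  expect_error(generate_taxonomy(-3, 2, 1), "positive")
  expect_error(domain_profile("DEV", c(0.5, 0.6), 10), "sum to 1")
  expect_error(domain_profile("DEV", c(0.5, 0.5), -1), "nonnegative")
})

test_that("category histogram converges to the profile prior", {
  K <- 11
  prior <- rep(1 / K, K)
  prof <- domain_profile("CLIN", prior, 10000, noise_scale = 1)
  cases <- generate_cases(tiny_tax, prof, d = 4, seed = 5)
  freq <- table(factor(cases$info$true_category, levels = tiny_tax$categories)) / 10000
  expect_true(all(abs(as.numeric(freq) - 1 / K) < 0.02))
  tv <- 0.5 * sum(abs(as.numeric(freq) - prior))
  expect_lt(tv, 3 * sqrt(K / 10000))
})

test_that("image counts cap below 5% above six and embeddings follow the noise model", {
  prof <- uniform_profile(tiny_tax, 2000, noise_scale = 1)
  cases <- generate_cases(tiny_tax, prof, d = 4, seed = 6)
  expect_lt(mean(cases$info$n_images > 6), 0.05)
  expect_true(all(cases$info$n_images >= 1 & cases$info$n_images <= 8))
  expect_true(all(vapply(cases$embeddings, nrow, 0L) == cases$info$n_images))

  # degenerate noise: all embeddings of one condition identical
  prof0 <- uniform_profile(tiny_tax, 100, noise_scale = 0)
  cases0 <- generate_cases(tiny_tax, prof0, d = 4, seed = 6)
  cond <- cases0$info$true_condition
  same <- which(cond == cond[1])
  embs <- do.call(rbind, cases0$embeddings[same])
  expect_equal(max(apply(embs, 2, stats::sd)), 0)

  # point-mass prior concentrates all conditions in one category
  point <- c(1, rep(0, 10))
  profp <- domain_profile("PAT", point, 200, 1)
  casesp <- generate_cases(tiny_tax, profp, d = 4, seed = 2)
  expect_true(all(casesp$info$true_category == tiny_tax$categories[1]))
})

test_that("case generation is byte-identical under a fixed seed", {
  prof <- uniform_profile(tiny_tax, 150, noise_scale = 1.5)
  a <- generate_cases(tiny_tax, prof, d = 6, seed = 11)
  b <- generate_cases(tiny_tax, prof, d = 6, seed = 11)
  expect_identical(a, b)
  c2 <- generate_cases(tiny_tax, prof, d = 6, seed = 12)
  expect_false(identical(a$embeddings, c2$embeddings))
})

test_that("metadata has 25 categorical fields and cases validate", {
  prof <- uniform_profile(tiny_tax, 50, 1)
  cases <- generate_cases(tiny_tax, prof, d = 4, seed = 1)
  expect_equal(ncol(cases$metadata), 25L)
  expect_true(all(unlist(cases$metadata) %in% c(paste0("L", 1:4), "unknown")))
  expect_true(all(cases$info$age >= 0))
  expect_error(generate_cases(tiny_tax, prof, d = 0, seed = 1), "positive")
})

test_that("rater panels respond to skill and ambiguity and reproduce exactly", {
  # oracle raters on an unambiguous case: all three top-1 equal the truth
  panel <- simulate_panel("C001", ambiguity = 0, tax = tiny_tax,
                          rater_skill = 1, seed = 3)
  expect_length(panel, 3L)
  tops <- vapply(panel, function(p) p$condition[1], "")
  expect_true(all(tops == "C001"))
  expect_true(all(unlist(lapply(panel, `[[`, "confidence")) >= 1))
  expect_true(all(unlist(lapply(panel, `[[`, "confidence")) <= 5))

  expect_identical(simulate_panel("C003", 1, tiny_tax, 0.8, seed = 5),
                   simulate_panel("C003", 1, tiny_tax, 0.8, seed = 5))
  expect_error(simulate_panel("C001", 1, tiny_tax, rater_skill = 0), "0, 1")
  expect_error(simulate_panel("nope", 1, tiny_tax, 0.5), "true condition")

  # skill monotonicity: top-1 agreement rises with skill, falls with noise
  agree_rate <- function(skill, amb, n = 300) {
    mean(vapply(seq_len(n), function(i) {
      p <- simulate_panel("C005", amb, tiny_tax, skill, seed = i)
      mean(vapply(p, function(r) r$condition[1] == "C005", TRUE))
    }, 0))
  }
  hi <- agree_rate(0.95, 0.5)
  lo <- agree_rate(0.25, 0.5)
  noisy <- agree_rate(0.95, 8)
  expect_gt(hi, lo)
  expect_gt(hi, noisy)
  # near-zero skill approaches the chance level (the true condition then
  # only surfaces through the occasional global random pick)
  floor_rate <- agree_rate(0.01, 0.5)
  expect_lt(floor_rate, 0.15)
})
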