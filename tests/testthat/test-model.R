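# Classifier core: pooling, FiLM, focal loss, metadata dropout, training
# regimes and score prediction.

test_that("image pooling averages and caps at six with seeded subsampling", {
  v <- c(1, 2, 3)
  expect_equal(pool_images(matrix(v, 1)), v)
  expect_equal(pool_images(rbind(v, -v)), c(0, 0, 0))
  eight <- matrix(rep(v, each = 8), 8)
  expect_equal(pool_images(eight, seed = 99), colMeans(eight))
  expect_error(pool_images(matrix(numeric(0), 0, 3)), "at least one")
  # over-cap selection is a 6-subset: mean of 8 distinct rows differs
  m <- matrix(seq_len(16), 8, 2)
  pooled <- pool_images(m, seed = 1)
  expect_identical(pooled, pool_images(m, seed = 1))
})

test_that("FiLM fusion is the affine modulation of the image embedding", {
  expect_equal(film_fuse(c(5, 7), alpha = c(1, 1), beta = c(0, 0)), c(5, 7))
  expect_equal(film_fuse(c(0, 0), alpha = c(2, 3), beta = c(4, 5)), c(4, 5))
  expect_equal(film_fuse(c(1, 2), alpha = c(2, 0.5), beta = c(-1, 1)), c(1, 2))
  expect_error(film_fuse(c(1, 2, 3), alpha = c(1, 1), beta = c(0, 0)),
               "dimension")
})

test_that("focal loss matches its closed form and reduces to cross entropy", {
  expect_equal(focal_loss(0.5, alpha = 1, gamma = 0), -log(0.5),
               tolerance = 1e-12)
  expect_equal(focal_loss(1, alpha = 1, gamma = 2), 0)
  expect_equal(focal_loss(0.9, alpha = 0.25, gamma = 2),
               0.25 * 0.01 * -log(0.9), tolerance = 1e-12)
  # monotone decreasing in p_t
  p <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(focal_loss(p, alpha = 0.5, gamma = 2)) < 0))
  expect_error(focal_loss(0), "positive")
})

test_that("metadata dropout replaces fields with unknown at the stated rate", {
  prof <- uniform_profile(tiny_tax, 400, 1)
  meta <- generate_cases(tiny_tax, prof, d = 4, seed = 1,
                         meta_missing = 0)$metadata
  expect_identical(apply_meta_dropout(meta, p = 0), meta)
  all_unknown <- apply_meta_dropout(meta, p = 1)
  expect_true(all(unlist(all_unknown) == "unknown"))
  # 400 cases x 25 fields = 10,000 Bernoulli(0.25) draws
  dropped <- apply_meta_dropout(meta, p = 0.25, seed = 4)
  frac <- mean(unlist(dropped) == "unknown")
  expect_lt(abs(frac - 0.25), 0.012)
  expect_error(apply_meta_dropout(meta, p = 1.5), "\\[0, 1\\]")
})

test_that("training drives a separable toy problem to zero error, matching a multinomial oracle", {
  tax3 <- generate_taxonomy(3, 3, 1, seed = 6)
  prof <- uniform_profile(tax3, 240, noise_scale = 0.1)
  cases <- generate_cases(tax3, prof, d = 8, seed = 5)
  labels <- cases$info$true_condition
  model <- train_classifier(cases, labels,
                            new_classifier(tax3, 8, d_meta = 4, seed = 1),
                            loss_config(train_steps = 300, learning_rate = 0.1,
                                        meta_dropout_p = 0, seed = 1))
  sc <- predict_scores(cases, model)
  acc <- mean(colnames(sc)[max.col(sc, ties.method = "first")] == labels)
  expect_equal(acc, 1)

  # independent oracle: multinomial logistic fit on the pooled embeddings
  X <- t(vapply(cases$embeddings, pool_images, numeric(8)))
  fit <- nnet::multinom(y ~ ., data = data.frame(y = factor(labels), X),
                        trace = FALSE, maxit = 500)
  oracle_acc <- mean(as.character(predict(fit)) == labels)
  expect_equal(oracle_acc, 1)
})

test_that("head-only training freezes the encoders bitwise and training is reproducible", {
  w <- small_world
  cfg <- loss_config(train_steps = 60, learning_rate = 0.05, seed = 11)
  tuned <- train_classifier(w$holdout, w$holdout_labels, w$model, cfg,
                            mode = "head_only")
  for (nm in c("M", "m0", "A", "a0", "B", "b0")) {
    expect_identical(tuned$par[[nm]], w$model$par[[nm]])
  }
  expect_false(identical(tuned$par$W, w$model$par$W))

  again <- train_classifier(w$holdout, w$holdout_labels, w$model, cfg,
                            mode = "head_only")
  expect_identical(tuned$par, again$par)
  expect_error(train_classifier(subset_cases(w$cases, integer(0)),
                                character(0), w$model, cfg), "empty")
})

test_that("predicted scores are softmax rows over the taxonomy", {
  w <- small_world
  sc <- predict_scores(w$holdout, w$model)
  expect_equal(dim(sc), c(n_cases(w$holdout), 44L))
  expect_true(all(abs(rowSums(sc) - 1) < 1e-9))
  expect_true(all(sc >= 0))

  # all-zero logits give the uniform row; shifting logits changes nothing
  zero <- w$model
  zero$par$W[] <- 0; zero$par$w0[] <- 0
  scz <- predict_scores(subset_cases(w$holdout, 1:5), zero)
  expect_equal(as.numeric(scz), rep(1 / 44, 5 * 44), tolerance = 1e-12)
  shifted <- w$model
  shifted$par$w0 <- shifted$par$w0 + 7.3
  scs <- predict_scores(subset_cases(w$holdout, 1:5), shifted)
  scb <- predict_scores(subset_cases(w$holdout, 1:5), w$model)
  expect_equal(as.numeric(scs), as.numeric(scb), tolerance = 1e-9)
})

test_that("metadata fusion does not hurt held-out top-3 accuracy (paired seeds)", {
  tax <- tiny_tax
  diffs <- vapply(1:5, function(s) {
    # strongly informative metadata in a high-noise image regime: the
    # fused model has signal the image-only model cannot reach
    prof <- uniform_profile(tax, 1500, noise_scale = 3.5)
    cases <- generate_cases(tax, prof, d = 8, seed = s,
                            meta_informativeness = 0.5)
    tr <- subset_cases(cases, 1:1200)
    te <- subset_cases(cases, 1201:1500)
    labels <- tr$info$true_condition
    cfg <- loss_config(train_steps = 200, learning_rate = 0.1, seed = s)
    fused <- train_classifier(tr, labels,
                              new_classifier(tax, 8, 8, TRUE, seed = s), cfg)
    imgonly <- train_classifier(tr, labels,
                                new_classifier(tax, 8, 8, FALSE, seed = s), cfg)
    ref <- te$info$true_condition
    mean(top3_flags(predict_scores(te, fused), ref)) -
      mean(top3_flags(predict_scores(te, imgonly), ref))
  }, 0)
  expect_gte(mean(diffs), 0)
  expect_gt(sum(diffs > 0), sum(diffs < 0))
})
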