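test_that("pair sampling is deterministic, label-correct and balanced", {
  d <- tiny_dataset(classes = 2, per_class = 2, side = 16)
  b1 <- sample_pairs(d, 8, seed = 5)
  b2 <- sample_pairs(d, 8, seed = 5)
  expect_identical(b1, b2)

  d2 <- tiny_dataset(classes = 3, per_class = 8, side = 16)
  b <- sample_pairs(d2, 1000, seed = 1)
  same_truth <- purrr::map2_lgl(b$image1, b$image2, function(x, y) {
    ix <- which(purrr::map_lgl(d2$image, identical, x))
    iy <- which(purrr::map_lgl(d2$image, identical, y))
    any(outer(as.character(d2$class[ix]), as.character(d2$class[iy]), "=="))
  })
  expect_true(all((b$label == 1) == same_truth))
  frac <- mean(b$label)
  expect_gte(frac, 0.45); expect_lte(frac, 0.55)

  single <- d[d$class == levels(d$class)[1], ]
  expect_error(sample_pairs(single, 4), "2 classes")
})

test_that("binary cross-entropy has its closed-form values and clipping", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  expect_equal(bce_loss(0.9, 0), -log(0.1), tolerance = 1e-12)
  expect_lt(bce_loss(1 - 1e-12, 1), 1e-10)
  expect_true(is.finite(bce_loss(0, 1)) && is.finite(bce_loss(1, 0)))
})

test_that("training decreases the loss, is finite and bitwise reproducible", {
  d <- tiny_dataset(classes = 2, per_class = 10, side = 32)
  arch <- tiny_arch()
  opt <- train_options(iterations = 60, batch_size = 16, seed = 4)
  fit <- train_snn(d, arch, opt)
  expect_true(all(is.finite(fit$trace$loss)))
  expect_lt(mean(utils::tail(fit$trace$loss, 20)), mean(utils::head(fit$trace$loss, 20)))

  fit2 <- train_snn(d, arch, opt)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$model$params, fit2$model$params)

  g <- glance(fit)
  expect_equal(g$iterations, 60L)
  expect_equal(tidy(fit), fit$trace)
})

test_that("training on shuffled labels yields chance-level pair discrimination", {
  d <- tiny_dataset(classes = 2, per_class = 24, side = 32, separation = 2)
  sp <- split_images(d, 0.7, seed = 2)
  shuffled <- sp$train
  # reassign labels balanced *within* each true class, so the random labels
  # carry exactly zero information about the texture
  set.seed(31)
  new_lab <- as.character(shuffled$class)
  for (cl in levels(shuffled$class)) {
    ix <- which(shuffled$class == cl)
    half <- sample(ix, length(ix) %/% 2)
    new_lab[half] <- levels(shuffled$class)[1]
    new_lab[setdiff(ix, half)] <- levels(shuffled$class)[2]
  }
  shuffled$class <- factor(new_lab)
  fit <- train_snn(shuffled, tiny_arch(),
                   train_options(iterations = 120, batch_size = 16, seed = 8))
  pb <- sample_pairs(sp$test, 300, seed = 17)
  s <- score_pairs(fit$model, pb$image1, pb$image2)
  auc <- auc_oracle(s, pb$label == 1)
  expect_gte(auc, 0.4); expect_lte(auc, 0.6)
})

test_that("augmentation keeps image size and training still runs", {
  d <- tiny_dataset(classes = 2, per_class = 6, side = 32)
  fit <- train_snn(d, tiny_arch(),
                   train_options(iterations = 5, batch_size = 8, seed = 3,
                                 augment = TRUE))
  expect_true(all(is.finite(fit$trace$loss)))
})
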