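test_that("leaky ReLU evaluates both branches and degenerates to ReLU", {
  expect_equal(leaky_relu(3, 0.5), 3)
  expect_equal(leaky_relu(-2, 0.01), -0.02)
  x <- c(-3, -0.5, 0, 0.5, 3)
  expect_equal(leaky_relu(x, 0), pmax(x, 0))
})

test_that("subtract block is an elementwise symmetric absolute difference", {
  f <- rnorm(10)
  expect_equal(subtract_block(f, f), rep(0, 10))
  expect_equal(subtract_block(c(1, -2), c(0, 1)), c(1, 3))
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(subtract_block(a, b), subtract_block(b, a))
  expect_error(subtract_block(1:3, 1:4), "equal length")
})

test_that("pair scores are symmetric, bounded and 0.5 at identity with zero bias", {
  arch <- tiny_arch()
  for (s in 1:100) {
    model <- snn_init(arch, seed = s)
    set.seed(s)
    x <- random_image(32); y <- random_image(32)
    sxy <- score_pair(model, x, y)
    syx <- score_pair(model, y, x)
    expect_equal(sxy, syx, tolerance = 1e-6)
    expect_true(sxy > 0 && sxy < 1)
  }
  model <- snn_init(arch, seed = 1)
  model$params[["head.b"]] <- 0
  x <- random_image(32)
  expect_equal(score_pair(model, x, x), 0.5)
  expect_error(score_pair(model, random_image(16), x), "input layer")
})

test_that("analytic gradients match central finite differences", {
  arch <- dissimspace:::new_architecture(
    98L,
    list(dissimspace:::conv_l(3, 4, stride = 2),
         dissimspace:::pool_l(2),
         dissimspace:::relu_l(),
         dissimspace:::conv_l(3, 4, groups = 2),
         dissimspace:::lrelu_l(0.1),
         dissimspace:::fc_l(5)),
    5L, input_size = 12, name = "gradcheck")
  model <- snn_init(arch, seed = 3)
  set.seed(42)
  n <- 3
  im1 <- lapply(1:n, function(i) random_image(12))
  im2 <- lapply(1:n, function(i) random_image(12))
  lab <- c(1, 0, 1)
  loss_fn <- function(params) {
    m <- model; m$params <- params
    X <- cbind(dissimspace:::stack_images(im1, 12), dissimspace:::stack_images(im2, 12))
    FF <- dissimspace:::snn_forward(m, X)$embed
    Y <- abs(FF[, 1:n] - FF[, n + 1:n])
    s <- dissimspace:::sigmoid(as.vector(crossprod(Y, m$params[["head.w"]])) +
                                 m$params[["head.b"]])
    mean(bce_loss(s, lab))
  }
  X <- cbind(dissimspace:::stack_images(im1, 12), dissimspace:::stack_images(im2, 12))
  fwd <- dissimspace:::snn_forward(model, X, training = TRUE)
  FF <- fwd$embed
  Y <- abs(FF[, 1:n] - FF[, n + 1:n])
  w <- model$params[["head.w"]]
  s <- dissimspace:::sigmoid(as.vector(crossprod(Y, w)) + model$params[["head.b"]])
  dlogit <- (s - lab) / n
  dY <- outer(w, dlogit)
  sgn <- sign(FF[, 1:n] - FF[, n + 1:n])
  grads <- c(list("head.w" = as.vector(Y %*% dlogit), "head.b" = sum(dlogit)),
             dissimspace:::snn_backward(model, fwd$caches, cbind(dY * sgn, -dY * sgn)))
  eps <- 1e-6
  for (nm in names(model$params)) {
    ix <- sample(length(model$params[[nm]]), min(5, length(model$params[[nm]])))
    for (j in ix) {
      pp <- model$params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- model$params; pm[[nm]][j] <- pm[[nm]][j] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(grads[[nm]][j], num, tolerance = 1e-5,
                   info = sprintf("gradient of %s[%d]", nm, j))
    }
  }
})

test_that("forward pass is deterministic at inference", {
  model <- snn_init(tiny_arch(), seed = 9)
  set.seed(1)
  imgs <- lapply(1:4, function(i) random_image(32))
  s1 <- score_pairs(model, imgs[1:2], imgs[3:4])
  s2 <- score_pairs(model, imgs[1:2], imgs[3:4])
  expect_identical(s1, s2)
})
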