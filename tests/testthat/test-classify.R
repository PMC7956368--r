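toy_design <- function(n_per = 10, gap = 4, seed = 1) {
  set.seed(seed)
  x1 <- cbind(rnorm(n_per), rnorm(n_per))
  x2 <- cbind(rnorm(n_per) + gap, rnorm(n_per) + gap)
  out <- tibble::tibble(
    id = as.character(1:(2 * n_per)),
    class = factor(rep(c("a", "b"), each = n_per)),
    f1 = c(x1[, 1], x2[, 1]), f2 = c(x1[, 2], x2[, 2])
  )
  class(out) <- c("dissim_design", class(out))
  out
}

test_that("one-vs-all SVM separates a separable toy and decides by argmax", {
  design <- toy_design()
  fit <- fit_ova_svm(design)
  scores <- predict(fit, design)
  expect_equal(accuracy(scores$.pred, design$class), 100)
  m <- dissimspace:::score_values(scores)
  expect_equal(as.character(scores$.pred),
               colnames(m)[max.col(m, ties.method = "first")])
  single <- design[design$class == "a", ]
  single$class <- droplevels(single$class)
  expect_error(fit_ova_svm(single), "2 classes")
})

test_that("z-normalization uses pooled population statistics", {
  m <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "a"))
  sm <- dissimspace:::new_score_matrix(m)
  z <- znorm(sm)
  expect_equal(unname(dissimspace:::score_values(z)[, 1]), c(-1, 1)) # population sd

  set.seed(3)
  big <- dissimspace:::new_score_matrix(
    matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c"))))
  zb <- dissimspace:::score_values(znorm(big))
  expect_equal(mean(zb), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((zb - mean(zb))^2)), 1, tolerance = 1e-9)

  const <- dissimspace:::new_score_matrix(
    matrix(2, 4, 2, dimnames = list(NULL, c("a", "b"))))
  expect_warning(zc <- znorm(const), "zero spread")
  expect_true(all(dissimspace:::score_values(zc) == 0))
})

test_that("sum rule is order-invariant and keeps single-member decisions", {
  set.seed(5)
  mk <- function() dissimspace:::new_score_matrix(
    matrix(rnorm(24), 8, 3, dimnames = list(NULL, c("a", "b", "c"))))
  m1 <- mk(); m2 <- mk(); m3 <- mk()
  expect_equal(sum_rule(list(m1))$.pred, m1$.pred)
  f123 <- sum_rule(list(m1, m2, m3))
  f312 <- sum_rule(list(m3, m1, m2))
  expect_equal(dissimspace:::score_values(f123),
               dissimspace:::score_values(f312))
  neg <- dissimspace:::new_score_matrix(-dissimspace:::score_values(m1))
  expect_true(all(dissimspace:::score_values(sum_rule(list(m1, neg))) == 0))
  bad <- dissimspace:::new_score_matrix(
    matrix(0, 7, 3, dimnames = list(NULL, c("a", "b", "c"))))
  expect_error(sum_rule(list(m1, bad)), "share shape")
})

test_that("weighted sum matches the hand-computed normalized fusion", {
  siam <- matrix(c(0.9, 0.1, 0.2, 0.8,
                   0.7, 0.3, 0.4, 0.6), 4, 2,
                 dimnames = list(NULL, c("a", "b")))
  cnn <- matrix(c(5, -1, 0, 3,
                  -2, 4, 1, -3), 4, 2,
                dimnames = list(NULL, c("a", "b")))
  hand_z <- function(m) (m - mean(m)) / sqrt(mean((m - mean(m))^2))
  expected <- 4 * hand_z(cnn) + 1 * hand_z(siam)
  fused <- weighted_sum(
    list(dissimspace:::new_score_matrix(cnn), dissimspace:::new_score_matrix(siam)),
    weights = c(4, 1))
  expect_equal(dissimspace:::score_values(fused), expected, tolerance = 1e-12)

  # unit weights equal the sum rule over z-normalized members
  unit <- weighted_sum(
    list(dissimspace:::new_score_matrix(cnn), dissimspace:::new_score_matrix(siam)),
    weights = c(1, 1))
  via_sum <- sum_rule(list(znorm(dissimspace:::new_score_matrix(cnn)),
                           znorm(dissimspace:::new_score_matrix(siam))))
  expect_equal(dissimspace:::score_values(unit),
               dissimspace:::score_values(via_sum), tolerance = 1e-12)

  # rescaling all weights never changes decisions
  scaled <- weighted_sum(
    list(dissimspace:::new_score_matrix(cnn), dissimspace:::new_score_matrix(siam)),
    weights = c(8, 2))
  expect_equal(scaled$.pred, fused$.pred)
  expect_error(weighted_sum(list(dissimspace:::new_score_matrix(cnn)), c(-1)),
               "positive")
})

test_that("ensemble size is the topology-by-kc product", {
  expect_equal(ensemble_size(1:6, c(15, 30, 45, 60)), 24)
  expect_equal(ensemble_size(1:8, c(15, 30, 45, 60)), 32)
  expect_equal(ensemble_size(3, 15), 1)
  expect_error(ensemble_size(integer(0), 1:4), "nonempty")
})

test_that("score matrices roundtrip through CSV with provenance", {
  set.seed(9)
  sm <- dissimspace:::new_score_matrix(
    matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c"))),
    source_id = "external_cnn")
  path <- file.path(tempdir(), "scores.csv")
  write_scores(sm, path)
  back <- read_scores(path)
  expect_equal(attr(back, "source_id"), "external_cnn")
  expect_equal(dissimspace:::score_values(back), dissimspace:::score_values(sm),
               tolerance = 1e-10)
  expect_equal(back$.pred, sm$.pred)
})
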