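test_that("low-level feature stack has depth 6 and null derivatives where expected", {
  img <- matrix(0.4, 10, 12)
  st <- low_level_features(img)
  expect_equal(dim(st), c(10, 12, 6))
  expect_equal(st[, , 1], img)
  for (m in 2:6) expect_equal(max(abs(st[, , m])), 0)

  # horizontal ramp: intensity varies along columns only, so the vertical
  # derivative map is zero everywhere (replicated borders included)
  ramp <- matrix(rep(seq(0, 1, length.out = 12), each = 10), 10, 12)
  st2 <- low_level_features(ramp)
  expect_equal(max(abs(st2[, , 3])), 0)

  bad <- img; bad[2, 2] <- NA
  expect_error(low_level_features(bad), "non-finite")
  expect_error(low_level_features(matrix(1, 2, 2)), "at least 3 x 3")
})

test_that("joint histogram normalizes and matches its marginals", {
  jh <- joint_histogram(rep(1, 9), rep(1, 9), bins = 4)
  expect_equal(sum(jh$probabilities == 1), 1)
  expect_equal(sum(jh$probabilities), 1)

  jh2 <- joint_histogram(c(0, 1), c(0, 1), bins = 2)
  expect_equal(diag(jh2$probabilities), c(0.5, 0.5))
  expect_equal(sum(jh2$probabilities) - sum(diag(jh2$probabilities)), 0)

  set.seed(1)
  a <- rnorm(500); b <- runif(500)
  jh3 <- joint_histogram(a, b, bins = 7)
  expect_equal(sum(jh3$probabilities), 1, tolerance = 1e-12)
  expect_equal(rowSums(jh3$probabilities),
               tabulate(dissimspace:::bin_index(a, 7), 7) / 500)
  expect_equal(colSums(jh3$probabilities),
               tabulate(dissimspace:::bin_index(b, 7), 7) / 500)

  expect_error(joint_histogram(1:3, 1:4, 2), "equal length")
  expect_error(joint_histogram(1:3, 1:3, 0), "bins")
})

test_that("binned entropy has its closed-form values", {
  expect_equal(entropy(rep(2.5, 40), bins = 16), 0)
  # values filling 8 bins uniformly -> log(8)
  a <- rep(seq_len(8), each = 10)
  expect_equal(entropy(a, bins = 8), log(8), tolerance = 1e-12)
  expect_error(entropy(numeric(0)), "nonempty")
})

test_that("plug-in MI is nonnegative, symmetric, matches the brute-force oracle", {
  set.seed(7)
  for (rep_i in 1:10) {
    a <- rnorm(200); b <- a * (rep_i %% 3) + rnorm(200)
    mi_ab <- mutual_information(a, b, bins = 6)
    expect_gte(mi_ab, 0)
    expect_equal(mi_ab, mutual_information(b, a, bins = 6), tolerance = 1e-12)
    expect_equal(mi_ab, mi_oracle(a, b, 6), tolerance = 1e-9)
  }
  # MI(a, a) = entropy(a)
  a <- rnorm(300)
  expect_equal(mutual_information(a, a, bins = 28), entropy(a, bins = 28),
               tolerance = 1e-9)
  # constant marginal -> zero MI
  expect_equal(mutual_information(rep(1, 50), rnorm(50), bins = 8), 0)
})

test_that("independent samples give near-zero MI", {
  set.seed(11)
  a <- runif(1e5); b <- runif(1e5)
  expect_lt(mutual_information(a, b, bins = 8), 0.02)
})

test_that("EMI matrix: symmetric, entropies on the diagonal, zero for constants", {
  st <- low_level_features(matrix(0.7, 8, 8))
  expect_equal(unclass(emi_matrix(st))[1:6, 1:6], matrix(0, 6, 6), ignore_attr = TRUE)

  set.seed(3)
  img <- random_image(12)
  st2 <- low_level_features(img)
  em <- emi_matrix(st2, bins = 10)
  expect_equal(unclass(em), t(unclass(em)), ignore_attr = TRUE)
  for (i in 1:6) {
    expect_equal(em[i, i], entropy(as.vector(st2[, , i]), bins = 10), tolerance = 1e-12)
  }
  # duplicated map: MI equals the entropy
  st3 <- st2; st3[, , 2] <- st3[, , 1]
  em3 <- emi_matrix(st3, bins = 10)
  expect_equal(em3[1, 2], entropy(as.vector(st3[, , 1]), bins = 10), tolerance = 1e-9)
})

test_that("COV matrix is a symmetric PSD sample covariance", {
  st <- low_level_features(matrix(1, 5, 5))
  expect_equal(max(abs(cov_matrix(st))), 0)

  # two-pixel hand case: cov with denominator n - 1
  two <- array(c(0, 2, 0, 4), dim = c(1, 2, 2))
  cv <- cov_matrix(two)
  expect_equal(cv[1, 2], 4)
  expect_equal(cv[1, 1], 2)

  set.seed(5)
  cv2 <- cov_matrix(low_level_features(random_image(15)))
  expect_equal(unclass(cv2), t(unclass(cv2)), ignore_attr = TRUE)
  expect_gte(min(eigen(cv2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("HASC descriptor is the 72-long EMI||COV concatenation", {
  expect_length(hasc_descriptor(random_image(10)), 72)
  expect_equal(hasc_descriptor(matrix(0.3, 9, 9)), rep(0, 72))
  set.seed(13)
  for (i in 1:50) {
    img <- random_image(sample(8:16, 1))
    st <- low_level_features(img)
    oracle <- c(as.vector(emi_matrix(st, 28)), as.vector(cov_matrix(st)))
    expect_equal(hasc_descriptor(img, 28), oracle)
  }
})

test_that("HASC image tiles the maps into a 3 x 2 mosaic and resizes", {
  img <- random_image(20)
  out <- hasc_image(img, out_size = 30)
  expect_equal(dim(out), c(30, 30))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(dim(hasc_image(img)), c(224, 224))
  # constant image: the five derivative tiles are uniformly zero and the
  # intensity tile rescales to one
  flat <- hasc_image(matrix(0.5, 12, 12), 36)
  expect_equal(flat[4, 4], 1)   # inside the intensity tile
  expect_equal(flat[4, 30], 0)  # inside the |dx| tile
  expect_equal(max(abs(flat[20:35, ])), 0) # rows of tiles 3-6
  expect_error(hasc_image(img, out_size = 0), "out_size")

  # without resizing, the mosaic is 3h x 2w with map 1 in the top-left tile
  st <- low_level_features(img)
  mosaic <- rbind(cbind(st[, , 1], st[, , 2]),
                  cbind(st[, , 3], st[, , 4]),
                  cbind(st[, , 5], st[, , 6]))
  expect_equal(dim(mosaic), c(3 * 20, 2 * 20))
  rescaled <- (mosaic - min(mosaic)) / diff(range(mosaic))
  expect_equal(hasc_image(img, out_size = 60)[1, 1],
               resize_image(rescaled, 60)[1, 1])
})

test_that("dataset-level HASC verbs preserve labels and shapes", {
  d <- tiny_dataset(classes = 2, per_class = 3, side = 16)
  feats <- hasc_features(d, bins = 10)
  expect_equal(dim(feats), c(6, 2 + 72))
  expect_equal(feats$class, d$class)

  hi <- hasc_images(d, out_size = 20)
  expect_equal(hi$class, d$class)
  expect_equal(dim(hi$image[[1]]), c(20, 20))
})
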