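test_that("clustering vectorization flattens the resized image", {
  img <- matrix(0.25, 32, 32)
  v <- vectorize_for_clustering(img, side = 32)
  expect_length(v, 1024)
  expect_true(all(v == 0.25))
  expect_identical(vectorize_for_clustering(img), vectorize_for_clustering(img))
  expect_length(vectorize_for_clustering(random_image(50), side = 16), 256)
})

test_that("k-means handles the degenerate ends and recovers separated blobs", {
  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2)
  km_all <- cluster_kmeans(pts, k = 10, seed = 1)
  expect_equal(km_all$objective, 0, tolerance = 1e-12)

  km1 <- cluster_kmeans(pts, k = 1, seed = 1)
  expect_equal(as.vector(km1$centroids), colMeans(pts), tolerance = 1e-12)

  set.seed(8)
  blobs <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
                 matrix(rnorm(100, 10, 0.1), 50, 2))
  km2 <- cluster_kmeans(blobs, k = 2, seed = 3)
  cents <- km2$centroids[order(km2$centroids[, 1]), ]
  expect_lt(max(abs(cents[1, ] - c(0, 0))), 0.1)
  expect_lt(max(abs(cents[2, ] - c(10, 10))), 0.1)

  expect_error(cluster_kmeans(matrix(1, 4, 2), k = 2), "distinct")
})

test_that("k-means objective trace is monotone non-increasing", {
  set.seed(4)
  for (rep_i in 1:5) {
    pts <- matrix(rnorm(200 * 3), 200, 3)
    km <- cluster_kmeans(pts, k = 5, seed = rep_i)
    expect_true(all(diff(km$objective_trace) <= 1e-8))
    # every point assigned to its nearest centroid at convergence
    D <- as.matrix(dist(rbind(pts, km$centroids)))[1:200, 200 + 1:5]
    expect_equal(km$assignment, unname(max.col(-D, ties.method = "first")))
  }
})

test_that("k-means objective is comparable to the reference implementation", {
  set.seed(10)
  pts <- matrix(rnorm(300 * 4), 300, 4)
  ours <- cluster_kmeans(pts, k = 4, seed = 6)$objective
  ref <- stats::kmeans(pts, centers = 4, nstart = 10, iter.max = 100)$tot.withinss
  expect_lt(abs(ours - ref) / ref, 0.1)
})

test_that("supervised prototype selection yields kc centroids per class", {
  d <- tiny_dataset(classes = 4, per_class = 16, side = 16)
  protos <- select_prototypes(d, kc = 15, side = 8, seed = 2)
  expect_equal(nrow(protos), 60) # kc * c
  expect_equal(unname(table(protos$class)), rep(15L, 4), ignore_attr = TRUE)

  d2 <- tiny_dataset(classes = 2, per_class = 5, side = 16)
  p1 <- select_prototypes(d2, kc = 1, side = 8, seed = 1)
  expect_equal(nrow(p1), 2)
  for (cl in levels(d2$class)) {
    pts <- do.call(rbind, lapply(d2$image[d2$class == cl],
                                 vectorize_for_clustering, side = 8))
    expect_equal(p1$centroid[[which(p1$class == cl)]], colMeans(pts),
                 tolerance = 1e-12)
  }

  p_again <- select_prototypes(d, kc = 15, side = 8, seed = 2)
  expect_identical(protos$centroid, p_again$centroid)

  expect_error(select_prototypes(d2, kc = 9), "class_01")
})

test_that("prototype sets roundtrip through CSV", {
  d <- tiny_dataset(classes = 2, per_class = 6, side = 16)
  protos <- select_prototypes(d, kc = 2, side = 8, seed = 5)
  path <- file.path(tempdir(), "protos.csv")
  write_prototypes(protos, path)
  back <- read_prototypes(path)
  expect_equal(attr(back, "kc"), 2L)
  expect_equal(attr(back, "side"), 8L)
  expect_equal(do.call(rbind, back$centroid), do.call(rbind, protos$centroid),
               tolerance = 1e-10)
})
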