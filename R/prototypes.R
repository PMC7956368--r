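#' Vector-space representation of an image for clustering
#'
#' Flattens the image resized to `side` x `side` into a vector in `[0, 1]`,
#' the representation in which the per-class k-means prototypes are computed.
#'
#' @param image Numeric image matrix.
#' @param side Downsampling side (default 32).
#' @return Numeric vector of length `side^2`.
#' @export
vectorize_for_clustering <- function(image, side = 32) {
  check_image(image)
  as.vector(resize_image(image, side))
}

#' Lloyd k-means with weighted-probability seeding
#'
#' Standard k-means: initial centroids are drawn from the data points with a
#' k-means++-style weighted probability distribution (each next centroid is
#' sampled with probability proportional to its squared distance from the
#' nearest centroid chosen so far), then assignment and mean-update steps
#' alternate until the assignments are stable or `max_iter` is reached. The
#' within-cluster sum of squared Euclidean distances is checked to be
#' non-increasing at every iteration. Empty clusters are repaired by
#' re-seeding from the point farthest from its centroid.
#'
#' @param points Numeric matrix, one point per row.
#' @param k Number of clusters (1 <= k <= number of distinct points).
#' @param seed Integer seed.
#' @param max_iter Iteration cap (default 300).
#' @return List with `centroids` (k x d matrix), `assignment` (integer
#'   vector), `objective` (final within-cluster SS) and `objective_trace`.
#' @export
cluster_kmeans <- function(points, k, seed = 1, max_iter = 300) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1) abort("`k` must be >= 1.")
  n_distinct <- nrow(unique(points))
  if (k > n_distinct) {
    abort(sprintf("`k` (%d) exceeds the number of distinct points (%d).", k, n_distinct))
  }
  sq_dist_to <- function(centroids) {
    # n x k matrix of squared Euclidean distances
    cp <- tcrossprod(points, centroids)
    outer(rowSums(points^2), rowSums(centroids^2), "+") - 2 * cp
  }
  with_seed(derive_seed(seed, "kmeans"), {
    centers <- matrix(NA_real_, k, ncol(points))
    centers[1, ] <- points[sample.int(n, 1), ]
    if (k > 1) {
      for (j in 2:k) {
        d2 <- apply(sq_dist_to(centers[seq_len(j - 1), , drop = FALSE]), 1, min)
        d2 <- pmax(d2, 0)
        probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- points[sample.int(n, 1, prob = probs), ]
      }
    }
    trace <- numeric(0)
    assign_old <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      D <- sq_dist_to(centers)
      assign_new <- max.col(-D, ties.method = "first")
      for (j in which(tabulate(assign_new, nbins = k) == 0L)) {
        far <- which.max(D[cbind(seq_len(n), assign_new)])
        centers[j, ] <- points[far, ]
        assign_new[far] <- j
        D <- sq_dist_to(centers)
      }
      obj <- sum(pmax(D[cbind(seq_len(n), assign_new)], 0))
      if (length(trace) > 0 && obj > utils::tail(trace, 1) + 1e-8) {
        abort("k-means objective increased; this should not happen.")
      }
      trace <- c(trace, obj)
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      for (j in seq_len(k)) {
        centers[j, ] <- colMeans(points[assign_new == j, , drop = FALSE])
      }
    }
    list(centroids = centers, assignment = assign_old,
         objective = utils::tail(trace, 1), objective_trace = trace)
  })
}

#' Supervised k-means prototype selection
#'
#' Runs k-means independently inside each class on the downsampled-pixel
#' representation of the images, keeping `kc` centroids per class, so the
#' resulting prototype set has `k = kc * c` members for `c` classes. The
#' prototypes define the dissimilarity space: every image is later
#' represented by its learned distances to them.
#'
#' @param data Dataset tibble; every class needs at least `kc` samples.
#' @param kc Prototypes per class (the published grid uses 15, 30, 45, 60;
#'   any positive value is accepted).
#' @param side Clustering representation side (see
#'   [vectorize_for_clustering()]).
#' @param seed Integer seed.
#' @return A `prototype_set`: tibble with `class`, `prototype_id` and the
#'   list-column `centroid`; attributes `kc`, `side`, `seed`.
#' @export
select_prototypes <- function(data, kc, side = 32, seed = 1) {
  check_dataset(data)
  if (kc < 1) abort("`kc` must be >= 1.")
  classes <- levels(factor(data$class))
  rows <- purrr::map(seq_along(classes), function(ci) {
    cl <- classes[ci]
    ix <- which(data$class == cl)
    if (length(ix) < kc) {
      abort(sprintf("Class '%s' has %d samples, fewer than kc = %d.",
                    cl, length(ix), kc))
    }
    pts <- do.call(rbind, lapply(data$image[ix], vectorize_for_clustering, side = side))
    km <- cluster_kmeans(pts, kc, seed = derive_seed(seed, paste0("class", ci)))
    tibble(
      class = cl,
      prototype_id = sprintf("%s_p%02d", cl, seq_len(kc)),
      centroid = lapply(seq_len(kc), function(j) km$centroids[j, ])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$class <- factor(out$class, levels = classes)
  structure(out, class = c("prototype_set", class(tibble())),
            kc = as.integer(kc), side = as.integer(side), seed = as.integer(seed))
}

# Render prototype centroids back to images at a given side.
prototype_images <- function(prototypes, out_side) {
  side <- attr(prototypes, "side")
  lapply(prototypes$centroid, function(v) {
    resize_image(matrix(v, side, side), out_side)
  })
}

#' Write / read a prototype set as CSV
#'
#' One centroid per row: `class`, `prototype_id`, then pixel columns; the
#' representation side, `kc` and seed are stored in a JSON sidecar.
#'
#' @param prototypes A `prototype_set`.
#' @param path CSV path (`.json` sidecar written next to it).
#' @return `path`, invisibly (writer); a `prototype_set` (reader).
#' @export
write_prototypes <- function(prototypes, path) {
  mat <- do.call(rbind, prototypes$centroid)
  colnames(mat) <- paste0("px", seq_len(ncol(mat)))
  df <- dplyr::bind_cols(prototypes[c("class", "prototype_id")], as_tibble(mat))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(kc = attr(prototypes, "kc"), side = attr(prototypes, "side"),
               seed = attr(prototypes, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prototypes
#' @export
read_prototypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- as.matrix(df[, grep("^px", names(df)), drop = FALSE])
  out <- tibble(
    class = factor(df$class), prototype_id = df$prototype_id,
    centroid = lapply(seq_len(nrow(px)), function(i) unname(px[i, ]))
  )
  structure(out, class = c("prototype_set", class(tibble())),
            kc = as.integer(meta$kc), side = as.integer(meta$side),
            seed = as.integer(meta$seed))
}
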