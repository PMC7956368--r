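#' Low-level feature maps for HASC
#'
#' Computes the stack of d = 6 low-level feature maps from which the HASC
#' relational matrices are built: raw intensity, absolute first derivatives
#' |dI/dx| and |dI/dy|, absolute second derivatives |d2I/dx2| and |d2I/dy2|,
#' and the gradient magnitude. Derivatives use central differences with
#' replicated borders, so a constant image yields identically zero derivative
#' maps. Here x indexes columns and y indexes rows.
#'
#' @param image Numeric matrix with finite entries, min dimension >= 3.
#' @return A h x w x 6 array (`feature_stack` class) of feature maps.
#' @export
low_level_features <- function(image) {
  check_image(image)
  h <- nrow(image); w <- ncol(image)
  if (min(h, w) < 3) abort("Image must be at least 3 x 3.")
  dx <- (image[, c(2:w, w)] - image[, c(1, 1:(w - 1))]) / 2
  dy <- (image[c(2:h, h), ] - image[c(1, 1:(h - 1)), ]) / 2
  dxx <- image[, c(2:w, w)] - 2 * image + image[, c(1, 1:(w - 1))]
  dyy <- image[c(2:h, h), ] - 2 * image + image[c(1, 1:(h - 1)), ]
  stack <- array(0, dim = c(h, w, 6))
  stack[, , 1] <- image
  stack[, , 2] <- abs(dx)
  stack[, , 3] <- abs(dy)
  stack[, , 4] <- abs(dxx)
  stack[, , 5] <- abs(dyy)
  stack[, , 6] <- sqrt(dx^2 + dy^2)
  structure(stack, class = c("feature_stack", "array"))
}

# Map values to equal-width bins over [min, max]; a degenerate vector
# (min == max) falls entirely in the first bin.
bin_index <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep(1L, length(x)))
  ix <- floor((x - lo) / (hi - lo) * bins) + 1L
  pmin(ix, bins)
}

#' Joint 2D normalized histogram
#'
#' Bins two equal-length vectors on equal-width grids over their own ranges
#' and returns the joint probability table. Marginals (row/column sums) equal
#' the 1D histograms of the inputs.
#'
#' @param a,b Numeric vectors of equal length.
#' @param bins Number of bins per axis (>= 1).
#' @return A list of class `joint_histogram` with `probabilities` (bins x bins,
#'   summing to 1), `bin_edges_a` and `bin_edges_b`.
#' @export
joint_histogram <- function(a, b, bins = 28) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 1) abort("Inputs must be nonempty.")
  if (bins < 1) abort("`bins` must be >= 1.")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("Inputs must be finite.")
  bins <- as.integer(bins)
  ia <- bin_index(a, bins)
  ib <- bin_index(b, bins)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(ia, levels = seq_len(bins)), factor(ib, levels = seq_len(bins)))
  counts[] <- as.numeric(tab)
  structure(list(
    probabilities = counts / length(a),
    bin_edges_a = seq(min(a), max(a), length.out = bins + 1L),
    bin_edges_b = seq(min(b), max(b), length.out = bins + 1L)
  ), class = "joint_histogram")
}

#' Plug-in entropy of a binned vector (nats)
#'
#' Entropy of the equal-width-binned marginal distribution of `a`, with the
#' convention 0 log 0 = 0. Equals [mutual_information()] of `a` with itself.
#'
#' @inheritParams joint_histogram
#' @return Nonnegative entropy in nats.
#' @export
entropy <- function(a, bins = 28) {
  if (length(a) < 1) abort("Input must be nonempty.")
  if (!all(is.finite(a))) abort("Input must be finite.")
  p <- tabulate(bin_index(a, as.integer(bins)), nbins = as.integer(bins)) / length(a)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Plug-in mutual information of two binned vectors (nats)
#'
#' Estimates MI from the joint 2D normalized histogram:
#' `sum_ij p_ij log(p_ij / (p_i q_j))`, with 0 log 0 = 0. Nonnegative and
#' symmetric in its arguments; reduces to the entropy when `a == b`.
#'
#' @inheritParams joint_histogram
#' @return Nonnegative MI estimate in nats.
#' @export
mutual_information <- function(a, b, bins = 28) {
  jh <- joint_histogram(a, b, bins)
  p <- jh$probabilities
  pa <- rowSums(p)
  pb <- colSums(p)
  pos <- p > 0
  denom <- outer(pa, pb)
  mi <- sum(p[pos] * log(p[pos] / denom[pos]))
  max(mi, 0)
}

#' Entropy/mutual-information (EMI) relational matrix
#'
#' d x d symmetric matrix over the feature maps of a stack: the main diagonal
#' holds the per-map entropies (the unpredictability of each feature) and the
#' off-diagonal entries the pairwise mutual information, both estimated by
#' joint 2D histograms with `bins` bins per axis.
#'
#' @param stack A `feature_stack` (h x w x d array) from [low_level_features()].
#' @param bins Histogram bins per axis.
#' @return d x d matrix of class `relational_matrix` with attribute
#'   `kind = "EMI"`.
#' @export
emi_matrix <- function(stack, bins = 28) {
  d <- dim(stack)[3] %||% 0
  if (is.na(d) || d < 1) abort("Stack must have at least one feature map.")
  maps <- lapply(seq_len(d), function(i) as.vector(stack[, , i]))
  m <- matrix(0, d, d)
  for (i in seq_len(d)) {
    m[i, i] <- entropy(maps[[i]], bins)
    if (i < d) {
      for (j in seq((i + 1), d)) {
        m[i, j] <- m[j, i] <- mutual_information(maps[[i]], maps[[j]], bins)
      }
    }
  }
  structure(m, class = c("relational_matrix", "matrix"), kind = "EMI")
}

#' Covariance (COV) relational matrix
#'
#' Sample covariance (denominator n - 1) of the d feature maps over pixels;
#' symmetric and positive semidefinite.
#'
#' @inheritParams emi_matrix
#' @return d x d matrix of class `relational_matrix`, attribute `kind = "COV"`.
#' @export
cov_matrix <- function(stack) {
  d <- dim(stack)[3] %||% 0
  if (is.na(d) || d < 1) abort("Stack must have at least one feature map.")
  n <- prod(dim(stack)[1:2])
  if (n < 2) abort("Need at least 2 pixels for a sample covariance.")
  x <- matrix(stack, nrow = n, ncol = d)
  m <- stats::cov(x)
  m <- (m + t(m)) / 2
  structure(m, class = c("relational_matrix", "matrix"), kind = "COV")
}

#' HASC descriptor of an image
#'
#' Concatenates the vectorized EMI and COV matrices of the image's 6 low-level
#' feature maps into a single descriptor of length 2 d^2 = 72.
#'
#' @param image Numeric image matrix.
#' @param bins Histogram bins for the EMI estimates.
#' @return Numeric vector of length 72 (EMI entries first, then COV).
#' @export
hasc_descriptor <- function(image, bins = 28) {
  stack <- low_level_features(image)
  c(as.vector(emi_matrix(stack, bins)), as.vector(cov_matrix(stack)))
}

#' HASC image: tiled feature-map mosaic
#'
#' Tiles the 6 low-level feature maps as a 3-row x 2-column mosaic (maps 1-2
#' on the first row of tiles, 3-4 on the second, 5-6 on the third), rescales
#' the mosaic linearly to `[0, 1]` and resizes it to `out_size` x `out_size`.
#' This is the alternative input representation fed to the Siamese networks.
#'
#' @param image Numeric image matrix.
#' @param out_size Output side in pixels (default 224, the network input size).
#' @return `out_size` x `out_size` matrix in `[0, 1]`.
#' @export
hasc_image <- function(image, out_size = 224) {
  if (out_size < 1) abort("`out_size` must be >= 1.")
  stack <- low_level_features(image)
  h <- dim(stack)[1]; w <- dim(stack)[2]
  mosaic <- rbind(
    cbind(stack[, , 1], stack[, , 2]),
    cbind(stack[, , 3], stack[, , 4]),
    cbind(stack[, , 5], stack[, , 6])
  )
  rng <- range(mosaic)
  if (rng[2] > rng[1]) {
    mosaic <- (mosaic - rng[1]) / (rng[2] - rng[1])
  } else {
    mosaic <- mosaic * 0
  }
  resize_image(mosaic, out_size)
}

#' HASC descriptors for every image of a dataset
#'
#' @param data Dataset tibble (`id`, `class`, `image`).
#' @param bins Histogram bins for the EMI estimates.
#' @return Tibble with `id`, `class` and 72 descriptor columns
#'   `emi_1_1 ... cov_6_6`.
#' @export
hasc_features <- function(data, bins = 28) {
  check_dataset(data)
  d <- 6
  nm <- c(
    paste0("emi_", rep(seq_len(d), d), "_", rep(seq_len(d), each = d)),
    paste0("cov_", rep(seq_len(d), d), "_", rep(seq_len(d), each = d))
  )
  desc <- purrr::map(data$image, hasc_descriptor, bins = bins)
  mat <- do.call(rbind, desc)
  colnames(mat) <- nm
  dplyr::bind_cols(data[c("id", "class")], as_tibble(mat))
}

#' Replace dataset images by their HASC images
#'
#' @param data Dataset tibble.
#' @param out_size Side of the tiled HASC image.
#' @return Dataset tibble with the `image` column replaced (labels preserved).
#' @export
hasc_images <- function(data, out_size = 224) {
  check_dataset(data)
  data$image <- purrr::map(data$image, hasc_image, out_size = out_size)
  data
}
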