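#' Generate a labeled multi-class image dataset with controllable separability
#'
#' Draws `per_class` images for each of `classes` classes. Each class is
#' defined by a band-limited texture: a class-specific spatial frequency and
#' orientation sinusoid plus a half-frequency harmonic, mimicking the
#' harmonic/band structure of audio spectrograms. Within a class, images share
#' the texture but differ in a random phase and in i.i.d. Gaussian pixel noise.
#' `separation` scales the texture amplitude relative to the noise: at
#' `separation = 0` all class-conditional image distributions are identical,
#' so no classifier can beat chance; large values give well-separated classes.
#'
#' Pixels are clipped to `[0, 1]`. The dataset is bitwise reproducible for a
#' given `seed`.
#'
#' @param classes Number of classes (>= 2).
#' @param per_class Images per class (>= 1).
#' @param side Image side in pixels (square images, >= 16).
#' @param separation Between-class texture contrast (>= 0). The sinusoid
#'   amplitude is `separation / 4`, so `separation = 2` spans half the
#'   intensity range before noise.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param seed Integer seed; every random draw is derived from it.
#' @return A tibble with columns `id` (character), `class` (factor) and
#'   `image` (list of `side` x `side` matrices in `[0, 1]`).
#' @examples
#' d <- synth_images(classes = 2, per_class = 3, side = 32, seed = 1)
#' dplyr::count(d, class)
#' @export
synth_images <- function(classes = 3, per_class = 40, side = 64,
                         separation = 2, noise_sd = 0.3, seed = 1) {
  if (classes < 2) abort("`classes` must be >= 2.")
  if (per_class < 1) abort("`per_class` must be >= 1.")
  if (side < 16) abort("`side` must be >= 16 pixels.")
  if (separation < 0 || noise_sd < 0) {
    abort("`separation` and `noise_sd` must be nonnegative.")
  }
  grid <- seq(0, 1, length.out = side)
  xx <- matrix(grid, side, side, byrow = TRUE)
  yy <- matrix(grid, side, side)
  with_seed(derive_seed(seed, "synth"), {
    rows <- purrr::map(seq_len(classes), function(cl) {
      freq <- 2 + 1.5 * (cl - 1)
      theta <- pi * (cl - 1) / classes
      u <- cos(theta) * yy + sin(theta) * xx
      purrr::map(seq_len(per_class), function(j) {
        phase <- runif(1, 0, 2 * pi)
        pattern <- sin(2 * pi * freq * u + phase) +
          0.5 * sin(4 * pi * freq * u + 2 * phase)
        img <- 0.5 + (separation / 4) * pattern +
          matrix(rnorm(side * side, sd = noise_sd), side, side)
        tibble(
          id = sprintf("class_%02d/img_%03d", cl, j),
          class = sprintf("class_%02d", cl),
          image = list(pmin(pmax(img, 0), 1))
        )
      })
    })
    out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
    out$class <- factor(out$class)
    out
  })
}

#' Stratified train/test split of an image dataset
#'
#' @param data Dataset tibble as returned by [synth_images()] or
#'   [read_image_folder()].
#' @param train_fraction Fraction of each class assigned to the training set
#'   (strictly between 0 and 1).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`; the two are disjoint and
#'   their union is `data`.
#' @export
split_images <- function(data, train_fraction = 0.75, seed = 1) {
  check_dataset(data)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  counts <- table(data$class)
  if (any(counts < 2)) {
    abort(sprintf(
      "Every class needs >= 2 samples to split; offending class: %s.",
      names(counts)[which(counts < 2)[1]]
    ))
  }
  with_seed(derive_seed(seed, "split"), {
    idx_train <- unlist(lapply(split(seq_len(nrow(data)), data$class), function(ix) {
      n_tr <- max(1L, min(length(ix) - 1L, round(train_fraction * length(ix))))
      sort(sample(ix, n_tr))
    }), use.names = FALSE)
  })
  list(
    train = data[sort(idx_train), , drop = FALSE],
    test = data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE]
  )
}

#' Write a dataset as an image folder tree
#'
#' Writes `class_<i>/img_<j>.png` grayscale files under `dir`, the layout
#' consumed by [read_image_folder()] and the command-line interface.
#'
#' @param data Dataset tibble.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_image_folders <- function(data, dir) {
  check_dataset(data)
  for (cl in levels(factor(data$class))) {
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(nrow(data))) {
    path <- file.path(dir, paste0(data$id[i], ".png"))
    if (!grepl("/", data$id[i])) {
      path <- file.path(dir, as.character(data$class[i]), paste0(data$id[i], ".png"))
    }
    png::writePNG(pmin(pmax(data$image[[i]], 0), 1), path)
  }
  invisible(dir)
}

#' Read a labeled image folder tree
#'
#' Expects one subdirectory per class containing PNG images; images are read
#' as grayscale in `[0, 1]` (RGB images are converted by channel averaging).
#'
#' @param dir Directory with `class/<image>.png` structure.
#' @return Dataset tibble with `id`, `class`, `image` columns.
#' @export
read_image_folder <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) abort("No class subdirectories found.")
  rows <- purrr::map(classes, function(cl) {
    files <- sort(list.files(file.path(dir, cl), pattern = "\\.png$", full.names = TRUE))
    purrr::map(files, function(f) {
      px <- png::readPNG(f)
      if (length(dim(px)) == 3) px <- apply(px[, , seq_len(min(3, dim(px)[3])), drop = FALSE], c(1, 2), mean)
      tibble(
        id = paste0(cl, "/", sub("\\.png$", "", basename(f))),
        class = cl, image = list(px)
      )
    })
  })
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  out$class <- factor(out$class)
  out
}
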