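#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif cov sd
NULL

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a root seed; keeps results
# reproducible when stages are re-run in isolation. Stays below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587 + 1)
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (!all(is.finite(image))) {
    abort(sprintf("`%s` contains non-finite pixels.", arg))
  }
  invisible(image)
}

check_dataset <- function(data, arg = "data") {
  if (!is.data.frame(data) || !all(c("class", "image") %in% names(data))) {
    abort(sprintf("`%s` must be a data frame with `class` and `image` columns.", arg))
  }
  if (nrow(data) == 0L) abort(sprintf("`%s` has no rows.", arg))
  invisible(data)
}

#' Resize a numeric image matrix
#'
#' Bilinear resize of a 2D intensity grid, used to bring images to a network's
#' input size and to downsample images for clustering.
#'
#' @param image Numeric matrix.
#' @param height,width Target size in pixels; `width` defaults to `height`.
#' @return A `height` x `width` numeric matrix.
#' @export
resize_image <- function(image, height, width = height) {
  check_image(image)
  if (height < 1 || width < 1) abort("Target size must be >= 1 pixel.")
  if (nrow(image) == height && ncol(image) == width) return(image)
  out <- EBImage::resize(EBImage::Image(image), w = height, h = width)
  matrix(EBImage::imageData(out), nrow = height, ncol = width)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
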