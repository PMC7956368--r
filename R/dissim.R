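#' Project an image into the dissimilarity space
#'
#' Component `i` of the projection is the learned pair score between the
#' image and prototype `i` (the centroid rendered back to an image at the
#' model's input size), in prototype order:
#' `F(x) = [d(x, p1), ..., d(x, pk)]`.
#'
#' @param image Image matrix.
#' @param prototypes A `prototype_set`.
#' @param model An `snn_model` (or `snn_fit`).
#' @return Named numeric vector of length `k = kc * c`, entries in `(0, 1)`.
#' @export
project <- function(image, prototypes, model) {
  check_image(image)
  model <- as_snn_model(model)
  protos <- prototype_images(prototypes, model$input_size)
  s <- score_pairs(model, rep(list(image), length(protos)), protos)
  stats::setNames(s, prototypes$prototype_id)
}

as_snn_model <- function(model) {
  if (inherits(model, "snn_fit")) model$model
  else if (inherits(model, "snn_model")) model
  else abort("Expected an `snn_model` or `snn_fit`.")
}

#' Dissimilarity design matrix of a dataset
#'
#' Projects every image of `data` onto the prototype set with the trained
#' model. Scoring is batched for throughput; the result is independent of
#' `batch_size`.
#'
#' @param data Dataset tibble.
#' @param prototypes A `prototype_set`.
#' @param model An `snn_model` or `snn_fit`.
#' @param batch_size Images scored per forward pass.
#' @return A `dissim_design` tibble: `id`, `class`, then one column per
#'   prototype (named by `prototype_id`), row `i` being the projection of
#'   sample `i`.
#' @export
build_design_matrix <- function(data, prototypes, model, batch_size = 64) {
  check_dataset(data)
  model <- as_snn_model(model)
  k <- nrow(prototypes)
  protos <- prototype_images(prototypes, model$input_size)
  n <- nrow(data)
  scores <- matrix(NA_real_, n, k, dimnames = list(NULL, prototypes$prototype_id))
  pairs_per_batch <- max(1L, as.integer(batch_size))
  # batch over (image, prototype) pairs in row-major blocks of images
  imgs_per_block <- max(1L, pairs_per_batch %/% k)
  start <- 1L
  while (start <= n) {
    stop_ <- min(n, start + imgs_per_block - 1L)
    block <- data$image[start:stop_]
    nb <- length(block)
    left <- rep(block, each = k)
    right <- rep(protos, times = nb)
    s <- score_pairs(model, left, right)
    scores[start:stop_, ] <- matrix(s, nb, k, byrow = TRUE)
    start <- stop_ + 1L
  }
  out <- dplyr::bind_cols(data[c("id", "class")], as_tibble(scores))
  class(out) <- c("dissim_design", class(out))
  out
}

design_features <- function(design) {
  as.matrix(design[, setdiff(names(design), c("id", "class")), drop = FALSE])
}

#' Write / read a design matrix as CSV
#'
#' Header holds the prototype ids; the label column is last.
#'
#' @param design A `dissim_design` tibble.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `dissim_design` (reader).
#' @export
write_design_matrix <- function(design, path) {
  df <- design[, c("id", setdiff(names(design), c("id", "class")), "class")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_matrix
#' @export
read_design_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- as_tibble(df[, c("id", "class", setdiff(names(df), c("id", "class")))])
  out$class <- factor(out$class)
  class(out) <- c("dissim_design", class(out))
  out
}
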