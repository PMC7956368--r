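#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_tile
#'   facet_wrap labs scale_fill_gradient theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Tidy the training trace of a Siamese fit
#'
#' @param x An `snn_fit`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `loss`.
#' @export
tidy.snn_fit <- function(x, ...) x$trace

#' One-row summary of a Siamese fit
#'
#' @param x An `snn_fit`.
#' @param ... Unused.
#' @return Tibble with architecture name, iteration count, parameter count,
#'   first/final loss and the mean loss over the last 50 iterations.
#' @export
glance.snn_fit <- function(x, ...) {
  n <- nrow(x$trace)
  tibble(
    architecture = x$architecture$name,
    iterations = n,
    n_parameters = sum(vapply(x$model$params, length, 1L)),
    first_loss = x$trace$loss[1],
    final_loss = x$trace$loss[n],
    mean_loss_last50 = mean(x$trace$loss[max(1, n - 49):n])
  )
}

#' Loss curve of a Siamese fit
#'
#' @param object An `snn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snn_fit <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$iteration, y = .data$loss)) +
    geom_line(color = "steelblue") +
    labs(x = "iteration", y = "binary cross-entropy",
         title = paste("Training loss:", object$architecture$name)) +
    theme_minimal()
}

#' Tidy the per-layer table of an architecture
#'
#' @param x An `snn_architecture`.
#' @param ... Unused.
#' @return The [architecture_table()] tibble.
#' @export
tidy.snn_architecture <- function(x, ...) architecture_table(x)

#' One-row summary of an architecture
#'
#' @param x An `snn_architecture`.
#' @param ... Unused.
#' @return Tibble with id, name, input size, embedding dim, layer and
#'   parameter totals.
#' @export
glance.snn_architecture <- function(x, ...) {
  tibble(id = x$id, name = x$name, input_size = x$input_size,
         embedding_dim = x$embedding_dim, n_layers = length(x$layers),
         total_parameters = total_parameters(x))
}

#' Tidy a one-vs-all SVM
#'
#' @param x An `ova_svm`.
#' @param ... Unused.
#' @return Tibble with one row per binary sub-model: class, support-vector
#'   count and bias.
#' @export
tidy.ova_svm <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$classes), function(i) {
    tibble(class = x$classes[i], n_support = x$fits[[i]]$tot.nSV,
           rho = unname(x$fits[[i]]$rho))
  }))
}

#' One-row summary of a pipeline run
#'
#' @param x A `dissim_pipeline`.
#' @param ... Unused.
#' @return Tibble with member count, fused accuracy, AUC, and n.
#' @export
glance.dissim_pipeline <- function(x, ...) {
  dplyr::bind_cols(tibble(n_members = nrow(x$members)), x$report)
}

#' Per-member results of a pipeline run
#'
#' @param x A `dissim_pipeline`.
#' @param ... Unused.
#' @return Tibble with one row per ensemble member and its test accuracy.
#' @export
tidy.dissim_pipeline <- function(x, ...) {
  x$members[, c("representation", "architecture", "architecture_name",
                "kc", "accuracy")]
}

#' Heatmap of a dissimilarity design matrix
#'
#' Rows are samples (grouped by class), columns prototypes; cell color is the
#' learned same-class score. On well-separated data the block structure of
#' high scores against own-class prototypes is visible.
#'
#' @param object A `dissim_design` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dissim_design <- function(object, ...) {
  df <- object
  df$.row <- order(order(df$class))
  long <- tidyr::pivot_longer(df, cols = -c("id", "class", ".row"),
                              names_to = "prototype", values_to = "score")
  long$prototype <- factor(long$prototype, levels = setdiff(names(object), c("id", "class")))
  ggplot(long, aes(x = .data$prototype, y = .data$.row, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkred", limits = c(0, 1)) +
    labs(x = "prototype", y = "sample (sorted by class)", fill = "d(x, p)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Montage of example images per class
#'
#' @param data Dataset tibble.
#' @param per_class Images shown per class.
#' @return A ggplot.
#' @export
plot_dataset <- function(data, per_class = 3) {
  check_dataset(data)
  shown <- dplyr::slice_head(dplyr::group_by(data, .data$class), n = per_class)
  shown <- dplyr::ungroup(shown)
  long <- purrr::map_dfr(seq_len(nrow(shown)), function(i) {
    im <- shown$image[[i]]
    tibble(id = shown$id[i], class = as.character(shown$class[i]),
           row = rep(seq_len(nrow(im)), ncol(im)),
           col = rep(seq_len(ncol(im)), each = nrow(im)),
           value = as.vector(im))
  })
  ggplot(long, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    facet_wrap(~id) +
    coord_equal() +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
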