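#' Train one-vs-all linear SVMs on a dissimilarity design matrix
#'
#' Fits one binary SVM per class (that class against all others) on the
#' prototype-score columns of `design`. Prediction returns the per-class
#' signed margins as confidence scores; the decision is the class with the
#' highest confidence. The default kernel is linear with `cost = 1`: the
#' dissimilarity vectors are already a learned representation, so no further
#' kernel nonlinearity is assumed.
#'
#' @param design A `dissim_design` tibble (or any tibble with `class` plus
#'   numeric feature columns).
#' @param cost SVM regularization constant.
#' @param kernel Kernel name passed to [e1071::svm()].
#' @return An `ova_svm` object.
#' @importFrom e1071 svm
#' @export
fit_ova_svm <- function(design, cost = 1, kernel = "linear") {
  check_dataset_design(design)
  x <- design_features(design)
  y <- factor(design$class)
  classes <- levels(y)
  if (length(classes) < 2) abort("Need at least 2 classes.")
  fits <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x, yy, kernel = kernel, cost = cost, scale = FALSE)
  })
  structure(list(fits = fits, classes = classes,
                 features = colnames(x), cost = cost, kernel = kernel),
            class = "ova_svm")
}

check_dataset_design <- function(design) {
  if (!is.data.frame(design) || !"class" %in% names(design)) {
    abort("`design` must be a data frame with a `class` column.")
  }
  if (nrow(design) == 0) abort("`design` has no rows.")
  invisible(design)
}

#' Per-class confidence scores of a one-vs-all SVM
#'
#' @param object An `ova_svm`.
#' @param new_data Tibble with the same feature columns the model was
#'   trained on.
#' @param ... Unused.
#' @return A `score_matrix` tibble: `id` (if present), one signed-margin
#'   column per class, and `.pred` (argmax class).
#' @export
predict.ova_svm <- function(object, new_data, ...) {
  x <- as.matrix(new_data[, object$features, drop = FALSE])
  margins <- vapply(seq_along(object$classes), function(i) {
    p <- stats::predict(object$fits[[i]], x, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # orient so positive margin favors the "pos" (target) class
    if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
  }, numeric(nrow(x)))
  margins <- matrix(margins, nrow = nrow(x),
                    dimnames = list(NULL, object$classes))
  new_score_matrix(margins, id = new_data[["id"]])
}

new_score_matrix <- function(m, id = NULL, source_id = NA_character_) {
  stopifnot(is.matrix(m))
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(id = id %||% as.character(seq_len(nrow(m)))), out)
  out$.pred <- factor(colnames(m)[max.col(m, ties.method = "first")],
                      levels = colnames(m))
  structure(out, class = c("score_matrix", class(tibble())),
            source_id = source_id)
}

score_classes <- function(scores) {
  setdiff(names(scores), c("id", ".pred"))
}

score_values <- function(scores) {
  as.matrix(scores[, score_classes(scores), drop = FALSE])
}

#' Z-normalize a score matrix
#'
#' Centers and scales all score entries by the mean and population standard
#' deviation (divide by n) pooled over the entries of `reference` — by
#' default the training-fold scores, so test scores can be normalized without
#' leakage. A zero-spread reference yields all-zero scores with a warning.
#'
#' @param scores A `score_matrix` tibble.
#' @param reference A `score_matrix` supplying the normalization statistics
#'   (defaults to `scores` itself).
#' @return A `score_matrix` with normalized entries (decisions recomputed).
#' @export
znorm <- function(scores, reference = scores) {
  v <- score_values(scores)
  r <- score_values(reference)
  if (length(r) == 0) abort("Reference is empty.")
  mu <- mean(r)
  sd_pop <- sqrt(mean((r - mu)^2))
  if (sd_pop == 0) {
    warn("Reference scores have zero spread; returning all-zero scores.")
    z <- v * 0
  } else {
    z <- (v - mu) / sd_pop
  }
  new_score_matrix(z, id = scores$id, source_id = attr(scores, "source_id"))
}

check_aligned <- function(members) {
  if (length(members) == 0) abort("Need at least one score matrix.")
  cls <- score_classes(members[[1]])
  n <- nrow(members[[1]])
  for (m in members) {
    if (nrow(m) != n || !identical(score_classes(m), cls)) {
      abort("Score matrices must share shape, class columns and sample order.")
    }
  }
  invisible(cls)
}

#' Sum-rule fusion of classifier score matrices
#'
#' Elementwise sum of aligned member score matrices; the fused decision is
#' the argmax row class. Invariant to member order.
#'
#' @param members List of aligned `score_matrix` tibbles.
#' @return Fused `score_matrix`.
#' @export
sum_rule <- function(members) {
  check_aligned(members)
  total <- Reduce(`+`, lapply(members, score_values))
  new_score_matrix(total, id = members[[1]]$id, source_id = "sum_rule")
}

#' Weighted sum-rule fusion with z-normalization
#'
#' Each member is z-normalized (by `references[[i]]`, defaulting to itself)
#' and then summed with its weight: `sum_i w_i * znorm(member_i)`. With unit
#' weights this equals [sum_rule()] of the z-normalized members. Scaling all
#' weights by a positive constant leaves decisions unchanged. The recipe for
#' combining an external CNN score file with a Siamese ensemble uses weights
#' 4 and 1.
#'
#' @param members List of aligned `score_matrix` tibbles.
#' @param weights Positive numeric vector, one per member.
#' @param references Optional list of reference `score_matrix`es for the
#'   normalization statistics.
#' @return Fused `score_matrix`.
#' @export
weighted_sum <- function(members, weights, references = NULL) {
  check_aligned(members)
  if (length(weights) != length(members)) {
    abort("`weights` must match the number of members.")
  }
  if (any(weights <= 0)) abort("`weights` must be positive.")
  normed <- lapply(seq_along(members), function(i) {
    ref <- if (is.null(references)) members[[i]] else references[[i]]
    score_values(znorm(members[[i]], ref)) * weights[i]
  })
  new_score_matrix(Reduce(`+`, normed), id = members[[1]]$id,
                   source_id = "weighted_sum")
}

#' Number of classifiers in an ensemble
#'
#' One member is trained per (topology, prototype count) combination for a
#' given input representation, so the ensemble size is
#' `length(topologies) * length(kc_grid)`; e.g. six topologies over the grid
#' `{15, 30, 45, 60}` give 24 classifiers.
#'
#' @param topologies Vector of backbone ids (subset of 1..8).
#' @param kc_grid Vector of per-class prototype counts.
#' @return Integer member count.
#' @export
ensemble_size <- function(topologies, kc_grid) {
  if (length(topologies) == 0 || length(kc_grid) == 0) {
    abort("`topologies` and `kc_grid` must be nonempty.")
  }
  length(unique(topologies)) * length(unique(kc_grid))
}

#' Write / read a score matrix as CSV
#'
#' Sample id, one column per class; the provenance tag is stored in a
#' `# source_id:` comment header. External classifier scores (e.g. from
#' pretrained CNNs) can be ingested through the same schema and fused with
#' [sum_rule()] / [weighted_sum()].
#'
#' @param scores A `score_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `score_matrix` (reader).
#' @export
write_scores <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source_id: %s", attr(scores, "source_id") %||% NA), con)
  utils::write.csv(scores[, c("id", score_classes(scores))], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  first <- readLines(path, n = 1)
  src <- if (startsWith(first, "# source_id:")) {
    trimws(sub("# source_id:", "", first))
  } else {
    NA_character_
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  new_score_matrix(m, id = as.character(df$id), source_id = src)
}
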