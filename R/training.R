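#' Training options for the Siamese trainer
#'
#' Defaults follow the standard ADAM recipe used for these networks:
#' learning rate 0.0001, gradient decay 0.9, squared-gradient decay 0.99,
#' 3000 iterations with no stopping criterion, batch size 32 pairs.
#'
#' @param learning_rate ADAM step size.
#' @param gradient_decay First-moment decay (beta1).
#' @param squared_gradient_decay Second-moment decay (beta2).
#' @param iterations Number of optimization steps (a fresh pair batch each).
#' @param batch_size Pairs per step.
#' @param seed Integer seed driving initialization, pair sampling and dropout.
#' @param augment Apply axis reflections and random rescaling (factor in
#'   `[1, 2]`) to training images; off by default.
#' @return A `train_options` list.
#' @export
train_options <- function(learning_rate = 1e-4, gradient_decay = 0.9,
                          squared_gradient_decay = 0.99, iterations = 3000,
                          batch_size = 32, seed = 1, augment = FALSE) {
  if (iterations < 1) abort("`iterations` must be >= 1.")
  if (batch_size < 1) abort("`batch_size` must be >= 1.")
  structure(list(
    learning_rate = learning_rate, gradient_decay = gradient_decay,
    squared_gradient_decay = squared_gradient_decay,
    iterations = as.integer(iterations), batch_size = as.integer(batch_size),
    seed = as.integer(seed), augment = isTRUE(augment)
  ), class = "train_options")
}

#' Sample labeled image pairs
#'
#' Draws `n` pairs balanced 50/50 in expectation between same-class and
#' different-class, sampling uniformly over classes and then over images
#' within a class. Pair label 1 means the two images share a class.
#'
#' @param data Dataset tibble with >= 2 classes.
#' @param n Number of pairs.
#' @param seed Integer seed; identical seeds give identical batches.
#' @return Tibble with list-columns `image1`, `image2` and integer `label`.
#' @export
sample_pairs <- function(data, n, seed = 1) {
  check_dataset(data)
  by_class <- split(seq_len(nrow(data)), data$class)
  by_class <- by_class[lengths(by_class) > 0]
  if (length(by_class) < 2) abort("Pair sampling needs at least 2 classes.")
  with_seed(derive_seed(seed, "pairs"), {
    same <- runif(n) < 0.5
    i1 <- integer(n); i2 <- integer(n)
    cls <- names(by_class)
    for (k in seq_len(n)) {
      if (same[k]) {
        cl <- sample(cls, 1)
        ix <- by_class[[cl]]
        i1[k] <- ix[sample.int(length(ix), 1)]
        i2[k] <- ix[sample.int(length(ix), 1)]
      } else {
        cl2 <- sample(cls, 2)
        ixa <- by_class[[cl2[1]]]; ixb <- by_class[[cl2[2]]]
        i1[k] <- ixa[sample.int(length(ixa), 1)]
        i2[k] <- ixb[sample.int(length(ixb), 1)]
      }
    }
    tibble(
      image1 = data$image[i1], image2 = data$image[i2],
      label = as.integer(data$class[i1] == data$class[i2])
    )
  })
}

#' Binary cross-entropy loss
#'
#' `-(label * log(score) + (1 - label) * log(1 - score))`, with scores
#' clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param score Predicted score(s) in `(0, 1)`.
#' @param label True pair label(s) in `{0, 1}`.
#' @return Elementwise loss.
#' @export
bce_loss <- function(score, label) {
  s <- pmin(pmax(score, 1e-12), 1 - 1e-12)
  -(label * log(s) + (1 - label) * log(1 - s))
}

# Reflections / rescale augmentation applied independently per image.
augment_image <- function(im) {
  if (runif(1) < 0.5) im <- im[nrow(im):1, , drop = FALSE]
  if (runif(1) < 0.5) im <- im[, ncol(im):1, drop = FALSE]
  fac <- runif(1, 1, 2)
  if (fac > 1.001) {
    big <- resize_image(im, round(nrow(im) * fac), round(ncol(im) * fac))
    r0 <- sample.int(nrow(big) - nrow(im) + 1L, 1)
    c0 <- sample.int(ncol(big) - ncol(im) + 1L, 1)
    im <- big[r0 + seq_len(nrow(im)) - 1L, c0 + seq_len(ncol(im)) - 1L]
  }
  im
}

#' Train a Siamese dissimilarity model
#'
#' Trains the twin network plus scoring head with ADAM on binary
#' cross-entropy over freshly sampled image pairs (one batch per iteration),
#' learning to output scores near 1 for same-class pairs and near 0 for
#' different-class pairs. Deterministic for a given `options$seed`.
#'
#' @param data Training dataset tibble (images are resized to the
#'   architecture's input layer as needed).
#' @param arch An `snn_architecture`.
#' @param options A [train_options()] list.
#' @param init,sigma Passed to [snn_init()].
#' @return An `snn_fit`: the trained `snn_model` plus a `trace` tibble with
#'   per-iteration `loss`.
#' @export
train_snn <- function(data, arch, options = train_options(),
                      init = "he", sigma = 0.01) {
  check_dataset(data)
  stopifnot(inherits(arch, "snn_architecture"))
  model <- snn_init(arch, seed = options$seed, init = init, sigma = sigma)
  side <- model$input_size
  images <- lapply(data$image, function(im) {
    if (nrow(im) != side || ncol(im) != side) resize_image(im, side) else im
  })
  work <- tibble(id = data$id, class = data$class, image = images)

  b1 <- options$gradient_decay
  b2 <- options$squared_gradient_decay
  lr <- options$learning_rate
  eps <- 1e-8
  m_state <- lapply(model$params, function(p) p * 0)
  v_state <- m_state
  losses <- numeric(options$iterations)

  with_seed(derive_seed(options$seed, "train"), {
    for (it in seq_len(options$iterations)) {
      batch <- sample_pairs(work, options$batch_size,
                            seed = derive_seed(options$seed, paste0("batch", it)))
      im1 <- batch$image1; im2 <- batch$image2
      if (options$augment) {
        im1 <- lapply(im1, augment_image)
        im2 <- lapply(im2, augment_image)
      }
      nb <- nrow(batch)
      X <- cbind(stack_images(im1, side), stack_images(im2, side))
      fwd <- snn_forward(model, X, training = TRUE)
      FF <- fwd$embed
      F1 <- FF[, seq_len(nb), drop = FALSE]
      F2 <- FF[, nb + seq_len(nb), drop = FALSE]
      Y <- abs(F1 - F2)
      w <- model$params[["head.w"]]
      logit <- as.vector(crossprod(Y, w)) + model$params[["head.b"]]
      s <- sigmoid(logit)
      loss <- mean(bce_loss(s, batch$label))
      if (!is.finite(loss)) {
        abort(sprintf("Non-finite loss at iteration %d; aborting training.", it))
      }
      losses[it] <- loss

      dlogit <- (s - batch$label) / nb
      grads <- list(
        "head.w" = as.vector(Y %*% dlogit),
        "head.b" = sum(dlogit)
      )
      dY <- outer(w, dlogit)
      sgn <- sign(F1 - F2)
      dF <- cbind(dY * sgn, -dY * sgn)
      grads <- c(grads, snn_backward(model, fwd$caches, dF))

      for (nm in names(grads)) {
        g <- grads[[nm]]
        m_state[[nm]] <- b1 * m_state[[nm]] + (1 - b1) * g
        v_state[[nm]] <- b2 * v_state[[nm]] + (1 - b2) * g^2
        mhat <- m_state[[nm]] / (1 - b1^it)
        vhat <- v_state[[nm]] / (1 - b2^it)
        model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  })
  structure(list(model = model, architecture = arch, options = options,
                 trace = tibble(iteration = seq_len(options$iterations),
                                loss = losses)),
            class = "snn_fit")
}

#' @export
print.snn_fit <- function(x, ...) {
  cat(sprintf("<snn_fit> %s, %d iterations, final loss %.4f\n",
              x$architecture$name, nrow(x$trace),
              x$trace$loss[nrow(x$trace)]))
  invisible(x)
}
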