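#' Leaky rectified linear activation
#'
#' `x` for `x >= 0`, `a * x` otherwise. `a = 0` reduces to the plain ReLU.
#'
#' @param x Numeric vector/array.
#' @param a Negative-branch slope (default 0.01).
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, a = 0.01) {
  pos <- x >= 0
  x * (pos + a * !pos)
}

#' Subtract block
#'
#' Elementwise absolute difference `|f1 - f2|` of two embeddings — the
#' operation that makes the Siamese pair score symmetric in its inputs.
#'
#' @param f1,f2 Numeric vectors of equal length.
#' @return `abs(f1 - f2)`.
#' @export
subtract_block <- function(f1, f2) {
  if (length(f1) != length(f2)) abort("Embeddings must have equal length.")
  abs(f1 - f2)
}

# ---- layer plans -----------------------------------------------------------
# A plan precomputes, for a fixed input size, everything a layer needs to run
# on a batch stored as a (h*w*c) x n matrix with pixel-fastest-then-channel
# row layout: im2col gather indices, sparse col2im scatter matrices and
# max-pool index tables.

# im2col index matrix: column j holds the linear indices (into an (h, w, c)
# array) of the j-th output position's receptive field, for channels chans.
im2col_index <- function(h, w, chans, f, stride) {
  oh <- (h - f) %/% stride + 1L
  ow <- (w - f) %/% stride + 1L
  patch <- as.vector(outer(seq_len(f), (seq_len(f) - 1L) * h, "+")) # f x f block
  patch <- as.vector(outer(patch, (chans - 1L) * h * w, "+"))       # x channels
  r0 <- (seq_len(oh) - 1L) * stride
  c0 <- (seq_len(ow) - 1L) * stride
  origins <- as.vector(outer(r0, c0 * h, "+")) # output positions, column-major
  idx <- outer(patch, origins, "+")
  list(idx = idx, oh = oh, ow = ow)
}

plan_layers <- function(arch, input_size) {
  h <- input_size; w <- input_size; c <- 1L
  plans <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    p <- list(kind = l$kind, in_h = h, in_w = w, in_c = c)
    if (l$kind %in% c("conv", "grouped_conv")) {
      g <- l$groups
      cg <- c %/% g
      if (cg * g != c) abort(sprintf("Layer %d: %d channels not divisible by %d groups.", i, c, g))
      nfg <- l$num_filters %/% g
      p$f <- l$filter_size; p$stride <- l$stride; p$groups <- g
      p$nf_g <- nfg; p$c_g <- cg
      p$idx <- vector("list", g)
      p$idxv <- vector("list", g)
      p$scat <- vector("list", g)
      for (gi in seq_len(g)) {
        ic <- im2col_index(h, w, (gi - 1L) * cg + seq_len(cg), l$filter_size, l$stride)
        p$idx[[gi]] <- ic$idx
        p$idxv[[gi]] <- as.vector(ic$idx)
        p$scat[[gi]] <- Matrix::sparseMatrix(
          i = as.vector(ic$idx), j = seq_along(ic$idx), x = 1,
          dims = c(h * w * c, length(ic$idx))
        )
        p$oh <- ic$oh; p$ow <- ic$ow
      }
      h <- p$oh; w <- p$ow; c <- l$num_filters
    } else if (l$kind == "max_pool") {
      ic <- im2col_index(h, w, seq_len(c), l$filter_size, l$stride)
      # reorder columns so output positions run fastest, then channels:
      # im2col_index stacks channels inside each column; redo per channel.
      per <- lapply(seq_len(c), function(ch) {
        im2col_index(h, w, ch, l$filter_size, l$stride)$idx
      })
      p$idx <- do.call(cbind, per) # (f^2) x (oh*ow*c)
      p$idxv <- as.vector(p$idx)
      p$f <- l$filter_size; p$oh <- ic$oh; p$ow <- ic$ow
      h <- p$oh; w <- p$ow
    } else if (l$kind == "fully_connected") {
      p$flat <- h * w * c
      p$units <- l$out_units
      h <- NA_integer_; w <- NA_integer_; c <- NA_integer_
    } else if (l$kind == "leaky_relu") {
      p$slope <- l$slope
    } else if (l$kind == "dropout") {
      p$prob <- l$prob
    }
    p$out_h <- h; p$out_w <- w; p$out_c <- c
    plans[[i]] <- p
  }
  plans
}

# ---- model -----------------------------------------------------------------

#' Initialize a Siamese dissimilarity model
#'
#' Builds the twin-branch parameters for `arch` plus the scoring head (a
#' fully-connected layer to one unit followed by a sigmoid, applied to the
#' subtract block `|F1 - F2|`). Both branches share the same weights by
#' construction. Default initialization is He-scaled Gaussian
#' (`sd = sqrt(2 / fan_in)`), appropriate for rectifier networks; a flat
#' narrow Gaussian (`init = "gaussian"`, `sigma`) is available.
#'
#' @param arch An `snn_architecture`.
#' @param seed Integer seed for the weight draw.
#' @param init `"he"` (default) or `"gaussian"`.
#' @param sigma Weight sd when `init = "gaussian"`.
#' @return An object of class `snn_model`.
#' @export
snn_init <- function(arch, seed = 1, init = c("he", "gaussian"), sigma = 0.01) {
  stopifnot(inherits(arch, "snn_architecture"))
  init <- match.arg(init)
  plans <- plan_layers(arch, arch$input_size)
  params <- list()
  with_seed(derive_seed(seed, "init"), {
    for (i in seq_along(plans)) {
      p <- plans[[i]]
      if (p$kind %in% c("conv", "grouped_conv")) {
        fan <- p$f^2 * p$c_g
        sdv <- if (init == "he") sqrt(2 / fan) else sigma
        for (gi in seq_len(p$groups)) {
          params[[sprintf("L%d.W%d", i, gi)]] <-
            matrix(rnorm(fan * p$nf_g, sd = sdv), fan, p$nf_g)
        }
        params[[sprintf("L%d.b", i)]] <- numeric(p$groups * p$nf_g)
      } else if (p$kind == "fully_connected") {
        sdv <- if (init == "he") sqrt(2 / p$flat) else sigma
        params[[sprintf("L%d.W", i)]] <-
          matrix(rnorm(p$flat * p$units, sd = sdv), p$flat, p$units)
        params[[sprintf("L%d.b", i)]] <- numeric(p$units)
      }
    }
    e <- arch$embedding_dim
    params[["head.w"]] <- rnorm(e, sd = if (init == "he") sqrt(2 / e) else sigma)
    params[["head.b"]] <- 0
  })
  structure(list(architecture = arch, input_size = arch$input_size,
                 plans = plans, params = params),
            class = "snn_model")
}

#' @export
print.snn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<snn_model> %s: input %d x %d, embedding %d, %s trainable parameters\n",
              x$architecture$name, x$input_size, x$input_size,
              x$architecture$embedding_dim, format(np, big.mark = ",")))
  invisible(x)
}

# Forward pass of one branch on a batch X: (side^2) x n matrix (single
# channel). Returns list(embed, caches) where caches holds what backward
# needs; caches is NULL unless `training`.
snn_forward <- function(model, X, training = FALSE) {
  plans <- model$plans
  params <- model$params
  caches <- if (training) vector("list", length(plans)) else NULL
  n <- ncol(X)
  for (i in seq_along(plans)) {
    p <- plans[[i]]
    if (p$kind %in% c("conv", "grouped_conv")) {
      L <- p$oh * p$ow
      outs <- vector("list", p$groups)
      cols_all <- if (training) vector("list", p$groups) else NULL
      b <- params[[sprintf("L%d.b", i)]]
      for (gi in seq_len(p$groups)) {
        Mg <- X[p$idxv[[gi]], , drop = FALSE]
        dim(Mg) <- c(nrow(p$idx[[gi]]), L * n)
        Yg <- crossprod(params[[sprintf("L%d.W%d", i, gi)]], Mg) +
          b[(gi - 1L) * p$nf_g + seq_len(p$nf_g)]
        A <- array(Yg, c(p$nf_g, L, n))
        outs[[gi]] <- matrix(aperm(A, c(2, 1, 3)), L * p$nf_g, n)
        if (training) cols_all[[gi]] <- Mg
      }
      X <- do.call(rbind, outs)
      if (training) caches[[i]] <- list(cols = cols_all)
    } else if (p$kind == "max_pool") {
      p2 <- p$f^2
      K0 <- ncol(p$idx)                 # oh*ow*c positions per image
      V <- X[p$idxv, , drop = FALSE]
      dim(V) <- c(p2, K0 * n)
      mx <- V[1, ]
      am <- rep(1L, K0 * n)
      for (r in seq_len(p2)[-1]) {
        upd <- V[r, ] > mx
        mx[upd] <- V[r, upd]
        am[upd] <- r
      }
      am <- matrix(am, K0, n)
      idxv <- p$idxv
      rows <- idxv[(seq_len(K0) - 1L) * p2 + am]
      dim(rows) <- c(K0, n)
      hwc <- p$in_h * p$in_w * p$in_c
      lin <- rows + matrix((seq_len(n) - 1L) * hwc, K0, n, byrow = TRUE)
      X <- matrix(mx, K0, n)
      if (training) caches[[i]] <- list(lin = lin, hwc = hwc)
    } else if (p$kind == "relu") {
      mask <- X > 0
      X <- X * mask
      if (training) caches[[i]] <- list(factor = mask)
    } else if (p$kind == "leaky_relu") {
      fac <- (X >= 0) + p$slope * (X < 0)
      X <- X * fac
      if (training) caches[[i]] <- list(factor = fac)
    } else if (p$kind == "dropout") {
      if (training) {
        keep <- matrix(runif(length(X)) >= p$prob, nrow(X), ncol(X)) / (1 - p$prob)
        X <- X * keep
        caches[[i]] <- list(factor = keep)
      }
    } else if (p$kind == "fully_connected") {
      Xin <- X
      X <- crossprod(params[[sprintf("L%d.W", i)]], X) + params[[sprintf("L%d.b", i)]]
      if (training) caches[[i]] <- list(input = Xin)
    }
  }
  list(embed = X, caches = caches)
}

# Backward pass of one branch: dX is the gradient at the embedding
# ((embed) x n). Returns list of parameter gradients (named like params).
snn_backward <- function(model, caches, dX) {
  plans <- model$plans
  params <- model$params
  grads <- list()
  n <- ncol(dX)
  for (i in rev(seq_along(plans))) {
    p <- plans[[i]]
    cc <- caches[[i]]
    if (p$kind %in% c("conv", "grouped_conv")) {
      L <- p$oh * p$ow
      db <- numeric(p$groups * p$nf_g)
      dXnew <- 0
      for (gi in seq_len(p$groups)) {
        rows <- (gi - 1L) * L * p$nf_g + seq_len(L * p$nf_g)
        B <- array(dX[rows, , drop = FALSE], c(L, p$nf_g, n))
        dY <- matrix(aperm(B, c(2, 1, 3)), p$nf_g, L * n)
        Mg <- cc$cols[[gi]]
        grads[[sprintf("L%d.W%d", i, gi)]] <- tcrossprod(Mg, dY)
        db[(gi - 1L) * p$nf_g + seq_len(p$nf_g)] <- rowSums(dY)
        dM <- params[[sprintf("L%d.W%d", i, gi)]] %*% dY
        dim(dM) <- c(nrow(p$idx[[gi]]) * L, n)
        dXnew <- dXnew + as.matrix(p$scat[[gi]] %*% dM)
      }
      grads[[sprintf("L%d.b", i)]] <- db
      dX <- dXnew
    } else if (p$kind == "max_pool") {
      dXnew <- numeric(cc$hwc * n)
      dXnew[as.vector(cc$lin)] <- as.vector(dX)
      dX <- matrix(dXnew, cc$hwc, n)
    } else if (p$kind %in% c("relu", "leaky_relu")) {
      dX <- dX * cc$factor
    } else if (p$kind == "dropout") {
      if (!is.null(cc)) dX <- dX * cc$factor
    } else if (p$kind == "fully_connected") {
      grads[[sprintf("L%d.W", i)]] <- tcrossprod(cc$input, dX)
      grads[[sprintf("L%d.b", i)]] <- rowSums(dX)
      dX <- params[[sprintf("L%d.W", i)]] %*% dX
    }
  }
  grads
}

# Stack a list of image matrices into the (side^2) x n batch layout,
# resizing to the model input size when needed.
stack_images <- function(images, side) {
  X <- vapply(images, function(im) {
    if (nrow(im) != side || ncol(im) != side) im <- resize_image(im, side)
    as.vector(im)
  }, numeric(side * side))
  matrix(X, side * side, length(images))
}

#' Score image pairs with a dissimilarity model
#'
#' Runs both images of each pair through the shared twin branch, applies the
#' subtract block and the sigmoid head, and returns the pair scores in
#' `(0, 1)`. By the operational convention used throughout the package,
#' larger scores mean the model believes the two images belong to the same
#' class. The score is symmetric: `score_pairs(m, x, y) == score_pairs(m, y, x)`.
#'
#' @param model An `snn_model`.
#' @param images1,images2 Lists of image matrices (paired elementwise); a
#'   single matrix is treated as a one-element list.
#' @return Numeric vector of scores in `(0, 1)`.
#' @export
score_pairs <- function(model, images1, images2) {
  if (is.matrix(images1)) images1 <- list(images1)
  if (is.matrix(images2)) images2 <- list(images2)
  if (length(images1) != length(images2)) abort("Pair lists must have equal length.")
  n <- length(images1)
  X <- cbind(stack_images(images1, model$input_size),
             stack_images(images2, model$input_size))
  FF <- snn_forward(model, X)$embed
  Y <- abs(FF[, seq_len(n), drop = FALSE] - FF[, n + seq_len(n), drop = FALSE])
  as.vector(sigmoid(crossprod(Y, model$params[["head.w"]]) + model$params[["head.b"]]))
}

#' Pair score for two single images
#'
#' Strict single-pair form of [score_pairs()]: the images must already match
#' the model's input layer.
#'
#' @param model An `snn_model`.
#' @param x,y Image matrices sized to the model input.
#' @return A score in `(0, 1)`; larger means "same class".
#' @export
score_pair <- function(model, x, y) {
  check_image(x, "x"); check_image(y, "y")
  s <- model$input_size
  if (any(dim(x) != c(s, s)) || any(dim(y) != c(s, s))) {
    abort(sprintf("Images must match the %d x %d input layer.", s, s))
  }
  score_pairs(model, list(x), list(y))
}
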