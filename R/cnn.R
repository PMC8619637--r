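# Small convolutional patch classifier used for descriptor-free feature
# matching: two 3x3 same-padded convolution layers (ReLU, 2x2 max pooling
# after each) followed by two fully connected layers with dropout on the
# first and a softmax over the n feature categories. The network is
# deliberately compact (16x16 single-channel input) and trains on a CPU in
# minutes; all layers are implemented as dense matrix products so the heavy
# lifting is done by BLAS.
#
# Feature-map layout: a batch of B maps of size H x W with C channels is a
# (H*W*B) x C matrix, rows ordered spatial-major within each image
# (s = i + H*(j-1)) then by image. A 3x3 same-padded convolution is then a
# sum over the 9 kernel offsets of row-shifted matrix products, with
# out-of-image rows reading from an appended all-zero row.

conv_offsets <- expand.grid(di = -1:1, dj = -1:1)

# Row-gather indices implementing the 9 spatial shifts for an H x W map
# replicated over B images; index H*W*B + 1 is the zero row.
make_shift_idx <- function(H, W, B) {
  S <- H * W
  zero_row <- S * B + 1L
  iv <- rep(seq_len(H), W)
  jv <- rep(seq_len(W), each = H)
  lapply(seq_len(9), function(k) {
    ii <- iv + conv_offsets$di[k]
    jj <- jv + conv_offsets$dj[k]
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    base <- ii + H * (jj - 1L)
    full <- rep(base, B) + S * rep(0:(B - 1L), each = S)
    full[!rep(ok, B)] <- zero_row
    full
  })
}

# Corner-gather indices for 2x2 max pooling (H, W even).
make_pool_idx <- function(H, W, B) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  So <- Ho * Wo
  io <- rep(seq_len(Ho), Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(ab) {
    base <- (2L * io - 1L + ab[1]) + H * (2L * jo - 2L + ab[2])
    rep(base, B) + H * W * rep(0:(B - 1L), each = So)
  })
}

conv_forward <- function(M, Wk, bias, idx) {
  M_aug <- rbind(M, 0)
  Y <- matrix(rep(bias, each = nrow(M)), nrow(M), length(bias))
  for (k in seq_len(9)) Y <- Y + M_aug[idx[[k]], , drop = FALSE] %*% Wk[[k]]
  list(Y = Y, M_aug = M_aug)
}

conv_backward <- function(dY, M_aug, Wk, idx) {
  Cin <- ncol(M_aug)
  dM_aug <- matrix(0, nrow(M_aug), Cin)
  dW <- vector("list", 9)
  for (k in seq_len(9)) {
    dW[[k]] <- crossprod(M_aug[idx[[k]], , drop = FALSE], dY)
    dM_aug[idx[[k]], ] <- dM_aug[idx[[k]], , drop = FALSE] +
      tcrossprod(dY, Wk[[k]])
  }
  list(dM = dM_aug[-nrow(dM_aug), , drop = FALSE], dW = dW,
       db = colSums(dY))
}

pool_forward <- function(M, idx) {
  Y <- M[idx[[1]], , drop = FALSE]
  chosen <- matrix(1L, nrow(Y), ncol(Y))
  for (c in 2:4) {
    cand <- M[idx[[c]], , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    chosen[upd] <- c
  }
  list(Y = Y, chosen = chosen)
}

pool_backward <- function(dY, chosen, idx, n_in) {
  dM <- matrix(0, n_in, ncol(dY))
  for (c in 1:4) {
    contrib <- dY * (chosen == c)
    dM[idx[[c]], ] <- dM[idx[[c]], , drop = FALSE] + contrib
  }
  dM
}

#' Specify the patch-classification network
#'
#' The architecture is fixed in shape — exactly two convolutional layers
#' (3x3 kernels, stride 1, same padding, each followed by ReLU and 2x2 max
#' pooling) and two fully connected layers, ReLU and dropout after the
#' first, softmax with `n_categories` outputs after the second. Layer widths
#' default to 64 and 128 convolution kernels and 1024 hidden nodes.
#'
#' @param n_categories number of feature categories `n` (softmax outputs).
#' @param conv1,conv2 number of kernels in the two convolution layers.
#' @param fc nodes in the first fully connected layer.
#' @param dropout dropout rate applied after the first fully connected layer
#'   during training only; inference is deterministic.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(n_categories, conv1 = 64, conv2 = 128,
                            fc = 1024, dropout = 0.5) {
  stopifnot(n_categories >= 2, conv1 >= 1, conv2 >= 1, fc >= 1,
            dropout >= 0, dropout < 1)
  structure(list(n_categories = as.integer(n_categories),
                 conv1 = as.integer(conv1), conv2 = as.integer(conv2),
                 fc = as.integer(fc), dropout = dropout,
                 input = PATCH_SIZE),
            class = "classifier_spec")
}

nn_init <- function(spec) {
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  D <- (spec$input / 4)^2 * spec$conv2  # two 2x2 pools: 16 -> 8 -> 4
  list(
    Wc1 = lapply(seq_len(9), function(k) he(1, spec$conv1, 9)),
    bc1 = numeric(spec$conv1),
    Wc2 = lapply(seq_len(9), function(k) he(spec$conv1, spec$conv2, 9 * spec$conv1)),
    bc2 = numeric(spec$conv2),
    Wf1 = he(D, spec$fc, D),
    bf1 = numeric(spec$fc),
    Wf2 = he(spec$fc, spec$n_categories, spec$fc),
    bf2 = numeric(spec$n_categories)
  )
}

# Forward pass over a batch of patches (16 x 16 x B array). Returns softmax
# probabilities (B x n) and, when `train`, the cache needed for backprop.
nn_forward <- function(params, spec, patches, train = FALSE, drop_mask = NULL) {
  B <- dim(patches)[3]
  H <- spec$input
  idx1 <- make_shift_idx(H, H, B)
  pool1 <- make_pool_idx(H, H, B)
  idx2 <- make_shift_idx(H / 2, H / 2, B)
  pool2 <- make_pool_idx(H / 2, H / 2, B)
  M0 <- matrix(as.vector(patches), ncol = 1)

  c1 <- conv_forward(M0, params$Wc1, params$bc1, idx1)
  A1 <- pmax(c1$Y, 0)
  p1 <- pool_forward(A1, pool1)
  c2 <- conv_forward(p1$Y, params$Wc2, params$bc2, idx2)
  A2 <- pmax(c2$Y, 0)
  p2 <- pool_forward(A2, pool2)

  S2 <- (H / 4)^2
  arr <- array(p2$Y, dim = c(S2, B, spec$conv2))
  X <- t(matrix(aperm(arr, c(1, 3, 2)), nrow = S2 * spec$conv2))

  Z1 <- X %*% params$Wf1
  Z1 <- Z1 + matrix(params$bf1, nrow(Z1), ncol(Z1), byrow = TRUE)
  A3 <- pmax(Z1, 0)
  if (train && spec$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix((runif(length(A3)) >= spec$dropout) / (1 - spec$dropout),
                          nrow(A3), ncol(A3))
    A3d <- A3 * drop_mask
  } else {
    A3d <- A3
  }
  logits <- A3d %*% params$Wf2
  logits <- logits + matrix(params$bf2, nrow(logits), ncol(logits), byrow = TRUE)
  L <- logits - apply(logits, 1, max)
  E <- exp(L)
  P <- E / rowSums(E)
  out <- list(P = P)
  if (train)
    out$cache <- list(B = B, idx1 = idx1, pool1 = pool1, idx2 = idx2,
                      pool2 = pool2, c1 = c1, A1 = A1, p1 = p1, c2 = c2,
                      A2 = A2, p2 = p2, X = X, Z1 = Z1, A3 = A3,
                      drop_mask = drop_mask, A3d = A3d, S2 = S2)
  out
}

nn_backward <- function(params, spec, fwd, labels) {
  ch <- fwd$cache
  B <- ch$B
  dlogits <- fwd$P
  dlogits[cbind(seq_len(B), labels)] <- dlogits[cbind(seq_len(B), labels)] - 1
  dlogits <- dlogits / B

  g <- list()
  g$Wf2 <- crossprod(ch$A3d, dlogits)
  g$bf2 <- colSums(dlogits)
  dA3d <- tcrossprod(dlogits, params$Wf2)
  dA3 <- if (!is.null(ch$drop_mask)) dA3d * ch$drop_mask else dA3d
  dZ1 <- dA3 * (ch$Z1 > 0)
  g$Wf1 <- crossprod(ch$X, dZ1)
  g$bf1 <- colSums(dZ1)
  dX <- tcrossprod(dZ1, params$Wf1)

  arr2 <- array(t(dX), dim = c(ch$S2, spec$conv2, B))
  dP2 <- matrix(aperm(arr2, c(1, 3, 2)), nrow = ch$S2 * B, ncol = spec$conv2)

  dA2 <- pool_backward(dP2, ch$p2$chosen, ch$pool2, nrow(ch$A2))
  dY2 <- dA2 * (ch$c2$Y > 0)
  cb2 <- conv_backward(dY2, ch$c2$M_aug, params$Wc2, ch$idx2)
  g$Wc2 <- cb2$dW
  g$bc2 <- cb2$db
  dP1 <- cb2$dM
  dA1 <- pool_backward(dP1, ch$p1$chosen, ch$pool1, nrow(ch$A1))
  dY1 <- dA1 * (ch$c1$Y > 0)
  cb1 <- conv_backward(dY1, ch$c1$M_aug, params$Wc1, ch$idx1)
  g$Wc1 <- cb1$dW
  g$bc1 <- cb1$db
  g
}

# Adam over the (nested) parameter list.
adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  grads <- grads[names(params)]
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

#' Training configuration for the patch classifier
#'
#' @param epochs passes over the training set.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param seed RNG seed controlling initialization, shuffling and dropout;
#'   the same seed and data reproduce the run exactly.
#' @param verbose print per-epoch loss.
#' @return A list of training settings.
#' @export
train_config <- function(epochs = 30, learning_rate = 1e-3, batch_size = 64,
                         seed = 1, verbose = FALSE) {
  list(epochs = epochs, learning_rate = learning_rate,
       batch_size = batch_size, seed = seed, verbose = verbose)
}

#' Train the patch-classification network
#'
#' Minimizes the softmax cross-entropy over labelled 16x16 patches with
#' Adam. Training is reproducible given the seed in `config`.
#'
#' @param spec a [classifier_spec()].
#' @param patches `16 x 16 x N` array of training patches in `[0, 1]`.
#' @param labels integer vector of length `N`, values in
#'   `1..spec$n_categories`; every category must have at least one example.
#' @param config a [train_config()].
#' @return An object of class `patch_classifier` with elements `params`,
#'   `spec`, `train_accuracy`, `final_loss` and `loss_history`.
#' @export
train_classifier <- function(spec, patches, labels, config = train_config()) {
  stopifnot(inherits(spec, "classifier_spec"))
  stopifnot(length(dim(patches)) == 3,
            dim(patches)[1] == spec$input, dim(patches)[2] == spec$input)
  N <- dim(patches)[3]
  labels <- as.integer(labels)
  if (length(labels) != N) stop("labels length must match patch count")
  if (any(labels < 1L | labels > spec$n_categories))
    stop("labels must lie in 1..n_categories")
  if (length(unique(labels)) < spec$n_categories)
    stop("training-data error: every category needs at least one example")

  with_seed(config$seed, {
    params <- nn_init(spec)
    state <- adam_init(params)
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(N)
      bl <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_loss <- 0
      for (b in bl) {
        fwd <- nn_forward(params, spec, patches[, , b, drop = FALSE],
                          train = TRUE)
        p_true <- fwd$P[cbind(seq_along(b), labels[b])]
        ep_loss <- ep_loss + sum(-log(pmax(p_true, 1e-12)))
        grads <- nn_backward(params, spec, fwd, labels[b])
        st <- adam_step(params, grads, state, config$learning_rate)
        params <- st$params
        state <- st$state
      }
      losses[ep] <- ep_loss / N
      if (config$verbose)
        message(sprintf("epoch %d/%d  loss %.5f", ep, config$epochs, losses[ep]))
    }
    model <- structure(list(params = params, spec = spec,
                            final_loss = losses[config$epochs],
                            loss_history = losses),
                       class = "patch_classifier")
    pred <- classify_patches(model, patches)
    model$train_accuracy <- mean(pred$category == labels)
    model
  })
}

#' Classify feature patches
#'
#' Runs the trained network in inference mode (dropout disabled, fully
#' deterministic). The category is the argmax of the softmax vector and the
#' probability is that maximum.
#'
#' @param model a trained [train_classifier()] model.
#' @param patch a single 16x16 matrix (`classify_patch`) or a
#'   `16 x 16 x N` array (`classify_patches`).
#' @return `classify_patch()` returns `list(category, probability)`;
#'   `classify_patches()` a data frame with columns `category` and
#'   `probability` plus the full probability matrix as attribute `"probs"`.
#' @export
classify_patch <- function(model, patch) {
  stopifnot(is.matrix(patch))
  if (!all(dim(patch) == model$spec$input))
    stop("patch must be ", model$spec$input, "x", model$spec$input)
  res <- classify_patches(model, array(patch, dim = c(dim(patch), 1)))
  list(category = res$category[1], probability = res$probability[1])
}

#' @rdname classify_patch
#' @param patches `16 x 16 x N` array.
#' @export
classify_patches <- function(model, patches) {
  stopifnot(inherits(model, "patch_classifier"), length(dim(patches)) == 3)
  N <- dim(patches)[3]
  chunks <- split(seq_len(N), ceiling(seq_len(N) / 256))
  cat_out <- integer(N); prob_out <- numeric(N)
  probs <- matrix(0, N, model$spec$n_categories)
  for (b in chunks) {
    P <- nn_forward(model$params, model$spec,
                    patches[, , b, drop = FALSE])$P
    probs[b, ] <- P
    cat_out[b] <- max.col(P, ties.method = "first")
    prob_out[b] <- P[cbind(seq_along(b), cat_out[b])]
  }
  out <- data.frame(category = cat_out, probability = prob_out)
  attr(out, "probs") <- probs
  out
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf("<patch_classifier> %d categories, conv %d/%d, fc %d; train acc %.3f\n",
              x$spec$n_categories, x$spec$conv1, x$spec$conv2, x$spec$fc,
              x$train_accuracy %||% NA))
  invisible(x)
}

#' Save / load a trained classifier
#'
#' The model is stored in R's native serialization with a JSON sidecar
#' (`<path>.json`) recording the category count and, when supplied, the
#' category definitions (selection threshold, link radius and reference
#' positions) so a checkpoint is self-describing.
#'
#' @param model a `patch_classifier`.
#' @param path checkpoint path (`.rds` recommended).
#' @param manifest optional list stored in the JSON sidecar.
#' @return `save_classifier()` returns `path`; `load_classifier()` the model
#'   (with the manifest, if present, attached as attribute `"manifest"`).
#' @export
save_classifier <- function(model, path, manifest = NULL) {
  stopifnot(inherits(model, "patch_classifier"))
  atomic_write(path, function(tmp) saveRDS(model, tmp))
  side <- c(list(n_categories = model$spec$n_categories), manifest)
  atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(side, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(model, "manifest") <- jsonlite::read_json(side, simplifyVector = TRUE)
  model
}
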