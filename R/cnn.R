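#' Configuration of the two-branch grid CNN
#'
#' The classifier consumes a 5 x 5 grid of principal-component scores and
#' applies, in parallel, 64 valid-mode 4 x 4 filters (giving a 2 x 2 x 64
#' map) and 64 valid-mode 2 x 2 filters (4 x 4 x 64), each followed by a
#' rectified-linear activation. The flattened branch outputs
#' (256 + 1024 = 1280 units) feed two fully connected layers of width 64
#' with inverted dropout (rate 0.5), then a softmax over `n_classes`.
#' Training is plain stochastic gradient descent with momentum on the
#' softmax cross-entropy, batch size 32, momentum 0.9, learning rate 0.01.
#'
#' The epoch budget and patience are artifact choices (the reference method
#' states none): training stops at `max_epochs` or after `patience` epochs
#' without validation-accuracy improvement, and the best-validation
#' parameters are retained.
#'
#' @param n_classes 2 (binary) or 9 (all stages).
#' @param filters_per_branch Filters per convolution branch (64).
#' @param fc_width Width of the two fully connected layers (64).
#' @param dropout_rate Dropout probability on the FC layers, in `[0, 1)`.
#' @param batch_size,momentum,learning_rate SGD hyperparameters.
#' @param max_epochs,patience Early-stopping budget.
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout; identical seeds give bitwise-identical runs.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(n_classes, filters_per_branch = 64L, fc_width = 64L,
                       dropout_rate = 0.5, batch_size = 32L, momentum = 0.9,
                       learning_rate = 0.01, max_epochs = 200L,
                       patience = 20L, seed = 1L) {
  if (!n_classes %in% c(2L, 9L)) {
    stopf("n_classes must be 2 or 9, got %s", n_classes)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stopf("dropout_rate must be in [0, 1)")
  }
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  structure(
    list(n_classes = as.integer(n_classes),
         filters_per_branch = as.integer(filters_per_branch),
         branch_kernel_sizes = c(4L, 2L),
         fc_width = as.integer(fc_width), fc_layers = 2L,
         dropout_rate = dropout_rate, batch_size = as.integer(batch_size),
         momentum = momentum, learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
}

# Patch-extraction index tables for valid-mode convolution on the 5x5 grid
# (column-major linear indices). Rows = output positions, columns = the
# k*k linear offsets of one receptive field.
conv_index <- function(k, side = 5L) {
  npos <- side - k + 1L
  pos <- expand.grid(i = seq_len(npos), j = seq_len(npos))
  off <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L))
  idx <- matrix(0L, nrow(pos), k * k)
  for (p in seq_len(nrow(pos))) {
    idx[p, ] <- (pos$j[p] + off$dc - 1L) * side + (pos$i[p] + off$dr)
  }
  idx
}

CONV_IDX_4 <- conv_index(4L)   # 4 positions x 16 offsets
CONV_IDX_2 <- conv_index(2L)   # 16 positions x 4 offsets

# Stack receptive-field patches for a batch: X is n x 25, result is
# (n * npos) x klen with position-major row blocks of size n.
conv_patches <- function(X, idx) {
  do.call(rbind, lapply(seq_len(nrow(idx)),
                        function(p) X[, idx[p, ], drop = FALSE]))
}

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / nrow)), nrow, ncol)
}

#' Build an untrained grid CNN
#'
#' Allocates and seed-initializes all parameters of the architecture
#' described in [cnn_config] (He-scaled normal weights, zero biases).
#'
#' @param config A `cnn_config`.
#' @return An untrained `cnn_model`.
#' @export
build_cnn <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  f <- config$filters_per_branch
  w <- config$fc_width
  k <- config$n_classes
  params <- with_seed(config$seed, list(
    W1 = he_init(16L, f), b1 = numeric(f),       # 4x4 branch
    W2 = he_init(4L, f),  b2 = numeric(f),       # 2x2 branch
    W3 = he_init(4L * f + 16L * f, w), b3 = numeric(w),
    W4 = he_init(w, w), b4 = numeric(w),
    W5 = he_init(w, k), b5 = numeric(k)
  ))
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL), class = "cnn_model")
}

#' Total trainable parameter count of a model
#' @param model A `cnn_model`.
#' @return Integer count over all weight matrices and bias vectors.
#' @export
cnn_n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

relu <- function(x) x * (x > 0)

add_bias <- function(x, b) x + rep(b, each = nrow(x))

# Forward pass. masks: NULL (inference / no dropout) or list(m1, m2) of
# pre-scaled inverted-dropout masks matching the FC activations.
cnn_forward <- function(params, X, masks = NULL) {
  n <- nrow(X)
  P1 <- conv_patches(X, CONV_IDX_4)
  Z1 <- add_bias(P1 %*% params$W1, params$b1)
  C1 <- relu(Z1)
  A1 <- matrix(C1, n, ncol(Z1) * nrow(CONV_IDX_4))
  P2 <- conv_patches(X, CONV_IDX_2)
  Z2 <- add_bias(P2 %*% params$W2, params$b2)
  C2 <- relu(Z2)
  A2 <- matrix(C2, n, ncol(Z2) * nrow(CONV_IDX_2))
  A <- cbind(A1, A2)
  H1p <- add_bias(A %*% params$W3, params$b3)
  H1 <- relu(H1p)
  H1d <- if (is.null(masks)) H1 else H1 * masks$m1
  H2p <- add_bias(H1d %*% params$W4, params$b4)
  H2 <- relu(H2p)
  H2d <- if (is.null(masks)) H2 else H2 * masks$m2
  logits <- add_bias(H2d %*% params$W5, params$b5)
  lmax <- apply(logits, 1, max)
  e <- exp(logits - lmax)
  probs <- e / rowSums(e)
  list(P1 = P1, Z1 = Z1, P2 = P2, Z2 = Z2, A = A, H1p = H1p, H1d = H1d,
       H2p = H2p, H2d = H2d, probs = probs, n = n)
}

# Mean cross-entropy loss and analytical gradients for one batch.
# y is 0-based integer labels.
cnn_loss_grads <- function(params, X, y, masks = NULL) {
  fw <- cnn_forward(params, X, masks)
  n <- fw$n
  k <- ncol(fw$probs)
  picked <- fw$probs[cbind(seq_len(n), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlog <- fw$probs
  dlog[cbind(seq_len(n), y + 1L)] <- dlog[cbind(seq_len(n), y + 1L)] - 1
  dlog <- dlog / n
  g <- list()
  g$W5 <- crossprod(fw$H2d, dlog); g$b5 <- colSums(dlog)
  dH2d <- dlog %*% t(params$W5)
  dH2 <- if (is.null(masks)) dH2d else dH2d * masks$m2
  dH2p <- dH2 * (fw$H2p > 0)
  g$W4 <- crossprod(fw$H1d, dH2p); g$b4 <- colSums(dH2p)
  dH1d <- dH2p %*% t(params$W4)
  dH1 <- if (is.null(masks)) dH1d else dH1d * masks$m1
  dH1p <- dH1 * (fw$H1p > 0)
  g$W3 <- crossprod(fw$A, dH1p); g$b3 <- colSums(dH1p)
  dA <- dH1p %*% t(params$W3)
  n1 <- ncol(params$W1) * nrow(CONV_IDX_4)
  dC1 <- matrix(dA[, seq_len(n1)], nrow(fw$Z1), ncol(fw$Z1)) * (fw$Z1 > 0)
  g$W1 <- crossprod(fw$P1, dC1); g$b1 <- colSums(dC1)
  dC2 <- matrix(dA[, -seq_len(n1)], nrow(fw$Z2), ncol(fw$Z2)) * (fw$Z2 > 0)
  g$W2 <- crossprod(fw$P2, dC2); g$b2 <- colSums(dC2)
  list(loss = loss, grads = g)
}

# Coerce grids input: n x 25 matrix of grid-flattened rows, or a list of
# 5x5 pc_grid matrices.
as_grid_matrix <- function(grids) {
  if (is.matrix(grids) && ncol(grids) == 25L) return(grids)
  if (is.list(grids)) {
    return(do.call(rbind, lapply(grids, function(g) as.numeric(g))))
  }
  stopf("grids must be an n x 25 matrix or a list of 5 x 5 grids")
}

check_labels <- function(y, k) {
  y <- as.integer(y)
  if (any(y < 0L | y >= k)) {
    stopf("labels must lie in 0..%d", k - 1L)
  }
  y
}

#' Train the grid CNN
#'
#' Seeded SGD with momentum on the softmax cross-entropy. Per epoch the
#' training rows are reshuffled, inverted-dropout masks are redrawn per
#' batch, and validation accuracy (dropout disabled) is evaluated; the
#' parameters with the best validation accuracy seen so far are retained.
#' Training stops at `max_epochs` or once `patience` epochs pass without
#' improvement. All randomness derives from `config$seed`, so two runs
#' with identical seed and data are identical.
#'
#' @param model An (untrained or trained) `cnn_model`; its parameters are
#'   the starting point.
#' @param train_grids,val_grids n x 25 matrices of grid-flattened rows (or
#'   lists of 5 x 5 grids); the two sets must be disjoint.
#' @param train_labels,val_labels Integer labels in `0..n_classes-1`.
#' @return The trained `cnn_model` with `$history` (per-epoch mean training
#'   loss and validation accuracy) and `$trained = TRUE`.
#' @export
train_cnn <- function(model, train_grids, train_labels,
                      val_grids, val_labels) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  X <- as_grid_matrix(train_grids)
  Xv <- as_grid_matrix(val_grids)
  if (nrow(X) == 0) stopf("empty training set")
  y <- check_labels(train_labels, cfg$n_classes)
  yv <- check_labels(val_labels, cfg$n_classes)
  stopifnot(length(y) == nrow(X), length(yv) == nrow(Xv))
  rate <- cfg$dropout_rate
  params <- model$params
  vel <- lapply(params, function(p) p * 0)
  best <- list(acc = -Inf, params = params)
  hist_loss <- numeric(0); hist_acc <- numeric(0)
  stall <- 0L

  with_seed(derive_seed(cfg$seed, 1L), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(X))
      losses <- numeric(0)
      for (start in seq(1L, nrow(X), by = cfg$batch_size)) {
        rows <- ord[start:min(start + cfg$batch_size - 1L, nrow(X))]
        nb <- length(rows)
        masks <- if (rate > 0) {
          keep <- 1 - rate
          list(
            m1 = matrix(stats::rbinom(nb * cfg$fc_width, 1L, keep) / keep,
                        nb, cfg$fc_width),
            m2 = matrix(stats::rbinom(nb * cfg$fc_width, 1L, keep) / keep,
                        nb, cfg$fc_width))
        } else NULL
        lg <- cnn_loss_grads(params, X[rows, , drop = FALSE], y[rows], masks)
        losses <- c(losses, lg$loss)
        for (nm in names(params)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] -
            cfg$learning_rate * lg$grads[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
      }
      pv <- cnn_forward(params, Xv)$probs
      acc <- mean(max.col(pv, ties.method = "first") - 1L == yv)
      hist_loss <- c(hist_loss, mean(losses))
      hist_acc <- c(hist_acc, acc)
      if (acc > best$acc) {
        best <- list(acc = acc, params = params)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_along(hist_loss),
                              train_loss = hist_loss, val_accuracy = hist_acc)
  model
}

#' Predict class probabilities and labels
#'
#' Inference pass with dropout disabled; repeated calls on the same model
#' and input agree bitwise. Argmax ties break toward the lowest class
#' index.
#'
#' @param model A trained `cnn_model`.
#' @param grids n x 25 matrix of grid-flattened rows or list of 5 x 5
#'   grids.
#' @return List with `probabilities` (n x K, rows summing to 1) and
#'   `labels` (0-based integer predictions).
#' @export
predict_cnn <- function(model, grids) {
  stopifnot(inherits(model, "cnn_model"))
  if (!isTRUE(model$trained)) stopf("model has not been trained")
  X <- as_grid_matrix(grids)
  probs <- cnn_forward(model$params, X)$probs
  list(probabilities = probs,
       labels = max.col(probs, ties.method = "first") - 1L)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> %d-class, %d parameters, %s (%d epochs recorded)\n",
    x$config$n_classes, cnn_n_params(x),
    if (x$trained) "trained" else "untrained",
    if (is.null(x$history)) 0L else nrow(x$history)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Plain-text JSON checkpoints embedding the configuration, parameters
#' (full precision) and training history.
#'
#' @param model A `cnn_model`.
#' @param path Checkpoint file.
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  obj <- list(
    format = "vibemg-cnn-1",
    config = unclass(model$config),
    trained = model$trained,
    history = model$history,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vibemg-cnn-1")) {
    stopf("'%s' is not a recognized model checkpoint", path)
  }
  cfg <- do.call(cnn_config, obj$config[c(
    "n_classes", "filters_per_branch", "fc_width", "dropout_rate",
    "batch_size", "momentum", "learning_rate", "max_epochs", "patience",
    "seed")])
  params <- lapply(obj$params, function(p) {
    if (is.null(p$dim) || length(p$dim) == 0) as.numeric(p$data)
    else matrix(as.numeric(p$data), p$dim[1], p$dim[2])
  })
  structure(list(config = cfg, params = params,
                 trained = isTRUE(obj$trained),
                 history = if (is.null(obj$history)) NULL
                           else as.data.frame(obj$history)),
            class = "cnn_model")
}
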