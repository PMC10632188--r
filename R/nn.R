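# From-scratch 1D convolutional regressor for sequence -> C0.
#
# No deep-learning framework is available to R in this stack, so forward and
# backward passes are implemented directly with base matrix algebra:
#   one-hot (n x 50 x 4)
#     -> conv blocks: 1D convolution + ReLU (+ optional max pooling)
#     -> global average pooling over the position axis
#     -> dense ReLU (+ inverted dropout during training)
#     -> linear output
# trained by Adam on mean squared error with a seeded 70/30 train/test split
# and early stopping on a validation slice of the training set. Global
# average pooling plays the position-aggregation role of the recurrent layer
# in larger frameworks; with one-hot input a kernel-2 convolution filter can
# realize an exact dinucleotide-step detector (ReLU(x_i + x_{i+1} - 1)), so
# the architecture contains additive dinucleotide models as a special case.

#' Neural network configuration
#'
#' @param conv_blocks list of numeric triples `(filters, kernel, pool)`;
#'   `pool = 1` disables pooling for that block.
#' @param dense_units units in the fully connected ReLU layer.
#' @param dropout dropout fraction on the dense layer during training.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (best weights are restored).
#' @param val_fraction fraction of the training split held out for early
#'   stopping.
#' @param seed RNG seed controlling the split, initialization, batch order
#'   and dropout. Same seed + same library = identical training trajectory
#'   on one platform.
#' @return an object of class `neural_net_config`.
#' @export
neural_net_config <- function(conv_blocks = list(c(filters = 32, kernel = 2, pool = 1),
                                                 c(filters = 16, kernel = 3, pool = 2)),
                              dense_units = 32, dropout = 0.1,
                              learning_rate = 1e-3, batch_size = 128,
                              max_epochs = 40, early_stop_patience = 5,
                              val_fraction = 0.1, seed = 42) {
  conv_blocks <- lapply(conv_blocks, function(bl) {
    bl <- as.numeric(bl)
    if (length(bl) != 3L) stop("each conv block is (filters, kernel, pool)")
    names(bl) <- c("filters", "kernel", "pool")
    if (any(bl < 1)) stop("conv block sizes must be >= 1")
    bl
  })
  stopifnot(dense_units >= 1, dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1, early_stop_patience >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(conv_blocks = conv_blocks, dense_units = as.integer(dense_units),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "neural_net_config")
}

# ---- tensor helpers (n x L x C arrays) -------------------------------------

.im2col <- function(X, k) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; C <- d[3L]
  L_out <- L - k + 1L
  M <- matrix(0, n * L_out, k * C)
  for (dt in seq_len(k)) {
    M[, ((dt - 1L) * C + 1L):(dt * C)] <-
      matrix(X[, dt:(dt + L_out - 1L), , drop = FALSE], n * L_out, C)
  }
  M
}

.col2im <- function(dM, dimX, k) {
  n <- dimX[1L]; L <- dimX[2L]; C <- dimX[3L]
  L_out <- L - k + 1L
  dX <- array(0, dimX)
  for (dt in seq_len(k)) {
    dX[, dt:(dt + L_out - 1L), ] <- dX[, dt:(dt + L_out - 1L), , drop = FALSE] +
      array(dM[, ((dt - 1L) * C + 1L):(dt * C)], c(n, L_out, C))
  }
  dX
}

.maxpool_fwd <- function(X, p) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; C <- d[3L]
  L2 <- L %/% p
  idx <- function(j) seq.int(j, L2 * p, by = p)
  Y <- X[, idx(1L), , drop = FALSE]
  for (j in 2:p) Y <- pmax(Y, X[, idx(j), , drop = FALSE])
  list(Y = Y, X = X, p = p)
}

.maxpool_bwd <- function(cache, dY) {
  X <- cache$X; p <- cache$p
  d <- dim(X); L2 <- d[2L] %/% p
  idx <- function(j) seq.int(j, L2 * p, by = p)
  Y <- X[, idx(1L), , drop = FALSE]
  for (j in 2:p) Y <- pmax(Y, X[, idx(j), , drop = FALSE])
  dX <- array(0, d)
  assigned <- array(FALSE, dim(Y))
  for (j in seq_len(p)) {
    S <- X[, idx(j), , drop = FALSE]
    mask <- (S == Y) & !assigned
    g <- array(0, dim(Y))
    g[mask] <- dY[mask]
    dX[, idx(j), ] <- g
    assigned <- assigned | mask
  }
  dX
}

# ---- parameter init / forward / backward -----------------------------------

.nn_init <- function(cfg, L = 50L, C = 4L) {
  params <- list()
  c_in <- C
  len <- L
  for (i in seq_along(cfg$conv_blocks)) {
    bl <- cfg$conv_blocks[[i]]
    k <- bl["kernel"]; f <- bl["filters"]
    fan_in <- k * c_in
    params[[paste0("Wc", i)]] <-
      matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f)
    params[[paste0("bc", i)]] <- rep(0, f)
    len <- len - k + 1L
    if (bl["pool"] > 1) len <- len %/% bl["pool"]
    if (len < 1L) stop("conv/pool stack consumes the whole sequence")
    c_in <- f
  }
  params$Wd <- matrix(stats::rnorm(c_in * cfg$dense_units,
                                   sd = sqrt(2 / c_in)), c_in, cfg$dense_units)
  params$bd <- rep(0, cfg$dense_units)
  params$Wo <- matrix(stats::rnorm(cfg$dense_units, sd = sqrt(1 / cfg$dense_units)),
                      cfg$dense_units, 1L)
  params$bo <- 0
  params
}

.nn_forward <- function(params, cfg, X, train = FALSE, dropout_mask = NULL) {
  caches <- list()
  A <- X
  for (i in seq_along(cfg$conv_blocks)) {
    bl <- cfg$conv_blocks[[i]]
    k <- bl["kernel"]; f <- bl["filters"]
    M <- .im2col(A, k)
    Z <- sweep(M %*% params[[paste0("Wc", i)]], 2L,
               params[[paste0("bc", i)]], "+")
    R <- Z * (Z > 0)
    L_out <- dim(A)[2L] - k + 1L
    Aconv <- array(R, c(dim(A)[1L], L_out, f))
    cache <- list(M = M, Z = Z, dimA = dim(A), k = k)
    if (bl["pool"] > 1) {
      pc <- .maxpool_fwd(Aconv, bl["pool"])
      cache$pool <- pc
      A <- pc$Y
    } else {
      A <- Aconv
    }
    caches[[i]] <- cache
  }
  # global average pooling over the position axis
  dGAP <- dim(A)
  G <- matrix(0, dGAP[1L], dGAP[3L])
  for (f in seq_len(dGAP[3L])) G[, f] <- rowMeans(A[, , f, drop = FALSE])
  H0 <- sweep(G %*% params$Wd, 2L, params$bd, "+")
  H <- H0 * (H0 > 0)
  if (train && cfg$dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::runif(length(H)) >= cfg$dropout,
                             nrow(H), ncol(H)) / (1 - cfg$dropout)
    }
    H <- H * dropout_mask
  }
  yhat <- drop(H %*% params$Wo) + params$bo
  list(yhat = yhat, caches = caches, A_last = A, dGAP = dGAP, G = G,
       H0 = H0, H = H, dropout_mask = dropout_mask)
}

.nn_backward <- function(params, cfg, X, y, fwd) {
  n <- length(y)
  grads <- list()
  dy <- 2 * (fwd$yhat - y) / n                      # d MSE / d yhat
  grads$Wo <- crossprod(fwd$H, matrix(dy, ncol = 1L))
  grads$bo <- sum(dy)
  dH <- matrix(dy, ncol = 1L) %*% t(params$Wo)
  if (!is.null(fwd$dropout_mask)) dH <- dH * fwd$dropout_mask
  dH0 <- dH * (fwd$H0 > 0)
  grads$Wd <- crossprod(fwd$G, dH0)
  grads$bd <- colSums(dH0)
  dG <- dH0 %*% t(params$Wd)
  # backward through global average pooling
  dA <- array(0, fwd$dGAP)
  L_last <- fwd$dGAP[2L]
  for (f in seq_len(fwd$dGAP[3L])) {
    dA[, , f] <- matrix(dG[, f] / L_last, fwd$dGAP[1L], L_last)
  }
  for (i in rev(seq_along(cfg$conv_blocks))) {
    bl <- cfg$conv_blocks[[i]]
    cache <- fwd$caches[[i]]
    if (bl["pool"] > 1) dA <- .maxpool_bwd(cache$pool, dA)
    dR <- matrix(dA, nrow = nrow(cache$Z))
    dZ <- dR * (cache$Z > 0)
    grads[[paste0("Wc", i)]] <- crossprod(cache$M, dZ)
    grads[[paste0("bc", i)]] <- colSums(dZ)
    if (i > 1L) {
      dM <- dZ %*% t(params[[paste0("Wc", i)]])
      dA <- .col2im(dM, cache$dimA, cache$k)
    }
  }
  grads
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

new_neural_net_predictor <- function(params, config, provenance = list()) {
  structure(list(params = params, config = config, provenance = provenance,
                 kind = "neural"),
            class = c("neural_net_predictor", "flex_predictor"))
}

#' @export
print.neural_net_predictor <- function(x, ...) {
  blocks <- vapply(x$config$conv_blocks, function(b)
    sprintf("conv(f=%d,k=%d,pool=%d)", b[1], b[2], b[3]), character(1L))
  cat("<neural_net_predictor>", paste(blocks, collapse = " -> "),
      sprintf("-> GAP -> dense(%d) -> 1\n", x$config$dense_units))
  if (!is.null(x$provenance$test_pearson_r)) {
    cat(sprintf("  held-out r = %.3f, median |err| = %.3f (n_test = %d)\n",
                x$provenance$test_pearson_r,
                x$provenance$test_median_abs_distance, x$provenance$n_test))
  }
  invisible(x)
}

#' @export
score_raw.neural_net_predictor <- function(p, seqs) {
  out <- numeric(length(seqs))
  # chunk to bound the size of the one-hot tensor
  chunk <- 4096L
  for (s in seq.int(1L, length(seqs), by = chunk)) {
    e <- min(s + chunk - 1L, length(seqs))
    X <- one_hot_array(seqs[s:e])
    out[s:e] <- .nn_forward(p$params, p$config, X, train = FALSE)$yhat
  }
  out
}

#' Train the neural cyclizability regressor
#'
#' Strips adapters, one-hot encodes the 50-bp probes, splits the library
#' 70/30 into train and test with a seeded uniform random partition, and
#' minimizes the mean squared error with Adam. A validation slice of the
#' training split drives early stopping; the weights with the best
#' validation loss are restored. The held-out test set is scored with
#' reverse-complement averaging, as in downstream use.
#'
#' @param library data.frame with columns sequence (50 or 100 bp) and c0.
#' @param cfg a [neural_net_config()].
#' @param split fraction of the library used for training (default 0.7).
#' @return list with elements `predictor` (a `neural_net_predictor`) and
#'   `report`: n_train, n_test, loss_curve (train MSE per epoch), val_curve,
#'   test_pearson_r (NA and flagged when the targets are constant),
#'   test_median_abs_distance, epochs_run, seed.
#' @export
train_neural <- function(library, cfg = neural_net_config(), split = 0.7) {
  if (nrow(library) < 100L) stop("library must have >= 100 records")
  if (any(!is.finite(library$c0))) stop("non-finite c0 in training library")
  probes <- strip_adapters(library$sequence)
  if (any(nchar(probes) != 50L)) stop("probe sequences must be 50 bp")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  n <- length(probes)
  idx_train <- sort(sample.int(n, round(split * n)))
  idx_test <- setdiff(seq_len(n), idx_train)
  n_val <- max(1L, round(cfg$val_fraction * length(idx_train)))
  idx_val <- sort(sample(idx_train, n_val))
  idx_fit <- setdiff(idx_train, idx_val)

  Xfit <- one_hot_array(probes[idx_fit]);  yfit <- library$c0[idx_fit]
  Xval <- one_hot_array(probes[idx_val]);  yval <- library$c0[idx_val]

  params <- .nn_init(cfg)
  state <- list(m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  loss_curve <- numeric(0)
  val_curve <- numeric(0)
  tstep <- 0L
  nfit <- length(yfit)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(nfit)
    batch_losses <- numeric(0)
    for (s in seq.int(1L, nfit, by = cfg$batch_size)) {
      ids <- ord[s:min(s + cfg$batch_size - 1L, nfit)]
      Xb <- Xfit[ids, , , drop = FALSE]
      yb <- yfit[ids]
      fwd <- .nn_forward(params, cfg, Xb, train = TRUE)
      batch_losses <- c(batch_losses, mean((fwd$yhat - yb)^2))
      grads <- .nn_backward(params, cfg, Xb, yb, fwd)
      tstep <- tstep + 1L
      upd <- .adam_step(params, grads, state, cfg$learning_rate, tstep)
      params <- upd$params
      state <- upd$state
    }
    loss_curve <- c(loss_curve, mean(batch_losses))
    val_pred <- .nn_forward(params, cfg, Xval, train = FALSE)$yhat
    val_loss <- mean((val_pred - yval)^2)
    val_curve <- c(val_curve, val_loss)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$early_stop_patience) {
      break
    }
  }

  predictor <- new_neural_net_predictor(best$params, cfg)
  test_lib <- data.frame(sequence = probes[idx_test], c0 = library$c0[idx_test])
  ev <- evaluate_predictor(predictor, test_lib)
  predictor$provenance <- list(n_train = length(idx_train),
                               n_test = length(idx_test),
                               test_pearson_r = ev$pearson_r,
                               test_median_abs_distance = ev$median_abs_distance,
                               seed = cfg$seed)
  report <- list(n_train = length(idx_train), n_test = length(idx_test),
                 loss_curve = loss_curve, val_curve = val_curve,
                 test_pearson_r = ev$pearson_r, r_defined = ev$r_defined,
                 test_median_abs_distance = ev$median_abs_distance,
                 epochs_run = length(loss_curve), seed = cfg$seed)
  list(predictor = predictor, report = report)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
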