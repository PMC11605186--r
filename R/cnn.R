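#' Configuration of the sequence-only convolutional baseline
#'
#' A small 1-D convolutional classifier over the 41 x 4 one-hot window:
#' two convolution blocks (kernel 5; 32 then 64 channels; ReLU), global
#' max-pooling over positions, and a dense sigmoid output. Trained with
#' the same recipe as the deep cross network (Adam, BCE, batch 64,
#' 10 epochs).
#'
#' @param kernel convolution kernel width (positions).
#' @param channels integer vector of the two block widths.
#' @param learning_rate,epochs,batch_size training recipe.
#' @param adam_beta1,adam_beta2,adam_eps Adam constants.
#' @param seed integer seed.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(kernel = 5L, channels = c(32L, 64L),
                       learning_rate = 0.001, epochs = 10L, batch_size = 64L,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       adam_eps = 1e-8, seed = 1L) {
  stopifnot(kernel >= 1L, length(channels) == 2L, all(channels >= 1L))
  structure(list(kernel = as.integer(kernel),
                 channels = as.integer(channels),
                 n_pos = 41L, n_base = 4L,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Initialize the convolutional baseline
#'
#' @param config a [cnn_config()].
#' @return A `cnn_model`: list(params, config) with kernel matrices `W1`
#'   (kernel*4 x ch1), `W2` (kernel*ch1 x ch2), dense `w_out`, and biases.
#' @export
cnn_init <- function(config) {
  k <- config$kernel; ch <- config$channels
  f1 <- k * config$n_base
  f2 <- k * ch[1]
  params <- list(
    W1 = matrix(stats::runif(f1 * ch[1], -sqrt(1 / f1), sqrt(1 / f1)), f1),
    b1 = numeric(ch[1]),
    W2 = matrix(stats::runif(f2 * ch[2], -sqrt(1 / f2), sqrt(1 / f2)), f2),
    b2 = numeric(ch[2]),
    w_out = matrix(stats::runif(ch[2], -sqrt(1 / ch[2]), sqrt(1 / ch[2]))),
    b_out = 0
  )
  structure(list(params = params, config = config), class = "cnn_model")
}

# forward pass caching everything backprop needs; X is N x 164,
# position-major (pos1 A,C,G,U, pos2 ...)
.cnn_forward_cache <- function(model, X) {
  P <- model$params; cfg <- model$config
  k <- cfg$kernel; ch <- cfg$channels
  n <- nrow(X)
  L1 <- cfg$n_pos - k + 1L
  L2 <- L1 - k + 1L
  Z1 <- matrix(0, n, L1 * ch[1])
  for (p in seq_len(L1)) {
    xc <- ((p - 1L) * cfg$n_base + 1L):((p + k - 1L) * cfg$n_base)
    Z1[, ((p - 1L) * ch[1] + 1L):(p * ch[1])] <-
      sweep(X[, xc, drop = FALSE] %*% P$W1, 2L, P$b1, "+")
  }
  A1 <- pmax(Z1, 0)
  Z2 <- matrix(0, n, L2 * ch[2])
  for (p in seq_len(L2)) {
    ac <- ((p - 1L) * ch[1] + 1L):((p + k - 1L) * ch[1])
    Z2[, ((p - 1L) * ch[2] + 1L):(p * ch[2])] <-
      sweep(A1[, ac, drop = FALSE] %*% P$W2, 2L, P$b2, "+")
  }
  A2 <- pmax(Z2, 0)
  pooled <- matrix(0, n, ch[2])
  argmax <- matrix(0L, n, ch[2])
  for (cc in seq_len(ch[2])) {
    sub <- A2[, seq(cc, by = ch[2], length.out = L2), drop = FALSE]
    am <- max.col(sub, ties.method = "first")
    argmax[, cc] <- am
    pooled[, cc] <- sub[cbind(seq_len(n), am)]
  }
  out <- as.numeric(pooled %*% P$w_out) + P$b_out
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, pooled = pooled,
       argmax = argmax, out = out, p = sigmoid(out))
}

#' Predict probabilities with the convolutional baseline
#'
#' @param model a `cnn_model`.
#' @param X N x 164 one-hot matrix (position-major layout of
#'   [one_hot_matrix()]).
#' @return Length-N probability vector in (0,1).
#' @export
cnn_predict <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  .cnn_forward_cache(model, X)$p
}

#' Gradients of the mean BCE loss for the convolutional baseline
#'
#' @param model a `cnn_model`.
#' @param X N x 164 matrix; `y` binary labels.
#' @param y binary labels.
#' @return list(grads, loss, p).
#' @export
cnn_gradients <- function(model, X, y) {
  P <- model$params; cfg <- model$config
  k <- cfg$kernel; ch <- cfg$channels
  n <- nrow(X)
  L1 <- cfg$n_pos - k + 1L
  L2 <- L1 - k + 1L
  fc <- .cnn_forward_cache(model, X)
  dout <- matrix((fc$p - y) / n, ncol = 1L)
  g <- list()
  g$w_out <- t(fc$pooled) %*% dout
  g$b_out <- sum(dout)
  dpooled <- dout %*% t(P$w_out)
  dA2 <- matrix(0, n, L2 * ch[2])
  for (cc in seq_len(ch[2])) {
    cols <- (fc$argmax[, cc] - 1L) * ch[2] + cc
    dA2[cbind(seq_len(n), cols)] <- dA2[cbind(seq_len(n), cols)] +
      dpooled[, cc]
  }
  dZ2 <- dA2 * (fc$Z2 > 0)
  g$W2 <- matrix(0, nrow(P$W2), ncol(P$W2)); g$b2 <- numeric(ch[2])
  dA1 <- matrix(0, n, L1 * ch[1])
  for (p in seq_len(L2)) {
    oc <- ((p - 1L) * ch[2] + 1L):(p * ch[2])
    ac <- ((p - 1L) * ch[1] + 1L):((p + k - 1L) * ch[1])
    dZ2p <- dZ2[, oc, drop = FALSE]
    g$W2 <- g$W2 + t(fc$A1[, ac, drop = FALSE]) %*% dZ2p
    g$b2 <- g$b2 + colSums(dZ2p)
    dA1[, ac] <- dA1[, ac] + dZ2p %*% t(P$W2)
  }
  dZ1 <- dA1 * (fc$Z1 > 0)
  g$W1 <- matrix(0, nrow(P$W1), ncol(P$W1)); g$b1 <- numeric(ch[1])
  for (p in seq_len(L1)) {
    oc <- ((p - 1L) * ch[1] + 1L):(p * ch[1])
    xc <- ((p - 1L) * cfg$n_base + 1L):((p + k - 1L) * cfg$n_base)
    dZ1p <- dZ1[, oc, drop = FALSE]
    g$W1 <- g$W1 + t(X[, xc, drop = FALSE]) %*% dZ1p
    g$b1 <- g$b1 + colSums(dZ1p)
  }
  list(grads = g[names(P)], loss = bce_loss(y, fc$p), p = fc$p)
}

#' Train the convolutional sequence baseline
#'
#' Same recipe as [dcn_train()]: seeded mini-batch Adam on mean BCE with
#' per-epoch shuffling and minimum-validation-loss checkpointing.
#'
#' @param X_train,y_train,X_val,y_val data splits (one-hot matrices).
#' @param config a [cnn_config()].
#' @param select `"best_val"` or `"last"`.
#' @return list(model, history, best_epoch).
#' @export
cnn_train <- function(X_train, y_train, X_val, y_val, config,
                      select = c("best_val", "last")) {
  select <- match.arg(select)
  if (length(unique(y_train)) < 2L)
    ecn_stop("training split must contain both classes", "training_error")
  set.seed(stage_seed(config$seed, "train_cnn"))
  model <- cnn_init(config)
  state <- adam_init(model$params)
  n <- nrow(X_train); bs <- config$batch_size
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- list(val = Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- c(); sizes <- c()
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      gr <- cnn_gradients(model, X_train[idx, , drop = FALSE], y_train[idx])
      upd <- adam_step(model$params, gr$grads, state, config$learning_rate,
                       config$adam_beta1, config$adam_beta2, config$adam_eps)
      model$params <- upd$params
      state <- upd$state
      losses <- c(losses, gr$loss); sizes <- c(sizes, length(idx))
    }
    val_loss <- bce_loss(y_val, cnn_predict(model, X_val))
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = sum(losses * sizes) / sum(sizes),
                                   val_loss = val_loss))
    if (val_loss < best$val)
      best <- list(val = val_loss, params = model$params, epoch = ep)
  }
  if (select == "best_val") model$params <- best$params
  list(model = model, history = hist,
       best_epoch = if (select == "best_val") best$epoch else config$epochs)
}
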