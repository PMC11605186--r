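#' Deep cross network configuration
#'
#' Hyperparameters of the deep cross network (DCN): an affine embedding to
#' `embedding_dim`, a deep ReLU stack whose final layer compresses to one
#' dimension, one cross layer (elementwise square + linear map + residual)
#' with a learned scalar projection, and a sigmoid over the summed branch
#' outputs. Defaults follow the training recipe used throughout the
#' package: embedding 128, hidden width 64, Adam at learning rate 0.001,
#' 10 epochs, batch size 64.
#'
#' @param input_dim input width (216 for the integrated model: 41x4
#'   flattened one-hot + 52 genomic features; 164 sequence-only; 52
#'   genomic-only).
#' @param embedding_dim embedding width.
#' @param hidden_dims deep-stack widths; must end in 1.
#' @param learning_rate,epochs,batch_size Adam/SGD recipe.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and stability
#'   constant.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return A `dcn_config` list.
#' @export
dcn_config <- function(input_dim, embedding_dim = 128L,
                       hidden_dims = c(64L, 64L, 1L),
                       learning_rate = 0.001, epochs = 10L, batch_size = 64L,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       adam_eps = 1e-8, seed = 1L) {
  if (any(c(input_dim, embedding_dim, hidden_dims, batch_size) < 1L))
    ecn_stop("all dimensions must be positive", "parameter_error")
  if (utils::tail(hidden_dims, 1L) != 1L)
    ecn_stop("hidden_dims must end in 1 (scalar deep output)",
             "parameter_error")
  if (learning_rate <= 0 || epochs < 1L)
    ecn_stop("need learning_rate > 0 and epochs >= 1", "parameter_error")
  structure(list(input_dim = as.integer(input_dim),
                 embedding_dim = as.integer(embedding_dim),
                 hidden_dims = as.integer(hidden_dims),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "dcn_config")
}

# fan-in scaled uniform init for a (out x in) weight matrix
.init_w <- function(n_out, n_in) {
  s <- sqrt(1 / n_in)
  matrix(stats::runif(n_out * n_in, -s, s), nrow = n_out)
}

#' Initialize a deep cross network
#'
#' Draws fan-in-scaled uniform weights (biases zero) from the current RNG
#' stream; call under a seeded stream for reproducibility.
#'
#' @param config a [dcn_config()].
#' @return A `cross_net_model`: list(params, config), where `params` holds
#'   `W_embed`, `b_embed`, per-deep-layer `deep_W<l>`/`deep_b<l>`,
#'   `W_cross`, `b_cross`, `W_proj`, `b_proj`.
#' @export
dcn_init <- function(config) {
  e <- config$embedding_dim
  params <- list(W_embed = .init_w(e, config$input_dim),
                 b_embed = numeric(e))
  prev <- e
  for (l in seq_along(config$hidden_dims)) {
    w <- config$hidden_dims[l]
    params[[paste0("deep_W", l)]] <- .init_w(w, prev)
    params[[paste0("deep_b", l)]] <- numeric(w)
    prev <- w
  }
  params$W_cross <- .init_w(e, e)
  params$b_cross <- numeric(e)
  params$W_proj <- .init_w(1L, e)
  params$b_proj <- 0
  structure(list(params = params, config = config),
            class = "cross_net_model")
}

#' Embedding layer forward pass
#'
#' Affine map of the input into the embedding space:
#' `x_embed = W_embed x + b_embed`.
#'
#' @param model a `cross_net_model`.
#' @param x input matrix (N x input_dim) or a single vector.
#' @return N x embedding_dim matrix.
#' @export
dcn_embed <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(model$params$W_embed))
    ecn_stop("input width does not match embedding weights",
             "contract_violation")
  sweep(x %*% t(model$params$W_embed), 2L, model$params$b_embed, "+")
}

#' Deep branch forward pass
#'
#' Alternating affine maps and ReLU activations through the hidden stack;
#' the final affine layer has width 1 and no ReLU after it.
#'
#' @param model a `cross_net_model`.
#' @param x_embed N x embedding_dim matrix.
#' @return Length-N numeric vector of deep-branch scores.
#' @export
dcn_deep_forward <- function(model, x_embed) {
  if (is.vector(x_embed)) x_embed <- matrix(x_embed, nrow = 1L)
  h <- x_embed
  nl <- length(model$config$hidden_dims)
  for (l in seq_len(nl)) {
    z <- sweep(h %*% t(model$params[[paste0("deep_W", l)]]), 2L,
               model$params[[paste0("deep_b", l)]], "+")
    h <- if (l < nl) pmax(z, 0) else z
  }
  as.numeric(h)
}

#' Cross branch forward pass
#'
#' The feature-crossing transformation
#' `x_cross = W_cross (x_embed * x_embed) + b_cross + x_embed`
#' (elementwise square, linear map, bias, residual add). With zero weights
#' and bias it is the identity on its input.
#'
#' @param model a `cross_net_model`.
#' @param x_embed N x embedding_dim matrix.
#' @return N x embedding_dim matrix.
#' @export
dcn_cross_forward <- function(model, x_embed) {
  if (is.vector(x_embed)) x_embed <- matrix(x_embed, nrow = 1L)
  sweep((x_embed * x_embed) %*% t(model$params$W_cross), 2L,
        model$params$b_cross, "+") + x_embed
}

#' Predicted probability of the positive class
#'
#' Composes the branches: the deep-branch scalar plus a learned scalar
#' projection of the cross-branch output, pushed through a sigmoid.
#'
#' @param model a `cross_net_model`.
#' @param x input matrix (N x input_dim) or single vector.
#' @return Length-N vector of probabilities in (0,1).
#' @export
dcn_predict <- function(model, x) {
  pars <- unlist(model$params, use.names = FALSE)
  if (any(!is.finite(pars)))
    ecn_stop("model contains non-finite parameters", "numeric_error")
  e <- dcn_embed(model, x)
  s_deep <- dcn_deep_forward(model, e)
  cx <- dcn_cross_forward(model, e)
  s_cross <- as.numeric(cx %*% t(model$params$W_proj)) + model$params$b_proj
  sigmoid(s_deep + s_cross)
}

#' Binary cross-entropy loss
#'
#' `-[y log(p) + (1-y) log(1-p)]` with predictions clipped to
#' `[eps, 1-eps]` for numerical stability; the batch loss is the mean.
#'
#' @param y binary labels.
#' @param y_hat predicted probabilities.
#' @param eps clipping constant (default 1e-7).
#' @return Mean loss (nonnegative scalar).
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  p <- clip_prob(y_hat, eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

# full forward pass retaining intermediates needed by backprop
.dcn_forward_cache <- function(model, X) {
  P <- model$params
  nl <- length(model$config$hidden_dims)
  E <- sweep(X %*% t(P$W_embed), 2L, P$b_embed, "+")
  Hs <- vector("list", nl + 1L); Zs <- vector("list", nl)
  Hs[[1L]] <- E
  for (l in seq_len(nl)) {
    Zs[[l]] <- sweep(Hs[[l]] %*% t(P[[paste0("deep_W", l)]]), 2L,
                     P[[paste0("deep_b", l)]], "+")
    Hs[[l + 1L]] <- if (l < nl) pmax(Zs[[l]], 0) else Zs[[l]]
  }
  S <- E * E
  C <- sweep(S %*% t(P$W_cross), 2L, P$b_cross, "+") + E
  out <- as.numeric(Hs[[nl + 1L]]) +
    as.numeric(C %*% t(P$W_proj)) + P$b_proj
  list(E = E, Hs = Hs, Zs = Zs, S = S, C = C, out = out, p = sigmoid(out))
}

#' Gradients of the mean BCE loss for a deep cross network
#'
#' Analytic backpropagation through the sigmoid, both branches, and the
#' embedding. Returns gradients shaped exactly like `model$params`.
#'
#' @param model a `cross_net_model`.
#' @param X N x input_dim matrix.
#' @param y binary labels of length N.
#' @return list(grads, loss, p) with `grads` a named list matching the
#'   parameter layout.
#' @export
dcn_gradients <- function(model, X, y) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  P <- model$params
  nl <- length(model$config$hidden_dims)
  fc <- .dcn_forward_cache(model, X)
  n <- nrow(X)
  dout <- matrix((fc$p - y) / n, ncol = 1L) # d(mean BCE)/d(out)
  g <- list()
  # deep branch
  dH <- dout
  for (l in rev(seq_len(nl))) {
    dZ <- if (l < nl) dH * (fc$Zs[[l]] > 0) else dH
    g[[paste0("deep_W", l)]] <- t(dZ) %*% fc$Hs[[l]]
    g[[paste0("deep_b", l)]] <- colSums(dZ)
    dH <- dZ %*% P[[paste0("deep_W", l)]]
  }
  dE_deep <- dH
  # cross branch + projection
  g$W_proj <- t(dout) %*% fc$C
  g$b_proj <- sum(dout)
  dC <- dout %*% P$W_proj
  g$W_cross <- t(dC) %*% fc$S
  g$b_cross <- colSums(dC)
  dE_cross <- 2 * fc$E * (dC %*% P$W_cross) + dC
  # embedding
  dE <- dE_deep + dE_cross
  g$W_embed <- t(dE) %*% X
  g$b_embed <- colSums(dE)
  list(grads = g[names(P)], loss = bce_loss(y, fc$p), p = fc$p)
}

# ---- generic Adam optimizer over named parameter lists ---------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
  list(m = zero, v = zero, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- training --------------------------------------------------------------

#' Train a deep cross network
#'
#' Mini-batch Adam on the mean binary cross-entropy, with per-epoch
#' shuffling from a seeded stream. Records per-epoch mean train loss and
#' validation loss; the returned model carries the parameters of the epoch
#' with minimum validation loss (or the last epoch when
#' `select = "last"`).
#'
#' @param X_train,y_train training matrix and binary labels.
#' @param X_val,y_val validation matrix and labels.
#' @param config a [dcn_config()]; `input_dim` must match `ncol(X_train)`.
#' @param select checkpoint selection: `"best_val"` (default) or `"last"`.
#' @return list(model = `cross_net_model`, history = data.frame(epoch,
#'   train_loss, val_loss), best_epoch).
#' @export
dcn_train <- function(X_train, y_train, X_val, y_val, config,
                      select = c("best_val", "last")) {
  select <- match.arg(select)
  if (length(unique(y_train)) < 2L)
    ecn_stop("training split must contain both classes", "training_error")
  if (ncol(X_train) != config$input_dim)
    ecn_stop("config input_dim does not match the data", "contract_violation")
  set.seed(stage_seed(config$seed, "train"))
  model <- dcn_init(config)
  state <- adam_init(model$params)
  n <- nrow(X_train)
  bs <- config$batch_size
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- list(val = Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- c(); sizes <- c()
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      gr <- dcn_gradients(model, X_train[idx, , drop = FALSE], y_train[idx])
      upd <- adam_step(model$params, gr$grads, state, config$learning_rate,
                       config$adam_beta1, config$adam_beta2, config$adam_eps)
      model$params <- upd$params
      state <- upd$state
      losses <- c(losses, gr$loss); sizes <- c(sizes, length(idx))
    }
    train_loss <- sum(losses * sizes) / sum(sizes)
    val_loss <- bce_loss(y_val, dcn_predict(model, X_val))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = train_loss,
                                   val_loss = val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = model$params, epoch = ep)
    }
  }
  if (select == "best_val") model$params <- best$params
  list(model = model, history = hist,
       best_epoch = if (select == "best_val") best$epoch else config$epochs)
}

#' Train a model on an encoded dataset
#'
#' High-level entry point selecting the input representation by mode:
#' `"integrated"` concatenates the flattened one-hot block with the
#' normalized genomic features (sequence first), `"sequence_dcn"` uses only
#' the one-hot block through the DCN, `"genomic_only"` only the genomic
#' block, and `"sequence_cnn"` trains the convolutional sequence baseline.
#'
#' @param dataset an `encoded_dataset` from [encode_labeled_dataset()] or
#'   [assemble_dataset()].
#' @param mode input representation (see above).
#' @param config optional [dcn_config()] / [cnn_config()]; a default with
#'   the right `input_dim` is built when NULL.
#' @param seed seed used when building the default config.
#' @return list(model, history, mode, schema_hash) — a `trained_model`.
#' @export
train_model <- function(dataset,
                        mode = c("integrated", "sequence_cnn",
                                 "genomic_only", "sequence_dcn"),
                        config = NULL, seed = 1L) {
  mode <- match.arg(mode)
  tr <- dataset$split == "train"
  va <- dataset$split == "val"
  X <- switch(mode,
    integrated = cbind(dataset$one_hot, dataset$genomic),
    sequence_dcn = dataset$one_hot,
    sequence_cnn = dataset$one_hot,
    genomic_only = dataset$genomic)
  if (mode == "sequence_cnn") {
    if (is.null(config)) config <- cnn_config(seed = seed)
    fit <- cnn_train(X[tr, , drop = FALSE], dataset$labels[tr],
                     X[va, , drop = FALSE], dataset$labels[va], config)
  } else {
    if (is.null(config)) config <- dcn_config(input_dim = ncol(X), seed = seed)
    fit <- dcn_train(X[tr, , drop = FALSE], dataset$labels[tr],
                     X[va, , drop = FALSE], dataset$labels[va], config)
  }
  structure(list(model = fit$model, history = fit$history,
                 best_epoch = fit$best_epoch, mode = mode,
                 schema_hash = if (!is.null(dataset$schema))
                   schema_hash(dataset$schema) else NA_character_),
            class = "trained_model")
}

#' Predict with a trained model on an encoded dataset
#'
#' @param trained a `trained_model` from [train_model()].
#' @param dataset an `encoded_dataset`.
#' @param split which split to score ("test", "val", "train" or "all").
#' @return list(scores, labels) for the requested split.
#' @export
predict_split <- function(trained, dataset, split = "test") {
  idx <- if (split == "all") rep(TRUE, length(dataset$labels))
         else dataset$split == split
  X <- switch(trained$mode,
    integrated = cbind(dataset$one_hot, dataset$genomic),
    sequence_dcn = dataset$one_hot,
    sequence_cnn = dataset$one_hot,
    genomic_only = dataset$genomic)
  scores <- if (trained$mode == "sequence_cnn")
    cnn_predict(trained$model, X[idx, , drop = FALSE])
  else dcn_predict(trained$model, X[idx, , drop = FALSE])
  list(scores = scores, labels = dataset$labels[idx])
}
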