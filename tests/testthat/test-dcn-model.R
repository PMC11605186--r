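# Deep cross network: forward-pass fixtures against hand arithmetic,
# gradient correctness, training behavior, determinism.

test_that("embedding is the stated affine map", {
  m <- make_toy_dcn(input_dim = 3L, embedding_dim = 3L)
  m$params$W_embed <- diag(3)
  m$params$b_embed <- c(0, 0, 0)
  x <- c(1.5, -2, 0.25)
  expect_equal(as.numeric(dcn_embed(m, x)), x)
  m$params$b_embed <- c(1, 2, 3)
  expect_equal(as.numeric(dcn_embed(m, c(0, 0, 0))), c(1, 2, 3))
  # random 3 -> 2 case against hand matrix arithmetic
  m2 <- make_toy_dcn(input_dim = 3L, embedding_dim = 2L, seed = 7)
  W <- matrix(c(1, -1, 2, 0.5, 0, -2), nrow = 2, byrow = TRUE)
  m2$params$W_embed <- W
  m2$params$b_embed <- c(0.1, -0.2)
  x <- c(2, 3, -1)
  expect_equal(as.numeric(dcn_embed(m2, x)),
               c(1 * 2 - 1 * 3 + 2 * -1 + 0.1, 0.5 * 2 + 0 * 3 - 2 * -1 - 0.2))
})

test_that("deep branch applies ReLU between affine layers and none at the end", {
  m <- make_toy_dcn(input_dim = 2L, embedding_dim = 2L, hidden_dims = c(2L, 1L))
  # force all-negative pre-activations in the hidden layer
  m$params$deep_W1 <- matrix(-1, 2, 2); m$params$deep_b1 <- c(-1, -1)
  m$params$deep_W2 <- matrix(c(3, 4), 1); m$params$deep_b2 <- 0.5
  expect_equal(dcn_deep_forward(m, matrix(c(1, 1), 1)), 0.5) # ReLU zeros out
  # two-layer toy with fixed weights vs hand computation
  m$params$deep_W1 <- matrix(c(1, 0, 0, -1), 2, byrow = TRUE)
  m$params$deep_b1 <- c(0, 0)
  h <- c(pmax(2, 0), pmax(-(-3), 0)) # input (2, -3)
  expect_equal(dcn_deep_forward(m, matrix(c(2, -3), 1)),
               3 * h[1] + 4 * h[2] + 0.5)
  # single scalar identity layer
  m1 <- make_toy_dcn(input_dim = 1L, embedding_dim = 1L, hidden_dims = 1L)
  m1$params$deep_W1 <- matrix(1); m1$params$deep_b1 <- 0
  expect_equal(dcn_deep_forward(m1, matrix(4.2)), 4.2)
})

test_that("cross layer is square-linear-bias plus residual, identity at zero weights", {
  m <- make_toy_dcn(input_dim = 2L, embedding_dim = 2L)
  m$params$W_cross <- matrix(0, 2, 2); m$params$b_cross <- c(0, 0)
  x <- matrix(c(0.3, -1.7), 1)
  expect_equal(dcn_cross_forward(m, x), x) # pure residual
  m$params$W_cross <- diag(2)
  expect_equal(as.numeric(dcn_cross_forward(m, matrix(c(1, 2), 1))),
               c(1 + 1, 4 + 2))
  m$params$b_cross <- c(5, 6)
  expect_equal(as.numeric(dcn_cross_forward(m, matrix(c(0, 0), 1))), c(5, 6))
})

test_that("prediction composes the branches through a sigmoid", {
  m <- make_toy_dcn(input_dim = 2L, embedding_dim = 2L, hidden_dims = c(2L, 1L))
  # zero out everything: out = 0 -> probability one half
  for (nm in names(m$params)) m$params[[nm]][] <- 0
  expect_equal(dcn_predict(m, c(1, 2)), 0.5)
  # end-to-end fixed-weight fixture equals manual composition of the pieces
  m2 <- make_toy_dcn(input_dim = 2L, embedding_dim = 3L,
                     hidden_dims = c(2L, 1L), seed = 12)
  x <- c(0.7, -0.4)
  e <- dcn_embed(m2, x)
  manual_out <- dcn_deep_forward(m2, e) +
    as.numeric(dcn_cross_forward(m2, e) %*% t(m2$params$W_proj)) +
    m2$params$b_proj
  expect_equal(dcn_predict(m2, x), 1 / (1 + exp(-manual_out)),
               tolerance = 1e-12)
  # monotone sigmoid tail
  m2$params$b_proj <- 100
  expect_gt(dcn_predict(m2, x), 0.999)
  m2$params$b_proj <- NaN
  expect_error(dcn_predict(m2, x), class = "numeric_error")
})

test_that("BCE loss matches its closed form and clipping keeps it finite", {
  expect_equal(bce_loss(1, 1), -log(1 - 1e-7), tolerance = 1e-9)
  expect_lt(bce_loss(1, 1), 1e-6)
  expect_equal(bce_loss(1, 0.5), -log(0.5))
  expect_equal(bce_loss(0, 1), -log(1e-7), tolerance = 1e-6)
  expect_true(is.finite(bce_loss(0, 1)))
  expect_equal(bce_loss(c(1, 0), c(0.8, 0.3)),
               mean(c(-log(0.8), -log(0.7))))
})

test_that("analytic gradients match central finite differences", {
  cfg <- dcn_config(input_dim = 2L, embedding_dim = 3L,
                    hidden_dims = c(2L, 1L), seed = 2)
  set.seed(2)
  model <- dcn_init(cfg)
  set.seed(30)
  X <- matrix(rnorm(10), 5, 2)
  y <- c(1, 0, 1, 1, 0)
  ana <- dcn_gradients(model, X, y)$grads
  h <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    num <- p
    for (k in seq_along(p)) {
      mp <- model; mp$params[[nm]][k] <- p[k] + h
      mm <- model; mm$params[[nm]][k] <- p[k] - h
      num[k] <- (bce_loss(y, dcn_predict(mp, X)) -
                   bce_loss(y, dcn_predict(mm, X))) / (2 * h)
    }
    denom <- max(abs(num), abs(ana[[nm]]), 1e-8)
    expect_lt(max(abs(num - ana[[nm]])) / denom, 1e-4)
  }
})

test_that("training reduces loss on separable data and is reproducible", {
  set.seed(4)
  n <- 400
  X <- rbind(matrix(rnorm(n, 2), n / 2, 2), matrix(rnorm(n, -2), n / 2, 2))
  y <- rep(c(1L, 0L), each = n / 2)
  va <- sample(n, 60)
  cfg <- dcn_config(input_dim = 2L, embedding_dim = 8L,
                    hidden_dims = c(8L, 1L), epochs = 5L, seed = 6)
  fit <- dcn_train(X[-va, ], y[-va], X[va, ], y[va], cfg)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_gt(auroc(dcn_predict(fit$model, X[va, ]), y[va]), 0.95)
  fit2 <- dcn_train(X[-va, ], y[-va], X[va, ], y[va], cfg)
  expect_identical(fit$history, fit2$history)
  expect_equal(fit$model$params, fit2$model$params)
  expect_error(dcn_train(X[y == 1, ], y[y == 1], X[va, ], y[va], cfg),
               class = "training_error")
})

test_that("checkpointing returns the minimum-validation-loss epoch", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, plogis(X[, 1]))
  cfg <- dcn_config(input_dim = 2L, embedding_dim = 4L,
                    hidden_dims = c(4L, 1L), epochs = 6L, seed = 3)
  fit <- dcn_train(X[1:150, ], y[1:150], X[151:200, ], y[151:200], cfg)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  fit_last <- dcn_train(X[1:150, ], y[1:150], X[151:200, ], y[151:200], cfg,
                        select = "last")
  expect_equal(fit_last$best_epoch, cfg$epochs)
})

test_that("CNN baseline gradients match finite differences on a tiny config", {
  cfg <- cnn_config(kernel = 3L, channels = c(2L, 2L), seed = 8)
  set.seed(8)
  model <- cnn_init(cfg)
  set.seed(9)
  X <- one_hot_matrix(vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "U"), 41, TRUE), collapse = ""),
    character(1)))
  y <- c(1, 0, 1, 0)
  ana <- cnn_gradients(model, X, y)$grads
  h <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    num <- p
    for (k in seq_along(p)) {
      mp <- model; mp$params[[nm]][k] <- p[k] + h
      mm <- model; mm$params[[nm]][k] <- p[k] - h
      num[k] <- (bce_loss(y, cnn_predict(mp, X)) -
                   bce_loss(y, cnn_predict(mm, X))) / (2 * h)
    }
    denom <- max(abs(num), abs(ana[[nm]]), 1e-8)
    expect_lt(max(abs(num - ana[[nm]])) / denom, 1e-4)
  }
})

test_that("CNN learns a planted motif and outputs probabilities", {
  set.seed(10)
  n <- 600
  base <- function() sample(c("A", "C", "G", "U"), 41, TRUE)
  wins <- character(n)
  y <- rep(c(1L, 0L), each = n / 2)
  for (i in 1:n) {
    w <- base()
    if (y[i] == 1) w[5:9] <- c("G", "G", "C", "C", "G") # planted motif
    wins[i] <- paste(w, collapse = "")
  }
  X <- one_hot_matrix(wins)
  va <- sample(n, 100)
  cfg <- cnn_config(channels = c(8L, 8L), epochs = 6L, seed = 5)
  fit <- cnn_train(X[-va, ], y[-va], X[va, ], y[va], cfg)
  p <- cnn_predict(fit$model, X[va, ])
  expect_true(all(p > 0 & p < 1))
  expect_gt(auroc(p, y[va]), 0.8)
})
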