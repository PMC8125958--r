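# plain-R forward pass used as an independent oracle
r_forward <- function(X, W, b) {
  A <- as.matrix(X)
  L <- length(W)
  for (l in seq_len(L)) {
    Z <- A %*% W[[l]] + matrix(b[[l]], nrow(A), length(b[[l]]), byrow = TRUE)
    A <- if (l < L) 1 / (1 + exp(-Z)) else Z
  }
  A[, 1]
}

random_net <- function(sizes, seed) {
  set.seed(seed)
  L <- length(sizes) - 1
  list(W = lapply(seq_len(L), function(l)
         matrix(runif(sizes[l] * sizes[l + 1], -0.5, 0.5),
                sizes[l], sizes[l + 1])),
       b = lapply(seq_len(L), function(l) runif(sizes[l + 1], -0.5, 0.5)))
}

test_that("analytic backprop gradient matches central finite differences", {
  set.seed(20)
  X <- matrix(runif(9), 3, 3)  # 3-sample toy set
  y <- runif(3)
  for (hidden in list(c(4), c(5, 5, 5))) {
    net <- random_net(c(3, hidden, 1), seed = 30 + length(hidden))
    g <- bpnn_gradient(X, y, net$W, net$b)
    h <- 1e-6
    for (l in seq_along(net$W)) {
      for (idx in seq_len(length(net$W[[l]]))) {
        Wp <- net$W; Wm <- net$W
        Wp[[l]][idx] <- Wp[[l]][idx] + h
        Wm[[l]][idx] <- Wm[[l]][idx] - h
        fd <- (bpnn_loss(X, y, Wp, net$b) - bpnn_loss(X, y, Wm, net$b)) / (2 * h)
        expect_equal(g$gW[[l]][idx], fd,
                     tolerance = 1e-5 * max(1, abs(fd)))
      }
      for (idx in seq_along(net$b[[l]])) {
        bp <- net$b; bm <- net$b
        bp[[l]][idx] <- bp[[l]][idx] + h
        bm[[l]][idx] <- bm[[l]][idx] - h
        fd <- (bpnn_loss(X, y, net$W, bp) - bpnn_loss(X, y, net$W, bm)) / (2 * h)
        expect_equal(g$gb[[l]][idx], fd,
                     tolerance = 1e-5 * max(1, abs(fd)))
      }
    }
  }
})

test_that("zero iterations leaves the seeded initial network untouched", {
  set.seed(21)
  X <- matrix(runif(30), 10, 3)
  y <- runif(10, 8, 21)
  cfg <- bpnn_config(max_iterations = 0L)
  m1 <- bpnn_train(X, y, cfg, seed = 77)
  m2 <- bpnn_train(X, y, cfg, seed = 77)
  expect_identical(bpnn_predict(m1, X), bpnn_predict(m2, X))
  expect_equal(m1$epochs, 0L)
  # predictions equal the raw forward pass of the initial weights
  Xs <- ricefusion:::minmax_apply(m1$input_scaler, X)
  raw <- r_forward(Xs, m1$W, m1$b)
  expect_equal(bpnn_predict(m1, X),
               min(y) + raw * (max(y) - min(y)), tolerance = 1e-12)
})

test_that("training reduces the loss on noiseless linear data", {
  set.seed(22)
  x1 <- runif(30)
  X <- cbind(x1, runif(30))
  y <- 2 * x1 + 1
  m <- bpnn_train(X, y, bpnn_config(), seed = 3)
  m0 <- bpnn_train(X, y, bpnn_config(max_iterations = 1L), seed = 3)
  expect_lt(tail(m$rmse_trace, 1), m0$rmse_trace[1])
  expect_lt(rmse(y, bpnn_predict(m, X)), 0.05 * diff(range(y)))
  expect_gt(pearson_r(y, bpnn_predict(m, X)), 0.99)
})

test_that("prediction is deterministic, finite and row-consistent", {
  set.seed(23)
  X <- matrix(runif(60), 20, 3)
  y <- 8 + 10 * X[, 1] + rnorm(20, 0, 0.05)
  m <- bpnn_train(X, y, seed = 9)
  p <- bpnn_predict(m, X[c(1, 1, 2), ])
  expect_identical(p[1], p[2])
  expect_true(all(is.finite(bpnn_predict(m, matrix(runif(30), 10, 3)))))
  expect_identical(bpnn_predict(bpnn_train(X, y, seed = 9), X),
                   bpnn_predict(m, X))
})

test_that("a non-finite target RMSE runs exactly max_iterations epochs", {
  set.seed(24)
  X <- matrix(runif(20), 10, 2)
  y <- runif(10, 1, 2)
  m <- bpnn_train(X, y, bpnn_config(max_iterations = 17L, target_rmse = Inf),
                  seed = 2)
  expect_equal(m$epochs, 17L)
  expect_length(m$rmse_trace, 17L)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(runif(10), 5, 2)
  expect_error(bpnn_train(X, rep(3, 5)), "zero range")
  expect_error(bpnn_train(X, 1:4), "length")
  expect_error(bpnn_config(learning_rate = 0), "learning_rate")
  m <- bpnn_train(X, c(1, 2, 3, 4, 5))
  expect_error(bpnn_predict(m, matrix(0, 2, 3)), "dimension")
})

test_that("serialized models restore to identical predictions", {
  set.seed(25)
  X <- matrix(runif(40), 20, 2)
  y <- 5 + 3 * X[, 1] + rnorm(20, 0, 0.1)
  m <- bpnn_train(X, y, seed = 4)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(bpnn_predict(m2, X), bpnn_predict(m, X), tolerance = 1e-12)
  p <- pca_fit(X, 2)
  path2 <- tempfile(fileext = ".json")
  save_model(p, path2)
  p2 <- load_model(path2)
  expect_equal(pca_transform(p2, X), pca_transform(p, X), tolerance = 1e-12)
})
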