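test_that("correlation and RMSE follow their standard definitions", {
  y <- c(1, 2, 3)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(pearson_r(y, -y + 10), -1)
  expect_error(pearson_r(y, rep(2, 3)), "constant")
  expect_error(rmse(y, c(1, 2)), "length")
})

test_that("cross-validation recovers easy linear data", {
  set.seed(31)
  X <- matrix(runif(120), 40, 3)
  y <- 8 + 10 * X[, 1] + 2 * X[, 2]
  cv <- cross_validate(X, y, seed = 7)
  expect_lt(cv$rmse, 0.05 * diff(range(y)))
  expect_gt(cv$r, 0.99)
  expect_length(cv$predictions, 40L)
})

test_that("leave-one-out is a valid boundary scheme", {
  set.seed(32)
  X <- matrix(runif(12), 6, 2)
  y <- 1:6 + 0.1 * X[, 1]
  cv <- cross_validate(X, y, folds = 6, seed = 3)
  expect_true(is.finite(cv$r) && is.finite(cv$rmse))
  expect_equal(sort(unique(cv$fold)), 1:6)
})

test_that("cross-validation is deterministic in its seed", {
  set.seed(33)
  X <- matrix(runif(60), 20, 3)
  y <- 5 + X[, 1] + rnorm(20, 0, 0.1)
  a <- cross_validate(X, y, seed = 11)
  b <- cross_validate(X, y, seed = 11)
  expect_identical(a$fold, b$fold)
  expect_identical(a$predictions, b$predictions)
  expect_error(cross_validate(X, y, folds = 1), "folds")
  expect_error(cross_validate(X, y, folds = 21), "folds")
})

test_that("repeat_runs summarizes with exact closed forms", {
  # deterministic procedure: zero variance
  rs <- repeat_runs(function(seed) c(m = 1.5), n_runs = 5, master_seed = 1)
  expect_equal(rs$stats$var, 0)
  expect_equal(rs$stats$mean, 1.5)
  # two runs: mean (a+b)/2, sample variance (a-b)^2/2
  rs2 <- repeat_runs(function(seed) c(v = as.numeric(seed %% 100)),
                     n_runs = 2, master_seed = 9)
  a <- unname(rs2$values[1, 1]); b <- unname(rs2$values[2, 1])
  expect_equal(rs2$stats$mean, (a + b) / 2)
  expect_equal(rs2$stats$var, (a - b)^2 / 2)
  expect_equal(rs2$stats$sd, sqrt((a - b)^2 / 2))
})

test_that("repeat_runs is reproducible for a fixed master seed", {
  proc <- function(seed) { set.seed(seed); c(x = rnorm(1), y = runif(1)) }
  a <- repeat_runs(proc, n_runs = 4, master_seed = 42)
  b <- repeat_runs(proc, n_runs = 4, master_seed = 42)
  expect_identical(a$values, b$values)
  expect_identical(a$seeds, b$seeds)
  expect_error(repeat_runs(proc, n_runs = 1), "n_runs")
})
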