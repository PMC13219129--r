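test_that("forward pass with zeroed weights and gains returns the output bias", {
  cfg <- ann_config(input_dim = 3, width = 5)
  params <- ann_init(cfg, seed = 1)
  for (nm in names(params)) params[[nm]][] <- 0
  params$b4[1, 1] <- 4.2
  m <- list(params = params, config = cfg)
  set.seed(2)
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(ann_predict(m, X), rep(4.2, 4))
})

test_that("forward pass matches a hand-computed composition on a tiny network", {
  cfg <- ann_config(input_dim = 2, width = 2)
  params <- list(
    W1 = matrix(c(0.5, -0.25, 1, 0.75), 2, 2), b1 = cbind(c(0.1, -0.2)),
    g1 = cbind(c(1.5, 0.5)), o1 = cbind(c(0.2, -0.1)),
    W2 = matrix(c(1, 0, -1, 2), 2, 2), b2 = cbind(c(0, 0.3)),
    g2 = cbind(c(1, 1)), o2 = cbind(c(0, 0)),
    W3 = matrix(c(0.2, 0.4, -0.6, 0.8), 2, 2), b3 = cbind(c(-0.1, 0.1)),
    g3 = cbind(c(2, 1)), o3 = cbind(c(0.5, 0)),
    W4 = cbind(c(1.2, -0.7)), b4 = matrix(0.3))
  x <- c(0.4, -1.1)
  # step-by-step arithmetic, independent of the implementation
  sig <- function(z) 1 / (1 + exp(-z))
  ln <- function(s, g, o, eps = 1e-5) {
    mu <- mean(s); v <- mean((s - mu)^2)
    g * (s - mu) / sqrt(v + eps) + o
  }
  a1 <- ln(sig(as.numeric(t(params$W1) %*% x) + c(0.1, -0.2)),
           c(1.5, 0.5), c(0.2, -0.1))
  a2 <- ln(sig(as.numeric(t(params$W2) %*% a1) + c(0, 0.3)), c(1, 1), c(0, 0))
  a3 <- ln(sig(as.numeric(t(params$W3) %*% a2) + c(-0.1, 0.1)), c(2, 1), c(0.5, 0))
  expected <- sum(c(1.2, -0.7) * a3) + 0.3
  m <- list(params = params, config = cfg)
  expect_equal(ann_predict(m, x), expected)
  # determinism: bitwise-identical repeat
  expect_identical(ann_predict(m, x), ann_predict(m, x))
})

test_that("losses have their closed forms", {
  y <- c(1, 2, 3)
  expect_equal(ann_loss(y, y, "mse"), 0)
  expect_equal(ann_loss(y, y, "mae"), 0)
  expect_equal(ann_loss(y, y, "huber"), 0)
  p <- c(2, 1)
  t <- c(1, 2)  # residuals (1, -1)
  expect_equal(ann_loss(p, t, "mse"), 1.0)
  expect_equal(ann_loss(p, t, "mae"), 1.0)
  expect_equal(ann_loss(3, 1, "huber", huber_delta = 1), 1.5)  # delta(|r|-delta/2)
  expect_equal(ann_loss(1.4, 1, "huber", huber_delta = 1), 0.5 * 0.4^2)
})

test_that("the analytic gradient matches a central-difference gradient", {
  for (loss in c("mse", "huber")) {
    cfg <- ann_config(input_dim = 3, width = 2, loss = loss, huber_delta = 0.8)
    theta <- ann_pack(ann_init(cfg, seed = 4))
    set.seed(5)
    X <- matrix(rnorm(18), 6, 3)
    y <- rnorm(6)
    g <- ann_obj_grad(theta, X, y, cfg)$grad
    h <- 1e-6
    num <- vapply(seq_along(theta), function(k) {
      tp <- theta; tp[k] <- tp[k] + h
      tm <- theta; tm[k] <- tm[k] - h
      (ann_obj_grad(tp, X, y, cfg)$loss - ann_obj_grad(tm, X, y, cfg)$loss) / (2 * h)
    }, numeric(1))
    expect_equal(g, num, tolerance = 1e-5)
  }
})

test_that("outputs stay finite and bounded by the output layer for any finite input", {
  cfg <- ann_config(input_dim = 4, width = 5)
  params <- ann_init(cfg, seed = 6)
  m <- list(params = params, config = cfg)
  set.seed(7)
  X <- matrix(rnorm(40, sd = 1e4), 10, 4)  # extreme inputs
  pred <- ann_predict(m, X)
  expect_true(all(is.finite(pred)))
  # layer-normalized sigmoid activations are bounded, so |y - b4| is capped
  # by the weighted norm of the last hidden layer's activations
  gmax <- max(abs(params$g3)) + max(abs(params$o3))
  bound <- sum(abs(params$W4)) * (sqrt(cfg$width) + gmax * cfg$width) + abs(params$b4[1, 1])
  expect_true(all(abs(pred) <= bound + 1))
})

test_that("a single training point is interpolated to near-zero loss", {
  cfg <- ann_config(input_dim = 2, width = 5, loss = "mse", max_iter = 500)
  x <- matrix(c(0.3, -0.2), 1, 2)
  y <- 7.5
  m <- ann_train(NULL, x, y, x, y, cfg, seed = 8)
  expect_lt(m$train_loss, 1e-6)
})

test_that("a noiseless linear target is fit to R2 > 0.99", {
  set.seed(9)
  b <- c(1, -2, 0.5, 3, -1)
  Xt <- matrix(rnorm(200 * 5), 200, 5)
  yt <- as.numeric(Xt %*% b)
  Xv <- matrix(rnorm(60 * 5), 60, 5)
  yv <- as.numeric(Xv %*% b)
  m <- ann_train(NULL, Xt, yt, Xv, yv, ann_config(input_dim = 5, width = 10),
                 seed = 10)
  pred <- ann_predict(m, Xv)
  r2 <- 1 - sum((pred - yv)^2) / sum((yv - mean(yv))^2)
  expect_gt(r2, 0.99)
  # determinism contract: identical parameters across runs
  m2 <- ann_train(NULL, Xt, yt, Xv, yv, ann_config(input_dim = 5, width = 10),
                  seed = 10)
  expect_identical(m$params, m2$params)
})

test_that("hyperparameter search logs every restart and keeps the global best", {
  set.seed(11)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- as.numeric(X %*% c(1, 2, -1))
  data_fn <- function(s) {
    with_seed(s, {
      idx <- sample(60, 12)
      list(x_train = X[-idx, ], y_train = y[-idx],
           x_val = X[idx, ], y_val = y[idx])
    })
  }
  sr <- ann_hyperparameter_search(data_fn, input_dim = 3, widths = c(5, 10),
                                  losses = "mse", restarts = 3, seed = 12,
                                  control = list(max_iter = 60))
  expect_equal(nrow(sr$trace), 6L)  # 2 configs x 3 restarts
  expect_equal(as.vector(table(sr$trace$width)), c(3L, 3L))
  expect_equal(sr$best_val, min(sr$trace$val_loss))
  expect_equal(sr$best$validation_loss, sr$best_val)
  # single-config, single-restart grid returns that model
  sr1 <- ann_hyperparameter_search(data_fn, input_dim = 3, widths = 5,
                                   losses = "mse", restarts = 1, seed = 13,
                                   control = list(max_iter = 40))
  expect_equal(nrow(sr1$trace), 1L)
  expect_equal(sr1$best$config$width, 5L)
})
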