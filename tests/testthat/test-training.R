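test_that("cross-entropy matches closed forms and averages over the batch", {
  expect_equal(cross_entropy_loss(matrix(0, 2, 20), c(1, 7)), log(20))
  expect_equal(cross_entropy_loss(matrix(c(10, 0, 0), 1, 3), 1),
               log(1 + 2 * exp(-10)))
  s <- matrix(rnorm(6), 2, 3)
  expect_equal(cross_entropy_loss(s, c(2, 3)),
               mean(c(cross_entropy_loss(s[1, , drop = FALSE], 2),
                      cross_entropy_loss(s[2, , drop = FALSE], 3))))
  expect_error(cross_entropy_loss(matrix(0, 2, 3), c(1, 4)), "labels")
  expect_error(cross_entropy_loss(matrix(c(0, NaN), 1, 2), 1), "finite")
})

test_that("loss gradient is softmax minus one-hot over N", {
  s <- matrix(rnorm(8), 2, 4)
  g <- snnet:::cross_entropy_grad(s, c(3, 1))
  eps <- 1e-6
  for (i in seq_along(s)) {
    s1 <- s; s1[i] <- s1[i] + eps
    s2 <- s; s2[i] <- s2[i] - eps
    fd <- (cross_entropy_loss(s1, c(3, 1)) -
             cross_entropy_loss(s2, c(3, 1))) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-6)
  }
})

test_that("zero epochs return the model untouched with empty history", {
  task <- tiny_task()
  net <- build_network(network_config(30, 8, 3, kind = "adlif"), seed = 1)
  res <- train(net, task$train, cfg = train_config(epochs = 0))
  expect_identical(snnet:::get_params(res$model), snnet:::get_params(net))
  expect_identical(nrow(res$history), 0L)
})

test_that("training reduces the loss on a separable task, reproducibly", {
  task <- tiny_task(seed = 12)
  net <- build_network(network_config(30, c(16, 16), 3, kind = "adlif",
                                      dropout = 0), seed = 4)
  cfg <- train_config(lr = 0.01, epochs = 5, batch_size = 18, seed = 99)
  res <- train(net, task$train, task$valid, cfg)
  expect_identical(nrow(res$history), 5L)
  expect_true(all(diff(res$history$loss) < 0))
  # bitwise reproducibility under the same seed
  res2 <- train(build_network(network_config(30, c(16, 16), 3,
                                             kind = "adlif", dropout = 0),
                              seed = 4),
                task$train, task$valid, cfg)
  expect_identical(res$history, res2$history)
})

test_that("plateau scheduler multiplies the rate by 0.7 after 10 flat epochs", {
  # degenerate task: identical all-zero inputs with balanced labels keep
  # the validation accuracy pinned at 1/C, so no epoch ever improves on
  # the first and the drop lands exactly when patience runs out
  data <- list(x = array(0, c(8, 4, 5)), y = rep(1:2, 4))
  net <- build_network(network_config(5, 4, 2, kind = "lif"), seed = 1)
  cfg <- train_config(lr = 0.01, epochs = 12, batch_size = 8,
                      factor = 0.7, patience = 10, seed = 3)
  res <- train(net, data, data, cfg)
  expect_equal(res$history$valid_acc, rep(0.5, 12))
  expect_equal(res$history$lr[1:10], rep(0.01, 10))
  expect_equal(res$history$lr[11], 0.007)
  expect_equal(res$history$lr[12], 0.007)
})

test_that("constraints hold after every optimizer step", {
  task <- tiny_task(seed = 21)
  cfg <- network_config(30, c(8, 8), 3, kind = "radlif", dropout = 0)
  net <- build_network(cfg, seed = 7)
  net <- attach_masks(net, sparsity_config(0.5, "all_hidden_ff_and_rec",
                                           seed = 2))
  params <- snnet:::get_params(net)
  opt <- snnet:::adam_init(params)
  x <- task$train$x[1:10, , , drop = FALSE]
  y <- as.integer(task$train$y[1:10])
  r <- cfg$ranges
  for (step in 1:6) {
    out <- snnet:::forward_pass(net, x, training = TRUE, keep_cache = TRUE)
    g <- snnet:::backward_pass(net, out,
                               snnet:::cross_entropy_grad(out$scores, y))
    st <- snnet:::adam_step(snnet:::get_params(net), g, opt, lr = 0.05)
    opt <- st$state
    net <- snnet:::apply_constraints(snnet:::set_params(net, st$params))
    for (l in 1:2) {
      np <- net$layers[[l]]$np
      expect_true(all(np$alpha >= r$alpha[1] & np$alpha <= r$alpha[2]))
      expect_true(all(np$beta >= r$beta[1] & np$beta <= r$beta[2]))
      expect_true(all(np$a >= r$a[1] & np$a <= r$a[2]))
      expect_true(all(np$b >= r$b[1] & np$b <= r$b[2]))
      expect_identical(diag(net$layers[[l]]$V), rep(0, 8))
      mk <- net$masks[[l]]
      expect_identical(max(abs(net$layers[[l]]$W[mk$W == 0])), 0)
      expect_identical(max(abs(net$layers[[l]]$V[mk$V == 0])), 0)
    }
    expect_true(all(net$readout$np$alpha >= r$alpha[1] &
                      net$readout$np$alpha <= r$alpha[2]))
  }
  # the same holds across whole epochs through train()
  res <- train(net, task$train, task$valid,
               train_config(lr = 0.01, epochs = 2, batch_size = 12,
                            seed = 5))
  for (l in 1:2) {
    expect_identical(diag(res$model$layers[[l]]$V), rep(0, 8))
    mk <- res$model$masks[[l]]
    expect_identical(max(abs(res$model$layers[[l]]$W[mk$W == 0])), 0)
  }
})

test_that("evaluation is deterministic, chance-level for untrained nets", {
  task <- tiny_task(seed = 31)
  net <- build_network(network_config(30, 8, 3, kind = "adlif"), seed = 2)
  e1 <- evaluate(net, task$test)
  e2 <- evaluate(net, task$test)
  expect_identical(e1, e2)
  expect_identical(sum(e1$confusion), length(task$test$y))
  expect_equal(unname(rowSums(e1$confusion)),
               as.vector(table(factor(task$test$y, levels = 1:3))))

  # many random examples: accuracy concentrates near 1/C
  snnet:::with_seed(77, {
    xr <- array(rbinom(300 * 10 * 30, 1, 0.05), c(300, 10, 30))
    yr <- sample(1:3, 300, replace = TRUE)
  })
  acc <- evaluate(net, list(x = xr, y = yr))$accuracy
  expect_lt(abs(acc - 1 / 3), 0.12)
})

test_that("training aborts with a diagnostic on numeric blow-up", {
  data <- list(x = array(1, c(4, 3, 2)), y = rep(1:2, 2))
  net <- build_network(network_config(2, 3, 2, kind = "lif"), seed = 1)
  net$readout$bias <- c(NaN, 0)   # corrupted state surfaces immediately
  expect_error(train(net, data, cfg = train_config(epochs = 1)),
               "non-finite")
  expect_error(snn_forward(net, data$x), "readout")
})
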