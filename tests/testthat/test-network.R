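test_that("stimulus computation follows the index convention", {
  W <- matrix(c(1, 3, 2, 4), 2, 2)   # W[j, i]: row = presynaptic
  expect_equal(
    compute_stimulus(c(1, 0), weights = list(W = W, bias = c(0.5, 0.5))),
    c(1.5, 2.5))
  # zero activity passes only the bias through
  expect_equal(
    compute_stimulus(c(0, 0), c(0, 0),
                     list(W = W, V = matrix(1, 2, 2), bias = c(-1, 2))),
    c(-1, 2))
  # an own previous spike contributes nothing: diagonal masked
  V <- matrix(c(5, 0, 0, 5), 2, 2)
  I <- compute_stimulus(c(0, 0), c(1, 0),
                        list(W = W, V = V, bias = c(0, 0)))
  expect_equal(I, c(0, 0))
  expect_error(compute_stimulus(c(1, 0, 0), weights = list(W = W)),
               "nrow")
})

test_that("zero_diagonal is exact and idempotent", {
  expect_identical(zero_diagonal(diag(3)), matrix(0, 3, 3))
  V <- matrix(rnorm(16), 4, 4); diag(V) <- 0
  expect_identical(zero_diagonal(V), V)
  expect_error(zero_diagonal(matrix(1, 2, 3)), "square")
})

test_that("configuration validation lists offending fields", {
  expect_error(network_config(10, c(8, 0), 4), "hidden")
  expect_error(network_config(10, 8, 1), "n_classes")
  expect_error(network_config(10, 8, 4, dropout = 1), "dropout")
  expect_error(network_config(10, 8, 4, kind = "lstm"), "unknown unit kind")
})

test_that("built networks are reproducible and respect structure", {
  cfg <- network_config(12, c(6, 6), 4, kind = "radlif")
  n1 <- build_network(cfg, seed = 3)
  n2 <- build_network(cfg, seed = 3)
  expect_identical(snnet:::get_params(n1), snnet:::get_params(n2))
  expect_false(identical(snnet:::get_params(n1),
                         snnet:::get_params(build_network(cfg, seed = 4))))
  for (l in 1:2) {
    expect_identical(diag(n1$layers[[l]]$V), rep(0, 6))
    r <- cfg$ranges
    expect_true(all(n1$layers[[l]]$np$alpha >= r$alpha[1] &
                      n1$layers[[l]]$np$alpha <= r$alpha[2]))
  }
})

test_that("the (N, T, F) to (N, C) contract holds and rasters are binary", {
  cfg <- network_config(3, c(6, 5), 4, kind = "radlif", dropout = 0.1)
  net <- build_network(cfg, seed = 1)
  x <- array(rbinom(2 * 5 * 3, 1, 0.5), c(2, 5, 3))
  out <- snn_forward(net, x, rasters = TRUE)
  expect_identical(dim(out$scores), c(2L, 4L))
  expect_length(out$rates, 2)
  for (r in out$rasters) {
    expect_identical(dim(r)[1:2], c(2L, 5L))
    expect_true(all(r %in% c(0, 1)))
  }
  # cumulative-softmax scores sum to T per example
  expect_equal(unname(rowSums(out$scores)), rep(5, 2))

  # all-zero input with zero bias: uniform scores T / C
  net0 <- build_network(network_config(3, 6, 4, kind = "lif", dropout = 0),
                        seed = 2)
  sc <- snn_forward(net0, array(0, c(2, 5, 3)))$scores
  expect_equal(unname(sc), matrix(5 / 4, 2, 4))
})

test_that("vectorized forward equals the scalar reference loop", {
  for (kind in c("adlif", "radlif", "lif", "rlif")) {
    net <- make_active_net(kind)
    snnet:::with_seed(21, {
      x <- array(rbinom(3 * 8 * 5, 1, 0.5) * 4, c(3, 8, 5))
    })
    impl <- snn_forward(net, x)$scores
    ref <- ref_snn_forward(net, x)$scores
    expect_equal(unname(impl), ref, tolerance = 1e-12)
  }
})

test_that("readout schemes compute their stated formulas", {
  expect_equal(readout_scores(matrix(1, 3, 2)), c(1.5, 1.5))
  expect_equal(readout_scores(matrix(c(log(3), 0), 1, 2)), c(0.75, 0.25))
  raster <- cbind(c(1, 1, 1, 1, 1), 0, c(1, 1, 0, 0, 0))
  expect_equal(readout_scores(raster, "spike_count"), c(5, 0, 2))
  tr <- matrix(c(1, 2, 3, 6, 5, 4), 3, 2)
  expect_equal(readout_scores(tr, "last_potential"), c(3, 4))
  expect_equal(readout_scores(tr, "max_potential"), c(3, 6))
  expect_error(readout_scores(tr, "mean_potential"), "arg")
})

test_that("every readout scheme runs end to end in the network", {
  x <- array(rbinom(2 * 6 * 5, 1, 0.5) * 4, c(2, 6, 5))
  for (m in c("cumulative_softmax", "spike_count", "last_potential",
              "max_potential")) {
    cfg <- network_config(5, 4, 3, kind = "adlif", readout = m,
                          dropout = 0, batchnorm = FALSE)
    net <- build_network(cfg, seed = 6)
    sc <- snn_forward(net, x)$scores
    expect_identical(dim(sc), c(2L, 3L))
    expect_true(all(is.finite(sc)))
  }
})

test_that("MLP and RNN baselines reduce to each other when V = 0", {
  cfg_m <- network_config(5, c(4, 4), 3, kind = "mlp", dropout = 0,
                          batchnorm = FALSE)
  net_m <- build_network(cfg_m, seed = 3)
  # sigma(0) = 0.5 everywhere when all weights and biases vanish
  net0 <- net_m
  for (l in 1:2) {
    net0$layers[[l]]$Wh <- net0$layers[[l]]$Wh * 0
    net0$layers[[l]]$bh <- net0$layers[[l]]$bh * 0
  }
  x <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
  out0 <- snnet:::forward_pass(net0, x, keep_cache = TRUE)
  expect_true(all(out0$cache$layers[[1]]$Y == 0.5))
  expect_true(all(out0$cache$layers[[2]]$Y == 0.5))

  cfg_r <- network_config(5, c(4, 4), 3, kind = "rnn", dropout = 0,
                          batchnorm = FALSE)
  net_r <- build_network(cfg_r, seed = 3)
  for (l in 1:2) {
    net_r$layers[[l]]$Wh <- net_m$layers[[l]]$Wh
    net_r$layers[[l]]$bh <- net_m$layers[[l]]$bh
    net_r$layers[[l]]$Vh <- net_r$layers[[l]]$Vh * 0
  }
  # readouts differ between recurrent and non-recurrent baselines; compare
  # the hidden sequences, which must agree exactly
  out_m <- snnet:::forward_pass(net_m, x, keep_cache = TRUE)
  out_r <- snnet:::forward_pass(net_r, x, keep_cache = TRUE)
  expect_identical(out_r$cache$layers[[2]]$Y, out_m$cache$layers[[2]]$Y)
})

test_that("dropout is inert at evaluation and active in training", {
  cfg <- network_config(5, 6, 3, kind = "adlif", dropout = 0.4)
  net <- build_network(cfg, seed = 1)
  snnet:::with_seed(4, {
    net$layers[[1]]$bias <- runif(6, 1, 2)   # guarantee spiking activity
  })
  x <- array(rbinom(3 * 6 * 5, 1, 0.6) * 3, c(3, 6, 5))
  s1 <- snn_forward(net, x)$scores
  s2 <- snn_forward(net, x)$scores
  expect_identical(s1, s2)
  set.seed(10)
  t1 <- snnet:::forward_pass(net, x, training = TRUE)$scores
  t2 <- snnet:::forward_pass(net, x, training = TRUE)$scores
  expect_false(identical(t1, t2))
})

test_that("non-finite potentials fail with layer and step named", {
  cfg <- network_config(3, 4, 2, kind = "lif", dropout = 0)
  net <- build_network(cfg, seed = 1)
  net$layers[[1]]$bias <- rep(Inf, 4)
  expect_error(snn_forward(net, array(0, c(1, 3, 3))),
               "layer 1 at step 1")
})

test_that("spiking backward equals the independent scalar BPTT reference", {
  for (kind in c("adlif", "radlif")) {
    net <- make_active_net(kind)
    snnet:::with_seed(31, {
      x <- array(rbinom(2 * 10 * 5, 1, 0.5) * 6, c(2, 10, 5))
    })
    y <- c(2, 3)
    out <- snnet:::forward_pass(net, x, keep_cache = TRUE)
    expect_gt(sum(out$cache$layers[[1]]$S), 3)   # all paths exercised
    g <- snnet:::backward_pass(net, out,
                               snnet:::cross_entropy_grad(out$scores, y))
    ref <- ref_snn_grads(net, x, y)
    expect_equal(cross_entropy_loss(out$scores, y), ref$loss)
    for (nm in names(ref$grads)) {
      expect_equal(g[[nm]], ref$grads[[nm]], tolerance = 1e-10,
                   label = paste("gradient", nm, "for", kind))
    }
  }
})

test_that("smooth baseline gradients match central finite differences", {
  snnet:::with_seed(42, {
    x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  })
  y <- c(1, 2, 3)
  for (kind in c("mlp", "rnn", "ligru", "gru")) {
    for (bn in c(FALSE, TRUE)) {
      cfg <- network_config(5, c(4, 4), 3, kind = kind, dropout = 0,
                            batchnorm = bn)
      net <- build_network(cfg, seed = 9)
      out <- snnet:::forward_pass(net, x, training = TRUE,
                                  keep_cache = TRUE)
      g <- snnet:::backward_pass(net, out,
                                 snnet:::cross_entropy_grad(out$scores, y))
      params <- snnet:::get_params(net)
      snnet:::with_seed(5, {
        for (nm in names(params)) {
          for (i in sample(length(params[[nm]]),
                           min(3, length(params[[nm]])))) {
            fd <- fd_grad(net, x, y, nm, i)
            expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                         label = sprintf("%s grad %s[%d] (bn=%s)", kind,
                                         nm, i, bn))
          }
        }
      })
    }
  }
})
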