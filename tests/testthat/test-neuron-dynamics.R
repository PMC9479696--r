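test_that("continuous-to-discrete conversion applies the change of variables", {
  m <- continuous_neuron_model(tau_u = 10, tau_w = 100, dt = 1)
  p <- continuous_to_discrete(m)
  expect_equal(p$alpha, exp(-0.1))
  expect_equal(p$beta, exp(-0.01))
  expect_identical(p$theta, 1)
  expect_identical(p$u_r, 0)

  # couplings rescale by R and the threshold gap
  m2 <- continuous_neuron_model(tau_u = 10, tau_w = 100, R = 2,
                                u_rest = -65, u_r = -65, theta_phys = -45,
                                a_phys = 0.3, b_phys = 4)
  p2 <- continuous_to_discrete(m2)
  expect_equal(p2$a, 2 * 0.3)
  expect_equal(p2$b, 2 * 4 / 20)

  # pure integrator limit
  p3 <- continuous_to_discrete(continuous_neuron_model(tau_u = 1e9))
  expect_equal(p3$alpha, 1, tolerance = 1e-8)

  # physiological time constants land inside the stated training ranges
  for (tau in c(2, 10, 24)) {
    a <- continuous_to_discrete(continuous_neuron_model(tau_u = tau))$alpha
    expect_true(a >= 0.60 && a <= 0.96)
  }
  for (tau in c(25, 60, 99)) {
    b <- continuous_to_discrete(continuous_neuron_model(tau_w = tau))$beta
    expect_true(b >= 0.96 && b <= 0.99)
  }

  expect_error(continuous_neuron_model(tau_u = -1), "positive")
  expect_error(continuous_neuron_model(tau_w = 0), "positive")
  expect_error(continuous_neuron_model(theta_phys = -1, u_r = 0), "exceed")
})

test_that("heterogeneous initialization is seeded and respects ranges", {
  p1 <- init_neuron_params(4, seed = 42)
  p2 <- init_neuron_params(4, seed = 42)
  expect_identical(p1, p2)
  expect_false(identical(p1, init_neuron_params(4, seed = 43)))

  big <- init_neuron_params(1000, seed = 1)
  r <- default_param_ranges()
  expect_true(all(big$alpha >= r$alpha[1] & big$alpha <= r$alpha[2]))
  expect_true(all(big$beta >= r$beta[1] & big$beta <= r$beta[2]))
  expect_true(all(big$a >= r$a[1] & big$a <= r$a[2]))
  expect_true(all(big$b >= r$b[1] & big$b <= r$b[2]))

  deg <- init_neuron_params(10, ranges = list(alpha = c(0.9, 0.9)),
                            seed = 1)
  expect_identical(deg$alpha, rep(0.9, 10))
  expect_error(init_neuron_params(3, ranges = list(alpha = c(1, 0))),
               "range")
  expect_error(init_neuron_params(0), "count")
})

test_that("clamping projects onto closed intervals and is idempotent", {
  p <- neuron_params(alpha = c(0.99, 0.80, 0.10), beta = 0.97,
                     a = c(-3, 0.2, 3), b = c(-1, 1, 5))
  cl <- clamp_neuron_params(p)
  expect_equal(cl$alpha, c(0.96, 0.80, 0.60))
  expect_equal(cl$a, c(-1, 0.2, 1))
  expect_equal(cl$b, c(0, 1, 2))
  expect_identical(clamp_neuron_params(cl), cl)
})

test_that("adLIF step reproduces hand-computed updates and the soft reset", {
  # rest is a fixed point
  st <- neuron_state(3)
  out <- adlif_step(st, rep(0, 3), neuron_params(0.9, 0.98, 0.5, 0.1))
  expect_identical(out$u, rep(0, 3))
  expect_identical(out$w, rep(0, 3))
  expect_identical(out$s, rep(0, 3))

  # direct substitution
  st <- neuron_state(1)
  st$u <- 0.5; st$w <- 0.1
  out <- adlif_step(st, 1, neuron_params(0.9, 0.98, 0.5, 0.1))
  expect_equal(out$u, 0.9 * 0.5 + 0.1 * 1 - 0.1)              # 0.45
  expect_equal(out$w, 0.98 * 0.1 + 0.02 * 0.5 * 0.5)          # 0.103
  expect_identical(out$s, 0)

  # crossing threshold, then soft reset by threshold subtraction
  st <- neuron_state(1)
  st$u <- 0.95
  p <- neuron_params(0.9, 0, 0, 0)
  out <- adlif_step(st, 6, p)
  expect_equal(out$u, 0.9 * 0.95 + 0.1 * 6)                   # 1.455
  expect_identical(out$s, 1)
  out2 <- adlif_step(out, 0, p)
  expect_equal(out2$u, 0.9 * 1.455 - 1)                       # 0.3095
  expect_error(adlif_step(neuron_state(2), 1, p), "stimulus length")
})

test_that("LIF is the a = b = 0 reduction of adLIF", {
  st <- neuron_state(1); st$u <- 0.5
  out <- lif_step(st, 1, neuron_params(alpha = 0.9))
  expect_equal(out$u, 0.55)
  expect_identical(out$s, 0)

  set.seed(7)
  p_l <- init_neuron_params(6, seed = 3, which = "alpha")
  p_a <- p_l; p_a$a <- rep(0, 6); p_a$b <- rep(0, 6)
  st <- neuron_state(6)
  for (t in 1:20) {
    I <- rnorm(6, 0.5, 1)
    s_l <- lif_step(st, I, p_l)
    s_a <- adlif_step(st, I, p_a)
    expect_identical(s_l$u, s_a$u)
    expect_identical(s_l$s, s_a$s)
    st <- s_l
  }

  # zero-input geometric decay, exact
  st <- neuron_state(1); st$u <- 0.5
  for (t in 1:10) {
    st <- lif_step(st, 0, neuron_params(alpha = 0.9))
    expect_equal(st$u, 0.9^t * 0.5)
  }
})

test_that("moving threshold rises with spikes and decays geometrically", {
  p <- list(alpha = 0.9, rho = 0.9, gamma = 0.5, theta0 = 1)
  # gamma = 0 reduces to plain LIF trajectories
  p0 <- list(alpha = 0.9, rho = 0.9, gamma = 0, theta0 = 1)
  st_m <- st_l <- neuron_state(1)
  set.seed(2)
  for (t in 1:30) {
    I <- rnorm(1, 0.8, 1.5)
    st_m <- moving_threshold_step(st_m, I, p0)
    st_l <- lif_step(st_l, I, list(alpha = 0.9))
    expect_identical(st_m$u, st_l$u)
    expect_identical(st_m$s, st_l$s)
  }

  # one spike raises the next-step threshold to theta0 + gamma
  st <- neuron_state(1)
  st <- moving_threshold_step(st, 50, p)   # forces a spike
  expect_identical(st$s, 1)
  st2 <- moving_threshold_step(st, 0, p)
  expect_equal(attr(st2, "theta_t"), 1 + 0.5 * (0.9 * 0 + 1))  # 1.5

  # sustained forced firing: threshold approaches theta0 + gamma/(1 - rho)
  st <- neuron_state(1)
  th <- numeric(60)
  for (t in 1:60) {
    st <- moving_threshold_step(st, 1e4, p)
    th[t] <- attr(st, "theta_t")[1]
    expect_identical(st$s, 1)
  }
  expect_true(all(diff(th) >= -1e-12))
  expect_equal(th[60], 1 + 0.5 / (1 - 0.9), tolerance = 1e-2)
  expect_error(moving_threshold_step(neuron_state(1), 0,
                                     list(alpha = 0.9, rho = 1.2,
                                          gamma = 1)), "rho")
})

test_that("layer rollout matches a scalar per-step loop and stays binary", {
  set.seed(4)
  Tn <- 20; n <- 5
  stim <- matrix(rnorm(Tn * n, 0.8, 1.2), Tn, n)
  p <- init_neuron_params(n, seed = 8)
  roll <- run_layer_dynamics(stim, p, mode = "adlif")
  st <- neuron_state(n)
  for (t in seq_len(Tn)) {
    st <- adlif_step(st, stim[t, ], p)
    expect_identical(roll$u[t, ], st$u)
    expect_identical(roll$w[t, ], st$w)
    expect_identical(roll$spikes[t, ], st$s)
  }
  expect_true(all(roll$spikes %in% c(0, 1)))
  expect_gt(sum(roll$spikes), 0)

  # zero stimulus keeps everything at rest
  z <- run_layer_dynamics(matrix(0, 10, 3), p[c("alpha", "beta", "a", "b")])
  expect_identical(sum(abs(z$u)), 0)
  expect_identical(sum(z$spikes), 0)

  # readout mode never spikes, whatever the drive
  ro <- run_layer_dynamics(matrix(100, 15, 2),
                           neuron_params(alpha = c(0.8, 0.9)),
                           mode = "readout")
  expect_identical(sum(ro$spikes), 0)
  expect_true(all(is.finite(ro$u)))
  expect_error(run_layer_dynamics(matrix(0, 0, 3), p), "non-empty")
})

test_that("LIF spike count grows with constant drive; subthreshold never fires", {
  p <- neuron_params(alpha = 0.9)
  counts <- vapply(seq(0, 3, by = 0.25), function(I) {
    sum(run_layer_dynamics(matrix(I, 50, 1), p, mode = "lif")$spikes)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  # constant I < theta: potential converges to I from below, no spikes
  r <- run_layer_dynamics(matrix(0.95, 200, 1), p, mode = "lif")
  expect_identical(sum(r$spikes), 0)
  expect_equal(r$u[200, 1], 0.95, tolerance = 1e-8)
})
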