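#' Network configuration
#'
#' Describes a sequence classifier mapping inputs of shape (N, T, F) to
#' class scores of shape (N, C): a stack of hidden layers of spiking
#' (LIF / adLIF / moving-threshold, optionally recurrent) or conventional
#' (MLP / RNN / light-gated / GRU) units, followed by a readout. Spiking
#' readouts are non-recurrent and, except for the \code{spike_count} scheme,
#' non-spiking leaky integrators.
#'
#' @param input_size number of input features/channels F.
#' @param hidden integer vector of hidden layer sizes (default two layers of
#'   128; with the readout this is the "3-layer" architecture).
#' @param n_classes number of classes C.
#' @param kind unit kind: \code{"lif"}, \code{"adlif"}, \code{"rlif"},
#'   \code{"radlif"}, \code{"mtlif"}, \code{"rmtlif"} (spiking; the r-
#'   prefix adds layer-wise recurrent connections with zero diagonal), or
#'   \code{"mlp"}, \code{"rnn"}, \code{"ligru"}, \code{"gru"}
#'   (non-spiking baselines).
#' @param readout readout scheme for spiking networks: one of
#'   \code{"cumulative_softmax"} (default; per-step softmax over class
#'   potentials summed over time), \code{"spike_count"},
#'   \code{"last_potential"}, \code{"max_potential"}. Non-spiking networks
#'   use the cumulative-softmax of the penultimate layer followed by a
#'   linear map when recurrent, and a cumulative sum of the final linear
#'   outputs when not.
#' @param dropout dropout probability on each hidden layer's output
#'   activity (default 0.1).
#' @param batchnorm logical; batch-normalize the feedforward stimulus term,
#'   with statistics pooled over batch and time (default TRUE).
#' @param surrogate a [surrogate_spec()] (default boxcar).
#' @param activation activation g for non-spiking units
#'   (\code{"sigmoid"}, \code{"tanh"} or \code{"relu"}).
#' @param ranges trainable ranges for neuron parameters, see
#'   [default_param_ranges()].
#' @return Object of class \code{"network_config"}.
#' @export
network_config <- function(input_size, hidden = c(128, 128), n_classes,
                           kind = "adlif",
                           readout = c("cumulative_softmax", "spike_count",
                                       "last_potential", "max_potential"),
                           dropout = 0.1, batchnorm = TRUE,
                           surrogate = surrogate_spec("boxcar"),
                           activation = c("sigmoid", "tanh", "relu"),
                           ranges = default_param_ranges()) {
  kinds <- c("lif", "adlif", "rlif", "radlif", "mtlif", "rmtlif",
             "mlp", "rnn", "ligru", "gru")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop("unknown unit kind; valid kinds: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  readout <- match.arg(readout)
  activation <- match.arg(activation)
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(input_size) && length(input_size) == 1L && input_size >= 1,
      "input_size must be a positive count")
  chk(is.numeric(hidden) && length(hidden) >= 1L && all(hidden >= 1),
      "hidden must give at least one hidden layer of size >= 1")
  chk(is.numeric(n_classes) && length(n_classes) == 1L && n_classes >= 2,
      "n_classes must be >= 2")
  chk(is.numeric(dropout) && length(dropout) == 1L && dropout >= 0 &&
        dropout < 1, "dropout must lie in [0, 1)")
  if (length(problems)) {
    stop("invalid network configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  spiking <- kind %in% c("lif", "adlif", "rlif", "radlif", "mtlif", "rmtlif")
  unit <- switch(kind,
    lif = , rlif = "lif",
    adlif = , radlif = "adlif",
    mtlif = , rmtlif = "mtlif",
    kind)
  recurrent <- kind %in% c("rlif", "radlif", "rmtlif", "rnn", "ligru", "gru")
  structure(
    list(input_size = as.integer(input_size),
         hidden = as.integer(hidden),
         n_classes = as.integer(n_classes),
         kind = kind, unit = unit, type = if (spiking) "snn" else "ann",
         recurrent = recurrent, readout = readout,
         dropout = dropout, batchnorm = isTRUE(batchnorm),
         surrogate = as_surrogate_spec(surrogate),
         activation = activation,
         ranges = check_ranges(utils::modifyList(default_param_ranges(),
                                                 as.list(ranges)))),
    class = "network_config"
  )
}

#' Zero the diagonal of a recurrent weight matrix
#'
#' Self-excitation through positive diagonal recurrent weights would act
#' against refractoriness, so the diagonal of every recurrent matrix is
#' forced to zero — at build time and again after every optimizer update.
#'
#' @param V square numeric matrix.
#' @return \code{V} with \code{diag(V) = 0}. Idempotent.
#' @export
zero_diagonal <- function(V) {
  if (!is.matrix(V) || nrow(V) != ncol(V)) {
    stop("V must be a square matrix", call. = FALSE)
  }
  diag(V) <- 0
  V
}

#' Synaptic stimulus of one layer at one time step
#'
#' \deqn{I_i = \sum_j W_{ji} x_j + \sum_{k \ne i} V_{ki} s_k + b_i}
#' The feedforward term reads the current-step activity of the layer below;
#' the recurrent term reads the same layer's previous-step activity, with
#' the diagonal of V masked to zero. The identical formula serves
#' non-spiking units with real-valued activities.
#'
#' @param inputs activity vector of the layer below at time t (length = rows
#'   of W).
#' @param prev_spikes same-layer activity at time t-1 (length = columns of
#'   W), or NULL when the layer has no recurrent connections.
#' @param weights list with feedforward matrix \code{W} (pre x post),
#'   optional recurrent matrix \code{V} (post x post) and \code{bias}.
#' @return Stimulus vector of length \code{ncol(W)}.
#' @export
compute_stimulus <- function(inputs, prev_spikes = NULL, weights) {
  W <- weights$W
  if (!is.matrix(W) || length(inputs) != nrow(W)) {
    stop("input length must match nrow(W)", call. = FALSE)
  }
  I <- as.vector(inputs %*% W)
  if (!is.null(weights$V) && !is.null(prev_spikes)) {
    V <- zero_diagonal(weights$V)
    if (length(prev_spikes) != nrow(V) || ncol(V) != ncol(W)) {
      stop("recurrent shapes inconsistent with layer size", call. = FALSE)
    }
    I <- I + as.vector(prev_spikes %*% V)
  }
  b <- weights$bias %||% 0
  I + b
}

init_weight <- function(n_in, n_out) {
  lim <- 1 / sqrt(n_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

ann_blocks <- function(unit) {
  switch(unit, mlp = , rnn = "h", ligru = c("z", "h"), gru = c("z", "r", "h"))
}

#' Build a network from its configuration
#'
#' Instantiates all trainable tensors: feedforward weights with uniform
#' fan-in initialization, zero-diagonal recurrent weights, zero biases, and
#' heterogeneous per-neuron parameters drawn uniformly from their ranges.
#' Reproducible for a fixed seed.
#'
#' @param config a [network_config()].
#' @param seed integer seed.
#' @return Object of class \code{"sg_network"}.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, {
    sizes <- c(config$input_size, config$hidden)
    layers <- vector("list", length(config$hidden))
    for (l in seq_along(config$hidden)) {
      n_in <- sizes[l]
      n_out <- sizes[l + 1]
      if (config$type == "snn") {
        np_which <- switch(config$unit, lif = "alpha",
                           adlif = c("alpha", "beta", "a", "b"),
                           mtlif = "alpha")
        np <- init_neuron_params(n_out, config$ranges, which = np_which)
        if (config$unit == "mtlif") {
          np$rho <- stats::runif(n_out, config$ranges$rho[1],
                                 config$ranges$rho[2])
          np$gamma <- stats::runif(n_out, config$ranges$gamma[1],
                                   config$ranges$gamma[2])
          np$theta0 <- 1
        }
        layers[[l]] <- list(
          W = init_weight(n_in, n_out),
          V = if (config$recurrent) zero_diagonal(init_weight(n_out, n_out))
              else NULL,
          bias = numeric(n_out),
          np = np,
          bn = if (config$batchnorm) list(mean = numeric(n_out),
                                          var = rep(1, n_out)) else NULL
        )
      } else {
        blocks <- ann_blocks(config$unit)
        lay <- list(bn = NULL)
        for (g in blocks) {
          lay[[paste0("W", g)]] <- init_weight(n_in, n_out)
          lay[[paste0("V", g)]] <- if (config$recurrent)
            init_weight(n_out, n_out) else NULL
          lay[[paste0("b", g)]] <- numeric(n_out)
        }
        if (config$batchnorm) {
          lay$bn <- lapply(stats::setNames(blocks, blocks), function(g)
            list(mean = numeric(n_out), var = rep(1, n_out)))
        }
        layers[[l]] <- lay
      }
    }
    n_last <- sizes[length(sizes)]
    ro <- list(W = init_weight(n_last, config$n_classes),
               bias = numeric(config$n_classes))
    if (config$type == "snn") {
      ro$np <- init_neuron_params(config$n_classes, config$ranges,
                                  which = "alpha")
    }
    structure(list(config = config, layers = layers, readout = ro,
                   masks = NULL),
              class = "sg_network")
  })
}

#' @export
print.sg_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sg_network> %s %s, %d -> %s -> %d\n",
              toupper(cfg$kind),
              if (cfg$type == "snn") "spiking network" else "network",
              cfg$input_size, paste(cfg$hidden, collapse = "x"),
              cfg$n_classes))
  pb <- count_parameters(cfg)
  cat(sprintf("  trainable parameters: %s%s\n",
              format(pb$total, big.mark = ","),
              if (!is.null(x$masks)) sprintf(" (%s after sparsification)",
                format(n_trainable(x), big.mark = ",")) else ""))
  invisible(x)
}

masked_W <- function(layer, mask) {
  if (is.null(mask) || is.null(mask$W)) layer$W else layer$W * mask$W
}
masked_V <- function(layer, mask) {
  if (is.null(layer$V)) return(NULL)
  if (is.null(mask) || is.null(mask$V)) layer$V else layer$V * mask$V
}

byrow_mat <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

activation_fun <- function(name) {
  switch(name,
    sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                   df = function(x, y) y * (1 - y)),
    tanh = list(f = tanh, df = function(x, y) 1 - y^2),
    relu = list(f = function(x) pmax(x, 0), df = function(x, y) (x > 0) + 0))
}

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

bn_forward <- function(A, bn, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(A)
    v <- colMeans(A^2) - mu^2
    v <- pmax(v, 0)
    bn$mean <- (1 - momentum) * bn$mean + momentum * mu
    bn$var <- (1 - momentum) * bn$var + momentum * v
  } else {
    mu <- bn$mean
    v <- bn$var
  }
  sd <- sqrt(v + eps)
  xhat <- sweep(sweep(A, 2, mu, "-"), 2, sd, "/")
  list(xhat = xhat, sd = sd, bn = bn)
}

check_finite <- function(u, layer, t) {
  if (!all(is.finite(u))) {
    stop(sprintf(
      "numeric failure: non-finite membrane potential in layer %s at step %d",
      layer, t), call. = FALSE)
  }
}

# Core forward pass over one batch.
# x: N x T x F array. Returns scores plus (optionally) full per-layer caches
# for backpropagation. All per-layer activations are stored as (N*T) x H
# matrices whose row r = n + (t-1)*N holds example n at step t.
forward_pass <- function(net, x, training = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  dm <- dim(x)
  if (is.null(dm) || length(dm) != 3L) {
    stop("input batch must be an N x T x F array", call. = FALSE)
  }
  N <- dm[1]; T_len <- dm[2]; F_in <- dm[3]
  if (T_len < 1L) stop("empty sequence: T must be >= 1", call. = FALSE)
  if (F_in != cfg$input_size) {
    stop(sprintf("input has %d features but the network expects %d",
                 F_in, cfg$input_size), call. = FALSE)
  }
  X <- matrix(x, N * T_len, F_in)
  idx_of <- function(t) ((t - 1L) * N + 1L):(t * N)
  caches <- vector("list", length(net$layers))
  spike_mats <- vector("list", length(net$layers))
  rates <- numeric(length(net$layers))

  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    mask <- net$masks[[l]]
    H <- cfg$hidden[l]
    fw <- if (cfg$type == "snn") {
      snn_layer_forward(cfg, lay, mask, X, N, T_len, H, l, training, idx_of)
    } else {
      ann_layer_forward(cfg, lay, mask, X, N, T_len, H, l, training, idx_of)
    }
    net$layers[[l]]$bn <- fw$bn_state
    rates[l] <- if (cfg$type == "snn") mean(fw$S) else NA_real_
    spike_mats[[l]] <- fw$S
    if (keep_cache) {
      fw$X <- X
      caches[[l]] <- fw
    }
    X <- fw$out
  }

  ro <- readout_forward(cfg, net$readout, X, N, T_len, idx_of)
  list(scores = ro$scores, rates = rates,
       spike_mats = if (cfg$type == "snn") spike_mats else NULL,
       dims = c(N = N, T = T_len),
       cache = if (keep_cache) list(layers = caches, readout = ro,
                                    idx_of = idx_of, N = N, T_len = T_len)
               else NULL,
       net = net)
}

snn_layer_forward <- function(cfg, lay, mask, X, N, T_len, H, l, training,
                              idx_of) {
  Wm <- masked_W(lay, mask)
  Vm <- masked_V(lay, mask)
  A <- X %*% Wm
  bn_state <- lay$bn
  if (!is.null(bn_state)) {
    bf <- bn_forward(A, bn_state, training)
    Ah <- bf$xhat; bn_sd <- bf$sd; bn_state <- bf$bn
  } else {
    Ah <- A; bn_sd <- NULL
  }
  np <- lay$np
  AlphaM <- byrow_mat(np$alpha, N)
  BetaM <- byrow_mat(np$beta, N)
  Am <- byrow_mat(np$a, N)
  Bm <- byrow_mat(np$b, N)
  bias <- byrow_mat(lay$bias, N)
  mt <- cfg$unit == "mtlif"
  if (mt) {
    RhoM <- byrow_mat(np$rho, N)
    GammaM <- byrow_mat(np$gamma, N)
  }
  U <- Wad <- S <- SD <- Imat <- matrix(0, N * T_len, H)
  DM <- if (training && cfg$dropout > 0) matrix(0, N * T_len, H) else NULL
  ETA <- if (mt) matrix(0, N * T_len, H) else NULL
  THT <- if (mt) matrix(0, N * T_len, H) else NULL
  u <- w <- s <- sd <- eta <- matrix(0, N, H)
  keep_p <- 1 - cfg$dropout
  for (t in seq_len(T_len)) {
    idx <- idx_of(t)
    I_t <- Ah[idx, , drop = FALSE] + bias
    if (!is.null(Vm)) I_t <- I_t + sd %*% Vm
    if (mt) {
      eta <- RhoM * eta + s
      theta_t <- 1 + GammaM * eta
      u <- AlphaM * u + (1 - AlphaM) * I_t - s   # soft reset by theta0 = 1
      s_new <- (u >= theta_t) + 0
      ETA[idx, ] <- eta
      THT[idx, ] <- theta_t
    } else {
      u_new <- AlphaM * u + (1 - AlphaM) * I_t - w - s
      if (cfg$unit == "adlif") {
        w <- BetaM * w + (1 - BetaM) * Am * u + Bm * s
      }
      u <- u_new
      s_new <- (u >= 1) + 0
    }
    check_finite(u, l, t)
    s <- s_new
    if (!is.null(DM)) {
      m_t <- (matrix(stats::runif(N * H), N, H) >= cfg$dropout) / keep_p
      DM[idx, ] <- m_t
      sd <- s * m_t
    } else {
      sd <- s
    }
    U[idx, ] <- u
    Wad[idx, ] <- w
    S[idx, ] <- s
    SD[idx, ] <- sd
    Imat[idx, ] <- I_t
  }
  list(out = SD, U = U, Wad = Wad, S = S, SD = SD, DM = DM, Imat = Imat,
       ETA = ETA, THT = THT, Ah = Ah, bn_sd = bn_sd, bn_state = bn_state,
       Wm = Wm, Vm = Vm)
}

ann_layer_forward <- function(cfg, lay, mask, X, N, T_len, H, l, training,
                              idx_of) {
  act <- activation_fun(cfg$activation)
  blocks <- ann_blocks(cfg$unit)
  Ah <- list(); bn_sd <- list(); bn_state <- lay$bn
  Wm_ff <- list()
  for (g in blocks) {
    Wg <- lay[[paste0("W", g)]]
    if (!is.null(mask) && !is.null(mask$W)) Wg <- Wg * mask$W
    Wm_ff[[g]] <- Wg
    Ag <- X %*% Wg
    if (!is.null(bn_state)) {
      bf <- bn_forward(Ag, bn_state[[g]], training)
      Ah[[g]] <- bf$xhat; bn_sd[[g]] <- bf$sd; bn_state[[g]] <- bf$bn
    } else {
      Ah[[g]] <- Ag; bn_sd[[g]] <- NULL
    }
  }
  Vm <- list()
  for (g in blocks) {
    Vg <- lay[[paste0("V", g)]]
    if (!is.null(Vg) && !is.null(mask) && !is.null(mask$V)) Vg <- Vg * mask$V
    Vm[[g]] <- Vg
  }
  bias <- lapply(blocks, function(g) byrow_mat(lay[[paste0("b", g)]], N))
  names(bias) <- blocks
  Y <- YD <- matrix(0, N * T_len, H)
  Ipre <- stats::setNames(
    lapply(blocks, function(g) matrix(0, N * T_len, H)), blocks)
  Zc <- if (cfg$unit %in% c("ligru", "gru")) matrix(0, N * T_len, H)
  Rc <- if (cfg$unit == "gru") matrix(0, N * T_len, H)
  Hc <- if (cfg$unit %in% c("ligru", "gru")) matrix(0, N * T_len, H)
  DM <- if (training && cfg$dropout > 0) matrix(0, N * T_len, H) else NULL
  yd <- matrix(0, N, H)
  keep_p <- 1 - cfg$dropout
  for (t in seq_len(T_len)) {
    idx <- idx_of(t)
    drive <- function(g) {
      I_g <- Ah[[g]][idx, , drop = FALSE] + bias[[g]]
      if (!is.null(Vm[[g]])) I_g <- I_g + yd %*% Vm[[g]]
      I_g
    }
    if (cfg$unit %in% c("mlp", "rnn")) {
      I_h <- drive("h")
      y <- act$f(I_h)
      Ipre$h[idx, ] <- I_h
    } else if (cfg$unit == "ligru") {
      I_z <- drive("z"); z <- 1 / (1 + exp(-I_z))
      I_h <- drive("h"); hc <- act$f(I_h)
      y <- z * yd + (1 - z) * hc
      Ipre$z[idx, ] <- I_z; Ipre$h[idx, ] <- I_h
      Zc[idx, ] <- z; Hc[idx, ] <- hc
    } else { # gru
      I_z <- drive("z"); z <- 1 / (1 + exp(-I_z))
      I_r <- drive("r"); r <- 1 / (1 + exp(-I_r))
      I_h <- Ah$h[idx, , drop = FALSE] + bias$h
      if (!is.null(Vm$h)) I_h <- I_h + (r * yd) %*% Vm$h
      hc <- act$f(I_h)
      y <- z * yd + (1 - z) * hc
      Ipre$z[idx, ] <- I_z; Ipre$r[idx, ] <- I_r; Ipre$h[idx, ] <- I_h
      Zc[idx, ] <- z; Rc[idx, ] <- r; Hc[idx, ] <- hc
    }
    check_finite(y, l, t)
    Y[idx, ] <- y
    if (!is.null(DM)) {
      m_t <- (matrix(stats::runif(N * H), N, H) >= cfg$dropout) / keep_p
      DM[idx, ] <- m_t
      yd <- y * m_t
    } else {
      yd <- y
    }
    YD[idx, ] <- yd
  }
  list(out = YD, Y = Y, YD = YD, DM = DM, Ipre = Ipre, Zc = Zc, Rc = Rc,
       Hc = Hc, Ah = Ah, bn_sd = bn_sd, bn_state = bn_state, Wm = Wm_ff,
       Vm = Vm, S = NULL)
}

readout_forward <- function(cfg, ro, X, N, T_len, idx_of) {
  C <- cfg$n_classes
  A <- X %*% ro$W
  grp <- rep(seq_len(N), times = T_len)
  if (cfg$type == "ann") {
    if (cfg$recurrent) {
      # cumulative softmax over the penultimate layer, then a linear map
      P <- softmax_rows(X)
      Rsum <- rowsum(P, grp)
      scores <- Rsum %*% ro$W + byrow_mat(ro$bias, N)
      return(list(scores = scores, method = "ann_recurrent", A = A, X = X,
                  P = P, Rsum = Rsum))
    }
    O_all <- A + byrow_mat(ro$bias, N * T_len)
    scores <- rowsum(O_all, grp)
    return(list(scores = scores, method = "ann_plain", A = A, X = X))
  }
  AlphaM <- byrow_mat(ro$np$alpha, N)
  bias <- byrow_mat(ro$bias, N)
  U <- matrix(0, N * T_len, C)
  S <- if (cfg$readout == "spike_count") matrix(0, N * T_len, C) else NULL
  u <- s <- matrix(0, N, C)
  for (t in seq_len(T_len)) {
    idx <- idx_of(t)
    I_t <- A[idx, , drop = FALSE] + bias
    if (cfg$readout == "spike_count") {
      u <- AlphaM * u + (1 - AlphaM) * I_t - s
      s <- (u >= 1) + 0
      S[idx, ] <- s
    } else {
      u <- AlphaM * u + (1 - AlphaM) * I_t
    }
    check_finite(u, "readout", t)
    U[idx, ] <- u
  }
  scores <- switch(cfg$readout,
    cumulative_softmax = rowsum(softmax_rows(U), grp),
    spike_count = rowsum(S, grp),
    last_potential = U[idx_of(T_len), , drop = FALSE],
    max_potential = {
      sc <- matrix(-Inf, N, C)
      tmax <- matrix(1L, N, C)
      for (t in seq_len(T_len)) {
        u_t <- U[idx_of(t), , drop = FALSE]
        upd <- u_t > sc
        sc[upd] <- u_t[upd]
        tmax[upd] <- t
      }
      attr(sc, "tmax") <- tmax
      sc
    })
  tmax <- attr(scores, "tmax")
  attr(scores, "tmax") <- NULL
  list(scores = scores, method = cfg$readout, A = A, X = X, U = U, S = S,
       tmax = tmax)
}

#' Forward pass of a spiking network
#'
#' Runs the full (N, T, F) to (N, C) computation: for each hidden layer the
#' synaptic stimulus (feedforward + recurrent + bias, with optional batch
#' normalization of the feedforward term), the discrete neuron update, the
#' threshold comparison and dropout; then the non-spiking readout
#' integration and scoring.
#'
#' @param model an \code{"sg_network"} built with a spiking kind.
#' @param x input array (N, T, F); a T x F matrix is treated as one example.
#' @param training logical; enables dropout and batch statistics.
#' @param rasters logical; also return per-layer binary spike rasters as
#'   (N, T, H) arrays.
#' @return List with \code{scores} (N x C), \code{rates} (average firing
#'   rate per hidden layer) and optionally \code{rasters}.
#' @export
snn_forward <- function(model, x, training = FALSE, rasters = FALSE) {
  stopifnot(inherits(model, "sg_network"))
  if (model$config$type != "snn") {
    stop("model is not a spiking network; use ann_forward()", call. = FALSE)
  }
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  out <- forward_pass(model, x, training = training)
  res <- list(scores = out$scores, rates = out$rates)
  if (rasters) {
    N <- out$dims[["N"]]; T_len <- out$dims[["T"]]
    res$rasters <- lapply(out$spike_mats, function(S)
      array(S, c(N, T_len, ncol(S))))
  }
  res
}

#' Forward pass of a non-spiking baseline network
#'
#' @inheritParams snn_forward
#' @param model an \code{"sg_network"} built with kind \code{"mlp"},
#'   \code{"rnn"}, \code{"ligru"} or \code{"gru"}.
#' @return List with \code{scores} (N x C).
#' @export
ann_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "sg_network"))
  if (model$config$type != "ann") {
    stop("model is not a non-spiking network; use snn_forward()",
         call. = FALSE)
  }
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  out <- forward_pass(model, x, training = training)
  list(scores = out$scores)
}

#' Readout scores from a potential trace or spike raster
#'
#' Standalone implementation of the four readout schemes on a single
#' sequence: \code{spike_count} sums a spike raster per class;
#' \code{last_potential} takes the final potential; \code{max_potential}
#' the per-class maximum over time; \code{cumulative_softmax} applies a
#' softmax across classes at every step and sums over steps (so the class
#' sum equals T).
#'
#' @param trace T x C matrix: membrane potentials over time (or a binary
#'   raster for \code{spike_count}).
#' @param method one of \code{"spike_count"}, \code{"last_potential"},
#'   \code{"max_potential"}, \code{"cumulative_softmax"}.
#' @return Numeric score vector of length C.
#' @export
readout_scores <- function(trace, method = c("cumulative_softmax",
                                             "spike_count", "last_potential",
                                             "max_potential")) {
  method <- match.arg(method)
  trace <- as.matrix(trace)
  switch(method,
    spike_count = colSums(trace),
    last_potential = trace[nrow(trace), ],
    max_potential = apply(trace, 2, max),
    cumulative_softmax = colSums(softmax_rows(trace)))
}
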