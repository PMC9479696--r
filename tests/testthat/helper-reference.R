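# Independent scalar-loop reference implementations used as oracles for
# the vectorized forward and backward passes. Everything here is written
# with explicit per-example / per-neuron / per-step loops, directly from
# the update equations, and shares no code with the package internals.

ref_boxcar <- function(u, theta = 1) 0.5 * (abs(u - theta) <= 0.5)

# Scalar forward pass for a 1-hidden-layer spiking net (adLIF or LIF, with
# or without recurrence, no batch norm, no dropout) with the
# cumulative-softmax readout. Returns scores and all traces.
ref_snn_forward <- function(net, x) {
  cfg <- net$config
  lay <- net$layers[[1]]
  ro <- net$readout
  H <- cfg$hidden[1]
  C <- cfg$n_classes
  N <- dim(x)[1]; Tn <- dim(x)[2]; Fi <- dim(x)[3]
  scores <- matrix(0, N, C)
  traces <- vector("list", N)
  for (n in seq_len(N)) {
    U <- Wd <- S <- Im <- matrix(0, Tn, H)
    Ur <- Ir <- matrix(0, Tn, C)
    up <- wp <- sp <- numeric(H); urp <- numeric(C)
    for (t in seq_len(Tn)) {
      for (i in seq_len(H)) {
        I <- lay$bias[i]
        for (j in seq_len(Fi)) I <- I + lay$W[j, i] * x[n, t, j]
        if (!is.null(lay$V)) for (k in seq_len(H)) {
          I <- I + lay$V[k, i] * sp[k]
        }
        Im[t, i] <- I
        U[t, i] <- lay$np$alpha[i] * up[i] + (1 - lay$np$alpha[i]) * I -
          wp[i] - sp[i]
        Wd[t, i] <- lay$np$beta[i] * wp[i] +
          (1 - lay$np$beta[i]) * lay$np$a[i] * up[i] + lay$np$b[i] * sp[i]
        S[t, i] <- as.numeric(U[t, i] >= 1)
      }
      up <- U[t, ]; wp <- Wd[t, ]; sp <- S[t, ]
      for (cc in seq_len(C)) {
        I <- ro$bias[cc]
        for (i in seq_len(H)) I <- I + ro$W[i, cc] * S[t, i]
        Ir[t, cc] <- I
        Ur[t, cc] <- ro$np$alpha[cc] * urp[cc] + (1 - ro$np$alpha[cc]) * I
      }
      urp <- Ur[t, ]
    }
    P <- exp(Ur - apply(Ur, 1, max)); P <- P / rowSums(P)
    scores[n, ] <- colSums(P)
    traces[[n]] <- list(U = U, W = Wd, S = S, Im = Im, Ur = Ur, Ir = Ir,
                        P = P)
  }
  list(scores = scores, traces = traces)
}

# Scalar BPTT for the same model class: gradients of the mean
# cross-entropy loss, accumulated with explicit loops.
ref_snn_grads <- function(net, x, y) {
  cfg <- net$config
  lay <- net$layers[[1]]
  ro <- net$readout
  H <- cfg$hidden[1]; C <- cfg$n_classes
  N <- dim(x)[1]; Tn <- dim(x)[2]; Fi <- dim(x)[3]
  fwd <- ref_snn_forward(net, x)
  gW <- matrix(0, Fi, H); gV <- matrix(0, H, H); gb <- numeric(H)
  gal <- gbe <- gaa <- gbb <- numeric(H)
  gWro <- matrix(0, H, C); gbro <- numeric(C); galr <- numeric(C)
  loss <- 0
  for (n in seq_len(N)) {
    tr <- fwd$traces[[n]]
    o <- fwd$scores[n, ]
    sm <- exp(o - max(o)); sm <- sm / sum(sm)
    loss <- loss + (log(sum(exp(o - max(o)))) + max(o) - o[y[n]]) / N
    go <- sm / N; go[y[n]] <- go[y[n]] - 1 / N
    gur_next <- numeric(C); gS <- matrix(0, Tn, H)
    for (t in seq(Tn, 1)) {
      gud <- tr$P[t, ] * go - tr$P[t, ] * sum(tr$P[t, ] * go)
      gur <- gud + ro$np$alpha * gur_next
      gI <- (1 - ro$np$alpha) * gur
      urprev <- if (t > 1) tr$Ur[t - 1, ] else numeric(C)
      galr <- galr + gur * (urprev - tr$Ir[t, ])
      gbro <- gbro + gI
      for (cc in seq_len(C)) for (i in seq_len(H)) {
        gWro[i, cc] <- gWro[i, cc] + tr$S[t, i] * gI[cc]
        gS[t, i] <- gS[t, i] + ro$W[i, cc] * gI[cc]
      }
      gur_next <- gur
    }
    gu_next <- gw_next <- gI_next <- numeric(H)
    for (t in seq(Tn, 1)) {
      gs <- gS[t, ]
      if (t < Tn) {
        if (!is.null(lay$V)) for (i in seq_len(H)) for (k in seq_len(H)) {
          gs[i] <- gs[i] + lay$V[i, k] * gI_next[k]
        }
        gs <- gs - gu_next + lay$np$b * gw_next
      }
      gu <- gs * ref_boxcar(tr$U[t, ])
      if (t < Tn) {
        gu <- gu + lay$np$alpha * gu_next +
          (1 - lay$np$beta) * lay$np$a * gw_next
      }
      gw <- if (t < Tn) lay$np$beta * gw_next - gu_next else numeric(H)
      gI <- (1 - lay$np$alpha) * gu
      uprev <- if (t > 1) tr$U[t - 1, ] else numeric(H)
      wprev <- if (t > 1) tr$W[t - 1, ] else numeric(H)
      sprev <- if (t > 1) tr$S[t - 1, ] else numeric(H)
      gal <- gal + gu * (uprev - tr$Im[t, ])
      gbe <- gbe + gw * (wprev - lay$np$a * uprev)
      gaa <- gaa + gw * (1 - lay$np$beta) * uprev
      gbb <- gbb + gw * sprev
      gb <- gb + gI
      for (j in seq_len(Fi)) for (i in seq_len(H)) {
        gW[j, i] <- gW[j, i] + x[n, t, j] * gI[i]
      }
      if (!is.null(lay$V) && t > 1) {
        for (k in seq_len(H)) for (i in seq_len(H)) {
          gV[k, i] <- gV[k, i] + sprev[k] * gI[i]
        }
      }
      gu_next <- gu; gw_next <- gw; gI_next <- gI
    }
  }
  g <- list("l1.W" = gW, "l1.bias" = gb, "l1.alpha" = gal,
            "ro.W" = gWro, "ro.bias" = gbro, "ro.alpha" = galr)
  if (cfg$unit == "adlif") {
    g$`l1.beta` <- gbe; g$`l1.a` <- gaa; g$`l1.b` <- gbb
  }
  if (!is.null(lay$V)) {
    diag(gV) <- 0
    g$`l1.V` <- gV
  }
  list(loss = loss, grads = g)
}

# A small spiking net with plenty of activity in all paths.
make_active_net <- function(kind = "radlif", Fi = 5, H = 4, C = 3,
                            seed = 11) {
  cfg <- network_config(Fi, H, C, kind = kind, dropout = 0,
                        batchnorm = FALSE)
  net <- build_network(cfg, seed = seed)
  snnet:::with_seed(seed + 1, {
    net$layers[[1]]$bias <- stats::runif(H, 1.0, 2.0)
    if (!is.null(net$layers[[1]]$V)) {
      net$layers[[1]]$V <- zero_diagonal(net$layers[[1]]$V * 4)
    }
    net$readout$W <- net$readout$W * 3
  })
  net
}

# Central finite-difference gradient of the training-mode loss wrt a few
# entries of each parameter tensor (valid only for smooth, non-spiking
# models).
fd_grad <- function(net, x, y, nm, i, eps = 1e-5) {
  params <- snnet:::get_params(net)
  lossf <- function(p) {
    out <- snnet:::forward_pass(snnet:::set_params(net, p), x,
                                training = TRUE)
    cross_entropy_loss(out$scores, y)
  }
  p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
  p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
  (lossf(p1) - lossf(p2)) / (2 * eps)
}

# Byte construction of a 16-bit PCM WAV file for reader tests.
write_pcm16_wav <- function(path, samples, sample_rate,
                            n_channels = 1L) {
  ints <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  data_size <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(as.integer(n_channels), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_channels * 2L), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_channels * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

# Tiny synthetic task for fast end-to-end training tests.
tiny_task <- function(n_classes = 3, seed = 5) {
  synth_spike_task(synth_task_config(
    n_classes = n_classes, n_channels = 30, n_steps = 20,
    events_per_template = 15, jitter_sd = 1, background_rate = 0.01,
    n_train = 12, n_valid = 4, n_test = 4, seed = seed))
}
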