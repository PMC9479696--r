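# Backpropagation through time.
#
# The forward pass stores, per layer, the full (N*T) x H traces needed to
# run the adjoint recursion backward in time. The spike nonlinearity
# contributes surrogate factors (surrogate_grad) in place of the undefined
# step derivative; every other path (leak, reset, adaptation, recurrence,
# batch norm, dropout, readout) is differentiated exactly. Gradients flow
# through the soft-reset term (no detaching).

bn_backward <- function(g, xhat, sd) {
  gm <- byrow_mat(colMeans(g), nrow(g))
  gxm <- byrow_mat(colMeans(g * xhat), nrow(g))
  sweep(g - gm - xhat * gxm, 2, sd, "/")
}

zeros_like <- function(m) matrix(0, nrow(m), ncol(m))

# Returns list(grads = named list, gX = gradient wrt the layer input).
snn_layer_backward <- function(cfg, lay, fw, gSD, N, T_len, idx_of, l) {
  H <- ncol(fw$U)
  np <- lay$np
  AlphaM <- byrow_mat(np$alpha, N)
  BetaM <- byrow_mat(np$beta, N)
  Am <- byrow_mat(np$a, N)
  Bm <- byrow_mat(np$b, N)
  mt <- cfg$unit == "mtlif"
  adlif <- cfg$unit == "adlif"
  if (mt) {
    RhoM <- byrow_mat(np$rho, N)
    GammaM <- byrow_mat(np$gamma, N)
  }
  GAh <- matrix(0, N * T_len, H)
  gbias <- numeric(H)
  galpha <- gbeta <- ga <- gb <- numeric(H)
  grho <- ggamma <- numeric(H)
  gV <- if (!is.null(fw$Vm)) matrix(0, H, H) else NULL
  gu_next <- gw_next <- gI_next <- geta_next <- NULL
  z0 <- matrix(0, N, H)
  for (t in seq(T_len, 1L)) {
    idx <- idx_of(t)
    first <- t == 1L
    last <- t == T_len
    gsd_t <- gSD[idx, , drop = FALSE]
    if (!last && !is.null(fw$Vm)) gsd_t <- gsd_t + gI_next %*% t(fw$Vm)
    gs <- if (!is.null(fw$DM)) gsd_t * fw$DM[idx, , drop = FALSE] else gsd_t
    if (!last) {
      gs <- gs - gu_next               # soft reset, theta = 1 (theta0 for mt)
      if (adlif) gs <- gs + Bm * gw_next
      if (mt) gs <- gs + geta_next     # spike feeds the threshold trace
    }
    u_t <- fw$U[idx, , drop = FALSE]
    if (mt) {
      sg <- surrogate_grad(u_t - fw$THT[idx, , drop = FALSE], theta = 0,
                           spec = cfg$surrogate)
      gtheta <- -(gs * sg)
      eta_t <- fw$ETA[idx, , drop = FALSE]
      eta_prev <- if (first) z0 else fw$ETA[idx_of(t - 1L), , drop = FALSE]
      ggamma <- ggamma + colSums(gtheta * eta_t)
      geta_t <- GammaM * gtheta
      if (!last) geta_t <- geta_t + RhoM * geta_next
      grho <- grho + colSums(geta_t * eta_prev)
      geta_next <- geta_t
    } else {
      sg <- surrogate_grad(u_t, theta = 1, spec = cfg$surrogate)
    }
    gu_t <- gs * sg
    if (!last) {
      gu_t <- gu_t + AlphaM * gu_next
      if (adlif) gu_t <- gu_t + (1 - BetaM) * Am * gw_next
    }
    gw_t <- if (adlif && !last) BetaM * gw_next - gu_next else z0
    gI_t <- (1 - AlphaM) * gu_t
    GAh[idx, ] <- gI_t
    gbias <- gbias + colSums(gI_t)
    u_prev <- if (first) z0 else fw$U[idx_of(t - 1L), , drop = FALSE]
    galpha <- galpha + colSums(gu_t * (u_prev - fw$Imat[idx, , drop = FALSE]))
    if (adlif) {
      w_prev <- if (first) z0 else fw$Wad[idx_of(t - 1L), , drop = FALSE]
      s_prev <- if (first) z0 else fw$S[idx_of(t - 1L), , drop = FALSE]
      gbeta <- gbeta + colSums(gw_t * (w_prev - Am * u_prev))
      ga <- ga + colSums(gw_t * (1 - BetaM) * u_prev)
      gb <- gb + colSums(gw_t * s_prev)
    }
    if (!is.null(gV) && !first) {
      gV <- gV + crossprod(fw$SD[idx_of(t - 1L), , drop = FALSE], gI_t)
    }
    gu_next <- gu_t
    gw_next <- gw_t
    gI_next <- gI_t
  }
  gA <- if (!is.null(fw$bn_sd)) bn_backward(GAh, fw$Ah, fw$bn_sd) else GAh
  gW <- crossprod(fw$X, gA)
  gX <- gA %*% t(fw$Wm)
  grads <- list(W = gW, bias = gbias, alpha = galpha)
  if (adlif) {
    grads$beta <- gbeta; grads$a <- ga; grads$b <- gb
  }
  if (mt) {
    grads$rho <- grho; grads$gamma <- ggamma
  }
  if (!is.null(gV)) {
    diag(gV) <- 0
    grads$V <- gV
  }
  list(grads = grads, gX = gX)
}

ann_layer_backward <- function(cfg, lay, fw, gYD, N, T_len, idx_of, l) {
  H <- ncol(fw$Y)
  act <- activation_fun(cfg$activation)
  blocks <- ann_blocks(cfg$unit)
  GAh <- lapply(stats::setNames(blocks, blocks),
                function(g) matrix(0, N * T_len, H))
  gbias <- lapply(stats::setNames(blocks, blocks), function(g) numeric(H))
  gVmat <- lapply(stats::setNames(blocks, blocks), function(g)
    if (!is.null(fw$Vm[[g]])) matrix(0, H, H) else NULL)
  carry <- matrix(0, N, H)
  for (t in seq(T_len, 1L)) {
    idx <- idx_of(t)
    first <- t == 1L
    ydm1 <- if (first) matrix(0, N, H)
            else fw$YD[idx_of(t - 1L), , drop = FALSE]
    gyd_t <- gYD[idx, , drop = FALSE] + carry
    gy <- if (!is.null(fw$DM)) gyd_t * fw$DM[idx, , drop = FALSE] else gyd_t
    carry <- matrix(0, N, H)
    if (cfg$unit %in% c("mlp", "rnn")) {
      y_t <- fw$Y[idx, , drop = FALSE]
      gI <- gy * act$df(fw$Ipre$h[idx, , drop = FALSE], y_t)
      GAh$h[idx, ] <- gI
      gbias$h <- gbias$h + colSums(gI)
      if (!is.null(fw$Vm$h)) {
        carry <- carry + gI %*% t(fw$Vm$h)
        if (!first) gVmat$h <- gVmat$h + crossprod(ydm1, gI)
      }
    } else {
      z <- fw$Zc[idx, , drop = FALSE]
      hc <- fw$Hc[idx, , drop = FALSE]
      gz <- gy * (ydm1 - hc)
      ghc <- gy * (1 - z)
      carry <- carry + gy * z
      gIh <- ghc * act$df(fw$Ipre$h[idx, , drop = FALSE], hc)
      gIz <- gz * z * (1 - z)
      GAh$h[idx, ] <- gIh
      GAh$z[idx, ] <- gIz
      gbias$h <- gbias$h + colSums(gIh)
      gbias$z <- gbias$z + colSums(gIz)
      carry <- carry + gIz %*% t(fw$Vm$z)
      if (!first) gVmat$z <- gVmat$z + crossprod(ydm1, gIz)
      if (cfg$unit == "ligru") {
        carry <- carry + gIh %*% t(fw$Vm$h)
        if (!first) gVmat$h <- gVmat$h + crossprod(ydm1, gIh)
      } else {
        r <- fw$Rc[idx, , drop = FALSE]
        g_ry <- gIh %*% t(fw$Vm$h)
        gr <- g_ry * ydm1
        carry <- carry + g_ry * r
        gIr <- gr * r * (1 - r)
        GAh$r[idx, ] <- gIr
        gbias$r <- gbias$r + colSums(gIr)
        carry <- carry + gIr %*% t(fw$Vm$r)
        if (!first) {
          gVmat$r <- gVmat$r + crossprod(ydm1, gIr)
          gVmat$h <- gVmat$h + crossprod(r * ydm1, gIh)
        }
      }
    }
  }
  grads <- list()
  gX <- NULL
  for (g in blocks) {
    gA <- if (!is.null(fw$bn_sd[[g]]))
      bn_backward(GAh[[g]], fw$Ah[[g]], fw$bn_sd[[g]]) else GAh[[g]]
    grads[[paste0("W", g)]] <- crossprod(fw$X, gA)
    grads[[paste0("b", g)]] <- gbias[[g]]
    if (!is.null(gVmat[[g]])) grads[[paste0("V", g)]] <- gVmat[[g]]
    contrib <- gA %*% t(fw$Wm[[g]])
    gX <- if (is.null(gX)) contrib else gX + contrib
  }
  list(grads = grads, gX = gX)
}

readout_backward <- function(cfg, ro, rc, gscores, N, T_len, idx_of) {
  grp <- rep(seq_len(N), times = T_len)
  C <- cfg$n_classes
  if (cfg$type == "ann") {
    if (cfg$recurrent) {
      gRsum <- gscores %*% t(ro$W)
      gW <- crossprod(rc$Rsum, gscores)
      gbias <- colSums(gscores)
      gP <- gRsum[grp, , drop = FALSE]
      P <- rc$P
      gX <- P * gP - P * rowSums(P * gP)
      return(list(grads = list(W = gW, bias = gbias), gX = gX))
    }
    gO <- gscores[grp, , drop = FALSE]
    gW <- crossprod(rc$X, gO)
    gbias <- colSums(gO)
    gX <- gO %*% t(ro$W)
    return(list(grads = list(W = gW, bias = gbias), gX = gX))
  }
  AlphaM <- byrow_mat(ro$np$alpha, N)
  bias <- byrow_mat(ro$bias, N)
  GI <- matrix(0, N * T_len, C)
  galpha <- numeric(C)
  gu_next <- NULL
  z0 <- matrix(0, N, C)
  for (t in seq(T_len, 1L)) {
    idx <- idx_of(t)
    last <- t == T_len
    u_t <- rc$U[idx, , drop = FALSE]
    gu_d <- switch(rc$method,
      cumulative_softmax = {
        P <- softmax_rows(u_t)
        P * gscores - P * rowSums(P * gscores)
      },
      last_potential = if (last) gscores else z0,
      max_potential = gscores * (rc$tmax == t),
      spike_count = z0)
    if (rc$method == "spike_count") {
      gs <- gscores
      if (!last) gs <- gs - gu_next
      gu_t <- gs * surrogate_grad(u_t, 1, cfg$surrogate)
      if (!last) gu_t <- gu_t + AlphaM * gu_next
    } else {
      gu_t <- gu_d
      if (!last) gu_t <- gu_t + AlphaM * gu_next
    }
    gI_t <- (1 - AlphaM) * gu_t
    GI[idx, ] <- gI_t
    u_prev <- if (t == 1L) z0 else rc$U[idx_of(t - 1L), , drop = FALSE]
    I_t <- rc$A[idx, , drop = FALSE] + bias
    galpha <- galpha + colSums(gu_t * (u_prev - I_t))
    gu_next <- gu_t
  }
  gW <- crossprod(rc$X, GI)
  gbias <- colSums(GI)
  gX <- GI %*% t(ro$W)
  list(grads = list(W = gW, bias = gbias, alpha = galpha), gX = gX)
}

# Full backward pass: `out` is the result of forward_pass(keep_cache = TRUE),
# gscores the gradient of the loss wrt the (N x C) scores. Returns a flat
# named list of gradients matching get_params().
backward_pass <- function(net, out, gscores) {
  cfg <- net$config
  cache <- out$cache
  if (is.null(cache)) {
    stop("forward_pass must be run with keep_cache = TRUE", call. = FALSE)
  }
  N <- cache$N
  T_len <- cache$T_len
  idx_of <- cache$idx_of
  grads <- list()
  rb <- readout_backward(cfg, net$readout, cache$readout, gscores, N, T_len,
                         idx_of)
  for (nm in names(rb$grads)) grads[[paste0("ro.", nm)]] <- rb$grads[[nm]]
  gX <- rb$gX
  for (l in rev(seq_along(net$layers))) {
    fw <- cache$layers[[l]]
    lb <- if (cfg$type == "snn") {
      snn_layer_backward(cfg, net$layers[[l]], fw, gX, N, T_len, idx_of, l)
    } else {
      ann_layer_backward(cfg, net$layers[[l]], fw, gX, N, T_len, idx_of, l)
    }
    for (nm in names(lb$grads)) {
      g <- lb$grads[[nm]]
      mk <- net$masks[[l]]
      if (!is.null(mk)) {
        if (nm %in% c("W", "Wz", "Wr", "Wh") && !is.null(mk$W)) g <- g * mk$W
        if (nm %in% c("V", "Vz", "Vr", "Vh") && !is.null(mk$V)) g <- g * mk$V
      }
      grads[[paste0("l", l, ".", nm)]] <- g
    }
    gX <- lb$gX
  }
  grads
}

np_fields <- function(cfg) {
  switch(cfg$unit,
    lif = "alpha",
    adlif = c("alpha", "beta", "a", "b"),
    mtlif = c("alpha", "rho", "gamma"),
    character(0))
}

# Flat named list of every trainable tensor in the network.
get_params <- function(net) {
  cfg <- net$config
  out <- list()
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    pre <- paste0("l", l, ".")
    if (cfg$type == "snn") {
      out[[paste0(pre, "W")]] <- lay$W
      if (!is.null(lay$V)) out[[paste0(pre, "V")]] <- lay$V
      out[[paste0(pre, "bias")]] <- lay$bias
      for (f in np_fields(cfg)) out[[paste0(pre, f)]] <- lay$np[[f]]
    } else {
      for (g in ann_blocks(cfg$unit)) {
        out[[paste0(pre, "W", g)]] <- lay[[paste0("W", g)]]
        if (!is.null(lay[[paste0("V", g)]])) {
          out[[paste0(pre, "V", g)]] <- lay[[paste0("V", g)]]
        }
        out[[paste0(pre, "b", g)]] <- lay[[paste0("b", g)]]
      }
    }
  }
  out[["ro.W"]] <- net$readout$W
  out[["ro.bias"]] <- net$readout$bias
  if (cfg$type == "snn") out[["ro.alpha"]] <- net$readout$np$alpha
  out
}

set_params <- function(net, params) {
  cfg <- net$config
  for (nm in names(params)) {
    v <- params[[nm]]
    if (startsWith(nm, "ro.")) {
      f <- sub("^ro\\.", "", nm)
      if (f == "alpha") net$readout$np$alpha <- v
      else net$readout[[f]] <- v
    } else {
      m <- regmatches(nm, regexec("^l([0-9]+)\\.(.+)$", nm))[[1]]
      l <- as.integer(m[2]); f <- m[3]
      if (cfg$type == "snn" && f %in% c("alpha", "beta", "a", "b",
                                        "rho", "gamma")) {
        net$layers[[l]]$np[[f]] <- v
      } else {
        net$layers[[l]][[f]] <- v
      }
    }
  }
  net
}

# Post-update projection: clamp neuron parameters into their ranges, force
# recurrent diagonals to zero, and keep masked weights exactly zero.
apply_constraints <- function(net) {
  cfg <- net$config
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    if (cfg$type == "snn") {
      # ANN recurrence (Eq 10-style) keeps its diagonal; only spiking
      # feedback must not self-excite against refractoriness.
      lay$np <- clamp_neuron_params(lay$np, cfg$ranges)
      if (!is.null(lay$V)) lay$V <- zero_diagonal(lay$V)
    }
    mk <- net$masks[[l]]
    if (!is.null(mk)) {
      if (!is.null(mk$W)) {
        for (wn in intersect(names(lay), c("W", "Wz", "Wr", "Wh"))) {
          lay[[wn]] <- lay[[wn]] * mk$W
        }
      }
      if (!is.null(mk$V)) {
        for (vn in intersect(names(lay), c("V", "Vz", "Vr", "Vh"))) {
          if (!is.null(lay[[vn]])) lay[[vn]] <- lay[[vn]] * mk$V
        }
      }
    }
    net$layers[[l]] <- lay
  }
  if (cfg$type == "snn") {
    net$readout$np <- clamp_neuron_params(net$readout$np, cfg$ranges)
  }
  net
}
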