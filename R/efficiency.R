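#' Trainable-parameter accounting
#'
#' Per-layer contributions for a layer of size N with N_prev inputs:
#' feedforward weights N_prev*N, recurrent weights N*N (the structurally
#' zero diagonal is included in the count), biases N, and neuron parameters
#' N for LIF (alpha), 4N for adLIF (alpha, beta, a, b), 3N for the
#' moving-threshold variant (alpha, rho, gamma). The readout layer counts
#' its feedforward weights, biases and (for spiking networks) one alpha per
#' readout unit. Gated non-spiking units multiply the weight and bias
#' blocks by their gate count (1 for MLP/RNN, 2 for the one-gate light
#' unit, 3 for the GRU).
#'
#' @param config a [network_config()].
#' @param sparsity optional [sparsity_config()]; when given, the total is
#'   reduced to the retained-weight count \code{round((1 - p) * E)} over
#'   the scope's maskable entries.
#' @return A data frame of class \code{"param_breakdown"} with one row per
#'   layer and columns \code{feedforward}, \code{recurrent}, \code{bias},
#'   \code{neuron}, plus attribute \code{total}.
#' @examples
#' cfg <- network_config(700, c(128, 128), 20, kind = "adlif")
#' count_parameters(cfg)$total  # 109864
#' @export
count_parameters <- function(config, sparsity = NULL) {
  stopifnot(inherits(config, "network_config"))
  sizes <- c(config$input_size, config$hidden)
  n_hidden <- length(config$hidden)
  gates <- if (config$type == "ann") length(ann_blocks(config$unit)) else 1L
  np_per <- if (config$type == "snn") length(np_fields(config)) else 0L
  rows <- lapply(seq_len(n_hidden), function(l) {
    H <- sizes[l + 1]
    data.frame(layer = paste0("hidden", l),
               feedforward = gates * sizes[l] * H,
               recurrent = if (config$recurrent) gates * H * H else 0,
               bias = gates * H,
               neuron = np_per * H)
  })
  C <- config$n_classes
  rows[[n_hidden + 1]] <- data.frame(
    layer = "readout",
    feedforward = sizes[n_hidden + 1] * C,
    recurrent = 0,
    bias = C,
    neuron = if (config$type == "snn") C else 0)
  bd <- do.call(rbind, rows)
  total <- sum(bd$feedforward) + sum(bd$recurrent) + sum(bd$bias) +
    sum(bd$neuron)
  if (!is.null(sparsity)) {
    E <- maskable_entries(config, sparsity$scope)
    total <- total - E + round((1 - sparsity$proportion) * E)
  }
  structure(bd, total = total, class = c("param_breakdown", "data.frame"))
}

#' @export
print.param_breakdown <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("total trainable parameters:",
      format(attr(x, "total"), big.mark = ","), "\n")
  invisible(x)
}

#' @rdname count_parameters
#' @param x a \code{"param_breakdown"}.
#' @export
total_parameters <- function(x) attr(x, "total")

# `$` on a data.frame would not reach the attribute; give the natural
# accessor used in examples.
#' @export
`$.param_breakdown` <- function(x, name) {
  if (identical(name, "total")) return(attr(x, "total"))
  NextMethod()
}

#' Sparsity configuration
#'
#' Random connection pruning: a proportion \code{p} of the maskable weight
#' entries is removed, where the scope is either the first layer's
#' feedforward matrix (useful when the input dimension dominates, e.g. 700
#' spike channels) or all hidden layers' feedforward and recurrent
#' matrices. The retained count is exact: \code{round((1 - p) * E)} ones
#' are placed uniformly at random over the \code{E} entries of the whole
#' scope.
#'
#' @param proportion removed proportion p in \[0, 1\].
#' @param scope \code{"first_layer_ff"} or \code{"all_hidden_ff_and_rec"}.
#' @param seed integer seed for the mask draw.
#' @return Object of class \code{"sparsity_config"}.
#' @export
sparsity_config <- function(proportion,
                            scope = c("first_layer_ff",
                                      "all_hidden_ff_and_rec"),
                            seed = 1L) {
  if (!is.numeric(proportion) || length(proportion) != 1L ||
      is.na(proportion) || proportion < 0 || proportion > 1) {
    stop("sparsity proportion must lie in [0, 1]", call. = FALSE)
  }
  structure(list(proportion = proportion, scope = match.arg(scope),
                 seed = as.integer(seed)),
            class = "sparsity_config")
}

scope_tensors <- function(config, scope) {
  sizes <- c(config$input_size, config$hidden)
  out <- list()
  if (scope == "first_layer_ff") {
    out[[1]] <- list(layer = 1L, which = "W", dim = c(sizes[1], sizes[2]))
  } else {
    k <- 0L
    for (l in seq_along(config$hidden)) {
      H <- sizes[l + 1]
      k <- k + 1L
      out[[k]] <- list(layer = l, which = "W", dim = c(sizes[l], H))
      if (config$recurrent) {
        k <- k + 1L
        out[[k]] <- list(layer = l, which = "V", dim = c(H, H))
      }
    }
  }
  out
}

maskable_entries <- function(config, scope) {
  sum(vapply(scope_tensors(config, scope),
             function(tn) prod(tn$dim), numeric(1)))
}

#' Random sparsity masks
#'
#' Draws the binary keep-masks implementing [sparsity_config()]: exactly
#' \code{round((1 - p) * E)} ones distributed uniformly at random over the
#' concatenated entries of every tensor in scope. Masks are applied
#' multiplicatively at every forward pass, and masked weights are reset to
#' exactly zero after every optimizer step.
#'
#' @param config a [network_config()].
#' @param sparsity a [sparsity_config()].
#' @return List with one element per hidden layer: \code{NULL} outside the
#'   scope, otherwise a list of binary matrices \code{W} and (when in
#'   scope) \code{V}.
#' @export
make_sparsity_masks <- function(config, sparsity) {
  stopifnot(inherits(config, "network_config"),
            inherits(sparsity, "sparsity_config"))
  tensors <- scope_tensors(config, sparsity$scope)
  E <- sum(vapply(tensors, function(tn) prod(tn$dim), numeric(1)))
  keep_n <- round((1 - sparsity$proportion) * E)
  keep <- logical(E)
  keep[with_seed(sparsity$seed, sample.int(E, keep_n))] <- TRUE
  masks <- vector("list", length(config$hidden))
  off <- 0L
  for (tn in tensors) {
    n_e <- prod(tn$dim)
    m <- matrix(as.numeric(keep[(off + 1L):(off + n_e)]),
                tn$dim[1], tn$dim[2])
    if (is.null(masks[[tn$layer]])) masks[[tn$layer]] <- list()
    masks[[tn$layer]][[tn$which]] <- m
    off <- off + n_e
  }
  masks
}

#' Attach sparsity masks to a built network
#'
#' @param net an \code{"sg_network"}.
#' @param sparsity a [sparsity_config()], or a mask list from
#'   [make_sparsity_masks()].
#' @return The network with masks attached and masked weights zeroed.
#' @export
attach_masks <- function(net, sparsity) {
  stopifnot(inherits(net, "sg_network"))
  masks <- if (inherits(sparsity, "sparsity_config")) {
    make_sparsity_masks(net$config, sparsity)
  } else {
    sparsity
  }
  net$masks <- masks
  apply_constraints(net)
}

# Number of trainable scalars actually free in a built network (masked
# entries excluded). Oracle counterpart of count_parameters().
n_trainable <- function(net) {
  total <- sum(vapply(get_params(net), length, numeric(1)))
  # the same mask covers every gate block of a gated unit
  blocks_per_mask <- if (net$config$type == "ann") {
    length(ann_blocks(net$config$unit))
  } else {
    1L
  }
  for (l in seq_along(net$layers)) {
    mk <- net$masks[[l]]
    if (is.null(mk)) next
    for (wch in names(mk)) {
      total <- total - sum(mk[[wch]] == 0) * blocks_per_mask
    }
  }
  total
}

#' Firing-rate statistics
#'
#' Average firing rate \eqn{\bar\nu}: the fraction of neuron-time cells
#' containing a spike, computed over all supplied rasters (per time step;
#' at the 1 ms convention a rate of 0.1 means one spike per 10 steps).
#'
#' @param rasters a binary spike array/matrix, or a (possibly named) list
#'   of them — e.g. one per layer.
#' @param counts allow non-binary (count) entries.
#' @return List with \code{nu_bar} and \code{per_layer} rates.
#' @export
firing_stats <- function(rasters, counts = FALSE) {
  if (!is.list(rasters)) rasters <- list(rasters)
  for (r in rasters) {
    if (!counts && !all(r %in% c(0, 1))) {
      stop("rasters must be binary (set counts = TRUE for count data)",
           call. = FALSE)
    }
  }
  tot <- sum(vapply(rasters, sum, numeric(1)))
  cells <- sum(vapply(rasters, length, numeric(1)))
  list(nu_bar = tot / cells,
       per_layer = vapply(rasters, mean, numeric(1)))
}

#' Synaptic-operation energy model
#'
#' Per time step, a dense layer of N units with N_prev inputs needs
#' N (N_prev + N + 1) multiply-and-accumulate (MAC) operations when
#' recurrent (N (N_prev + 1) when not). Binary spike trains let the same
#' dot products run as accumulates (AC) only where a spike occurred, i.e.
#' \eqn{\bar\nu N (N_{prev} + N + 1)} ACs — removing a fraction
#' \eqn{1 - \bar\nu} of the operations — and an AC costs 0.1 pJ against
#' 3.2 pJ for a MAC (45 nm CMOS figures). Neuron-internal state updates
#' scale only with N per layer and are reported separately, outside the
#' headline ratio.
#'
#' @param nu_bar average firing rate in \[0, 1\].
#' @param input_size,hidden,n_classes layer sizes; alternatively pass a
#'   [network_config()] as \code{config}.
#' @param recurrent logical (scalar or per hidden layer).
#' @param e_ac,e_mac energy per operation in pJ.
#' @param config optional [network_config()] overriding the size arguments.
#' @return List of class \code{"energy_report"}: per-layer and total MAC
#'   and AC counts, energies per time step (pJ), the fraction of
#'   dot-product operations removed, and the dense/spiking energy ratio.
#' @examples
#' energy_report(nu_bar = 0.1, input_size = 700, hidden = c(128, 128),
#'               n_classes = 20, recurrent = TRUE)$ratio  # 320
#' @export
energy_report <- function(nu_bar, input_size = NULL, hidden = NULL,
                          n_classes = NULL, recurrent = FALSE,
                          e_ac = 0.1, e_mac = 3.2, config = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "network_config"))
    input_size <- config$input_size
    hidden <- config$hidden
    n_classes <- config$n_classes
    recurrent <- config$recurrent
  }
  if (!is.numeric(nu_bar) || nu_bar < 0 || nu_bar > 1) {
    stop("nu_bar must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(e_ac > 0, e_mac > 0)
  sizes <- c(input_size, hidden, n_classes)
  n_lay <- length(sizes) - 1L
  rec <- rep_len(as.logical(recurrent), n_lay)
  rec[n_lay] <- FALSE   # readout has no recurrent connections
  macs <- vapply(seq_len(n_lay), function(l) {
    sizes[l + 1] * (sizes[l] + (if (rec[l]) sizes[l + 1] else 0) + 1)
  }, numeric(1))
  acs <- nu_bar * macs
  ratio <- if (nu_bar > 0) (sum(macs) * e_mac) / (sum(acs) * e_ac) else Inf
  if (!is.finite(ratio)) {
    warning("nu_bar = 0: no spikes, dense/spiking energy ratio is infinite")
  }
  structure(list(
    per_layer = data.frame(layer = seq_len(n_lay),
                           macs = macs, acs = acs),
    macs = sum(macs), acs = sum(acs),
    e_mac = e_mac, e_ac = e_ac, nu_bar = nu_bar,
    dense_energy_pj = sum(macs) * e_mac,
    spiking_energy_pj = sum(acs) * e_ac,
    ops_removed_fraction = 1 - nu_bar,
    per_op_factor = e_mac / e_ac,
    ratio = ratio,
    neuron_update_ops = sum(sizes[-1])
  ), class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("Energy model (per time step), nu_bar = %.3g\n", x$nu_bar))
  cat(sprintf("  dense MACs: %s  (%.4g pJ)\n",
              format(x$macs, big.mark = ","), x$dense_energy_pj))
  cat(sprintf("  spiking ACs: %s  (%.4g pJ)\n",
              format(x$acs, big.mark = ","), x$spiking_energy_pj))
  cat(sprintf("  dot-product ops removed: %.1f%%\n",
              100 * x$ops_removed_fraction))
  cat(sprintf("  dense/spiking energy ratio: %.4g\n", x$ratio))
  invisible(x)
}
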