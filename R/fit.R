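#' Fit a spiking (or baseline) sequence classifier
#'
#' High-level modelling interface: builds the network described by the
#' arguments, holds out a validation split when none is supplied, runs
#' surrogate-gradient BPTT with Adam and the plateau scheduler, and
#' returns a fitted-model object with the usual methods
#' (\code{print}, \code{summary}, \code{coef}, \code{predict},
#' \code{plot}, \code{simulate}).
#'
#' @param x input sequences: an N x T x F array (binary spike rasters or
#'   real-valued feature frames).
#' @param y labels: factor or integer vector of length N.
#' @param hidden hidden layer sizes (default \code{c(128, 128)}).
#' @param kind unit kind, see [network_config()] (default \code{"adlif"}).
#' @param readout readout scheme, see [network_config()].
#' @param lr initial learning rate; the default 0.01 suits binary spike
#'   inputs, 0.001 is the convention for real-valued features.
#' @param epochs,batch_size,factor,patience see [train_config()].
#' @param valid either a fraction in (0, 1) held out from \code{x}
#'   (default 0.05), or a list \code{list(x =, y =)} used as-is, or
#'   \code{NULL} to monitor training accuracy instead.
#' @param sparsity optional [sparsity_config()].
#' @param dropout,batchnorm,surrogate,activation see [network_config()].
#' @param seed integer seed controlling initialization, the validation
#'   split, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return Object of class \code{"snn_fit"}.
#' @examples
#' \donttest{
#' task <- synth_spike_task(synth_task_config(
#'   n_classes = 4, n_channels = 40, n_steps = 30, events_per_template = 20,
#'   n_train = 8, n_valid = 2, n_test = 4, seed = 7))
#' fit <- snn_fit(task$train$x, task$train$y, hidden = c(16, 16),
#'                epochs = 5, seed = 7)
#' predict(fit, task$test$x)
#' }
#' @export
snn_fit <- function(x, y, hidden = c(128, 128), kind = "adlif",
                    readout = "cumulative_softmax", lr = 0.01,
                    epochs = 100, batch_size = 128, factor = 0.7,
                    patience = 10, valid = 0.05, sparsity = NULL,
                    dropout = 0.1, batchnorm = TRUE,
                    surrogate = surrogate_spec("boxcar"),
                    activation = "sigmoid", seed = 1L, verbose = FALSE) {
  cl <- match.call()
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(y))
  y_fac <- if (is.factor(y)) y else factor(y)
  levels <- levels(y_fac)
  y_int <- as.integer(y_fac)
  cfg <- network_config(input_size = dim(x)[3], hidden = hidden,
                        n_classes = length(levels), kind = kind,
                        readout = readout, dropout = dropout,
                        batchnorm = batchnorm, surrogate = surrogate,
                        activation = activation)
  net <- build_network(cfg, seed = seed)
  if (!is.null(sparsity)) net <- attach_masks(net, sparsity)
  if (is.numeric(valid) && length(valid) == 1L) {
    sp <- split_train_valid(list(x = x, y = y_int), fraction = valid,
                            seed = seed)
    train_data <- sp$train
    valid_data <- sp$valid
  } else if (is.list(valid)) {
    train_data <- list(x = x, y = y_int)
    vy <- if (is.factor(valid$y)) as.integer(factor(valid$y,
                                                    levels = levels))
          else as.integer(valid$y)
    valid_data <- list(x = valid$x, y = vy)
  } else {
    train_data <- list(x = x, y = y_int)
    valid_data <- NULL
  }
  tc <- train_config(lr = lr, epochs = epochs, batch_size = batch_size,
                     factor = factor, patience = patience, seed = seed,
                     verbose = verbose)
  res <- train(net, train_data, valid_data, tc)
  structure(list(network = res$model, history = res$history,
                 levels = levels, config = cfg, train_config = tc,
                 call = cl),
            class = "snn_fit")
}

#' @export
print.snn_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Surrogate-gradient %s classifier (%s)\n",
              if (cfg$type == "snn") "spiking" else "non-spiking",
              toupper(cfg$kind)))
  cat(sprintf("  architecture: %d -> %s -> %d classes; readout: %s\n",
              cfg$input_size, paste(cfg$hidden, collapse = " x "),
              cfg$n_classes,
              if (cfg$type == "snn") cfg$readout else "cumulative sum"))
  h <- x$history
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf(
      "  %d epochs; final loss %.4f, train acc %.3f, valid acc %s\n",
      nrow(h), last$loss, last$train_acc,
      ifelse(is.na(last$valid_acc), "-", sprintf("%.3f", last$valid_acc))))
  }
  invisible(x)
}

#' @export
summary.snn_fit <- function(object, ...) {
  pb <- count_parameters(object$config)
  out <- list(config = object$config, params = pb,
              n_trainable = n_trainable(object$network),
              history = object$history)
  class(out) <- "summary.snn_fit"
  out
}

#' @export
print.summary.snn_fit <- function(x, ...) {
  cat("Parameter breakdown:\n")
  print(x$params)
  if (x$n_trainable != attr(x$params, "total")) {
    cat("after sparsification:", format(x$n_trainable, big.mark = ","),
        "\n")
  }
  h <- x$history
  if (nrow(h)) {
    cat(sprintf("training: %d epochs, final lr %.3g\n", nrow(h),
                h$lr[nrow(h)]))
  }
  invisible(x)
}

#' @export
coef.snn_fit <- function(object, ...) {
  get_params(object$network)
}

#' Predict from a fitted classifier
#'
#' @param object an \code{"snn_fit"}.
#' @param newdata N x T x F array (or a single T x F matrix).
#' @param type \code{"class"} (default), \code{"score"} (raw readout
#'   activities), or \code{"prob"} (softmax of the scores).
#' @param ... unused.
#' @return Factor of predicted classes, or an N x C matrix.
#' @export
predict.snn_fit <- function(object, newdata,
                            type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) {
    newdata <- array(newdata, c(1L, nrow(newdata), ncol(newdata)))
  }
  sc <- scores_of(object$network, newdata)
  colnames(sc) <- object$levels
  switch(type,
    class = factor(object$levels[predict_classes(sc)],
                   levels = object$levels),
    score = sc,
    prob = softmax_rows(sc))
}

#' @export
plot.snn_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Loss", ...)
  ylim <- range(c(h$train_acc, h$valid_acc), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_acc, type = "l", ylim = ylim,
                 xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  if (any(!is.na(h$valid_acc))) {
    graphics::lines(h$epoch, h$valid_acc, lty = 2)
    graphics::legend("bottomright", c("train", "valid"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Simulate spiking responses of a fitted network
#'
#' Runs the fitted network on the given inputs and returns the hidden
#' layers' binary spike rasters — the network's simulated spiking activity
#' — together with the average firing rate per layer.
#'
#' @param object a fitted \code{"snn_fit"} with a spiking architecture.
#' @param nsim number of input examples to simulate (taken from the first
#'   \code{nsim} rows of \code{newdata}).
#' @param seed unused (inference is deterministic); kept for the generic.
#' @param newdata N x T x F input array.
#' @param ... unused.
#' @return List with \code{rasters} (one N x T x H binary array per hidden
#'   layer) and \code{rates}.
#' @export
simulate.snn_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (object$config$type != "snn") {
    stop("simulate() is only meaningful for spiking networks",
         call. = FALSE)
  }
  if (is.matrix(newdata)) {
    newdata <- array(newdata, c(1L, nrow(newdata), ncol(newdata)))
  }
  nsim <- min(nsim, dim(newdata)[1])
  out <- snn_forward(object$network,
                     newdata[seq_len(nsim), , , drop = FALSE],
                     rasters = TRUE)
  list(rasters = out$rasters, rates = out$rates)
}
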