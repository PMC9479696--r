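#' Training configuration
#'
#' Optimization recipe: Adam with an initial learning rate of 0.01 for
#' spike-raster inputs (0.001 is the convention for real-valued feature
#' inputs), and a plateau scheduler that multiplies the learning rate by
#' \code{factor} whenever the validation accuracy has not improved for
#' \code{patience} epochs in a row.
#'
#' @param lr initial learning rate.
#' @param epochs number of epochs (default 100).
#' @param batch_size minibatch size (default 128).
#' @param factor scheduler decay factor in (0, 1), default 0.7.
#' @param patience scheduler patience in epochs, default 10.
#' @param seed integer seed controlling shuffling and dropout.
#' @param shuffle reshuffle training examples every epoch.
#' @param verbose print one line per epoch.
#' @return Object of class \code{"train_config"}.
#' @export
train_config <- function(lr = 0.01, epochs = 100, batch_size = 128,
                         factor = 0.7, patience = 10, seed = 1L,
                         shuffle = TRUE, verbose = FALSE) {
  stopifnot(lr > 0, factor > 0, factor < 1, patience >= 1, epochs >= 0,
            batch_size >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), factor = factor,
                 patience = as.integer(patience), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), verbose = isTRUE(verbose)),
            class = "train_config")
}

check_batch <- function(data, n_classes) {
  if (!is.list(data) || is.null(data$x) || is.null(data$y)) {
    stop("data must be a list(x = N x T x F array, y = labels)",
         call. = FALSE)
  }
  if (length(dim(data$x)) != 3L) {
    stop("data$x must be an N x T x F array", call. = FALSE)
  }
  y <- as.integer(data$y)
  if (dim(data$x)[1] != length(y) || length(y) < 1L) {
    stop("data$y length must match the batch dimension of data$x",
         call. = FALSE)
  }
  if (any(y < 1L) || any(y > n_classes)) {
    stop("labels must be integers in 1..n_classes", call. = FALSE)
  }
  y
}

#' Cross-entropy loss on readout scores
#'
#' Mean over the batch of the negative log-softmax of the true-class score.
#'
#' @param scores N x C numeric matrix of per-class activities.
#' @param labels integer vector of true classes in 1..C.
#' @return Scalar loss.
#' @examples
#' cross_entropy_loss(matrix(0, 2, 20), c(1, 5))  # log(20)
#' @export
cross_entropy_loss <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(labels) != nrow(scores) || any(labels < 1L) ||
      any(labels > ncol(scores))) {
    stop("labels must be integers in 1..ncol(scores), one per row",
         call. = FALSE)
  }
  m <- apply(scores, 1, max)
  lse <- m + log(rowSums(exp(scores - m)))
  mean(lse - scores[cbind(seq_len(nrow(scores)), labels)])
}

cross_entropy_grad <- function(scores, labels) {
  P <- softmax_rows(as.matrix(scores))
  P[cbind(seq_len(nrow(P)), as.integer(labels))] <-
    P[cbind(seq_len(nrow(P)), as.integer(labels))] - 1
  P / nrow(P)
}

adam_init <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$step <- state$step + 1L
  c1 <- 1 - beta1^state$step
  c2 <- 1 - beta2^state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

scores_of <- function(net, x, training = FALSE) {
  forward_pass(net, x, training = training)$scores
}

predict_classes <- function(scores) max.col(scores, ties.method = "first")

batch_indices <- function(n, batch_size) {
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) s:min(s + batch_size - 1L, n))
}

#' Train a network by surrogate-gradient BPTT
#'
#' Runs minibatch Adam over the cross-entropy loss: forward pass, full
#' backpropagation through time (with the surrogate derivative standing in
#' for the spike-function derivative), optimizer step, then projection —
#' neuron parameters clamped into their ranges, recurrent diagonals
#' re-zeroed, sparsity masks re-applied. The plateau scheduler monitors
#' validation accuracy (training accuracy when no validation set is given).
#'
#' @param model an \code{"sg_network"} from [build_network()].
#' @param train_data list with \code{x} (N x T x F array) and \code{y}
#'   (integer labels in 1..C).
#' @param valid_data optional list of the same form.
#' @param cfg a [train_config()].
#' @return List with the updated \code{model} and \code{history}, a data
#'   frame with one row per epoch (loss, train/valid accuracy, lr).
#' @export
train <- function(model, train_data, valid_data = NULL,
                  cfg = train_config()) {
  stopifnot(inherits(model, "sg_network"), inherits(cfg, "train_config"))
  C <- model$config$n_classes
  y_tr <- check_batch(train_data, C)
  if (!is.null(valid_data)) y_va <- check_batch(valid_data, C)
  n <- length(y_tr)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_acc = numeric(0), valid_acc = numeric(0),
                        lr = numeric(0))
  if (cfg$epochs == 0L) return(list(model = model, history = history))

  with_seed(cfg$seed, {
    params <- get_params(model)
    opt <- adam_init(params)
    lr <- cfg$lr
    best_acc <- -Inf
    wait <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      t0 <- proc.time()[3]
      ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
      ep_loss <- 0
      ep_correct <- 0
      for (idx in batch_indices(n, cfg$batch_size)) {
        sel <- ord[idx]
        xb <- train_data$x[sel, , , drop = FALSE]
        yb <- y_tr[sel]
        out <- forward_pass(model, xb, training = TRUE, keep_cache = TRUE)
        model <- out$net   # batch-norm running statistics advance
        loss <- cross_entropy_loss(out$scores, yb)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged: non-finite loss at epoch %d",
                       epoch), call. = FALSE)
        }
        grads <- backward_pass(model, out, cross_entropy_grad(out$scores, yb))
        params <- get_params(model)
        st <- adam_step(params, grads, opt, lr)
        opt <- st$state
        model <- apply_constraints(set_params(model, st$params))
        ep_loss <- ep_loss + loss * length(sel)
        ep_correct <- ep_correct + sum(predict_classes(out$scores) == yb)
      }
      train_acc <- ep_correct / n
      valid_acc <- if (!is.null(valid_data)) {
        evaluate(model, valid_data)$accuracy
      } else NA_real_
      monitor <- if (is.na(valid_acc)) train_acc else valid_acc
      if (monitor > best_acc) {
        best_acc <- monitor
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) {
          lr <- lr * cfg$factor
          wait <- 0L
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = ep_loss / n, train_acc = train_acc,
        valid_acc = valid_acc, lr = lr))
      if (cfg$verbose) {
        message(sprintf(
          "epoch %3d  loss %.4f  train %.3f  valid %s  lr %.2e  (%.1fs)",
          epoch, ep_loss / n, train_acc,
          ifelse(is.na(valid_acc), "-", sprintf("%.3f", valid_acc)), lr,
          proc.time()[3] - t0))
      }
    }
    list(model = model, history = history)
  })
}

#' Evaluate a network
#'
#' Deterministic inference (dropout off, batch statistics frozen): the
#' predicted class is the readout neuron with the highest activity, ties
#' broken toward the lowest class index.
#'
#' @param model an \code{"sg_network"}.
#' @param data list with \code{x} and \code{y} as in [train()].
#' @param batch_size evaluation chunk size.
#' @return List with \code{accuracy} in \[0, 1\] and \code{confusion}, a
#'   C x C count matrix (rows = true class, columns = predicted).
#' @export
evaluate <- function(model, data, batch_size = 256L) {
  C <- model$config$n_classes
  y <- check_batch(data, C)
  pred <- integer(length(y))
  for (idx in batch_indices(length(y), batch_size)) {
    sc <- scores_of(model, data$x[idx, , , drop = FALSE])
    pred[idx] <- predict_classes(sc)
  }
  confusion <- matrix(0L, C, C,
                      dimnames = list(true = seq_len(C), pred = seq_len(C)))
  for (i in seq_along(y)) {
    confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  }
  list(accuracy = mean(pred == y), confusion = confusion)
}
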