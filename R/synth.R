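#' Synthetic task configuration
#'
#' Generator settings for the in-repo datasets that emulate the structure
#' of cochlear-encoded speech: each class is defined by a fixed random
#' spatiotemporal template; examples are the template corrupted by
#' per-event temporal jitter and background noise. By default (matching
#' the event-data convention) the grid is 700 channels by 100 time steps.
#'
#' @param n_classes number of classes (default 10).
#' @param n_channels channels F (default 700).
#' @param n_steps time steps T (default 100).
#' @param events_per_template anchor events (spike task) or spectro-
#'   temporal bumps (feature task) per class template (default 120).
#' @param jitter_sd per-event Gaussian temporal jitter, in steps
#'   (default 2).
#' @param background_rate background spike probability per
#'   (step, channel) cell (default 0.005).
#' @param noise_sd additive white-noise standard deviation for the
#'   feature-sequence task (default 0.1).
#' @param n_train,n_valid,n_test examples per class in each split
#'   (defaults 100/20/20, a scaled-down echo of the per-class abundance of
#'   the event-based speech benchmarks).
#' @param shared_channels if TRUE (default) every class places its events
#'   on one common pool of channels, so class identity is carried purely
#'   by spike timing rather than by which channels are active — the
#'   spatiotemporal structure a spiking network can exploit and a
#'   time-agnostic model cannot.
#' @param seed integer seed; the entire dataset is a deterministic
#'   function of the configuration.
#' @return Object of class \code{"synth_task_config"}.
#' @export
synth_task_config <- function(n_classes = 10, n_channels = 700,
                              n_steps = 100, events_per_template = 120,
                              jitter_sd = 2, background_rate = 0.005,
                              noise_sd = 0.1, n_train = 100, n_valid = 20,
                              n_test = 20, shared_channels = TRUE,
                              seed = 1L) {
  counts <- c(n_classes, n_channels, n_steps, events_per_template,
              n_train, n_valid, n_test)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (jitter_sd < 0 || background_rate < 0 || noise_sd < 0) {
    stop("jitter, background rate and noise sd must be >= 0", call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels),
                 n_steps = as.integer(n_steps),
                 events_per_template = as.integer(events_per_template),
                 jitter_sd = jitter_sd, background_rate = background_rate,
                 noise_sd = noise_sd, n_train = as.integer(n_train),
                 n_valid = as.integer(n_valid), n_test = as.integer(n_test),
                 shared_channels = isTRUE(shared_channels),
                 seed = as.integer(seed)),
            class = "synth_task_config")
}

make_templates <- function(cfg) {
  K <- cfg$events_per_template
  pool <- if (cfg$shared_channels) {
    sample.int(cfg$n_channels, K, replace = K > cfg$n_channels)
  } else {
    NULL
  }
  lapply(seq_len(cfg$n_classes), function(k) {
    data.frame(
      channel = pool %||% sample.int(cfg$n_channels, K,
                                     replace = K > cfg$n_channels),
      step = sample.int(cfg$n_steps, K, replace = TRUE)
    )
  })
}

spike_example <- function(tpl, cfg) {
  r <- matrix(0, cfg$n_steps, cfg$n_channels)
  steps <- round(tpl$step + stats::rnorm(nrow(tpl), 0, cfg$jitter_sd))
  steps <- pmin(pmax(steps, 1L), cfg$n_steps)   # jittered events clipped
  r[cbind(steps, tpl$channel)] <- 1
  if (cfg$background_rate > 0) {
    bg <- stats::runif(length(r)) < cfg$background_rate
    r[bg] <- 1
  }
  r
}

assemble_split <- function(examples, labels, cfg, shuffle = TRUE) {
  n <- length(labels)
  x <- array(0, c(n, cfg$n_steps, cfg$n_channels))
  for (i in seq_len(n)) x[i, , ] <- examples[[i]]
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  list(x = x[ord, , , drop = FALSE], y = labels[ord])
}

#' Synthetic spike-template classification task
#'
#' Deterministic (seeded) generator of a discriminable event-based task:
#' per class a fixed random template of (channel, step) anchor events;
#' each example is the template with independent Gaussian temporal jitter
#' on every event (rounded and clipped to the grid) plus independent
#' background spikes. Splits are disjoint by construction. In the
#' noiseless limit (zero jitter, zero background) every example equals its
#' class template exactly.
#'
#' @param cfg a [synth_task_config()].
#' @return List with \code{train}, \code{valid}, \code{test} — each a list
#'   of \code{x} (N x T x F binary array) and \code{y} (labels in 1..C) —
#'   plus the class \code{templates}.
#' @export
synth_spike_task <- function(cfg = synth_task_config()) {
  stopifnot(inherits(cfg, "synth_task_config"))
  with_seed(cfg$seed, {
    templates <- make_templates(cfg)
    gen_split <- function(per_class) {
      labels <- rep(seq_len(cfg$n_classes), each = per_class)
      examples <- lapply(labels, function(k)
        spike_example(templates[[k]], cfg))
      assemble_split(examples, labels, cfg)
    }
    list(train = gen_split(cfg$n_train),
         valid = gen_split(cfg$n_valid),
         test = gen_split(cfg$n_test),
         templates = templates)
  })
}

feature_template <- function(cfg) {
  K <- cfg$events_per_template
  tc <- stats::runif(K, 1, cfg$n_steps)
  fc <- stats::runif(K, 1, cfg$n_channels)
  amp <- stats::runif(K, 0.5, 1.5)
  tt <- seq_len(cfg$n_steps)
  ff <- seq_len(cfg$n_channels)
  tpl <- matrix(0, cfg$n_steps, cfg$n_channels)
  for (j in seq_len(K)) {
    tpl <- tpl + amp[j] * outer(exp(-(tt - tc[j])^2 / (2 * 5^2)),
                                exp(-(ff - fc[j])^2 / (2 * 3^2)))
  }
  tpl
}

#' Synthetic feature-sequence classification task
#'
#' Real-valued analog of [synth_spike_task()]: each class template is a
#' smooth sum of Gaussian spectro-temporal bumps; examples add white noise
#' of standard deviation \code{noise_sd}. With \code{noise_sd = 0} all
#' examples of a class are identical. Typical use mimics a log-mel
#' front-end, e.g. \code{n_channels = 40}, \code{n_steps = 100}.
#'
#' @inheritParams synth_spike_task
#' @return As [synth_spike_task()], with real-valued \code{x}.
#' @export
synth_feature_task <- function(cfg = synth_task_config(n_channels = 40,
                                                       events_per_template =
                                                         8)) {
  stopifnot(inherits(cfg, "synth_task_config"))
  with_seed(cfg$seed, {
    templates <- lapply(seq_len(cfg$n_classes),
                        function(k) feature_template(cfg))
    gen_split <- function(per_class) {
      labels <- rep(seq_len(cfg$n_classes), each = per_class)
      examples <- lapply(labels, function(k) {
        templates[[k]] + matrix(stats::rnorm(cfg$n_steps * cfg$n_channels,
                                             0, cfg$noise_sd),
                                cfg$n_steps, cfg$n_channels)
      })
      assemble_split(examples, labels, cfg)
    }
    list(train = gen_split(cfg$n_train),
         valid = gen_split(cfg$n_valid),
         test = gen_split(cfg$n_test),
         templates = templates)
  })
}

#' Hold out a validation split
#'
#' Datasets without an official validation split get a seeded held-out
#' fraction of the training examples, label-stratified where possible
#' (largest-remainder allocation across classes).
#'
#' @param data either a list with \code{x} (N x T x F array) and \code{y},
#'   or a list of [event_record()]s.
#' @param fraction held-out fraction in (0, 1), default 0.05.
#' @param seed integer seed.
#' @return List with \code{train} and \code{valid} in the same format as
#'   the input.
#' @export
split_train_valid <- function(data, fraction = 0.05, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  is_records <- !is.null(data[[1]]) && inherits(data[[1]], "event_record")
  y <- if (is_records) {
    vapply(data, `[[`, integer(1), "label")
  } else {
    as.integer(data$y)
  }
  n <- length(y)
  m <- max(1L, round(fraction * n))
  with_seed(seed, {
    classes <- sort(unique(y))
    valid_idx <- if (length(classes) > m) {
      warning("too few held-out examples to stratify by label; ",
              "falling back to an unstratified split")
      sample.int(n, m)
    } else {
      counts <- table(factor(y, levels = classes))
      quota <- fraction * as.numeric(counts)
      base <- floor(quota)
      short <- m - sum(base)
      if (short > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
        base[extra] <- base[extra] + 1
      } else if (short < 0) {
        trim <- order(quota - base)[seq_len(-short)]
        base[trim] <- pmax(0, base[trim] - 1)
      }
      unlist(lapply(seq_along(classes), function(i) {
        pool <- which(y == classes[i])
        if (base[i] > 0) sample(pool, min(base[i], length(pool)))
        else integer(0)
      }), use.names = FALSE)
    }
    take <- function(idx) {
      if (is_records) {
        data[idx]
      } else {
        list(x = data$x[idx, , , drop = FALSE], y = y[idx])
      }
    }
    list(train = take(setdiff(seq_len(n), valid_idx)),
         valid = take(valid_idx))
  })
}
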