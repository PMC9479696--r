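#' Neuron state container
#'
#' Membrane potential \code{u}, adaptation current \code{w} and spike
#' indicator \code{s} for a population of neurons, all initialized at rest
#' (zero). \code{eta} is the threshold trace used only by the
#' moving-threshold variant.
#'
#' @param n number of neurons.
#' @return List of class \code{"neuron_state"} with zero vectors \code{u},
#'   \code{w}, \code{s}, \code{eta}.
#' @export
neuron_state <- function(n) {
  z <- numeric(n)
  structure(list(u = z, w = z, s = z, eta = z), class = "neuron_state")
}

check_state <- function(state, stimulus) {
  if (!is.list(state) || is.null(state$u)) {
    stop("state must be a neuron_state-like list", call. = FALSE)
  }
  n <- length(state$u)
  if (length(state$s) != n || length(state$w %||% numeric(n)) != n) {
    stop("state fields u, w, s must have identical shapes", call. = FALSE)
  }
  if (length(stimulus) != n) {
    stop("stimulus length (", length(stimulus),
         ") does not match state size (", n, ")", call. = FALSE)
  }
  if (!all(state$s %in% c(0, 1))) {
    stop("spike indicator s must be binary", call. = FALSE)
  }
  invisible(n)
}

param_vec <- function(params, nm, n, default = 0) {
  v <- params[[nm]]
  if (is.null(v)) v <- default
  rep_len(as.numeric(v), n)
}

#' One discrete adLIF update step
#'
#' Applies the normalized discrete-time adaptive LIF recursion. Both the
#' potential and the adaptation current are computed from the previous-step
#' state:
#' \deqn{u' = \alpha u + (1-\alpha) I - w - \vartheta s}
#' \deqn{w' = \beta w + (1-\beta) a u + b s}
#' followed by the threshold comparison \eqn{s' = (u' \ge \vartheta)}. The
#' reset is "soft": crossing threshold subtracts \eqn{\vartheta} at the next
#' step rather than clamping the potential.
#'
#' @param state a [neuron_state()] (previous step).
#' @param stimulus numeric vector of input currents I\[t\], same length as
#'   the state.
#' @param params a [neuron_params()]; fields may be scalars or per-neuron
#'   vectors.
#' @return Updated \code{"neuron_state"}.
#' @export
adlif_step <- function(state, stimulus, params) {
  n <- check_state(state, stimulus)
  alpha <- param_vec(params, "alpha", n)
  beta <- param_vec(params, "beta", n)
  a <- param_vec(params, "a", n)
  b <- param_vec(params, "b", n)
  theta <- params$theta %||% 1
  u_new <- alpha * state$u + (1 - alpha) * stimulus - state$w -
    theta * state$s
  w_new <- beta * state$w + (1 - beta) * a * state$u + b * state$s
  s_new <- (u_new >= theta) + 0
  structure(list(u = u_new, w = w_new, s = s_new, eta = state$eta),
            class = "neuron_state")
}

#' One discrete LIF update step
#'
#' The non-adaptive special case of [adlif_step()] with \code{a = b = 0} and
#' \code{w} identically zero; only \code{alpha} is a live parameter.
#'
#' @inheritParams adlif_step
#' @export
lif_step <- function(state, stimulus, params) {
  state$w <- numeric(length(state$u))
  p <- params
  p$a <- 0
  p$b <- 0
  out <- adlif_step(state, stimulus, p)
  out$w <- numeric(length(out$u))
  out
}

#' One moving-threshold LIF update step
#'
#' Alternative adaptation scheme in which the firing threshold itself is
#' dynamic: an exponential trace \code{eta} decays with rate \code{rho} and
#' is incremented by each spike, and the effective threshold is
#' \code{theta0 + gamma * eta}. The potential follows the plain LIF update
#' (soft reset by \code{theta0}); a spike is emitted when the potential
#' reaches the current effective threshold. With \code{gamma = 0} the
#' trajectory is exactly the LIF one.
#'
#' @inheritParams adlif_step
#' @param params list with \code{alpha}, \code{rho} (trace decay in (0,1)),
#'   \code{gamma} (increment scale >= 0) and \code{theta0} (base threshold,
#'   default 1).
#' @return Updated state; the spike threshold actually applied this step is
#'   attached as attribute \code{"theta_t"}.
#' @export
moving_threshold_step <- function(state, stimulus, params) {
  n <- check_state(state, stimulus)
  alpha <- param_vec(params, "alpha", n)
  rho <- param_vec(params, "rho", n, default = 0.97)
  gamma <- param_vec(params, "gamma", n, default = 0)
  theta0 <- params$theta0 %||% params$theta %||% 1
  if (any(rho <= 0) || any(rho >= 1)) {
    stop("rho must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(gamma < 0)) stop("gamma must be non-negative", call. = FALSE)
  eta_new <- rho * (state$eta %||% numeric(n)) + state$s
  theta_t <- theta0 + gamma * eta_new
  u_new <- alpha * state$u + (1 - alpha) * stimulus - theta0 * state$s
  s_new <- (u_new >= theta_t) + 0
  out <- structure(list(u = u_new, w = numeric(n), s = s_new, eta = eta_new),
                   class = "neuron_state")
  attr(out, "theta_t") <- theta_t
  out
}

#' Roll a neuron layer over a stimulus sequence
#'
#' Iterates the chosen update rule over time from a resting start
#' (u = w = s = 0), returning the full spike raster and state traces.
#' \code{mode = "readout"} integrates \eqn{u[t] = \alpha u[t-1] +
#' (1-\alpha) I[t]} with no threshold, reset or adaptation — the non-spiking
#' leaky integrator used inside readout layers.
#'
#' @param stimulus_sequence T x N numeric matrix of input currents (rows are
#'   time steps).
#' @param params a [neuron_params()] (plus \code{rho}/\code{gamma} for the
#'   moving-threshold mode).
#' @param mode one of \code{"adlif"}, \code{"lif"}, \code{"moving_threshold"},
#'   \code{"readout"}.
#' @return List with T x N matrices \code{spikes}, \code{u}, \code{w} (the
#'   raster is all zero in readout mode).
#' @export
run_layer_dynamics <- function(stimulus_sequence, params,
                               mode = c("adlif", "lif", "moving_threshold",
                                        "readout")) {
  mode <- match.arg(mode)
  stimulus_sequence <- as.matrix(stimulus_sequence)
  T_len <- nrow(stimulus_sequence)
  n <- ncol(stimulus_sequence)
  if (T_len < 1L || n < 1L) {
    stop("stimulus sequence must be a non-empty T x N matrix", call. = FALSE)
  }
  U <- W <- S <- matrix(0, T_len, n)
  if (mode == "readout") {
    alpha <- param_vec(params, "alpha", n)
    u <- numeric(n)
    for (t in seq_len(T_len)) {
      u <- alpha * u + (1 - alpha) * stimulus_sequence[t, ]
      U[t, ] <- u
    }
    return(list(spikes = S, u = U, w = W))
  }
  step_fn <- switch(mode, adlif = adlif_step, lif = lif_step,
                    moving_threshold = moving_threshold_step)
  state <- neuron_state(n)
  for (t in seq_len(T_len)) {
    state <- step_fn(state, stimulus_sequence[t, ], params)
    U[t, ] <- state$u
    W[t, ] <- state$w
    S[t, ] <- state$s
  }
  list(spikes = S, u = U, w = W)
}
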