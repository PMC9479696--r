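#' Continuous-time adaptive LIF neuron model
#'
#' Physical parameterization of the (adaptive) leaky integrate-and-fire
#' neuron: membrane potential u relaxing toward rest with time constant
#' \code{tau_u} while integrating input current through resistance \code{R},
#' plus an adaptation current w with time constant \code{tau_w}, subthreshold
#' coupling \code{a_phys} and spike-triggered jump \code{b_phys}. A spike is
#' emitted when u crosses \code{theta_phys}; the Dirac reset/jump terms of
#' the continuous formulation are realized by the discrete soft reset.
#'
#' @param tau_u membrane time constant (ms), > 0. Physiological order 10 ms.
#' @param tau_w adaptation time constant (ms), > 0. Physiological order 100 ms.
#' @param R membrane resistance (arbitrary units), > 0.
#' @param u_rest resting potential (mV).
#' @param u_r reset potential (mV). The normalization assumes
#'   \code{u_r == u_rest}.
#' @param theta_phys firing threshold (mV), must exceed \code{u_r}.
#' @param a_phys subthreshold adaptation coupling.
#' @param b_phys spike-triggered adaptation jump.
#' @param dt integration step (ms), default 1.
#' @return Object of class \code{"continuous_neuron_model"}.
#' @seealso [continuous_to_discrete()]
#' @export
continuous_neuron_model <- function(tau_u = 10, tau_w = 100, R = 1,
                                    u_rest = 0, u_r = 0, theta_phys = 1,
                                    a_phys = 0, b_phys = 0, dt = 1) {
  if (!all(is.finite(c(tau_u, tau_w, R, u_rest, u_r, theta_phys,
                       a_phys, b_phys, dt)))) {
    stop("all neuron model fields must be finite numbers", call. = FALSE)
  }
  if (tau_u <= 0 || tau_w <= 0) {
    stop("time constants tau_u and tau_w must be positive", call. = FALSE)
  }
  if (dt <= 0) stop("integration step dt must be positive", call. = FALSE)
  if (theta_phys <= u_r) {
    stop("threshold theta_phys must exceed the reset potential u_r",
         call. = FALSE)
  }
  structure(
    list(tau_u = tau_u, tau_w = tau_w, R = R, u_rest = u_rest, u_r = u_r,
         theta_phys = theta_phys, a_phys = a_phys, b_phys = b_phys, dt = dt),
    class = "continuous_neuron_model"
  )
}

#' Convert a continuous neuron model to normalized discrete parameters
#'
#' Change of variables mapping the physical adLIF formulation onto the
#' dimensionless discrete update (exponential-integrator step of size
#' \code{dt}): potential rescaled so that threshold becomes 1 and reset 0,
#' decays become \code{alpha = exp(-dt/tau_u)} and \code{beta =
#' exp(-dt/tau_w)}, the couplings become \code{a = R * a_phys} and
#' \code{b = R * b_phys / (theta_phys - u_rest)}.
#'
#' @param model a [continuous_neuron_model()].
#' @return Object of class \code{"neuron_params"} with fields \code{alpha},
#'   \code{beta}, \code{a}, \code{b}, \code{theta = 1}, \code{u_r = 0}.
#' @examples
#' m <- continuous_neuron_model(tau_u = 10, tau_w = 100, dt = 1)
#' continuous_to_discrete(m)$alpha  # exp(-0.1)
#' @export
continuous_to_discrete <- function(model) {
  if (!inherits(model, "continuous_neuron_model")) {
    model <- do.call(continuous_neuron_model, as.list(model))
  }
  neuron_params(
    alpha = exp(-model$dt / model$tau_u),
    beta = exp(-model$dt / model$tau_w),
    a = model$R * model$a_phys,
    b = model$R * model$b_phys / (model$theta_phys - model$u_rest)
  )
}

#' @rdname continuous_to_discrete
#' @param alpha,beta,a,b numeric vectors of per-neuron discrete parameters
#'   (recycled to a common length): membrane decay, adaptation decay,
#'   subthreshold coupling, spike-triggered jump.
#' @export
neuron_params <- function(alpha, beta = 0, a = 0, b = 0) {
  n <- max(length(alpha), length(beta), length(a), length(b))
  p <- list(alpha = rep_len(as.numeric(alpha), n),
            beta = rep_len(as.numeric(beta), n),
            a = rep_len(as.numeric(a), n),
            b = rep_len(as.numeric(b), n),
            theta = 1, u_r = 0)
  if (!all(vapply(p[1:4], function(v) all(is.finite(v)), logical(1)))) {
    stop("neuron parameters must be finite", call. = FALSE)
  }
  structure(p, class = "neuron_params")
}

#' Default trainable ranges for discrete neuron parameters
#'
#' The physiologically motivated ranges within which each per-neuron
#' parameter is initialized and kept (by projection) during training:
#' alpha in \[0.60, 0.96\] (tau_u roughly 2-25 ms at dt = 1 ms), beta in
#' \[0.96, 0.99\] (tau_w roughly 25-100 ms), a in \[-1, 1\], b in \[0, 2\].
#' The moving-threshold variant reuses the beta range for its trace decay
#' \code{rho} and the b range for its increment scale \code{gamma}.
#'
#' @return Named list of length-2 numeric intervals.
#' @export
default_param_ranges <- function() {
  list(alpha = c(0.60, 0.96),
       beta = c(0.96, 0.99),
       a = c(-1, 1),
       b = c(0, 2),
       rho = c(0.96, 0.99),
       gamma = c(0, 2))
}

check_ranges <- function(ranges) {
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || !all(is.finite(r)) ||
        r[1] > r[2]) {
      stop("invalid range for '", nm,
           "': need finite numeric c(lo, hi) with lo <= hi", call. = FALSE)
    }
  }
  ranges
}

#' Initialize heterogeneous per-neuron parameters
#'
#' Draws each per-neuron parameter independently and uniformly from its
#' range, giving every neuron its own decay and adaptation behavior
#' ("trainable and heterogeneous" parameterization).
#'
#' @param n_neurons number of neurons (>= 1).
#' @param ranges named list of intervals as from [default_param_ranges()];
#'   entries missing there keep the defaults.
#' @param seed optional integer; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @param which character vector of parameter names to draw (default the
#'   four adLIF parameters).
#' @return A \code{"neuron_params"} object with length-\code{n_neurons}
#'   vectors.
#' @export
init_neuron_params <- function(n_neurons, ranges = default_param_ranges(),
                               seed = NULL,
                               which = c("alpha", "beta", "a", "b")) {
  if (!is.numeric(n_neurons) || length(n_neurons) != 1L || n_neurons < 1) {
    stop("n_neurons must be a positive count", call. = FALSE)
  }
  ranges <- check_ranges(utils::modifyList(default_param_ranges(),
                                           as.list(ranges)))
  draw <- function(nm) {
    if (nm %in% which) {
      r <- ranges[[nm]]
      stats::runif(n_neurons, r[1], r[2])
    } else {
      rep(0, n_neurons)
    }
  }
  runner <- function() {
    neuron_params(alpha = draw("alpha"), beta = draw("beta"),
                  a = draw("a"), b = draw("b"))
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' Project neuron parameters back into their ranges
#'
#' Elementwise clamp of each parameter vector to its closed interval;
#' applied after every optimizer step so trained parameters stay within the
#' stated ranges. Idempotent.
#'
#' @param params a \code{"neuron_params"} object (extra fields such as
#'   \code{rho}/\code{gamma} are clamped when a range of that name exists).
#' @param ranges named list of intervals.
#' @return Clamped \code{"neuron_params"}.
#' @export
clamp_neuron_params <- function(params, ranges = default_param_ranges()) {
  ranges <- check_ranges(utils::modifyList(default_param_ranges(),
                                           as.list(ranges)))
  for (nm in intersect(names(ranges), names(params))) {
    r <- ranges[[nm]]
    params[[nm]] <- pmin(pmax(params[[nm]], r[1]), r[2])
  }
  params
}

# Evaluate code under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
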