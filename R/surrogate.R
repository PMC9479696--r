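#' Surrogate gradient specification
#'
#' The derivative of the Heaviside spike function is zero almost everywhere
#' and undefined at threshold, so backpropagation through time replaces it
#' with a finite "surrogate" shape evaluated at the membrane potential.
#' The forward pass always remains an exact threshold comparison; the
#' surrogate only enters the backward pass.
#'
#' Available kinds and their shape parameter:
#' \describe{
#'   \item{\code{boxcar}}{constant 0.5 wherever \eqn{|u - \vartheta| \le}
#'     \code{param}, zero outside; \code{param} is the half-width
#'     (default 0.5, the package default surrogate).}
#'   \item{\code{sigmoid_derivative}}{\eqn{k \sigma'(k(u-\vartheta))} with
#'     slope \code{param = k} (default 10).}
#'   \item{\code{gaussian}}{Gaussian density with standard deviation
#'     \code{param} (default 0.5).}
#'   \item{\code{piecewise_linear}}{triangular bump of half-width
#'     \code{param} (default 1), peak \code{1/param}, zero outside.}
#' }
#'
#' @param kind character; one of \code{"boxcar"}, \code{"sigmoid_derivative"},
#'   \code{"gaussian"}, \code{"piecewise_linear"}.
#' @param param positive shape parameter; \code{NULL} picks the default for
#'   the chosen kind.
#' @return An object of class \code{"surrogate_spec"}.
#' @examples
#' sg <- surrogate_spec("boxcar")
#' surrogate_grad(c(0.4, 1, 1.6), theta = 1, spec = sg)
#' @export
surrogate_spec <- function(kind = c("boxcar", "sigmoid_derivative",
                                    "gaussian", "piecewise_linear"),
                           param = NULL) {
  kind <- match.arg(kind)
  if (is.null(param)) {
    param <- switch(kind,
      boxcar = 0.5,
      sigmoid_derivative = 10,
      gaussian = 0.5,
      piecewise_linear = 1
    )
  }
  if (!is.numeric(param) || length(param) != 1L || !is.finite(param) ||
      param <= 0) {
    stop("surrogate shape parameter must be a single positive number",
         call. = FALSE)
  }
  structure(list(kind = kind, param = param), class = "surrogate_spec")
}

as_surrogate_spec <- function(spec) {
  if (inherits(spec, "surrogate_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1L) return(surrogate_spec(spec))
  if (is.list(spec)) {
    return(surrogate_spec(spec$kind %||% "boxcar", spec$param))
  }
  stop("cannot interpret surrogate specification", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surrogate derivative factors
#'
#' Evaluates the surrogate pseudo-derivative of the spike function at the
#' given membrane potentials. For the default boxcar this is 0.5 wherever
#' \eqn{|u - \vartheta| \le 0.5} (boundary inclusive) and 0 elsewhere.
#'
#' @param u numeric vector/matrix/array of membrane potentials.
#' @param theta firing threshold (default 1, the normalized convention).
#' @param spec a [surrogate_spec()] (or kind string).
#' @return Derivative factors with the same shape as \code{u}.
#' @export
surrogate_grad <- function(u, theta = 1, spec = surrogate_spec("boxcar")) {
  spec <- as_surrogate_spec(spec)
  d <- u - theta
  g <- switch(spec$kind,
    boxcar = 0.5 * (abs(d) <= spec$param),
    sigmoid_derivative = {
      s <- 1 / (1 + exp(-spec$param * d))
      spec$param * s * (1 - s)
    },
    gaussian = exp(-d^2 / (2 * spec$param^2)) / (spec$param * sqrt(2 * pi)),
    piecewise_linear = pmax(0, 1 - abs(d) / spec$param) / spec$param
  )
  if (is.array(u)) array(g, dim = dim(u)) else as.numeric(g)
}

#' Spike function with custom backward rule
#'
#' Forward pass: exact Heaviside comparison \code{u >= theta}, returning 0/1
#' spikes. Backward pass: the incoming gradient is multiplied elementwise by
#' the surrogate derivative, never by the true (zero / undefined) derivative
#' of the step. The returned object carries the backward closure so the rule
#' travels with the values, in the manner of a custom autodiff function.
#'
#' @inheritParams surrogate_grad
#' @return A list of class \code{"spike_fn"} with elements \code{spikes}
#'   (same shape as \code{u}, values in \{0,1\}) and \code{backward}, a
#'   function mapping an upstream gradient array to the downstream gradient
#'   with respect to \code{u}.
#' @examples
#' sf <- spike_function(c(0.8, 1.0, 1.2), theta = 1)
#' sf$spikes            # 0 1 1
#' sf$backward(c(1, 1, 1))  # boxcar factors: 0.5 0.5 0.5
#' @export
spike_function <- function(u, theta = 1, spec = surrogate_spec("boxcar")) {
  spec <- as_surrogate_spec(spec)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    stop("theta must be a single finite number", call. = FALSE)
  }
  s <- (u >= theta) + 0
  if (is.array(u)) s <- array(s, dim = dim(u))
  g <- surrogate_grad(u, theta, spec)
  structure(
    list(
      spikes = s,
      backward = function(grad_out) {
        if (length(grad_out) != length(g)) {
          stop("gradient shape does not match forward input", call. = FALSE)
        }
        grad_out * g
      }
    ),
    class = "spike_fn"
  )
}
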