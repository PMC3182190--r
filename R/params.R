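#' Plasticity parameters of the competing-synapse model
#'
#' The whole dynamics is parameterized by two neuron-activation
#' probabilities: a neuron fires with probability `alpha` when its *other*
#' adjacent synapse (the one not currently under consideration for an
#' update) is strong, and with probability `beta` when it is weak. Both
#' must lie strictly inside (0, 1); boundary values make the dynamics
#' degenerate (absorbing at the level of a single update) and are rejected.
#'
#' @param alpha Activation probability conferred by a strong adjacent
#'   synapse, in (0, 1).
#' @param beta Activation probability conferred by a weak adjacent synapse,
#'   in (0, 1).
#' @return An object of class `plasticity_params`: a named list with
#'   elements `alpha` and `beta`.
#' @examples
#' p <- plasticity_params(0.8, 0.2)
#' stable_fixed_point(p)
#' @export
plasticity_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(beta), length(beta) == 1, is.finite(beta))
  eps <- 1e-9
  if (alpha <= eps || alpha >= 1 - eps) {
    stop("`alpha` must lie strictly inside (0, 1); got ", alpha, call. = FALSE)
  }
  if (beta <= eps || beta >= 1 - eps) {
    stop("`beta` must lie strictly inside (0, 1); got ", beta, call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "plasticity_params")
}

as_plasticity_params <- function(x) {
  if (inherits(x, "plasticity_params")) return(x)
  if (is.numeric(x) && length(x) == 2) return(plasticity_params(x[[1]], x[[2]]))
  if (is.list(x) && all(c("alpha", "beta") %in% names(x))) {
    return(plasticity_params(x$alpha, x$beta))
  }
  stop("cannot interpret input as plasticity parameters", call. = FALSE)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf("<plasticity_params> alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

#' @export
format.plasticity_params <- function(x, ...) {
  sprintf("(alpha = %g, beta = %g)", x$alpha, x$beta)
}
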