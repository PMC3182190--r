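#' Perturb the activation parameters with a signal
#'
#' A signal of strength `s` acts as a biasing field: it shifts the two
#' activation probabilities by equal and opposite amounts,
#' `(alpha, beta) -> (alpha + s, beta - s)`, preserving `alpha + beta`.
#' Perturbed states therefore move parallel to the `alpha = 1 - beta`
#' diagonal of the parameter plane, along which the range of imposable
#' signals is maximal.
#'
#' @param params A [plasticity_params()] object.
#' @param s Signal strength (positive signals favour the strong type).
#' @return The perturbed `plasticity_params`.
#' @examples
#' apply_signal(plasticity_params(0.3, 0.7), 0.2)
#' @export
apply_signal <- function(params, s) {
  params <- as_plasticity_params(params)
  stopifnot(is.numeric(s), length(s) == 1, is.finite(s))
  rng <- allowed_signal_range(params)
  if (s <= rng[[1]] || s >= rng[[2]]) {
    stop(sprintf(paste0("inadmissible signal s = %g for parameters ",
                        "(alpha = %g, beta = %g): allowed open interval is ",
                        "(%g, %g)"),
                 s, params$alpha, params$beta, rng[[1]], rng[[2]]),
         call. = FALSE)
  }
  plasticity_params(params$alpha + s, params$beta - s)
}

#' Admissible signal range
#'
#' The open interval of signal strengths `s` for which
#' [apply_signal()] keeps both perturbed probabilities strictly inside
#' (0, 1): `(max(-alpha, beta - 1), min(1 - alpha, beta))`. Its length is
#' maximal (equal to 1) exactly on the diagonal `alpha + beta = 1`.
#'
#' @param params A [plasticity_params()] object.
#' @return A named numeric vector `c(lower, upper)` describing the open
#'   interval.
#' @examples
#' allowed_signal_range(plasticity_params(0.5, 0.5))
#' @export
allowed_signal_range <- function(params) {
  params <- as_plasticity_params(params)
  eps <- 1e-9
  c(lower = max(-params$alpha, params$beta - 1) + eps,
    upper = min(1 - params$alpha, params$beta) - eps)
}

#' Build a signal protocol
#'
#' Encodes the piecewise-constant signal shapes of the three adaptation
#' paradigms as an ordered list of phases, each applied until the state
#' saturates (the per-unit-time change drops below tolerance):
#'
#' * `constant`: a single phase at `s`;
#' * `deadaptation` (Signal – No Signal): `s`, then `0`;
#' * `downscaling` (Signal – Half-Signal): `s`, then `s / 2`;
#' * `reversal` (Signal – Reverse Signal, anterograde interference):
#'   `s`, then `-s`.
#'
#' @param kind Protocol kind, one of `"constant"`, `"deadaptation"`,
#'   `"downscaling"`, `"reversal"`.
#' @param s Signal strength; must be non-zero for the two-phase protocols
#'   (a zero shift leaves the fixed point in place and the learning time
#'   undefined).
#' @return An object of class `signal_protocol`: a tibble with columns
#'   `phase`, `s` and `termination`, and attribute `kind`.
#' @examples
#' build_protocol("deadaptation", 0.2)
#' @export
build_protocol <- function(kind = c("constant", "deadaptation", "downscaling",
                                    "reversal"), s) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(s), length(s) == 1, is.finite(s))
  if (kind != "constant" && s == 0) {
    stop("zero-shift signal: the learning time is undefined for s = 0",
         call. = FALSE)
  }
  phases <- switch(kind,
    constant = s,
    deadaptation = c(s, 0),
    downscaling = c(s, s / 2),
    reversal = c(s, -s)
  )
  out <- tibble::tibble(phase = seq_along(phases), s = phases,
                        termination = "until_saturation")
  class(out) <- c("signal_protocol", class(out))
  attr(out, "kind") <- kind
  out
}

protocol_kind <- function(protocol) {
  stopifnot(inherits(protocol, "signal_protocol"))
  attr(protocol, "kind")
}
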