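#' Outcome probabilities of a single synaptic update
#'
#' Enumerates the four joint activation outcomes of the two neurons flanking
#' a candidate synapse, given the types of its two neighbouring synapses,
#' and classifies each outcome by its polarity. Each flanking neuron fires
#' independently, with probability `alpha` if its other adjacent synapse is
#' strong and `beta` if it is weak; the candidate synapse itself plays no
#' role. The update potentiates the candidate exactly when the neighbours
#' are of mixed type and only the strong-adjacent neuron fires, depresses it
#' when only the weak-adjacent neuron fires, and otherwise leaves it
#' unchanged — in particular, same-type neighbour configurations never
#' change the candidate (the synaptic current is zero or unpolarized).
#'
#' @param left_type,right_type Types of the two neighbouring synapses,
#'   `"strong"` or `"weak"`.
#' @param params A [plasticity_params()] object.
#' @return A one-row tibble with columns `p_potentiate`, `p_depress`,
#'   `p_none`, summing to 1.
#' @examples
#' neighbor_outcome_probs("strong", "weak", plasticity_params(0.8, 0.2))
#' @export
neighbor_outcome_probs <- function(left_type, right_type, params) {
  params <- as_plasticity_params(params)
  p <- outcome_probs_num(synapse_type_code(left_type),
                         synapse_type_code(right_type),
                         params$alpha, params$beta)
  tibble::tibble(p_potentiate = p[[1]], p_depress = p[[2]], p_none = p[[3]])
}

synapse_type_code <- function(type) {
  if (is.numeric(type) && length(type) == 1 && type %in% c(0, 1)) {
    return(as.integer(type))
  }
  if (is.character(type) && length(type) == 1 && type %in% c("strong", "weak")) {
    return(if (type == "strong") 1L else 0L)
  }
  stop("synapse type must be \"strong\" or \"weak\"", call. = FALSE)
}

# Enumeration core: left/right in {1 = strong, 0 = weak}. Returns
# c(p_potentiate, p_depress, p_none) by summing over the 2x2 table of joint
# neuron activations. This function is the single source of truth for the
# plasticity rules; every drift/fixed-point/timescale quantity in the
# package traces back to it.
outcome_probs_num <- function(left, right, alpha, beta) {
  fire_prob <- function(type) if (type == 1L) alpha else beta
  pl <- fire_prob(left)
  pr <- fire_prob(right)
  p_pot <- 0
  p_dep <- 0
  for (fl in c(0L, 1L)) {
    for (fr in c(0L, 1L)) {
      w <- (if (fl) pl else 1 - pl) * (if (fr) pr else 1 - pr)
      if (left != right && xor(fl == 1L, fr == 1L)) {
        fired_type <- if (fl == 1L) left else right
        if (fired_type == 1L) p_pot <- p_pot + w else p_dep <- p_dep + w
      }
    }
  }
  c(p_pot, p_dep, 1 - p_pot - p_dep)
}

#' Mean-field drift of the strong-synapse fraction
#'
#' In the effective description every synapse is strong with the same
#' probability `x` and spatial correlations are ignored. The rate of change
#' of `x` is `(1 - x) * W_up(x) - x * W_down(x)`, where the transition
#' probabilities `W_up`/`W_down` average the single-update potentiation and
#' depression probabilities over neighbour configurations drawn
#' independently with strong-probability `x` (mixed configurations carrying
#' weight `2 x (1 - x)`). The averages are built by enumeration via
#' [neighbor_outcome_probs()]; the closed forms in
#' [fixed_point_closed_form()] and [relaxation_time_closed_form()] are
#' derived from this enumeration and cross-checked against it.
#'
#' @param x Fraction of strong synapses, in \[0, 1\] (vectorized).
#' @param params A [plasticity_params()] object.
#' @return `dx/dt`, a numeric vector the length of `x`.
#' @examples
#' drift(0.5, plasticity_params(0.8, 0.2))
#' @export
drift <- function(x, params) {
  params <- as_plasticity_params(params)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  w <- transition_probs(x, params)
  (1 - x) * w$w_up - x * w$w_down
}

# W_up(x), W_down(x): enumeration-built averages over the three neighbour
# configurations (both strong: x^2, mixed: 2x(1-x), both weak: (1-x)^2).
transition_probs <- function(x, params) {
  p_ss <- outcome_probs_num(1L, 1L, params$alpha, params$beta)
  p_sw <- outcome_probs_num(1L, 0L, params$alpha, params$beta)
  p_ws <- outcome_probs_num(0L, 1L, params$alpha, params$beta)
  p_ww <- outcome_probs_num(0L, 0L, params$alpha, params$beta)
  w_ss <- x^2
  w_mx <- x * (1 - x)  # weight of each of the two mixed orderings
  w_ww <- (1 - x)^2
  list(
    w_up = w_ss * p_ss[1] + w_mx * (p_sw[1] + p_ws[1]) + w_ww * p_ww[1],
    w_down = w_ss * p_ss[2] + w_mx * (p_sw[2] + p_ws[2]) + w_ww * p_ww[2]
  )
}

# Exact cubic coefficients (c0, c1, c2, c3) of the enumeration-built drift.
# W_up/W_down are quadratics in x; their coefficients are recovered exactly
# from values at x = 0, 1/2, 1, and the drift cubic follows by expanding
# (1-x) W_up - x W_down. Machine-exact for polynomials; no transcription of
# printed algebra is involved.
drift_coefs <- function(params) {
  quad_coefs <- function(f0, fh, f1) {
    a2 <- 2 * f0 + 2 * f1 - 4 * fh
    a1 <- f1 - f0 - a2
    c(f0, a1, a2)
  }
  tp <- function(x) transition_probs(x, params)
  t0 <- tp(0); th <- tp(0.5); t1 <- tp(1)
  u <- quad_coefs(t0$w_up, th$w_up, t1$w_up)
  d <- quad_coefs(t0$w_down, th$w_down, t1$w_down)
  c(u[1],
    u[2] - u[1] - d[1],
    u[3] - u[2] - d[2],
    -u[3] - d[3])
}

drift_derivative <- function(x, params) {
  cf <- drift_coefs(as_plasticity_params(params))
  cf[2] + 2 * cf[3] * x + 3 * cf[4] * x^2
}

#' Stable interior fixed point of the mean-field dynamics
#'
#' Besides the trivial unstable fixed points at 0 and 1 (homogeneous,
#' absorbing configurations), the drift has a unique stable interior root,
#' found here by bracketed root-finding on the enumeration-built drift and
#' polished by Newton steps to full precision. Stability
#' (`drift'(x*) < 0`) is asserted.
#'
#' @param params A [plasticity_params()] object.
#' @return The stable fixed point `x*`, a number in (0, 1).
#' @seealso [fixed_point_closed_form()] for the derived closed form.
#' @examples
#' stable_fixed_point(plasticity_params(0.8, 0.2))
#' @export
stable_fixed_point <- function(params) {
  params <- as_plasticity_params(params)
  eps <- 1e-9
  f <- function(x) drift(x, params)
  if (f(eps) <= 0 || f(1 - eps) >= 0) {
    stop("degenerate parameters: no interior sign change of the drift",
         call. = FALSE)
  }
  x <- stats::uniroot(f, c(eps, 1 - eps), tol = 1e-12)$root
  for (i in 1:3) {  # Newton polish on the exact cubic
    d <- drift_derivative(x, params)
    x <- x - f(x) / d
  }
  if (drift_derivative(x, params) >= 0) {
    stop("located root is not stable", call. = FALSE)
  }
  x
}

#' Relaxation time of the mean-field dynamics
#'
#' The exponential time constant `tau = -1 / drift'(x*)` governing the
#' approach of small perturbations to the stable fixed point, in units of
#' one update sweep. It controls both learning (with the end state set by
#' the signal-on parameters) and forgetting (end state = default
#' parameters).
#'
#' @param params A [plasticity_params()] object.
#' @return The relaxation time `tau`, a positive number.
#' @seealso [relaxation_time_closed_form()]
#' @examples
#' relaxation_time(plasticity_params(0.5, 0.5))
#' @export
relaxation_time <- function(params) {
  params <- as_plasticity_params(params)
  xs <- stable_fixed_point(params)
  d <- drift_derivative(xs, params)
  if (abs(d) < 1e-12) {
    stop("marginal stability: |drift'(x*)| below tolerance", call. = FALSE)
  }
  -1 / d
}

#' Closed-form fixed point and relaxation time
#'
#' Closed forms derived from the enumeration-built drift
#' `dx/dt = 2 x (1 - x) ((1 - x) A - x B)` with `A = alpha (1 - beta)` (the
#' mixed-neighbour potentiation probability) and `B = beta (1 - alpha)` (the
#' mixed-neighbour depression probability): `x* = A / (A + B)` and
#' `tau = (A + B) / (2 A B)`. They are cross-checked against the
#' enumeration route ([stable_fixed_point()], [relaxation_time()]) in the
#' test suite and exist mainly for fast grid sweeps.
#'
#' @param params A [plasticity_params()] object.
#' @return A number: `x*` in (0, 1), resp. `tau > 0`.
#' @export
fixed_point_closed_form <- function(params) {
  params <- as_plasticity_params(params)
  a <- params$alpha * (1 - params$beta)
  b <- params$beta * (1 - params$alpha)
  a / (a + b)
}

#' @rdname fixed_point_closed_form
#' @export
relaxation_time_closed_form <- function(params) {
  params <- as_plasticity_params(params)
  a <- params$alpha * (1 - params$beta)
  b <- params$beta * (1 - params$alpha)
  (a + b) / (2 * a * b)
}

#' Integrate the mean-field dynamics for a fixed duration
#'
#' Deterministic explicit-Euler integration of the drift, with one unit of
#' time equal to one expected update attempt per synapse (one sweep).
#'
#' @param x0 Initial strong-synapse fraction, in \[0, 1\].
#' @param params A [plasticity_params()] object.
#' @param duration Total integration time (sweeps).
#' @param dt Euler step, default 0.01.
#' @param record_every Record every this many steps (the initial and final
#'   points are always recorded).
#' @return A tibble of class `mf_trajectory` with columns `t` and `x`.
#' @examples
#' mf_integrate(0.3, plasticity_params(0.8, 0.2), duration = 50)
#' @export
mf_integrate <- function(x0, params, duration, dt = 0.01, record_every = 1L) {
  params <- as_plasticity_params(params)
  stopifnot(is.numeric(x0), length(x0) == 1, x0 >= 0, x0 <= 1,
            is.numeric(duration), duration > 0, is.numeric(dt), dt > 0)
  n_steps <- as.integer(ceiling(duration / dt))
  res <- cpp_euler_integrate(drift_coefs(params), x0, dt, n_steps,
                             as.integer(record_every))
  if (isTRUE(res$unstable)) {
    stop("integration left [0, 1]: decrease `dt`", call. = FALSE)
  }
  out <- tibble::tibble(t = res$t, x = res$x)
  class(out) <- c("mf_trajectory", class(out))
  attr(out, "params") <- params
  out
}
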