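#' Saturation-detection configuration
#'
#' A phase is considered saturated when the change of the strong fraction
#' per unit time falls below `tol`. The criterion is evaluated per unit
#' time (one sweep), not per integrator micro-step, so measured times are
#' independent of `dt` to first order.
#'
#' With the default `normalize = "change"` the criterion is the absolute
#' change of the fraction, `|x(t + 1) - x(t)| < tol`, which is invariant
#' under the exact strong/weak relabeling symmetry of the model (so, e.g.,
#' mirror-image protocols measure mirror-image times). Setting
#' `normalize = "state"` divides by `max(|x|, 1e-9)` instead, i.e. uses the
#' relative change of `x`; this breaks the relabeling symmetry of measured
#' times by a term logarithmic in the end state and is provided for
#' comparison.
#'
#' @param tol Change-per-unit-time threshold, in (0, 1). Default `1e-6`.
#' @param dt Euler step, default 0.01.
#' @param max_time Safety cap on any single phase, in sweeps.
#' @param normalize `"change"` (absolute change of the fraction, default)
#'   or `"state"` (change relative to the current value).
#' @return An object of class `saturation_config`.
#' @export
saturation_config <- function(tol = 1e-6, dt = 0.01, max_time = 1e5,
                              normalize = c("change", "state")) {
  normalize <- match.arg(normalize)
  stopifnot(is.numeric(tol), length(tol) == 1, tol > 0, tol < 1,
            is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(max_time), length(max_time) == 1, max_time > 0)
  structure(list(tol = tol, dt = dt, max_time = max_time,
                 normalize = normalize),
            class = "saturation_config")
}

#' Evolve the mean-field state until it saturates
#'
#' Integrates the drift from `x0` under fixed parameters and stops at the
#' first step where the change of `x` per unit time (see
#' [saturation_config()] for the two normalizations) drops below
#' `cfg$tol`. The end state lies at the stable fixed point of `params` up
#' to the saturation tolerance. If the very first step is already below
#' tolerance (e.g. `x0` at the fixed point) the elapsed time is 0 and the
#' result is flagged degenerate.
#'
#' @param x0 Initial strong fraction.
#' @param params A [plasticity_params()] object.
#' @param cfg A [saturation_config()].
#' @param record_every Trajectory recording stride, in integrator steps.
#' @param cross_level Optional level in \[0, 1\]; if given, the first
#'   crossing time is located by linear interpolation between steps and
#'   returned as `t_cross`.
#' @return A list with `t_sat`, `x_end`, `trajectory` (tibble `t`, `x`),
#'   `degenerate` and `t_cross`.
#' @examples
#' evolve_until_saturation(0.5, plasticity_params(0.8, 0.2),
#'                         saturation_config())
#' @export
evolve_until_saturation <- function(x0, params, cfg = saturation_config(),
                                    record_every = 10L, cross_level = NULL) {
  params <- as_plasticity_params(params)
  stopifnot(inherits(cfg, "saturation_config"),
            is.numeric(x0), length(x0) == 1, x0 >= 0, x0 <= 1)
  level <- if (is.null(cross_level)) NA_real_ else as.numeric(cross_level)
  res <- cpp_euler_saturate(drift_coefs(params), x0, cfg$dt, cfg$tol,
                            cfg$max_time, as.integer(record_every), level,
                            identical(cfg$normalize, "state"))
  if (isTRUE(res$unstable)) {
    stop("integration left [0, 1]: decrease `dt`", call. = FALSE)
  }
  if (!isTRUE(res$converged)) {
    stop("saturation not reached within `max_time`", call. = FALSE)
  }
  list(t_sat = res$t_sat, x_end = res$x_end,
       trajectory = tibble::tibble(t = res$t, x = res$x),
       degenerate = isTRUE(res$degenerate), t_cross = res$t_cross)
}

#' Run a signal protocol on the mean-field system
#'
#' Implements the measurement procedure for the adaptation paradigms. The
#' state starts at the stable fixed point of the default (unperturbed)
#' parameters. Phase 1 applies the signal and measures the learning time
#' `t_learn` from signal onset to saturation. The second phase depends on
#' the protocol:
#'
#' * de-adaptation / downscaling: the signal is removed (resp. halved) and
#'   `t_second` is the time from the change to the new saturation;
#' * reversal (anterograde interference): the sign of the signal is
#'   reversed; the system first evolves back to the *default* fixed-point
#'   level, and the relearning time `t_second` is measured only from that
#'   crossing (located by linear interpolation) until saturation at the
#'   reversed-signal fixed point.
#'
#' The analytic counterpart `analytic_ratio` is the ratio of the
#' relaxation time constants of the two end states, since each relaxation
#' time is a function of the parameters of its end state only (see
#' [analytic_timescale_ratio()]).
#'
#' @param default_params The unperturbed [plasticity_params()].
#' @param protocol A [build_protocol()] object with two phases.
#' @param cfg A [saturation_config()].
#' @param record_every Trajectory recording stride, in integrator steps.
#' @return An object of class `protocol_result`: a list with `t_learn`,
#'   `t_second`, `ratio = t_second / t_learn`, `analytic_ratio`,
#'   `trajectory` (tibble `t`, `x`, `phase`), `kind`, `s`,
#'   `default_params`.
#' @examples
#' run_protocol(plasticity_params(0.3, 0.7),
#'              build_protocol("deadaptation", 0.1))
#' @export
run_protocol <- function(default_params, protocol, cfg = saturation_config(),
                         record_every = 10L) {
  default_params <- as_plasticity_params(default_params)
  kind <- protocol_kind(protocol)
  # admissibility of every phase is checked up front by apply_signal
  phase_params <- lapply(protocol$s, function(s) {
    if (s == 0) default_params else apply_signal(default_params, s)
  })
  x_default <- stable_fixed_point(default_params)
  s1 <- protocol$s[[1]]
  if (s1 == 0) {
    stop("zero-shift signal: the learning time is undefined for s = 0",
         call. = FALSE)
  }

  ph1 <- evolve_until_saturation(x_default, phase_params[[1]], cfg,
                                 record_every = record_every)
  if (ph1$degenerate) {
    stop("degenerate protocol: the perturbed system saturates immediately",
         call. = FALSE)
  }
  t_learn <- ph1$t_sat
  traj <- dplyr::mutate(ph1$trajectory, phase = 1L)

  if (kind == "constant") {
    out <- list(t_learn = t_learn, t_second = NA_real_, ratio = NA_real_,
                analytic_ratio = NA_real_, trajectory = traj, kind = kind,
                s = s1, default_params = default_params)
    class(out) <- "protocol_result"
    return(out)
  }

  p2 <- phase_params[[2]]
  cross <- if (kind == "reversal") x_default else NULL
  ph2 <- evolve_until_saturation(ph1$x_end, p2, cfg,
                                 record_every = record_every,
                                 cross_level = cross)
  if (ph2$degenerate) {
    stop("degenerate protocol: the second phase saturates immediately",
         call. = FALSE)
  }
  if (kind == "reversal") {
    if (!is.finite(ph2$t_cross)) {
      stop("default fixed-point level never reached in the reversal phase",
           call. = FALSE)
    }
    t_second <- ph2$t_sat - ph2$t_cross
  } else {
    t_second <- ph2$t_sat
  }
  traj2 <- dplyr::mutate(ph2$trajectory, t = t + t_learn, phase = 2L)
  out <- list(
    t_learn = t_learn, t_second = t_second, ratio = t_second / t_learn,
    analytic_ratio = analytic_timescale_ratio(default_params, protocol),
    trajectory = dplyr::bind_rows(traj, traj2), kind = kind, s = s1,
    default_params = default_params
  )
  class(out) <- "protocol_result"
  out
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s, s = %g, default %s\n", x$kind, x$s,
              format(x$default_params)))
  cat(sprintf("  t_learn = %.4g, t_second = %.4g, ratio = %.4g, analytic = %.4g\n",
              x$t_learn, x$t_second, x$ratio, x$analytic_ratio))
  invisible(x)
}

#' Analytic ratio of the protocol's time constants
#'
#' Because relaxation towards any fixed point is exponential with a time
#' constant set by the parameters of the end state, each phase of a
#' protocol has an analytic time constant `tau` attached to its end-state
#' parameters. This returns `tau(phase-2 end state) / tau(phase-1 end
#' state)` — for de-adaptation, `tau(default) / tau(signal-on)`, i.e. the
#' forgetting-to-learning ratio.
#'
#' @inheritParams run_protocol
#' @return A positive number.
#' @examples
#' analytic_timescale_ratio(plasticity_params(0.3, 0.7),
#'                          build_protocol("deadaptation", 0.1))
#' @export
analytic_timescale_ratio <- function(default_params, protocol) {
  default_params <- as_plasticity_params(default_params)
  kind <- protocol_kind(protocol)
  if (kind == "constant") {
    stop("the timescale ratio is defined for two-phase protocols only",
         call. = FALSE)
  }
  if (protocol$s[[1]] == 0) {
    stop("zero-shift signal: the learning time is undefined for s = 0",
         call. = FALSE)
  }
  tau_of <- function(s) {
    p <- if (s == 0) default_params else apply_signal(default_params, s)
    relaxation_time(p)
  }
  tau_of(protocol$s[[2]]) / tau_of(protocol$s[[1]])
}
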