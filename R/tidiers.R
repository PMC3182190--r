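#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a protocol result
#'
#' @param x A [run_protocol()] result.
#' @param ... Unused.
#' @return The trajectory as a tibble with columns `t`, `x` and `phase`.
#' @method tidy protocol_result
#' @export
tidy.protocol_result <- function(x, ...) {
  dplyr::mutate(x$trajectory, phase = factor(.data$phase))
}

#' One-row summary of a protocol result
#'
#' @param x A [run_protocol()] result.
#' @param ... Unused.
#' @return A one-row tibble with the protocol kind, signal strength,
#'   measured times, their ratio and the analytic time-constant ratio.
#' @method glance protocol_result
#' @export
glance.protocol_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, s = x$s,
                 alpha = x$default_params$alpha, beta = x$default_params$beta,
                 t_learn = x$t_learn, t_second = x$t_second,
                 ratio = x$ratio, analytic_ratio = x$analytic_ratio)
}

#' Plot a protocol trajectory
#'
#' @param object A [run_protocol()] result.
#' @param ... Unused.
#' @return A ggplot of the strong fraction against time, coloured by phase.
#' @method autoplot protocol_result
#' @export
autoplot.protocol_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$t, y = .data$x,
                               colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (sweeps)", y = "strong fraction x",
                  colour = "phase",
                  title = sprintf("%s protocol, s = %g", object$kind,
                                  object$s))
}

#' Plot a mean-field or lattice trajectory
#'
#' @param object An [mf_integrate()] or [run_sweeps()] trajectory.
#' @param ... Unused.
#' @return A ggplot of the strong fraction against time.
#' @method autoplot mf_trajectory
#' @export
autoplot.mf_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (sweeps)", y = "strong fraction x")
}

#' @rdname autoplot.mf_trajectory
#' @method autoplot lattice_trajectory
#' @export
autoplot.lattice_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sweep,
                                       y = .data$strong_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sweep", y = "strong fraction")
}

#' Plot a relaxation-rate map
#'
#' @param object A [rate_map()] tibble.
#' @param ... Unused.
#' @return A ggplot heat map of `1 / tau` over the `(alpha, beta)` plane.
#' @method autoplot rate_map
#' @export
autoplot.rate_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                       fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(alpha), y = expression(beta),
                  fill = "1 / tau")
}

#' Plot a learning-versus-forgetting phase map
#'
#' Inadmissible cells are rendered blank.
#'
#' @param object A [ratio_map()] tibble.
#' @param ... Unused.
#' @return A ggplot heat map of the log timescale ratio over the `(a, s)`
#'   plane.
#' @method autoplot phase_map
#' @export
autoplot.phase_map <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$admissible),
                  ggplot2::aes(x = .data$a, y = .data$s,
                               fill = .data$log_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "diagonal default a", y = "signal strength s",
                  fill = "ln ratio",
                  title = sprintf("%s (%s)", attr(object, "kind"),
                                  attr(object, "method")))
}
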