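#' Relaxation-rate map over the parameter plane
#'
#' Evaluates the inverse relaxation time `1 / tau` on a grid of
#' `(alpha, beta)` pairs. Dark (slow) regions near the corners of the
#' plane correspond to default configurations with long retention times;
#' the rate is symmetric under swapping `alpha` and `beta` (a strong/weak
#' relabeling).
#'
#' @param alpha_grid,beta_grid Strictly increasing grids inside (0, 1);
#'   `beta_grid` defaults to `alpha_grid`.
#' @return A tibble of class `rate_map` with columns `alpha`, `beta`,
#'   `rate`.
#' @examples
#' rate_map(seq(0.1, 0.9, by = 0.2))
#' @export
rate_map <- function(alpha_grid, beta_grid = alpha_grid) {
  check_grid(alpha_grid)
  check_grid(beta_grid)
  out <- tidyr::expand_grid(alpha = alpha_grid, beta = beta_grid) |>
    dplyr::mutate(rate = purrr::map2_dbl(alpha, beta, function(a, b) {
      1 / relaxation_time(plasticity_params(a, b))
    }))
  class(out) <- c("rate_map", class(out))
  out
}

check_grid <- function(g) {
  if (length(g) < 1 || any(!is.finite(g)) || any(diff(g) <= 0)) {
    stop("grid must be nonempty, finite and strictly increasing",
         call. = FALSE)
  }
  invisible(g)
}

#' Learning-versus-forgetting ratio map
#'
#' Sweeps the diagonal default parameter `a` (default parameters
#' `(a, 1 - a)`, the line along which the admissible signal range is
#' maximal) and the signal strength `s`, and computes the natural log of
#' the protocol's timescale ratio at every admissible cell, by either the
#' analytic route ([analytic_timescale_ratio()]) or the numeric route
#' ([run_protocol()] saturation times). Cells where any phase of the
#' protocol is inadmissible — or degenerate, e.g. `s = 0` — are masked
#' (`admissible = FALSE`, `log_ratio = NA`).
#'
#' @param kind Protocol kind: `"deadaptation"`, `"downscaling"` or
#'   `"reversal"`.
#' @param a_grid Strictly increasing grid of diagonal defaults in (0, 1).
#' @param s_grid Strictly increasing grid of signal strengths.
#' @param method `"analytic"` or `"numeric"`.
#' @param cfg A [saturation_config()] (numeric route only).
#' @return A tibble of class `phase_map` with columns `a`, `s`,
#'   `log_ratio`, `admissible`, and attributes `kind` and `method`.
#' @examples
#' ratio_map("deadaptation", seq(0.2, 0.8, by = 0.2),
#'           seq(-0.15, 0.15, by = 0.1), method = "analytic")
#' @export
ratio_map <- function(kind = c("deadaptation", "downscaling", "reversal"),
                      a_grid, s_grid, method = c("analytic", "numeric"),
                      cfg = saturation_config()) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  check_grid(a_grid)
  check_grid(s_grid)
  if (any(a_grid <= 0) || any(a_grid >= 1)) {
    stop("`a_grid` must lie strictly inside (0, 1)", call. = FALSE)
  }
  cell <- function(a, s) {
    default <- plasticity_params(a, 1 - a)
    if (s == 0) return(NA_real_)
    proto <- build_protocol(kind, s)
    rng <- allowed_signal_range(default)
    if (any(proto$s[proto$s != 0] <= rng[[1]] | proto$s[proto$s != 0] >= rng[[2]])) {
      return(NA_real_)
    }
    if (method == "analytic") {
      log(analytic_timescale_ratio(default, proto))
    } else {
      res <- tryCatch(run_protocol(default, proto, cfg, record_every = 0L),
                      error = function(e) NULL)
      if (is.null(res)) NA_real_ else log(res$ratio)
    }
  }
  out <- tidyr::expand_grid(a = a_grid, s = s_grid) |>
    dplyr::mutate(log_ratio = purrr::map2_dbl(a, s, cell),
                  admissible = is.finite(log_ratio))
  if (!any(out$admissible)) {
    stop("empty admissible region for this grid and protocol", call. = FALSE)
  }
  class(out) <- c("phase_map", class(out))
  attr(out, "kind") <- kind
  attr(out, "method") <- method
  out
}

#' Compare two phase maps
#'
#' Summarizes the agreement of two [ratio_map()] results on identical
#' grids: Spearman rank correlation and maximal absolute difference of the
#' log-ratios over the jointly admissible cells.
#'
#' @param map_a,map_b `phase_map` objects on the same grid and protocol.
#' @return A one-row tibble with columns `spearman`, `max_abs_diff`,
#'   `n_cells`.
#' @export
compare_maps <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "phase_map"), inherits(map_b, "phase_map"))
  if (!identical(map_a$a, map_b$a) || !identical(map_a$s, map_b$s)) {
    stop("phase maps are on different grids", call. = FALSE)
  }
  if (!identical(attr(map_a, "kind"), attr(map_b, "kind"))) {
    stop("phase maps describe different protocols", call. = FALSE)
  }
  joint <- map_a$admissible & map_b$admissible
  va <- map_a$log_ratio[joint]
  vb <- map_b$log_ratio[joint]
  tibble::tibble(
    spearman = stats::cor(va, vb, method = "spearman"),
    max_abs_diff = max(abs(va - vb)),
    n_cells = sum(joint)
  )
}
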