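# Draws n random parameter pairs, uniform over (lo, hi)^2.
random_params <- function(n, lo = 0.2, hi = 0.8) {
  tibble::tibble(alpha = stats::runif(n, lo, hi),
                 beta = stats::runif(n, lo, hi))
}

# Independent oracle for the relaxation time: integrates the mean-field
# trajectory from a small displacement off the fixed point and fits the
# exponential decay rate of log|x(t) - x*| over the window where the
# deviation lies in [lo, hi]. Returns the fitted rate (compare to 1/tau).
fit_decay_rate <- function(params, lo = 1e-5, hi = 1e-3, dt = 0.01) {
  xs <- stable_fixed_point(params)
  tau <- relaxation_time(params)
  x0 <- if (xs < 0.9) xs + 0.05 else xs - 0.05
  dur <- tau * (log(abs(x0 - xs) / lo) + 2)
  traj <- mf_integrate(x0, params, duration = dur, dt = dt, record_every = 1L)
  dev <- abs(traj$x - xs)
  w <- dev >= lo & dev <= hi
  stopifnot(sum(w) > 10)
  -unname(stats::coef(stats::lm(log(dev[w]) ~ traj$t[w]))[2])
}
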