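test_that("single-update outcome probabilities follow the polarity rules", {
  p <- plasticity_params(0.8, 0.2)

  # same-type neighbours carry zero or unpolarized current
  for (type in c("strong", "weak")) {
    probs <- neighbor_outcome_probs(type, type, p)
    expect_equal(unlist(probs), c(p_potentiate = 0, p_depress = 0, p_none = 1))
  }

  # mixed neighbours: pot = alpha (1 - beta), dep = beta (1 - alpha)
  probs <- neighbor_outcome_probs("strong", "weak", p)
  expect_equal(probs$p_potentiate, 0.64)
  expect_equal(probs$p_depress, 0.04)
  expect_equal(probs$p_none, 0.32)
  # and the mirrored ordering gives the same classification
  expect_equal(unlist(neighbor_outcome_probs("weak", "strong", p)),
               unlist(probs))

  # equal activation probabilities make potentiation and depression equal
  sym <- neighbor_outcome_probs("strong", "weak", plasticity_params(0.5, 0.5))
  expect_equal(sym$p_potentiate, 0.25)
  expect_equal(sym$p_depress, 0.25)

  expect_error(neighbor_outcome_probs("fast", "weak", p), "strong")
})

test_that("outcome probabilities conserve to machine precision", {
  withr::local_seed(421)
  draws <- random_params(2000, lo = 0.01, hi = 0.99)
  configs <- list(c("strong", "strong"), c("strong", "weak"),
                  c("weak", "strong"), c("weak", "weak"))
  for (cfg in configs) {
    sums <- purrr::map2_dbl(draws$alpha, draws$beta, function(a, b) {
      pr <- neighbor_outcome_probs(cfg[1], cfg[2], plasticity_params(a, b))
      stopifnot(all(unlist(pr) >= 0), all(unlist(pr) <= 1))
      sum(unlist(pr))
    })
    expect_lt(max(abs(sums - 1)), 1e-12)
  }
})

test_that("drift vanishes at homogeneous states and repels the boundaries", {
  p <- plasticity_params(0.8, 0.2)
  expect_identical(drift(0, p), 0)
  expect_identical(drift(1, p), 0)
  expect_equal(drift(0.5, plasticity_params(0.4, 0.4)), 0)

  # interior stable point: positive drift below it, negative above
  expect_gt(drift(0.5, p), 0)
  expect_lt(drift(0.99, p), 0)
  expect_gt(drift(1e-6, p), 0)
  expect_lt(drift(1 - 1e-6, p), 0)

  expect_error(drift(1.2, p), "\\[0, 1\\]")
})

test_that("closed forms agree with the enumeration-built dynamics", {
  grid <- seq(0.05, 0.95, length.out = 10)
  xs <- c(0.1, 0.37, 0.5, 0.82)
  for (a in grid) for (b in grid) {
    p <- plasticity_params(a, b)
    A <- a * (1 - b)
    B <- b * (1 - a)
    expect_lt(max(abs(drift(xs, p) - 2 * xs * (1 - xs) * ((1 - xs) * A - xs * B))),
              1e-12)
    expect_lt(abs(stable_fixed_point(p) - fixed_point_closed_form(p)), 1e-12)
    expect_lt(abs(relaxation_time(p) / relaxation_time_closed_form(p) - 1),
              1e-12)
  }
})

test_that("stable fixed point: symmetric value and relabeling symmetry", {
  expect_equal(stable_fixed_point(plasticity_params(0.5, 0.5)), 0.5)
  expect_equal(stable_fixed_point(plasticity_params(0.8, 0.2)), 0.64 / 0.68,
               tolerance = 1e-10)

  withr::local_seed(7)
  draws <- random_params(20, lo = 0.05, hi = 0.95)
  purrr::pwalk(draws, function(alpha, beta) {
    expect_equal(stable_fixed_point(plasticity_params(alpha, beta)),
                 1 - stable_fixed_point(plasticity_params(beta, alpha)),
                 tolerance = 1e-12)
  })
})

test_that("relaxation time: swap symmetry, oracle value, corner growth", {
  expect_equal(relaxation_time(plasticity_params(0.3, 0.7)),
               relaxation_time(plasticity_params(0.7, 0.3)),
               tolerance = 1e-12)

  # independent oracle: exponential rate fitted to an integrated trajectory
  p_sym <- plasticity_params(0.5, 0.5)
  tau <- relaxation_time(p_sym)
  expect_equal(tau, 4, tolerance = 1e-9)
  expect_equal(fit_decay_rate(p_sym), 1 / tau, tolerance = 0.01)

  # near-corner defaults have much longer retention times
  expect_gt(relaxation_time(plasticity_params(0.99, 0.01)), 20 * tau)
})

test_that("trajectory-fit rates match 1/tau for random parameters", {
  withr::local_seed(99)
  draws <- random_params(5)
  purrr::pwalk(draws, function(alpha, beta) {
    p <- plasticity_params(alpha, beta)
    expect_equal(fit_decay_rate(p), 1 / relaxation_time(p), tolerance = 0.01)
  })
})

test_that("mean-field trajectories relax monotonically to the fixed point", {
  p <- plasticity_params(0.8, 0.2)
  xs <- stable_fixed_point(p)

  flat <- mf_integrate(xs, p, duration = 5)
  expect_lt(max(abs(flat$x - xs)), 1e-9)

  traj <- mf_integrate(0.3, p, duration = 400)
  expect_equal(traj$x[nrow(traj)], xs, tolerance = 1e-6)
  expect_true(all(diff(traj$x) >= 0))
  expect_true(all(traj$x >= 0 & traj$x <= 1))

  expect_error(mf_integrate(0.5, p, duration = 100, dt = 30), "dt")
})

test_that("Euler integration agrees with an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- plasticity_params(0.7, 0.4)
  traj <- mf_integrate(0.2, p, duration = 30, dt = 0.01, record_every = 100L)
  sol <- deSolve::ode(c(x = 0.2), times = traj$t,
                      func = function(t, y, parms) list(drift(y, p)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(traj$x, unname(sol[, "x"]), tolerance = 1e-4)
})
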