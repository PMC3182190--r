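test_that("evolve_until_saturation: degeneracy, end state, tolerance scaling", {
  p <- plasticity_params(0.8, 0.2)
  cfg <- saturation_config(tol = 1e-6)

  at_fp <- evolve_until_saturation(stable_fixed_point(p), p, cfg)
  expect_true(at_fp$degenerate)
  expect_equal(at_fp$t_sat, 0)

  run <- evolve_until_saturation(0.5, p, cfg)
  expect_false(run$degenerate)
  expect_equal(run$x_end, 0.64 / 0.68, tolerance = 1e-4)

  # the saturation time has an exponential tail: halving the tolerance
  # lengthens it by tau * ln 2
  run2 <- evolve_until_saturation(0.5, p, saturation_config(tol = 5e-7))
  expect_equal(run2$t_sat - run$t_sat, relaxation_time(p) * log(2),
               tolerance = 0.05)

  expect_error(
    evolve_until_saturation(0.5, p, saturation_config(max_time = 1)),
    "max_time")
})

test_that("de-adaptation measures learning then forgetting", {
  default <- plasticity_params(0.3, 0.7)
  res <- run_protocol(default, build_protocol("deadaptation", 0.1))

  expect_gt(res$t_learn, 0)
  expect_gt(res$t_second, 0)
  expect_equal(res$ratio, res$t_second / res$t_learn)
  # forgetting relaxes to the default state, learning to the signal-on one
  expect_equal(res$analytic_ratio,
               relaxation_time(default) /
                 relaxation_time(apply_signal(default, 0.1)),
               tolerance = 1e-12)

  # trajectories are monotone within each phase (one-dimensional flow)
  traj <- tidy(res)
  for (ph in levels(traj$phase)) {
    xs <- traj$x[traj$phase == ph]
    expect_true(all(diff(xs) >= 0) || all(diff(xs) <= 0))
  }
  expect_true(all(traj$x >= 0 & traj$x <= 1))
  # the phase boundary coincides with the measured learning time
  expect_equal(min(traj$t[traj$phase == "2"]), res$t_learn)
})

test_that("forgetting slows as the synaptic timescales separate", {
  t_forget <- function(a, b) {
    run_protocol(plasticity_params(a, b),
                 build_protocol("deadaptation", 0.1))$t_second
  }
  t_sym <- t_forget(0.5, 0.5)
  t_mid <- t_forget(0.3, 0.7)
  t_far <- t_forget(0.2, 0.8)
  expect_gt(t_mid, t_sym)
  expect_gt(t_far, t_mid)
})

test_that("reversal timing starts at the default-level crossing", {
  sym <- plasticity_params(0.5, 0.5)
  res <- run_protocol(sym, build_protocol("reversal", 0.2))
  # mirror symmetry: relearning the mirrored signal from the default level
  # takes as long as the original learning
  expect_equal(res$ratio, 1, tolerance = 0.01)
  expect_equal(res$analytic_ratio, 1, tolerance = 1e-12)

  # an asymmetric default breaks the tie: one signal orientation interferes
  # more than the other
  asym <- plasticity_params(0.3, 0.7)
  r_pos <- run_protocol(asym, build_protocol("reversal", 0.15))$ratio
  r_neg <- run_protocol(asym, build_protocol("reversal", -0.15))$ratio
  expect_gt(abs(log(r_pos / r_neg)), 0.1)
  # and mirroring both the default and the signal restores equality
  mirrored <- run_protocol(plasticity_params(0.7, 0.3),
                           build_protocol("reversal", -0.15))$ratio
  expect_equal(r_pos, mirrored, tolerance = 1e-6)
})

test_that("analytic learning time depends on the signal, forgetting does not", {
  default <- plasticity_params(0.3, 0.7)
  s_grid <- c(0.05, 0.1, 0.2, 0.29)
  tau_learn <- vapply(s_grid, function(s) {
    relaxation_time(apply_signal(default, s))
  }, numeric(1))
  tau_forget <- vapply(s_grid, function(s) {
    proto <- build_protocol("deadaptation", s)
    analytic_timescale_ratio(default, proto) *
      relaxation_time(apply_signal(default, s))
  }, numeric(1))
  expect_lt(max(abs(tau_forget - relaxation_time(default))), 1e-9)
  expect_gt(diff(range(tau_learn)), 1)
})

test_that("degenerate and inadmissible protocols are rejected", {
  p <- plasticity_params(0.5, 0.5)
  expect_error(run_protocol(p, build_protocol("deadaptation", 0.6)),
               "inadmissible")
  expect_error(analytic_timescale_ratio(p, build_protocol("constant", 0.1)),
               "two-phase")
  proto <- build_protocol("deadaptation", 0.1)
  proto$s[1] <- 0  # forced zero-shift phase
  expect_error(run_protocol(p, proto), "zero-shift")
})

test_that("de-adaptation regression fixture is stable", {
  res <- run_protocol(plasticity_params(0.2, 0.8),
                      build_protocol("deadaptation", 0.1))
  expect_equal(res$ratio, 1.5511488365, tolerance = 1e-8)
  expect_equal(res$analytic_ratio, 2.0196659483, tolerance = 1e-8)
})
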