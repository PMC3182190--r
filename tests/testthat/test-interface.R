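test_that("configurations resolve with defaults and reject unknown keys", {
  cfg <- resolve_config(list(alpha = 0.6, beta = 0.3), "protocol")
  expect_equal(cfg$signal, 0.1)   # default filled in
  expect_equal(cfg$tol, 1e-6)
  expect_equal(cfg$alpha, 0.6)

  # diagonal shorthand a => (a, 1 - a)
  cfg <- resolve_config(list(a = 0.2), "protocol")
  expect_equal(cfg$alpha, 0.2)
  expect_equal(cfg$beta, 0.8)

  expect_error(resolve_config(list(alpa = 0.5), "protocol"), "unknown config")
  expect_error(resolve_config(list(alpha = 1.4), "simulate"), "alpha")
})

test_that("config files round-trip through JSON and YAML", {
  cfg <- list(alpha = 0.3, beta = 0.7, signal = 0.15)
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jf, auto_unbox = TRUE)
  expect_equal(read_run_config(jf)$signal, 0.15)

  yf <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yf)
  expect_equal(read_run_config(yf), cfg)

  expect_error(read_run_config("no-such-file.json"), "not found")
})

test_that("cli_simulate writes trajectory, summary and resolved config", {
  out <- withr::local_tempdir()
  files <- cli_simulate(list(alpha = 0.5, beta = 0.5, x0 = 0.3,
                             duration = 200), out)
  expect_true(all(file.exists(file.path(out, c("config.json", "summary.json",
                                               "trajectory.csv")))))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(summ$x_final, 0.5, tolerance = 1e-3)
  expect_equal(summ$x_star, 0.5)
  expect_true(is.character(summ$config_hash))

  # determinism: byte-identical outputs on a re-run
  out2 <- withr::local_tempdir()
  cli_simulate(list(alpha = 0.5, beta = 0.5, x0 = 0.3, duration = 200), out2)
  expect_identical(readLines(file.path(out, "trajectory.csv")),
                   readLines(file.path(out2, "trajectory.csv")))
})

test_that("cli_lattice runs are seeded and byte-identical", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(alpha = 0.55, beta = 0.45, n = 500, sweeps = 50, seed = 4)
  cli_lattice(cfg, out1)
  cli_lattice(cfg, out2)
  expect_identical(readLines(file.path(out1, "trajectory.csv")),
                   readLines(file.path(out2, "trajectory.csv")))
})

test_that("cli_protocol reports the measured and analytic ratios", {
  out <- withr::local_tempdir()
  cli_protocol(list(alpha = 0.5, beta = 0.5, protocol = "reversal",
                    signal = 0.2), out)
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(summ$ratio, 1, tolerance = 0.01)
  expect_equal(summ$analytic_ratio, 1, tolerance = 1e-9)
  traj <- utils::read.csv(file.path(out, "trajectory.csv"),
                          comment.char = "#")
  expect_true(all(c("t", "x", "phase") %in% names(traj)))
})

test_that("cli_phasemap writes both maps with identical masks", {
  out <- withr::local_tempdir()
  cli_phasemap(list(protocol = "deadaptation", a_n = 5, s_n = 5,
                    a_min = 0.2, a_max = 0.8, s_min = -0.3, s_max = 0.3),
               out)
  ma <- utils::read.csv(file.path(out, "map_analytic.csv"),
                        comment.char = "#")
  mn <- utils::read.csv(file.path(out, "map_numeric.csv"),
                        comment.char = "#")
  expect_identical(ma$admissible, mn$admissible)
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_true(!is.null(summ$comparison$spearman))
})

test_that("cli_main dispatches subcommands and reports failures", {
  out <- withr::local_tempdir()
  cf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(alpha = 0.5, beta = 0.5, protocol = "reversal",
                            signal = 0.2), cf, auto_unbox = TRUE)
  code <- suppressMessages(
    cli_main(c("protocol", "--config", cf, "--out", out, "--quiet")))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "summary.json")))

  # an inadmissible signal is a clean nonzero exit naming the bound
  jsonlite::write_json(list(alpha = 0.5, beta = 0.5, protocol = "reversal",
                            signal = 0.9), cf, auto_unbox = TRUE)
  expect_message(
    code <- cli_main(c("protocol", "--config", cf, "--out", out)),
    "allowed open interval")
  expect_equal(code, 1L)

  expect_equal(suppressMessages(cli_main(character(0))), 1L)
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 1L)
})
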