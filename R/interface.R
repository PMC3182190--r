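#' Read and validate a run configuration
#'
#' Configurations are JSON (or YAML) objects. Unknown keys are rejected,
#' defaults are filled in, and every run writes the fully resolved
#' configuration next to its outputs, so a run can be reproduced from its
#' output directory alone.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list (unvalidated; see [resolve_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

config_schema <- function(command) {
  common <- list(alpha = 0.5, beta = 0.5, a = NULL, seed = 1L)
  fields <- switch(command,
    simulate = list(engine = "meanfield", x0 = 0.3, duration = 100,
                    dt = 0.01, record_every = 10L),
    lattice = list(n = 1000L, x0 = 0.5, sweeps = 200L, record_every = 1L,
                   burn_in = 0.2),
    protocol = list(protocol = "deadaptation", signal = 0.1, tol = 1e-6,
                    dt = 0.01, max_time = 1e5, record_every = 10L),
    phasemap = list(protocol = "deadaptation", method = "both",
                    a_min = 0.05, a_max = 0.95, a_n = 41L,
                    s_min = -0.95, s_max = 0.95, s_n = 41L,
                    tol = 1e-6, dt = 0.01, max_time = 1e5),
    stop("unknown command: ", command, call. = FALSE)
  )
  c(common, fields)
}

#' Resolve a configuration against the schema of a command
#'
#' Fills defaults, rejects unknown keys, and normalizes the parameter
#' specification: either `alpha`/`beta` or the diagonal shorthand `a`
#' (meaning `alpha = a`, `beta = 1 - a`) may be given.
#'
#' @param config A named list, e.g. from [read_run_config()].
#' @param command One of `"simulate"`, `"lattice"`, `"protocol"`,
#'   `"phasemap"`.
#' @return The resolved configuration list, with an attribute `command`.
#' @export
resolve_config <- function(config, command) {
  schema <- config_schema(command)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0) {
    stop("unknown config keys for `", command, "`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  resolved <- utils::modifyList(schema, config[!vapply(config, is.null, TRUE)])
  if (!is.null(resolved$a)) {
    resolved$alpha <- resolved$a
    resolved$beta <- 1 - resolved$a
  }
  resolved$a <- NULL
  # validates the probabilities early, with the standard error message
  plasticity_params(resolved$alpha, resolved$beta)
  attr(resolved, "command") <- command
  resolved
}

run_metadata <- function(config) {
  list(package = "compsyn",
       version = as.character(utils::packageVersion("compsyn")),
       config_hash = rlang::hash(config))
}

write_outputs <- function(out_dir, config, summary, tables = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- run_metadata(config)
  jsonlite::write_json(c(meta, list(config = config)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(meta, summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# compsyn %s config %s", meta$version,
                       meta$config_hash), con)
    utils::write.csv(tables[[nm]], con, row.names = FALSE)
    close(con)
  }
  invisible(file.path(out_dir,
                      c("config.json", "summary.json",
                        if (length(tables)) paste0(names(tables), ".csv"))))
}

#' Run a trajectory simulation from a configuration
#'
#' `cli_simulate()` integrates the mean-field dynamics (or, with
#' `engine = "lattice"`, delegates to [cli_lattice()]); `cli_lattice()`
#' runs the seeded stochastic chain. Both write `trajectory.csv`,
#' `summary.json` and the resolved `config.json` into `out_dir`.
#'
#' @param config A named list (see [resolve_config()]).
#' @param out_dir Output directory, created if needed.
#' @return The written file paths, invisibly.
#' @export
cli_simulate <- function(config, out_dir) {
  cfg <- resolve_config(config, "simulate")
  if (identical(cfg$engine, "lattice")) {
    stop("use cli_lattice() / the `lattice` subcommand for lattice runs",
         call. = FALSE)
  }
  params <- plasticity_params(cfg$alpha, cfg$beta)
  traj <- mf_integrate(cfg$x0, params, cfg$duration, cfg$dt, cfg$record_every)
  summary <- list(x0 = cfg$x0, x_final = traj$x[[nrow(traj)]],
                  x_star = stable_fixed_point(params),
                  tau = relaxation_time(params))
  write_outputs(out_dir, cfg, summary, list(trajectory = traj))
}

#' @rdname cli_simulate
#' @export
cli_lattice <- function(config, out_dir) {
  cfg <- resolve_config(config, "lattice")
  params <- plasticity_params(cfg$alpha, cfg$beta)
  lat <- init_lattice(cfg$n, cfg$x0, seed = cfg$seed)
  traj <- run_sweeps(lat, params, cfg$sweeps, cfg$record_every)
  stat <- stationary_fraction(traj, burn_in = cfg$burn_in)
  summary <- list(stationary_mean = stat$mean, stationary_stderr = stat$stderr,
                  absorbed = stat$absorbed,
                  x_star = stable_fixed_point(params))
  write_outputs(out_dir, cfg, summary, list(trajectory = traj))
}

#' Run a signal protocol from a configuration
#'
#' Writes `summary.json` (with `t_learn`, `t_second`, `ratio`,
#' `analytic_ratio`), the phase-labelled `trajectory.csv`, and the
#' resolved `config.json`.
#'
#' @inheritParams cli_simulate
#' @return The written file paths, invisibly.
#' @export
cli_protocol <- function(config, out_dir) {
  cfg <- resolve_config(config, "protocol")
  params <- plasticity_params(cfg$alpha, cfg$beta)
  proto <- build_protocol(cfg$protocol, cfg$signal)
  res <- run_protocol(params, proto,
                      saturation_config(cfg$tol, cfg$dt, cfg$max_time),
                      record_every = cfg$record_every)
  summary <- list(kind = res$kind, s = res$s, t_learn = res$t_learn,
                  t_second = res$t_second, ratio = res$ratio,
                  analytic_ratio = res$analytic_ratio)
  write_outputs(out_dir, cfg, summary, list(trajectory = tidy(res)))
}

#' Compute phase maps from a configuration
#'
#' Writes long-format CSV maps (`map_analytic.csv` / `map_numeric.csv`),
#' and, when both methods are requested, embeds the [compare_maps()]
#' summary in `summary.json`.
#'
#' @inheritParams cli_simulate
#' @return The written file paths, invisibly.
#' @export
cli_phasemap <- function(config, out_dir) {
  cfg <- resolve_config(config, "phasemap")
  a_grid <- seq(cfg$a_min, cfg$a_max, length.out = cfg$a_n)
  s_grid <- seq(cfg$s_min, cfg$s_max, length.out = cfg$s_n)
  scfg <- saturation_config(cfg$tol, cfg$dt, cfg$max_time)
  methods <- if (identical(cfg$method, "both")) c("analytic", "numeric")
             else cfg$method
  maps <- lapply(methods, function(m) {
    ratio_map(cfg$protocol, a_grid, s_grid, method = m, cfg = scfg)
  })
  names(maps) <- paste0("map_", methods)
  summary <- list(protocol = cfg$protocol, methods = methods,
                  n_admissible = vapply(maps, function(m) sum(m$admissible),
                                        integer(1)))
  if (length(maps) == 2) {
    summary$comparison <- as.list(compare_maps(maps[[1]], maps[[2]]))
  }
  write_outputs(out_dir, cfg, summary, maps)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `lattice`, `protocol`,
#' `phasemap` and `compare` used by the shipped `exec/compsyn` script.
#' Global flags: `--config <file>` (JSON/YAML), `--out <dir>`,
#' `--seed <int>` (overrides the config seed), `--quiet`.
#'
#' @param args Character vector of command-line arguments.
#' @return The exit code, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: compsyn <simulate|lattice|protocol|phasemap|",
                  "compare> --config FILE --out DIR [--seed N] [--quiet]")
  code <- tryCatch({
    if (length(args) < 1) stop(usage, call. = FALSE)
    command <- args[[1]]
    opt <- list(config = NULL, out = "compsyn-out", seed = NULL,
                quiet = FALSE)
    i <- 2
    while (i <= length(args)) {
      a <- args[[i]]
      if (a == "--quiet") { opt$quiet <- TRUE; i <- i + 1; next }
      if (!a %in% c("--config", "--out", "--seed") || i == length(args)) {
        stop(usage, call. = FALSE)
      }
      opt[[sub("^--", "", a)]] <- args[[i + 1]]
      i <- i + 2
    }
    config <- if (is.null(opt$config)) list() else read_run_config(opt$config)
    if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
    if (command == "compare") {
      maps <- lapply(file.path(opt$out, c("map_analytic.csv",
                                          "map_numeric.csv")),
                     read_phase_map_csv)
      print(compare_maps(maps[[1]], maps[[2]]))
      return(invisible(0L))
    }
    fun <- switch(command, simulate = cli_simulate, lattice = cli_lattice,
                  protocol = cli_protocol, phasemap = cli_phasemap,
                  stop(usage, call. = FALSE))
    files <- fun(config, opt$out)
    if (!opt$quiet) message("wrote: ", paste(files, collapse = ", "))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

# Reads back a map CSV written by cli_phasemap (metadata comment skipped).
read_phase_map_csv <- function(path, kind = "deadaptation") {
  df <- utils::read.csv(path, comment.char = "#")
  out <- tibble::as_tibble(df)
  class(out) <- c("phase_map", class(out))
  attr(out, "kind") <- kind
  attr(out, "method") <- "file"
  out
}
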