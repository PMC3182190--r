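#' Initialize a periodic chain of binary synapses
#'
#' Each site is independently strong with probability `x0` under the seeded
#' generator, so a fixed seed gives a reproducible lattice. The chain is
#' periodic: every synapse has exactly two synaptic neighbours.
#'
#' @param n Lattice size, at least 3.
#' @param x0 Initial strong probability per site, in \[0, 1\].
#' @param seed Integer seed for the random number generator; `NULL` leaves
#'   the ambient generator state untouched.
#' @return An object of class `lattice_state`: a list with `states`
#'   (integer vector, 1 = strong, 0 = weak), `n`, `boundary` and `seed`.
#' @examples
#' lat <- init_lattice(100, 0.5, seed = 1)
#' mean(lat$states)
#' @export
init_lattice <- function(n, x0, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, is.numeric(x0), length(x0) == 1,
            x0 >= 0, x0 <= 1)
  n <- as.integer(n)
  if (n < 3) stop("lattice size `n` must be at least 3", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  states <- as.integer(stats::runif(n) < x0)
  structure(list(states = states, n = n, boundary = "periodic",
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> n = %d (%s), strong fraction = %.4f\n",
              x$n, x$boundary, mean(x$states)))
  invisible(x)
}

#' Apply a single candidate-synapse update
#'
#' Samples the activations of the two neurons flanking site `idx` — each
#' fires with probability `alpha` or `beta` according to the type of its
#' *other* adjacent synapse, the common candidate synapse being ignored —
#' classifies the polarity of the resulting synaptic current, and sets the
#' candidate to strong on potentiation, weak on depression, and leaves it
#' unchanged otherwise. Draws two uniforms from the ambient generator.
#'
#' @param state A [init_lattice()] object.
#' @param idx Site index in `1:n`.
#' @param params A [plasticity_params()] object.
#' @return The updated `lattice_state`.
#' @export
update_once <- function(state, idx, params) {
  stopifnot(inherits(state, "lattice_state"))
  params <- as_plasticity_params(params)
  n <- state$n
  if (!is.numeric(idx) || length(idx) != 1 || idx < 1 || idx > n) {
    stop("`idx` must be a site index in 1..n", call. = FALSE)
  }
  idx <- as.integer(idx)
  lt <- state$states[if (idx == 1L) n else idx - 1L]
  rt <- state$states[if (idx == n) 1L else idx + 1L]
  u <- stats::runif(2)
  fire_l <- u[1] < (if (lt == 1L) params$alpha else params$beta)
  fire_r <- u[2] < (if (rt == 1L) params$alpha else params$beta)
  if (lt != rt && xor(fire_l, fire_r)) {
    fired_type <- if (fire_l) lt else rt
    state$states[idx] <- fired_type
  }
  state
}

#' Run random-sequential Monte-Carlo sweeps
#'
#' Performs `n_sweeps * n` candidate updates with uniform site choice (with
#' replacement); one sweep — `n` update attempts — is one unit of time,
#' matching the mean-field clock. The strong fraction is recorded on
#' schedule. Absorbing states (all strong or all weak) are detected and
#' flagged; once absorbed the configuration can never change, so updating
#' stops and the recorded fraction stays constant.
#'
#' Reproducibility: the simulation draws from R's generator, so
#' `init_lattice(n, x0, seed) |> run_sweeps(...)` is deterministic for a
#' fixed seed.
#'
#' @param state A [init_lattice()] object.
#' @param params A [plasticity_params()] object.
#' @param n_sweeps Number of sweeps, at least 1.
#' @param record_every Record the strong fraction every this many sweeps.
#' @return A tibble of class `lattice_trajectory` with columns `sweep` and
#'   `strong_fraction`, and attributes `absorbed` (logical) and
#'   `final_state` (the end-of-run `lattice_state`).
#' @examples
#' init_lattice(500, 0.5, seed = 1) |>
#'   run_sweeps(plasticity_params(0.8, 0.2), n_sweeps = 50)
#' @export
run_sweeps <- function(state, params, n_sweeps, record_every = 1L) {
  stopifnot(inherits(state, "lattice_state"))
  params <- as_plasticity_params(params)
  stopifnot(is.numeric(n_sweeps), length(n_sweeps) == 1, n_sweeps >= 1)
  res <- cpp_run_sweeps(state$states, params$alpha, params$beta,
                        as.integer(n_sweeps), as.integer(record_every))
  out <- tibble::tibble(sweep = res$sweep, strong_fraction = res$strong_fraction)
  class(out) <- c("lattice_trajectory", class(out))
  final <- state
  final$states <- res$state
  attr(out, "absorbed") <- res$absorbed
  attr(out, "final_state") <- final
  attr(out, "params") <- params
  out
}

#' Stationary strong fraction with batch-means error
#'
#' Discards a burn-in prefix and estimates the mean strong fraction together
#' with an autocorrelation-aware standard error by the method of batch
#' means: the post-burn-in window is split into `n_batches` contiguous
#' batches and the standard error of the batch averages is reported.
#'
#' @param traj A [run_sweeps()] trajectory.
#' @param burn_in Fraction of the trajectory to discard, in \[0, 1).
#' @param n_batches Number of batches, at least 10.
#' @return A one-row tibble with columns `mean`, `stderr`, `n_used`,
#'   `absorbed`.
#' @export
stationary_fraction <- function(traj, burn_in = 0.2, n_batches = 10L) {
  stopifnot(is.numeric(burn_in), burn_in >= 0, burn_in < 1)
  n_batches <- as.integer(n_batches)
  if (n_batches < 10L) stop("need at least 10 batches", call. = FALSE)
  x <- traj$strong_fraction
  keep <- x[-seq_len(floor(burn_in * length(x)))]
  if (length(keep) < n_batches) {
    stop("post-burn-in window too short for batching", call. = FALSE)
  }
  batch <- floor(seq_along(keep) * n_batches / (length(keep) + 1e-9)) + 1
  batch[batch > n_batches] <- n_batches
  means <- tapply(keep, batch, mean)
  se <- stats::sd(means) / sqrt(length(means))
  tibble::tibble(mean = mean(keep), stderr = se, n_used = length(keep),
                 absorbed = isTRUE(attr(traj, "absorbed")))
}

# Pure-R reference of run_sweeps, drawing uniforms in the same order as the
# compiled kernel (site, left neuron, right neuron). Used in tests to pin
# the C++ kernel update-for-update; far too slow for production sizes.
r_run_sweeps <- function(state, params, n_sweeps, record_every = 1L) {
  n <- state$n
  st <- state$states
  sweeps <- 0
  frac <- mean(st)
  absorbed <- all(st == 1L) || all(st == 0L)
  for (sw in seq_len(n_sweeps)) {
    if (!absorbed) {
      for (u in seq_len(n)) {
        i <- min(floor(stats::runif(1) * n), n - 1) + 1
        u_l <- stats::runif(1)
        u_r <- stats::runif(1)
        lt <- st[if (i == 1) n else i - 1]
        rt <- st[if (i == n) 1 else i + 1]
        if (lt == rt) next
        fire_l <- u_l < (if (lt == 1L) params$alpha else params$beta)
        fire_r <- u_r < (if (rt == 1L) params$alpha else params$beta)
        if (fire_l == fire_r) next
        st[i] <- if (fire_l) lt else rt
      }
      absorbed <- all(st == 1L) || all(st == 0L)
    }
    if ((record_every > 0 && sw %% record_every == 0) || sw == n_sweeps) {
      sweeps <- c(sweeps, sw)
      frac <- c(frac, mean(st))
    }
  }
  tibble::tibble(sweep = as.numeric(sweeps), strong_fraction = frac)
}
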