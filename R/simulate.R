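#' Stimulation protocol
#'
#' Bundles the timing settings of a simulation: the pre-stimulation
#' equilibration length, the stimulation length and dosage, the fixed
#' integrator step, and the sampling interval of the stored trajectory.
#'
#' @param TR Dimensionless stimulus dosage (>= 0); the IKKn -> IKKa
#'   activation proceeds at rate `TR * K1`.
#' @param t_equilibrate Equilibration length in hours (default 33 h) run
#'   with `TR = 0` from the all-cytoplasmic initial condition.
#' @param t_stimulate Stimulation length in hours (default 10 h).
#' @param dt Integrator step in seconds (default 1 s).
#' @param output_stride Sampling interval of the stored trajectory in
#'   seconds (default 60 s); must be at least `dt`.
#' @return A list of class `nfkb_protocol`.
#' @export
nfkb_protocol <- function(TR = 1, t_equilibrate = 33, t_stimulate = 10,
                          dt = 1, output_stride = 60) {
  stopifnot(
    is.numeric(TR), length(TR) == 1, TR >= 0,
    t_equilibrate >= 0, t_stimulate >= 0,
    dt > 0, output_stride >= dt
  )
  structure(
    list(TR = TR, t_equilibrate = t_equilibrate, t_stimulate = t_stimulate,
         dt = dt, output_stride = output_stride),
    class = "nfkb_protocol"
  )
}

#' Integrate a compiled mass-action model with fixed-step RK4
#'
#' Low-level driver around the compiled classical 4th-order Runge-Kutta
#' scheme. `model` is the list produced by [nfkb_model()] (or any list with
#' the same `k`/`sub1`/`sub2`/`Si`/`Sj`/`Sx`/`species` fields, which lets
#' tests integrate toy systems with the same engine).
#'
#' @param model Compiled model list.
#' @param state0 Non-negative initial state in `model$species` order.
#' @param duration Integration length in hours.
#' @param dt Step in seconds.
#' @param output_stride Sampling interval in seconds.
#' @param clamp_tol States are clamped at zero before flux evaluation;
#'   values below `-clamp_tol` after a step raise an integrity error
#'   (the default tolerates fixed-step truncation undershoot near zero
#'   while still catching genuine divergence).
#' @return A tibble with `time_h` (0 = start) and one column per species;
#'   the first row is `state0`.
#' @export
integrate_rk4 <- function(model, state0, duration, dt = 1,
                          output_stride = 60, clamp_tol = 1e-6) {
  stopifnot(dt > 0, duration >= 0, output_stride >= dt)
  state0 <- as.numeric(state0)
  stopifnot(length(state0) == length(model$species),
            all(is.finite(state0)), all(state0 >= 0))
  nsteps <- as.integer(round(duration * 3600 / dt))
  stride <- max(1L, as.integer(round(output_stride / dt)))
  mat <- rk4_mass_action(
    state0, model$k, as.integer(model$sub1), as.integer(model$sub2),
    as.integer(model$Si), as.integer(model$Sj), model$Sx,
    dt, nsteps, stride, clamp_tol
  )
  colnames(mat) <- model$species
  time_h <- (seq_len(nrow(mat)) - 1L) * stride * dt / 3600
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- tibble::add_column(out, time_h = time_h, .before = 1)
  out
}

#' Equilibrate the network before stimulation
#'
#' Starts from all NF-kB free in the cytoplasm (at `NFkB_total`) and zero
#' for every other species, and integrates with `TR = 0` for
#' `t_equilibrate` hours. A warning is emitted if the largest relative
#' time-derivative at the end exceeds `warn_tol` (the run length is fixed,
#' not iterated to convergence).
#'
#' @param params An `nfkb_params` vector.
#' @param protocol An [nfkb_protocol()]; only its timing fields are used
#'   (`TR` is forced to 0 during equilibration).
#' @param warn_tol Relative-derivative warning threshold, per second
#'   (default `1e-5`; the slowest IkB-isoform turnover leaves a residual
#'   drift of order `1e-6`/s after the fixed 33 h pre-run).
#' @return Named numeric state vector at the end of equilibration.
#' @export
equilibrate <- function(params, protocol = nfkb_protocol(),
                        warn_tol = 1e-5) {
  stopifnot(inherits(protocol, "nfkb_protocol"))
  model <- nfkb_model(params, TR = 0)
  st0 <- nfkb_initial_state(params)
  traj <- integrate_rk4(model, st0, protocol$t_equilibrate,
                        dt = protocol$dt,
                        output_stride = protocol$output_stride)
  st <- as.numeric(traj[nrow(traj), model$species])
  names(st) <- model$species
  dy <- nfkb_derivatives(st, params, TR = 0)
  rel <- max(abs(dy) / pmax(abs(st), 1e-9 * params[["NFkB_total"]]))
  if (rel > warn_tol) {
    warning(sprintf(
      "equilibration not converged: max relative derivative %.3g /s after %g h",
      rel, protocol$t_equilibrate), call. = FALSE)
  }
  st
}

#' Simulate the stimulated response of one replicate
#'
#' Equilibrates the network, then applies a persistent stimulus of dosage
#' `protocol$TR` for `t_stimulate` hours. Trajectory time 0 is stimulation
#' onset and the first row is the equilibrated pre-stimulus state.
#'
#' @param params An `nfkb_params` vector.
#' @param protocol An [nfkb_protocol()].
#' @param state0 Optional pre-equilibrated state (skips equilibration).
#' @return A tibble of class `nfkb_trajectory`: `time_h` plus one column
#'   per species, with the parameters and protocol attached as attributes.
#' @examples
#' \donttest{
#' p <- nfkb_parameters()
#' traj <- simulate_response(p, nfkb_protocol(TR = 1, t_stimulate = 6))
#' range(nfkb_total(traj, p))  # constant at NFkB_total = 0.06
#' }
#' @export
simulate_response <- function(params, protocol = nfkb_protocol(),
                              state0 = NULL) {
  stopifnot(inherits(protocol, "nfkb_protocol"))
  if (is.null(state0)) state0 <- equilibrate(params, protocol)
  model <- nfkb_model(params, TR = protocol$TR)
  traj <- integrate_rk4(model, state0[model$species], protocol$t_stimulate,
                        dt = protocol$dt,
                        output_stride = protocol$output_stride)
  structure(traj,
            params = params, protocol = protocol,
            class = c("nfkb_trajectory", class(traj)))
}

#' Default logarithmic TR grid for dose-response sweeps
#'
#' @param points_per_decade Grid density (default 20).
#' @param range Dosage range (default `c(1e-5, 1e-1)`).
#' @param include_zero Prepend `TR = 0` (default TRUE).
#' @return Ascending numeric vector of dosages.
#' @export
nfkb_tr_grid <- function(points_per_decade = 20, range = c(1e-5, 1e-1),
                         include_zero = TRUE) {
  stopifnot(length(range) == 2, range[1] > 0, range[2] > range[1])
  n <- ceiling(log10(range[2] / range[1]) * points_per_decade)
  grid <- 10^seq(log10(range[1]), log10(range[2]), length.out = n + 1)
  if (include_zero) grid <- c(0, grid)
  grid
}

#' Dose-response sweep with hysteresis check
#'
#' Steps the dosage up the TR grid and back down again, holding each step
#' for `t_hold` hours and carrying the state from step to step (a step-like
#' persistent-stimulation protocol). The response at each step is the
#' quasi-steady-state nuclear NF-kB level: the mean over the averaging
#' `window` (default hours 20-30 of each hold).
#'
#' @param params An `nfkb_params` vector.
#' @param tr_grid Ascending dosage grid (default [nfkb_tr_grid()]).
#' @param t_hold Hold length per dosage step, hours (default 30).
#' @param window Averaging window within each hold, hours (default
#'   `c(20, 30)`).
#' @param t_equilibrate Pre-sweep equilibration, hours.
#' @param dt,output_stride Integrator step and sampling interval, seconds.
#' @return A tibble of class `nfkb_dose_response` with columns `TR`,
#'   `forward`, `backward` (nuclear NF-kB levels).
#' @export
dose_response <- function(params, tr_grid = nfkb_tr_grid(), t_hold = 30,
                          window = c(20, 30), t_equilibrate = 33,
                          dt = 1, output_stride = 60) {
  tr_grid <- as.numeric(tr_grid)
  if (length(tr_grid) == 0) stop("empty TR grid", call. = FALSE)
  if (is.unsorted(tr_grid, strictly = TRUE)) {
    stop("tr_grid must be strictly ascending", call. = FALSE)
  }
  stopifnot(all(tr_grid >= 0), window[1] < window[2], window[2] <= t_hold)

  state <- equilibrate(params, nfkb_protocol(
    TR = 0, t_equilibrate = t_equilibrate, dt = dt,
    output_stride = output_stride))
  sp <- nfkb_species()$species

  hold_level <- function(state, TR) {
    model <- nfkb_model(params, TR = TR)
    traj <- integrate_rk4(model, state[sp], t_hold, dt = dt,
                          output_stride = output_stride)
    sel <- traj$time_h >= window[1] & traj$time_h <= window[2]
    list(level = mean(traj$NFkBn[sel]),
         state = stats::setNames(as.numeric(traj[nrow(traj), sp]), sp))
  }

  forward <- numeric(length(tr_grid))
  for (i in seq_along(tr_grid)) {
    h <- hold_level(state, tr_grid[i])
    forward[i] <- h$level
    state <- h$state
  }
  backward <- numeric(length(tr_grid))
  for (i in rev(seq_along(tr_grid))) {
    h <- hold_level(state, tr_grid[i])
    backward[i] <- h$level
    state <- h$state
  }
  structure(
    tibble::tibble(TR = tr_grid, forward = forward, backward = backward),
    window = window, t_hold = t_hold,
    class = c("nfkb_dose_response", class(tibble::tibble()))
  )
}

#' Forward/backward hysteresis check on a dose-response curve
#'
#' @param dr An [dose_response()] result.
#' @param threshold Maximum tolerated relative forward/backward gap
#'   (default 0.05).
#' @return A one-row tibble with `max_rel_gap` and logical `hysteresis`.
#' @export
hysteresis <- function(dr, threshold = 0.05) {
  stopifnot(inherits(dr, "nfkb_dose_response"))
  denom <- pmax(pmax(dr$forward, dr$backward), .Machine$double.xmin)
  gap <- max(abs(dr$forward - dr$backward) / denom)
  tibble::tibble(max_rel_gap = gap, hysteresis = gap > threshold)
}
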