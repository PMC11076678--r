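#' Simulation configuration
#'
#' Settings for the stochastic integration: total duration, fixed step,
#' transient discard, number of independent noise realizations (repeats) and
#' the base random seed. Defaults follow the study protocol: 30 s of
#' simulated time, 20 repeats, 1 ms step, with the first 2 s discarded
#' before spectral analysis.
#'
#' @param duration Total simulated time, s.
#' @param dt Integration and noise-hold step, s.
#' @param transient Initial span discarded from returned traces, s.
#' @param n_repeats Number of independent noise realizations.
#' @param seed Base random seed; repeat `i` uses `seed + i`.
#' @param initial_state Initial [neural_state()] (default: all zeros).
#' @param divergence_bound Absolute state bound beyond which integration is
#'   declared divergent.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(duration = 30, dt = 1e-3, transient = 2,
                              n_repeats = 20, seed = 1,
                              initial_state = neural_state(),
                              divergence_bound = 1e6) {
  if (!(dt > 0 && dt < duration))
    stop("`dt` must satisfy 0 < dt < duration", call. = FALSE)
  if (!(transient >= 0 && transient < duration))
    stop("`transient` must satisfy 0 <= transient < duration", call. = FALSE)
  if (!(n_repeats >= 1))
    stop("`n_repeats` must be at least 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a finite integer scalar", call. = FALSE)
  check_state(initial_state)
  structure(list(duration = duration, dt = dt, transient = transient,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 initial_state = initial_state,
                 divergence_bound = divergence_bound),
            class = "simulation_config")
}

n_steps_of <- function(config) as.integer(round(config$duration / config$dt))

#' Gaussian white-noise drive (zero-order hold)
#'
#' Generates one realization of the exogenous drive `P(t)`: i.i.d.
#' `Normal(mu_r, phi_r)` values held constant on each step interval
#' `[k*dt, (k+1)*dt)`. The realization is reproducible from the pair
#' `(config$seed, repeat_index)` (seed used: `seed + repeat_index`).
#'
#' @param config A [simulation_config()].
#' @param mu_r Drive mean, spikes/s.
#' @param phi_r Drive variance, (spikes/s)^2; `0` yields the constant drive
#'   `mu_r`.
#' @param repeat_index Which realization (1-based).
#' @return A function `t -> P(t)` of class `"zoh_drive"`, vectorized in `t`,
#'   carrying the held values as `attr(, "values")` and the hold step as
#'   `attr(, "dt")`.
#' @examples
#' cfg <- simulation_config(duration = 1, n_repeats = 1, seed = 7)
#' drv <- make_drive(cfg, mu_r = 86, phi_r = 1)
#' drv(c(0, 0.0005, 0.001))   # first two share the first held value
#' @export
make_drive <- function(config, mu_r = 86, phi_r = 1, repeat_index = 1) {
  if (phi_r < 0)
    stop("`phi_r` must be non-negative", call. = FALSE)
  n <- n_steps_of(config)
  vals <- if (phi_r == 0) rep(mu_r, n) else {
    set.seed(config$seed + repeat_index)
    rnorm(n, mean = mu_r, sd = sqrt(phi_r))
  }
  dt <- config$dt
  f <- function(t) vals[pmin(pmax(floor(t / dt), 0), n - 1) + 1]
  attr(f, "values") <- vals
  attr(f, "dt") <- dt
  class(f) <- c("zoh_drive", "function")
  f
}

# held drive values on the integration grid: fast path when the drive's own
# hold step equals dt, otherwise sample at left endpoints
held_values <- function(drive, n, dt) {
  v <- attr(drive, "values")
  if (!is.null(v) && isTRUE(all.equal(attr(drive, "dt"), dt)) &&
      length(v) >= n) return(v[seq_len(n)])
  drive((seq_len(n) - 1) * dt)
}

#' Integrate the thalamocortical system under a given drive
#'
#' Deterministic integration of the circuit for one drive realization. The
#' reference integrator is classical fixed-step RK4 at step `dt`, with the
#' drive held constant over each step (zero-order hold, the value at the
#' step's left endpoint used for all four stage evaluations). An adaptive
#' Runge-Kutta 4(5) mode over the same held drive is available for
#' comparison with adaptive-solver practice.
#'
#' @param params A [model_parameters()] object.
#' @param config A [simulation_config()].
#' @param drive A drive function `t -> P(t)`, typically from [make_drive()];
#'   defaults to the noise realization for repeat 1.
#' @param method `"rk4"` (fixed step, reference) or `"rk45"` (adaptive,
#'   via [deSolve::ode()]).
#' @param full_state Return the full six-column state trajectory as well as
#'   the output potential.
#' @return A list with `time` (the uniform grid, s), `v` (output potential,
#'   mV), and if `full_state` a matrix `state` (time points x 6).
#' @examples
#' cfg <- simulation_config(duration = 2, n_repeats = 1)
#' tr <- integrate_model(model_parameters(), cfg)
#' range(tr$v)
#' @export
integrate_model <- function(params, config,
                            drive = make_drive(config, params$mu_r,
                                               params$phi_r, 1),
                            method = c("rk4", "rk45"),
                            full_state = FALSE) {
  method <- match.arg(method)
  validate_params(params)
  n <- n_steps_of(config)
  tgrid <- (0:n) * config$dt
  if (method == "rk4") {
    u <- matrix(held_values(drive, n, config$dt), ncol = 1)
    res <- .rk4_core(as.numeric(config$initial_state), u, config$dt,
                     params_for_core(params), full_state,
                     config$divergence_bound)
    if (res$diverged_rep > 0)
      stop(sprintf("integration diverged at t = %.4f s (|state| > %g)",
                   res$diverged_t, config$divergence_bound), call. = FALSE)
    out <- list(time = tgrid, v = as.numeric(res$v))
    if (full_state) {
      st <- res$states[[1]]
      colnames(st) <- state_names
      out$state <- st
    }
  } else {
    core <- params_for_core(params)
    func <- function(t, y, parms) {
      list(as.numeric(.rhs_core(y, drive(t), core)))
    }
    sol <- deSolve::ode(y = as.numeric(config$initial_state), times = tgrid,
                        func = func, parms = NULL, method = "ode45")
    st <- unname(sol[, -1, drop = FALSE])
    if (!all(is.finite(st)) || max(abs(st)) > config$divergence_bound)
      stop("integration diverged (rk45 mode)", call. = FALSE)
    out <- list(time = tgrid, v = params$C3 * st[, 1] - params$C2 * st[, 5])
    if (full_state) {
      colnames(st) <- state_names
      out$state <- st
    }
  }
  out$method <- method
  out
}

#' Run repeated stochastic simulations
#'
#' Integrates `n_repeats` independent noise realizations of the circuit
#' (repeat `i` seeded with `seed + i`), discards the transient, and collects
#' the output-potential traces. The across-repeat mean trace is retained for
#' inspection; spectral analysis averages per-repeat power spectra instead
#' (see [analyze_simulation()]), since averaging incoherent oscillatory
#' traces cancels the rhythm.
#'
#' @param params A [model_parameters()] object (its `mu_r`, `phi_r` define
#'   the drive; its `tau_i` is typically set via [tau_inhibitory()]).
#' @param config A [simulation_config()].
#' @return An object of class `"simulation_result"`: list with `time`
#'   (post-transient grid, s), `traces` (matrix, time x repeats, mV),
#'   `mean_trace`, `tau_i_used` (ms), `seeds`, and the `params`/`config`
#'   used.
#' @examples
#' cfg <- simulation_config(duration = 4, n_repeats = 2, seed = 1)
#' sim <- run_repeats(model_parameters(), cfg)
#' sim
#' @export
run_repeats <- function(params, config = simulation_config()) {
  validate_params(params)
  n <- n_steps_of(config)
  u <- matrix(0, n, config$n_repeats)
  for (i in seq_len(config$n_repeats))
    u[, i] <- attr(make_drive(config, params$mu_r, params$phi_r, i), "values")
  res <- .rk4_core(as.numeric(config$initial_state), u, config$dt,
                   params_for_core(params), FALSE, config$divergence_bound)
  if (res$diverged_rep > 0)
    stop(sprintf(
      "integration diverged at t = %.4f s in repeat %d (|state| > %g)",
      res$diverged_t, res$diverged_rep, config$divergence_bound),
      call. = FALSE)
  keep <- (as.integer(round(config$transient / config$dt)) + 1):(n + 1)
  traces <- res$v[keep, , drop = FALSE]
  structure(list(time = (keep - 1) * config$dt,
                 traces = traces,
                 mean_trace = rowMeans(traces),
                 tau_i_used = params$tau_i,
                 seeds = config$seed + seq_len(config$n_repeats),
                 params = params, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Thalamocortical simulation result\n")
  cat(sprintf("  %d repeat(s), %d samples each (t = %.3g..%.3g s, dt = %g s)\n",
              ncol(x$traces), nrow(x$traces), min(x$time), max(x$time),
              x$config$dt))
  cat(sprintf("  tau_i = %.4g ms, mu_r = %.4g sp/s, phi_r = %.3g\n",
              x$tau_i_used, x$params$mu_r, x$params$phi_r))
  cat(sprintf("  output range: [%.3g, %.3g] mV\n",
              min(x$traces), max(x$traces)))
  invisible(x)
}

#' Write simulation traces as tidy CSV
#'
#' Long-format export: columns `time_s`, `repeat`, `v_mV`, one row per
#' sample per repeat, plus a key-value run manifest alongside.
#'
#' @param sim A [run_repeats()] result.
#' @param out_prefix Path prefix; writes `<prefix>_timeseries.csv` and
#'   `<prefix>_manifest.txt`.
#' @return Invisibly, the paths written.
#' @export
write_timeseries <- function(sim, out_prefix) {
  stopifnot(inherits(sim, "simulation_result"))
  df <- data.frame(
    time_s = rep(sim$time, times = ncol(sim$traces)),
    rep = rep(seq_len(ncol(sim$traces)), each = nrow(sim$traces)),
    v_mV = as.numeric(sim$traces))
  names(df)[2] <- "repeat"
  csv <- paste0(out_prefix, "_timeseries.csv")
  write.csv(df, csv, row.names = FALSE)
  man <- paste0(out_prefix, "_manifest.txt")
  write_manifest(man, c(
    unlist(sim$params[setdiff(names(sim$params), "trn_input")]),
    trn_input = sim$params$trn_input,
    duration = sim$config$duration, dt = sim$config$dt,
    transient = sim$config$transient, n_repeats = sim$config$n_repeats,
    base_seed = sim$config$seed,
    seeds = paste(sim$seeds, collapse = ","),
    tau_i_used_ms = sim$tau_i_used))
  invisible(c(csv, man))
}

write_manifest <- function(path, kv) {
  writeLines(paste0(names(kv), " = ", unname(kv)), path)
  invisible(path)
}
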