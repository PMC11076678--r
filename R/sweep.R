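#' Parameter sweep over the amyloid / connectivity / drive axes
#'
#' Runs the full pipeline — amyloid mapping, repeated stochastic
#' integration, repeat-averaged Welch PSD, alpha summary — at every value of
#' a one-dimensional grid over one of `beta_a` (amyloid load, SUVR), `C1`
#' (TCR-to-TRN excitatory gain) or `mu_r` (sensory drive mean, spikes/s),
#' holding the other two fixed. Every grid point reuses the same base seed,
#' so points differ only through the swept parameter (common random
#' numbers).
#'
#' @param parameter Which axis to sweep: `"beta_a"`, `"C1"` or `"mu_r"`.
#' @param grid Strictly increasing, non-empty numeric grid.
#' @param beta_a,C1,mu_r Values held fixed when not swept. The defaults
#'   (`beta_a = 2.10`, `C1 = 35`, `mu_r = 86`) are the moderate-to-severe
#'   operating point used by the connectivity and drive experiments.
#' @param params Baseline [model_parameters()] (its `tau_i` is overwritten
#'   from `beta_a` through `cal` at every point).
#' @param cal An [abeta_calibration()].
#' @param sim_config A [simulation_config()].
#' @param spec_config A [spectral_config()]; defaults to the simulation's
#'   sampling rate.
#' @return An object of class `"sweep_result"`: list with `parameter`,
#'   `table` (one row per grid point: swept value, `tau_i_ms`, `peak_power`,
#'   `dominant_freq`, per-sub-band powers, `alpha_power`), `summaries` (the
#'   full [alpha_summary()] objects) and the fixed settings.
#' @seealso [sweep_beta()], [sweep_c1()], [sweep_mu()], [write_sweep()]
#' @export
run_sweep <- function(parameter = c("beta_a", "C1", "mu_r"), grid,
                      beta_a = 2.10, C1 = 35, mu_r = 86,
                      params = model_parameters(),
                      cal = abeta_calibration(),
                      sim_config = simulation_config(),
                      spec_config = spectral_config(fs = 1 / sim_config$dt)) {
  parameter <- match.arg(parameter)
  if (length(grid) < 1 || !all(is.finite(grid)))
    stop("`grid` must be a non-empty finite numeric vector", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly increasing", call. = FALSE)
  if (parameter == "mu_r" && (min(grid) < 0 || max(grid) > 100))
    stop("`mu_r` grid must lie within [0, 100]", call. = FALSE)
  if (parameter == "C1" && min(grid) < 0)
    stop("`C1` grid must be non-negative", call. = FALSE)
  if (mu_r < 0 || mu_r > 100)
    stop("fixed `mu_r` must lie within [0, 100]", call. = FALSE)

  rows <- vector("list", length(grid))
  summaries <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    b <- if (parameter == "beta_a") grid[i] else beta_a
    p <- params
    p$C1 <- if (parameter == "C1") grid[i] else C1
    p$mu_r <- if (parameter == "mu_r") grid[i] else mu_r
    p$tau_i <- tau_inhibitory(b, cal)
    sim <- run_repeats(p, sim_config)
    sm <- analyze_simulation(sim, spec_config)
    summaries[[i]] <- sm
    rows[[i]] <- data.frame(
      parameter = parameter, value = grid[i], beta_a = b,
      C1 = p$C1, mu_r = p$mu_r, tau_i_ms = p$tau_i,
      peak_power = sm$peak_power, dominant_freq = sm$dominant_freq,
      as.list(structure(sm$subband_powers,
                        names = paste0("power_", gsub("[-.]", "_",
                                       sub("Hz$", "", names(sm$subband_powers)))))),
      alpha_power = sm$alpha_power)
  }
  structure(list(parameter = parameter, grid = grid,
                 table = do.call(rbind, rows), summaries = summaries,
                 fixed = list(beta_a = beta_a, C1 = C1, mu_r = mu_r),
                 cal = cal, sim_config = sim_config,
                 spec_config = spec_config),
            class = "sweep_result")
}

#' Amyloid-load sweep
#'
#' Sweeps the amyloid load `beta_a` (default grid 1.4 to 5.0 in steps of
#' 0.2, the normal-to-severely-pathological range) at fixed drive and
#' connectivity, reporting the alpha-band readouts at each load. With
#' rising load the inhibitory time constant lengthens and the alpha peak
#' power and dominant frequency fall — the alpha-slowing signature.
#'
#' @param grid Amyloid-load grid, SUVR.
#' @param mu_r,C1 Fixed drive mean and connectivity.
#' @param ... Passed to [run_sweep()] (e.g. `sim_config`, `cal`).
#' @return A `"sweep_result"`.
#' @examples
#' \donttest{
#' sw <- sweep_beta(grid = c(0.001, 1.92, 2.10, 3.00),
#'                  sim_config = simulation_config(duration = 10,
#'                                                 n_repeats = 5))
#' sw$table[, c("value", "tau_i_ms", "peak_power", "dominant_freq")]
#' }
#' @export
sweep_beta <- function(grid = seq(1.4, 5.0, by = 0.2), mu_r = 86, C1 = 35,
                       ...) {
  run_sweep("beta_a", grid, mu_r = mu_r, C1 = C1, ...)
}

#' Connectivity sweep
#'
#' Sweeps the TCR-to-TRN excitatory gain `C1` (default grid 0 to 100 by 10)
#' at a fixed, moderately-to-severely pathological amyloid load. Raising
#' `C1` strengthens the excitatory afferent of the inhibitory TRN population
#' and raises the alpha peak power.
#'
#' @param grid Connectivity grid (dimensionless).
#' @param beta_a,mu_r Fixed amyloid load and drive mean.
#' @param ... Passed to [run_sweep()].
#' @return A `"sweep_result"`.
#' @export
sweep_c1 <- function(grid = seq(0, 100, by = 10), beta_a = 2.10, mu_r = 86,
                     ...) {
  run_sweep("C1", grid, beta_a = beta_a, mu_r = mu_r, ...)
}

#' Sensory-drive sweep
#'
#' Sweeps the mean `mu_r` of the Gaussian white-noise sensory drive within
#' its admissible range \[0, 100\] (default grid 0 to 100 by 10) at a fixed
#' pathological amyloid load. Stronger drive raises the alpha peak power.
#'
#' @param grid Drive-mean grid, spikes/s, within \[0, 100\].
#' @param beta_a,C1 Fixed amyloid load and connectivity.
#' @param ... Passed to [run_sweep()].
#' @return A `"sweep_result"`.
#' @export
sweep_mu <- function(grid = seq(0, 100, by = 10), beta_a = 2.10, C1 = 35,
                     ...) {
  run_sweep("mu_r", grid, beta_a = beta_a, C1 = C1, ...)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Parameter sweep over %s (%d points)\n", x$parameter,
              length(x$grid)))
  fx <- x$fixed[setdiff(names(x$fixed),
                        switch(x$parameter, beta_a = "beta_a",
                               C1 = "C1", mu_r = "mu_r"))]
  cat("  fixed: ", paste(names(fx), unlist(fx), sep = " = ",
                         collapse = ", "), "\n", sep = "")
  print(x$table[, c("value", "tau_i_ms", "peak_power", "dominant_freq",
                    "alpha_power")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, what = c("peak_power", "psd", "subbands"),
                              log = "y", ...) {
  what <- match.arg(what)
  if (what == "peak_power") {
    plot(x$table$value, x$table$peak_power, type = "b", log = log,
         xlab = x$parameter, ylab = "alpha peak power (mV^2/Hz)", ...)
  } else if (what == "psd") {
    cols <- hcl.colors(length(x$summaries), "viridis")
    fr <- x$summaries[[1]]$freq
    keep <- fr >= 1 & fr <= x$spec_config$band_high
    ps <- sapply(x$summaries, function(s) s$psd)
    plot(NA, xlim = range(fr[keep]), ylim = range(ps[keep, ]), log = log,
         xlab = "frequency (Hz)", ylab = "PSD (mV^2/Hz)", ...)
    for (i in seq_along(x$summaries))
      lines(fr[keep], ps[keep, i], col = cols[i])
    legend("topright", legend = signif(x$grid, 3), col = cols, lty = 1,
           cex = 0.7, title = x$parameter)
  } else {
    sub <- t(sapply(x$summaries, function(s) s$subband_powers))
    barplot(sub, beside = TRUE, names.arg = colnames(sub),
            legend.text = signif(x$grid, 3),
            xlab = "alpha sub-band", ylab = "integrated power (mV^2)", ...)
  }
  invisible(x)
}

#' Write a sweep result to disk
#'
#' Writes the tidy per-grid-point table as CSV plus a key-value manifest of
#' every effective parameter and seed, so a run can be reproduced from its
#' outputs alone.
#'
#' @param result A `"sweep_result"`.
#' @param out_prefix Path prefix; writes `<prefix>_sweep.csv` and
#'   `<prefix>_manifest.txt`.
#' @return Invisibly, the paths written.
#' @export
write_sweep <- function(result, out_prefix) {
  stopifnot(inherits(result, "sweep_result"))
  if (nrow(result$table) == 0)
    stop("empty sweep result; nothing written", call. = FALSE)
  csv <- paste0(out_prefix, "_sweep.csv")
  write.csv(result$table, csv, row.names = FALSE)
  sc <- result$sim_config
  pc <- result$spec_config
  man <- paste0(out_prefix, "_manifest.txt")
  write_manifest(man, c(
    parameter = result$parameter,
    grid = paste(result$grid, collapse = ","),
    unlist(result$fixed),
    unlist(result$cal[c("beta_off", "beta_max", "s_max", "s_min",
                        "r_beta", "beta0")]),
    duration = sc$duration, dt = sc$dt, transient = sc$transient,
    n_repeats = sc$n_repeats, base_seed = sc$seed,
    fs = pc$fs, band = paste(pc$band_low, pc$band_high, sep = "-"),
    alpha_band = paste(pc$alpha_low, pc$alpha_high, sep = "-"),
    filter_order = pc$filter_order, welch_segment = pc$welch_segment,
    welch_overlap = pc$welch_overlap, window = pc$window))
  invisible(c(csv, man))
}
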