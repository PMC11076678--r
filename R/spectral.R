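#' Spectral-analysis configuration
#'
#' Settings for the EEG-style post-processing chain: zero-phase Butterworth
#' band-pass, Welch power spectral density, and alpha-band summaries.
#' Defaults: order-4 Butterworth with a 1-40 Hz passband (wide enough not to
#' distort the alpha peak), 4-s Hann segments at 50% overlap (0.25 Hz
#' resolution on a 28-s post-transient record), alpha band 8-13 Hz.
#'
#' @param fs Sampling rate, Hz (the reciprocal of the simulation step).
#' @param band_low,band_high Band-pass edges, Hz.
#' @param alpha_low,alpha_high Alpha-band edges, Hz.
#' @param filter_order Butterworth prototype order.
#' @param welch_segment Welch segment length, s.
#' @param welch_overlap Fractional segment overlap in `[0, 1)`.
#' @param window Taper name; only `"hann"` is provided.
#' @return An object of class `"spectral_config"`.
#' @export
spectral_config <- function(fs = 1000, band_low = 1, band_high = 40,
                            alpha_low = 8, alpha_high = 13,
                            filter_order = 4, welch_segment = 4,
                            welch_overlap = 0.5, window = "hann") {
  if (!(band_low > 0 && band_low < band_high && band_high < fs / 2))
    stop("passband infeasible: need 0 < band_low < band_high < fs/2",
         call. = FALSE)
  if (!(alpha_low >= band_low && alpha_high <= band_high &&
          alpha_low < alpha_high))
    stop("alpha band must lie inside the passband", call. = FALSE)
  if (!(welch_overlap >= 0 && welch_overlap < 1))
    stop("`welch_overlap` must lie in [0, 1)", call. = FALSE)
  if (!(welch_segment > 0 && filter_order >= 1))
    stop("`welch_segment` and `filter_order` must be positive", call. = FALSE)
  window <- match.arg(window, "hann")
  structure(list(fs = fs, band_low = band_low, band_high = band_high,
                 alpha_low = alpha_low, alpha_high = alpha_high,
                 filter_order = filter_order, welch_segment = welch_segment,
                 welch_overlap = welch_overlap, window = window),
            class = "spectral_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs an order-`filter_order` Butterworth band-pass and applies it
#' forward and backward ([signal::filtfilt()]), so the net response has zero
#' phase and squared magnitude. Output length equals input length.
#'
#' @param trace Numeric series, mV.
#' @param cfg A [spectral_config()].
#' @return Filtered series, same length.
#' @export
bandpass <- function(trace, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  if (length(trace) <= 3 * 2 * cfg$filter_order)
    stop("trace too short for the requested filter order", call. = FALSE)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low, cfg$band_high) / (cfg$fs / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, trace))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Welch power spectral density
#'
#' Averaged-periodogram PSD estimate: the series is split into
#' `welch_segment`-second segments with fractional overlap `welch_overlap`;
#' each segment is mean-removed, Hann-tapered (periodic taper) and
#' transformed; the one-sided density is averaged across segments. The
#' frequency resolution is `1/welch_segment` Hz and the density integrates
#' (approximately) to the signal variance.
#'
#' @param trace Numeric series, mV.
#' @param cfg A [spectral_config()].
#' @return List with `freq` (Hz, `0..fs/2`) and `psd` (mV^2/Hz).
#' @export
welch_psd <- function(trace, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  n_seg <- as.integer(round(cfg$welch_segment * cfg$fs))
  if (length(trace) < n_seg)
    stop(paste("trace shorter than one Welch segment;",
               "simulate longer or reduce `welch_segment`"), call. = FALSE)
  step <- max(1L, as.integer(round(n_seg * (1 - cfg$welch_overlap))))
  starts <- seq(1L, length(trace) - n_seg + 1L, by = step)
  w <- hann_window(n_seg)
  scale <- 1 / (cfg$fs * sum(w^2))
  n_half <- n_seg %/% 2
  acc <- numeric(n_half + 1)
  for (s in starts) {
    x <- trace[s:(s + n_seg - 1)]
    x <- (x - mean(x)) * w
    X <- fft(x)[1:(n_half + 1)]
    acc <- acc + Re(X * Conj(X))
  }
  psd <- 2 * scale * acc / length(starts)
  psd[1] <- psd[1] / 2
  if (n_seg %% 2 == 0) psd[n_half + 1] <- psd[n_half + 1] / 2
  list(freq = (0:n_half) * cfg$fs / n_seg, psd = psd)
}

# trapezoidal integral of (f, p) over [a, b], linearly interpolating the
# band edges onto the grid so adjacent bands tile exactly
band_power <- function(freq, psd, a, b) {
  inside <- freq > a & freq < b
  fa <- stats::approx(freq, psd, xout = a)$y
  fb <- stats::approx(freq, psd, xout = b)$y
  f <- c(a, freq[inside], b)
  p <- c(fa, psd[inside], fb)
  sum(diff(f) * (p[-length(p)] + p[-1]) / 2)
}

#' Alpha-band summary of a power spectrum
#'
#' Extracts the study's readouts from a PSD: the maximum density within the
#' closed alpha band (`peak_power`), the frequency at which it occurs
#' (`dominant_freq`; the smallest frequency on ties), and the integrated
#' power of each 1-Hz alpha sub-band (trapezoidal, band edges interpolated
#' onto the grid so the sub-bands tile the alpha band exactly).
#'
#' @param freq Frequency grid, Hz; must cover the alpha band.
#' @param psd Power spectral density on `freq`, mV^2/Hz.
#' @param cfg A [spectral_config()].
#' @return An object of class `"spectral_summary"`: list with `freq`, `psd`,
#'   `peak_power` (mV^2/Hz), `dominant_freq` (Hz), `subband_powers` (named
#'   numeric, mV^2) and `alpha_power` (their total, mV^2).
#' @export
alpha_summary <- function(freq, psd, cfg = spectral_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  if (min(freq) > cfg$alpha_low || max(freq) < cfg$alpha_high)
    stop("frequency grid does not cover the alpha band", call. = FALSE)
  idx <- freq >= cfg$alpha_low & freq <= cfg$alpha_high
  pk <- max(psd[idx])
  fdom <- freq[idx][which.max(psd[idx])]
  edges <- seq(cfg$alpha_low, cfg$alpha_high, by = 1)
  if (edges[length(edges)] < cfg$alpha_high)
    edges <- c(edges, cfg$alpha_high)
  sub <- vapply(seq_len(length(edges) - 1), function(i)
    band_power(freq, psd, edges[i], edges[i + 1]), numeric(1))
  names(sub) <- paste0(edges[-length(edges)], "-", edges[-1], "Hz")
  structure(list(freq = freq, psd = psd, peak_power = pk,
                 dominant_freq = fdom, subband_powers = sub,
                 alpha_power = sum(sub), config = cfg),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("Alpha-band spectral summary\n")
  cat(sprintf("  peak power:      %.6g mV^2/Hz at %.4g Hz\n",
              x$peak_power, x$dominant_freq))
  cat(sprintf("  alpha power:     %.6g mV^2 over %g-%g Hz\n",
              x$alpha_power, x$config$alpha_low, x$config$alpha_high))
  cat("  sub-band powers (mV^2):\n")
  print(signif(x$subband_powers, 4))
  invisible(x)
}

#' @export
plot.spectral_summary <- function(x, log = "y", xlim = NULL, ...) {
  if (is.null(xlim)) xlim <- c(0, x$config$band_high)
  pos <- x$psd > 0 | log != "y"
  plot(x$freq[pos], x$psd[pos], type = "l", log = log, xlim = xlim,
       xlab = "frequency (Hz)", ylab = "PSD (mV^2/Hz)", ...)
  abline(v = c(x$config$alpha_low, x$config$alpha_high),
         lty = 3, col = "grey50")
  invisible(x)
}

#' Spectral analysis of a repeated simulation
#'
#' The headline analysis pipeline: each repeat's post-transient trace is
#' band-pass filtered and its Welch PSD computed; the per-repeat densities
#' are averaged across repeats; the averaged spectrum is summarized over the
#' alpha band. Averaging spectra (not traces) preserves the rhythm of
#' incoherent noise-driven oscillations.
#'
#' @param sim A [run_repeats()] result.
#' @param cfg A [spectral_config()]; its `fs` must match the simulation step
#'   (`fs = 1/dt`).
#' @param keep_repeats Keep the per-repeat PSD matrix in the result.
#' @return A `"spectral_summary"` of the repeat-averaged PSD; if
#'   `keep_repeats`, with a `psd_repeats` matrix (frequency x repeat)
#'   attached.
#' @examples
#' cfg <- simulation_config(duration = 8, n_repeats = 3, seed = 1)
#' sim <- run_repeats(model_parameters(), cfg)
#' analyze_simulation(sim)
#' @export
analyze_simulation <- function(sim, cfg = spectral_config(fs = 1 / sim$config$dt),
                               keep_repeats = FALSE) {
  stopifnot(inherits(sim, "simulation_result"))
  if (!isTRUE(all.equal(cfg$fs, 1 / sim$config$dt)))
    stop("`cfg$fs` must equal the simulation sampling rate 1/dt",
         call. = FALSE)
  psds <- apply(sim$traces, 2, function(tr)
    welch_psd(bandpass(tr, cfg), cfg)$psd)
  n_seg <- as.integer(round(cfg$welch_segment * cfg$fs))
  freq <- (0:(n_seg %/% 2)) * cfg$fs / n_seg
  out <- alpha_summary(freq, rowMeans(psds), cfg)
  if (keep_repeats) out$psd_repeats <- psds
  out
}
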