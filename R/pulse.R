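#' Design the excitation pulse
#'
#' Gaussian-modulated sinusoid whose power spectrum is 10 dB below its peak
#' exactly at the requested band edges. The center frequency is the band
#' midpoint and the Gaussian envelope standard deviation is
#' `tau = sqrt(ln 10) / (2 pi df)` with `df` the half-bandwidth, which places
#' the -10 dB points of the Gaussian spectrum at the edges. The envelope is
#' delayed by `delay_sigmas` standard deviations so the waveform starts and
#' ends far below its peak (no truncation transient).
#'
#' @param band_low,band_high Band edges (-10 dB points), Hz. Defaults give
#'   the 0.5-2 GHz acquisition band.
#' @param dt Sample interval, s.
#' @param n_steps Number of samples.
#' @param delay_sigmas Envelope delay in units of the envelope standard
#'   deviation (>= 4).
#' @param amplitude Peak source amplitude (arbitrary units).
#' @return Object of class `pulse_waveform` with fields `samples`,
#'   `center_frequency`, `spectral_width` (envelope sd in Hz terms, i.e. the
#'   half-bandwidth), `delay`, `dt`.
#' @export
design_pulse <- function(band_low = 0.5e9, band_high = 2e9,
                         dt = 4.72e-12, n_steps = 5000,
                         delay_sigmas = 4.5, amplitude = 1) {
  if (!(band_low > 0 && band_low < band_high))
    stop("require 0 < band_low < band_high", call. = FALSE)
  if (band_high >= 1 / (2 * dt))
    stop("band_high violates the Nyquist limit 1/(2 dt)", call. = FALSE)
  if (delay_sigmas < 4)
    stop("delay_sigmas must be >= 4 to avoid truncation transients",
         call. = FALSE)
  fc <- (band_low + band_high) / 2
  df <- (band_high - band_low) / 2
  tau <- sqrt(log(10)) / (2 * pi * df)
  t0 <- delay_sigmas * tau
  t <- (seq_len(n_steps) - 1) * dt
  s <- amplitude * exp(-(t - t0)^2 / (2 * tau^2)) * sin(2 * pi * fc * (t - t0))
  p <- list(samples = s, center_frequency = fc, spectral_width = df,
            tau = tau, delay = t0, dt = dt)
  class(p) <- "pulse_waveform"
  p
}

#' @export
print.pulse_waveform <- function(x, ...) {
  edges <- measure_band_edges(x)
  cat(sprintf("Gaussian-modulated pulse: fc = %.3f GHz, tau = %.1f ps, delay = %.2f ns\n",
              x$center_frequency / 1e9, x$tau * 1e12, x$delay * 1e9))
  cat(sprintf("  measured -10 dB band: %.3f-%.3f GHz over %d samples at dt = %g ps\n",
              edges[1] / 1e9, edges[2] / 1e9, length(x$samples), x$dt * 1e12))
  invisible(x)
}

#' Power spectrum of a pulse
#'
#' Zero-padded FFT power spectrum on the positive-frequency axis.
#'
#' @param pulse A `pulse_waveform` (or numeric vector with `dt` supplied).
#' @param dt Sample interval when `pulse` is a bare vector.
#' @param pad_factor Zero-padding factor for frequency resolution.
#' @return Data frame with columns `frequency` (Hz) and `power` (linear,
#'   arbitrary units).
#' @export
pulse_spectrum <- function(pulse, dt = NULL, pad_factor = 8) {
  if (inherits(pulse, "pulse_waveform")) {
    s <- pulse$samples; dt <- pulse$dt
  } else {
    s <- as.numeric(pulse)
    if (is.null(dt)) stop("dt required for a bare sample vector", call. = FALSE)
  }
  nfft <- 2^ceiling(log2(length(s) * pad_factor))
  sp <- fft(c(s, numeric(nfft - length(s))))
  half <- seq_len(nfft %/% 2)
  data.frame(frequency = (half - 1) / (nfft * dt),
             power = Mod(sp[half])^2)
}

#' Measure the -10 dB band edges of a pulse
#'
#' Locates the frequencies nearest the spectral peak at which the power
#' spectrum falls `drop_db` below its maximum, with linear interpolation
#' between frequency bins.
#'
#' @param pulse A `pulse_waveform` or numeric sample vector.
#' @param dt Sample interval for bare vectors.
#' @param drop_db Level below the peak, dB (positive).
#' @return `c(low, high)` in Hz.
#' @export
measure_band_edges <- function(pulse, dt = NULL, drop_db = 10) {
  sp <- pulse_spectrum(pulse, dt = dt)
  p_db <- 10 * log10(sp$power / max(sp$power))
  ipk <- which.max(p_db)
  cross <- function(idx) {
    # linear interpolation of the -drop_db crossing between idx and idx+1
    f1 <- sp$frequency[idx]; f2 <- sp$frequency[idx + 1]
    p1 <- p_db[idx]; p2 <- p_db[idx + 1]
    f1 + (-(drop_db) - p1) * (f2 - f1) / (p2 - p1)
  }
  below_lo <- which(p_db[seq_len(ipk - 1)] < -drop_db)
  if (length(below_lo) == 0) stop("no lower band edge found", call. = FALSE)
  lo_idx <- max(below_lo)
  above <- seq(ipk, length(p_db) - 1)
  hi_idx <- above[which(p_db[above] >= -drop_db &
                        p_db[above + 1] < -drop_db)][1]
  if (is.na(hi_idx)) stop("no upper band edge found", call. = FALSE)
  c(low = cross(lo_idx), high = cross(hi_idx))
}
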