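# Excitation waveforms, echo synthesis on the acquisition time grid, and
# echo metrics (energy, peak, interaction count, spectrum).

#' Construct a waveform on the acquisition time grid
#'
#' @param samples Amplitude samples (V-equivalent).
#' @param rate Sample rate in S/s (default 2e7).
#' @return A `us_waveform` with `samples`, `rate`, `t` (seconds) and
#'   `duration`.
#' @export
waveform <- function(samples, rate = 2e7) {
  stopifnot(all(is.finite(samples)))
  w <- list(samples = as.numeric(samples), rate = rate,
            t = (seq_along(samples) - 1) / rate,
            duration = length(samples) / rate)
  class(w) <- "us_waveform"
  w
}

#' @export
print.us_waveform <- function(x, ...) {
  cat(sprintf("<us_waveform> %d samples @ %g S/s (%.3g us), peak %.4g\n",
              length(x$samples), x$rate, x$duration * 1e6,
              max(abs(x$samples))))
  invisible(x)
}

#' Gaussian excitation pulse
#'
#' `v(t) = 10 sin(omega t) exp(-[0.2 omega (t - 8 pi^2 / omega)]^2 / 20)`
#' with `omega = 2 pi f`: a 10 V sine burst under a Gaussian envelope
#' centred at `t = 8 pi^2 / omega`.
#'
#' @param frequency Hz (nominal range 1 to 10 MHz).
#' @param rate Sample rate, S/s (default 2e7, the acquisition rate).
#' @param duration Seconds (default 100e-6, the acquisition window).
#' @return A `us_waveform`.
#' @export
gaussian_pulse <- function(frequency, rate = 2e7, duration = 100e-6) {
  if (frequency <= 0) stop("frequency must be positive")
  omega <- 2 * pi * frequency
  t <- (seq_len(floor(rate * duration)) - 1) / rate
  v <- 10 * sin(omega * t) *
    exp(-(0.2 * omega * (t - 8 * pi^2 / omega))^2 / 20)
  waveform(v, rate)
}

#' Harmonic (sinewave) excitation
#'
#' @param frequency Hz.
#' @param amplitude Peak amplitude, nominal range up to 10 V.
#' @param rate Sample rate, S/s.
#' @param duration Seconds.
#' @return A `us_waveform`.
#' @export
harmonic_excitation <- function(frequency, amplitude = 10, rate = 2e7,
                                duration = 100e-6) {
  t <- (seq_len(floor(rate * duration)) - 1) / rate
  waveform(amplitude * sin(2 * pi * frequency * t), rate)
}

#' Synthesize the received echo waveform from arrival records
#'
#' Superposition of the excitation template shifted by each record's
#' arrival time and scaled by its amplitude, under the perfect
#' electromechanical coupling assumption (pressure-to-voltage factor 1).
#' Records arriving beyond the acquisition window are dropped with a
#' warning.
#'
#' @param records Data frame with `time` (s) and `amplitude`.
#' @param template A `us_waveform` (typically the excitation pulse).
#' @param rate Sample rate of the output, S/s.
#' @param duration Output window, seconds.
#' @return A `us_waveform`.
#' @export
synthesize_echo <- function(records, template, rate = 2e7,
                            duration = 100e-6) {
  n <- floor(rate * duration)
  out <- numeric(n)
  if (nrow(records) > 0L) {
    late <- records$time > duration
    if (any(late)) {
      warning(sum(late), " record(s) beyond the ", duration * 1e6,
              " us window dropped")
      records <- records[!late, , drop = FALSE]
    }
    for (k in seq_len(nrow(records))) {
      shift <- round(records$time[k] * rate)
      m <- min(length(template$samples), n - shift)
      if (m <= 0) next
      idx <- shift + seq_len(m)
      out[idx] <- out[idx] + records$amplitude[k] * template$samples[seq_len(m)]
    }
  }
  waveform(out, rate)
}

#' Echo metrics: energy, peak, interaction count and spectrum
#'
#' Energy is the sum of squared amplitudes over the window; the
#' interaction count is the number of contributing records above the
#' supplied threshold, capped at 1200; the spectrum is the one-sided
#' magnitude of the discrete Fourier transform.
#'
#' @param w A `us_waveform`.
#' @param records Optional data frame of contributing records (`amplitude`
#'   column) used for the interaction count.
#' @param threshold Amplitude threshold for counting (default 1e-5).
#' @param cap Interaction count cap (default 1200).
#' @return List with `energy`, `peak`, `n_interactions`, `spectrum`
#'   (data frame `frequency`, `magnitude`).
#' @export
echo_metrics <- function(w, records = NULL, threshold = 1e-5, cap = 1200L) {
  x <- w$samples
  energy <- sum(abs(x)^2)
  peak <- if (length(x)) max(abs(x)) else 0
  n_int <- 0L
  if (!is.null(records) && nrow(records) > 0L) {
    n_int <- min(sum(abs(records$amplitude) >= threshold), cap)
  }
  n <- length(x)
  half <- seq_len(max(1L, floor(n / 2) + 1L))
  spec <- data.frame(frequency = (half - 1) * w$rate / n,
                     magnitude = Mod(stats::fft(x))[half])
  list(energy = energy, peak = peak, n_interactions = as.integer(n_int),
       spectrum = spec)
}

#' Write a waveform (and optionally its spectrum) as CSV
#'
#' @param w A `us_waveform`.
#' @param file Output CSV path (`time`, `amplitude`).
#' @param spectrum_file Optional path for the spectrum CSV.
#' @return Invisibly, `file`.
#' @export
write_waveform <- function(w, file, spectrum_file = NULL) {
  utils::write.csv(data.frame(time = w$t, amplitude = w$samples), file,
                   row.names = FALSE)
  if (!is.null(spectrum_file)) {
    utils::write.csv(echo_metrics(w)$spectrum, spectrum_file,
                     row.names = FALSE)
  }
  invisible(file)
}
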