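# Spectral and temporal oscillation metrics shared by the rate and spiking
# layers.

#' Welch power spectral density
#'
#' Mean-detrended, Hann-windowed, overlapping-segment averaged periodogram.
#' The density is one-sided and scaled so that the sum of `power * df`
#' approximates the signal variance (Parseval, up to the windowing factor).
#' Segments are zero-padded to four times the next power of two for a finer
#' frequency grid.
#'
#' @param x uniformly sampled numeric signal.
#' @param fs sampling rate (Hz).
#' @param segment segment length in samples; default
#'   `min(floor(length(x)/4), 4096)`.
#' @param overlap fractional overlap between segments (default 0.5).
#' @param band frequency band (Hz) summarized in the result; default the
#'   beta band `c(13, 30)`.
#' @return object of class `spectrum_result`: `freq`, `power`, `df`,
#'   `dominant_frequency` (grid argmax for `f > 0`), `dominant_power`,
#'   `prominence` (peak power over median power), `band`, `band_power`.
#' @export
welch_psd <- function(x, fs, segment = NULL, overlap = 0.5,
                      band = c(13, 30)) {
  x <- as.numeric(x)
  N <- length(x)
  if (is.null(segment)) segment <- max(min(floor(N / 4), 4096L), 16L)
  segment <- as.integer(segment)
  step <- max(1L, as.integer(round(segment * (1 - overlap))))
  starts <- if (N >= segment) seq(1L, N - segment + 1L, by = step) else integer(0)
  if (length(starts) < 2L)
    stop("signal too short for Welch estimate: need at least 2 segments of ",
         segment, " samples")
  x <- x - mean(x)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(segment) / segment))  # periodic Hann
  U <- sum(win^2)
  nfft <- 4L * 2L^ceiling(log2(segment))
  nf <- nfft %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment - 1L)]
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(c(seg, numeric(nfft - segment)))
    P <- Mod(X[seq_len(nf)])^2 / (fs * U)
    P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]
    acc <- acc + P
  }
  power <- acc / length(starts)
  freq <- (seq_len(nf) - 1L) * fs / nfft
  pos <- freq > 0
  imax <- which(pos)[which.max(power[pos])]
  structure(list(freq = freq, power = power, df = fs / nfft, fs = fs,
                 dominant_frequency = freq[imax],
                 dominant_power = power[imax],
                 prominence = power[imax] / max(stats::median(power[pos]),
                                                .Machine$double.xmin),
                 band = band,
                 band_power = .band_power_num(freq, power, fs / nfft, band)),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("spectrum: dominant %.3g Hz, band [%g, %g) Hz power %.4g\n",
              x$dominant_frequency, x$band[1], x$band[2], x$band_power))
  invisible(x)
}

.band_power_num <- function(freq, power, df, band) {
  sum(power[freq >= band[1] & freq < band[2]]) * df
}

#' Integrated power over a frequency band
#'
#' Rectangle-rule integral of the power density over the half-open band
#' `[f_lo, f_hi)`; with half-open bands the measure is exactly additive over
#' adjacent bands.
#'
#' @param spec a `spectrum_result` from [welch_psd()].
#' @param band numeric `c(f_lo, f_hi)` with `f_lo < f_hi`, inside the grid.
#' @return numeric band power.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectrum_result"))
  if (band[1] >= band[2]) stop("inverted band")
  if (band[1] < 0 || band[2] > max(spec$freq) + spec$df)
    stop("band outside the frequency grid")
  .band_power_num(spec$freq, spec$power, spec$df, band)
}

# peak-to-trough amplitude per quarter of a signal (rows = time)
.quarter_amplitudes <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  qs <- floor(seq(0, n, length.out = 5))
  vapply(1:4, function(q) {
    rows <- (qs[q] + 1):qs[q + 1]
    max(apply(x[rows, , drop = FALSE], 2, function(col) diff(range(col))))
  }, 0)
}

#' Classify a signal as sustained, transient, or non-oscillatory
#'
#' Splits the signal into quarters and measures the peak-to-trough
#' amplitude of each: `sustained` when the final quarter's amplitude is
#' above the absolute floor and at least 0.9 times the previous quarter's
#' (the envelope has stopped decaying); `transient` when an earlier quarter
#' exceeded the floor but the final quarter has decayed below it; `none`
#' otherwise. The dominant frequency (from [welch_psd()] on the second half
#' of the signal, or the first half for transients) is reported for
#' oscillatory classes only.
#'
#' @param x numeric signal (uniformly sampled).
#' @param fs sampling rate (Hz).
#' @param floor absolute amplitude floor (default 1e-3, in signal units).
#' @return list with `class` (`"none"`, `"transient"`, `"sustained"`),
#'   `frequency` (NA for `"none"`), and `amplitudes` (per quarter).
#' @export
oscillation_class <- function(x, fs, floor = 1e-3) {
  x <- as.numeric(x)
  if (length(x) < 32) stop("signal too short to classify")
  amp <- .quarter_amplitudes(x)
  half <- function(which_half) {
    n <- length(x)
    if (which_half == "late") x[(n %/% 2 + 1):n] else x[1:(n %/% 2)]
  }
  if (amp[4] > floor && amp[4] >= 0.9 * amp[3]) {
    f <- tryCatch(welch_psd(half("late"), fs)$dominant_frequency,
                  error = function(e) NA_real_)
    return(list(class = "sustained", frequency = f, amplitudes = amp))
  }
  if (max(amp[1:3]) > floor && amp[4] < floor) {
    f <- tryCatch(welch_psd(half("early"), fs)$dominant_frequency,
                  error = function(e) NA_real_)
    return(list(class = "transient", frequency = f, amplitudes = amp))
  }
  list(class = "none", frequency = NA_real_, amplitudes = amp)
}

#' Classify a threshold-linear trajectory
#'
#' Operates on whole multivariate trajectories (all nodes jointly, using the
#' worst-case node): `converged-fixed-point` when every state in the last
#' quarter stays within 1e-4 of the final state; `sustained-oscillation`
#' when the last quarter's peak-to-trough amplitude exceeds 1e-3 and is at
#' least 0.9 times the previous quarter's; `transient-oscillation` when an
#' early quarter was oscillatory (amplitude above 1e-3) but the final
#' quarter has decayed below the floor; `undetermined` otherwise (e.g. an
#' oscillation still decaying at the end of the window).
#'
#' @param traj a `tln_trajectory` from [simulate_tln()] (or a numeric
#'   matrix, rows = time).
#' @return one of `"converged-fixed-point"`, `"sustained-oscillation"`,
#'   `"transient-oscillation"`, `"undetermined"`.
#' @export
classify_trajectory <- function(traj) {
  x <- if (inherits(traj, "tln_trajectory")) traj$x else as.matrix(traj)
  if (nrow(x) < 16) stop("trajectory too short to classify")
  n <- nrow(x)
  last_q <- x[(n - n %/% 4 + 1):n, , drop = FALSE]
  dev <- max(abs(sweep(last_q, 2, x[n, ])))
  if (dev < 1e-4) return("converged-fixed-point")
  amp <- .quarter_amplitudes(x)
  if (amp[4] > 1e-3 && amp[4] >= 0.9 * amp[3]) return("sustained-oscillation")
  if (max(amp[1:3]) > 1e-3 && amp[4] < 1e-3) return("transient-oscillation")
  "undetermined"
}
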