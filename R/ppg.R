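#' Synthesize a two-channel (IR/red) photoplethysmogram
#'
#' Generates a quasi-periodic pulse train at the requested heart rate with
#' respiratory amplitude and baseline modulation, sampled at `fs` (default
#' 300 samples/s). The red channel is a scaled copy of the IR pulsatile
#' component whose AC/DC ratio-of-ratios equals the value obtained by
#' inverting the SpO2 calibration line `spo2 = 110 - 25 R`, so
#' [estimate_spo2()] round-trips the requested saturation on clean signals.
#'
#' Beat-to-beat intervals can be jittered (`ibi_jitter_sd`, fractional
#' standard deviation) to give the pulse-rate variability that RMSSD
#' estimation needs; the generated inter-beat intervals are returned in the
#' `truth` element as ground truth.
#'
#' @param hr Mean heart rate, beats/min, in `[20, 240]`.
#' @param rr Respiratory rate, breaths/min.
#' @param spo2 Oxygen saturation, percent.
#' @param duration Signal length in seconds, > 0.
#' @param noise_sd Additive white-noise standard deviation (signal units;
#'   the pulse amplitude is 0.1).
#' @param seed Optional integer seed; identical seeds give identical signals.
#' @param fs Sampling rate, samples/s.
#' @param ibi_jitter_sd Fractional SD of beat-to-beat interval jitter
#'   (0 = metronomic).
#' @return An object of class `"ppg_signal"`: list with `fs`, `t`, `ir`,
#'   `red`, `start_time`, and `truth` (the generating parameters and beat
#'   times).
#' @examples
#' sig <- synthesize_ppg(hr = 72, rr = 15, spo2 = 98, duration = 30, seed = 1)
#' beats <- detect_peaks(sig)
#' estimate_hr(beats)
#' @export
synthesize_ppg <- function(hr, rr = 15, spo2 = 98, duration = 30,
                           noise_sd = 0.002, seed = NULL, fs = 300,
                           ibi_jitter_sd = 0) {
  if (!is.finite(hr) || hr < 20 || hr > 240)
    stop("non-physical heart rate (expect 20-240 beats/min)")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(spo2) || spo2 < 70 || spo2 > 100)
    stop("non-physical SpO2 (expect 70-100%)")
  if (!is.finite(rr) || rr < 4 || rr > 60)
    stop("non-physical respiratory rate (expect 4-60 breaths/min)")
  if (!is.null(seed)) set.seed(seed)

  mean_ibi <- 60 / hr
  n_beats <- ceiling((duration + 2) / mean_ibi) + 2
  ibis <- mean_ibi * (1 + ibi_jitter_sd * stats::rnorm(n_beats))
  ibis <- pmax(ibis, 0.25)                   # refractory floor
  beat_times <- cumsum(c(mean_ibi / 2, ibis))
  beat_times <- beat_times[beat_times < duration + 1]

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  sigma <- 0.09 * mean_ibi                   # pulse width
  pulse <- numeric(n)
  for (bt in beat_times) {
    i0 <- max(1L, floor((bt - 4 * sigma) * fs) + 1L)
    i1 <- min(n, ceiling((bt + 4 * sigma) * fs) + 1L)
    if (i0 > n || i1 < 1) next
    idx <- i0:i1
    pulse[idx] <- pulse[idx] + exp(-((t[idx] - bt)^2) / (2 * sigma^2))
  }

  resp <- sin(2 * pi * (rr / 60) * t)
  ac_ir <- 0.1
  am <- 0.15                                  # respiratory AM depth
  bw <- 0.02                                  # baseline wander amplitude
  pulsatile <- bw * resp + ac_ir * (1 + am * resp) * pulse
  ratio <- (110 - spo2) / 25                  # inverse calibration line
  ir  <- 1 + pulsatile + noise_sd * stats::rnorm(n)
  red <- 1 + ratio * pulsatile + noise_sd * stats::rnorm(n)

  structure(list(fs = fs, t = t, ir = ir, red = red,
                 start_time = as.POSIXct("2024-01-08 08:00:00", tz = "UTC"),
                 truth = list(hr = hr, rr = rr, spo2 = spo2,
                              beat_times = beat_times,
                              ibis_ms = diff(beat_times) * 1000)),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("PPG signal: %.1f s at %g samples/s (IR + red channels)\n",
              length(x$ir) / x$fs, x$fs))
  invisible(x)
}

# moving-average detrend; window in samples
detrend_ma <- function(x, w) {
  k <- rep(1 / w, w)
  base <- stats::filter(x, k, sides = 2)
  base[is.na(base)] <- mean(x)
  as.numeric(x - base)
}

#' Detect pulse peaks in a PPG signal
#'
#' Removes the slow baseline with a one-second moving average, then finds
#' local maxima above an adaptive threshold (40% of the 99.5th percentile of
#' the detrended signal) separated by at least a 0.25 s refractory period.
#'
#' @param signal A [synthesize_ppg()] object (or any list with `fs` and an
#'   `ir` channel).
#' @param channel Channel to use, `"ir"` (default) or `"red"`.
#' @param refractory Minimum inter-peak interval, seconds.
#' @return An object of class `"beat_series"`: list with `peak_times`
#'   (strictly increasing, seconds), `peak_index`, `peak_height`, and `ibis`
#'   (successive differences, ms).
#' @export
detect_peaks <- function(signal, channel = c("ir", "red"), refractory = 0.25) {
  channel <- match.arg(channel)
  x <- signal[[channel]]
  fs <- signal$fs
  if (length(x) < 2 * fs) stop("insufficient data: need at least 2 s of signal")
  xd <- detrend_ma(x, round(fs))
  amp <- stats::quantile(xd, 0.995, names = FALSE)
  if (!is.finite(amp) || amp <= 1e-8 || stats::sd(xd) < 1e-9)
    stop("no beats detected: flat or empty signal")
  thr <- 0.4 * amp
  pk <- pracma::findpeaks(xd, minpeakheight = thr,
                          minpeakdistance = max(1L, round(refractory * fs)))
  if (is.null(pk) || nrow(pk) < 1) stop("no beats detected")
  ord <- order(pk[, 2])
  idx <- pk[ord, 2]
  times <- (idx - 1) / fs
  structure(list(peak_times = times, peak_index = idx,
                 peak_height = pk[ord, 1], ibis = diff(times) * 1000),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series: %d peaks over %.1f s (mean IBI %.0f ms)\n",
              length(x$peak_times), diff(range(x$peak_times)),
              mean(x$ibis)))
  invisible(x)
}

as_ibis <- function(beats) {
  if (inherits(beats, "beat_series")) beats$ibis else as.numeric(beats)
}

#' Estimate heart rate from a beat series
#'
#' `60000 / mean(IBI in ms)` over the window.
#'
#' @param beats A [detect_peaks()] result, or a numeric vector of inter-beat
#'   intervals in milliseconds.
#' @return Heart rate in beats/min.
#' @examples
#' estimate_hr(c(800, 810, 790))  # 75
#' @export
estimate_hr <- function(beats) {
  ibis <- as_ibis(beats)
  if (length(ibis) < 1)
    stop("insufficient data: need at least 2 beats to estimate heart rate")
  60000 / mean(ibis)
}

#' Pulse-rate variability as RMSSD
#'
#' Root mean square of successive inter-beat-interval differences,
#' `sqrt(mean(diff(IBI)^2))`, in ms. Invariant to adding a constant to all
#' intervals; homogeneous of degree 1 in the successive differences.
#'
#' @inheritParams estimate_hr
#' @return RMSSD in ms.
#' @examples
#' estimate_prv_rmssd(c(800, 810, 790))  # sqrt(250)
#' @export
estimate_prv_rmssd <- function(beats) {
  ibis <- as_ibis(beats)
  if (length(ibis) < 2)
    stop("insufficient data: need at least 2 inter-beat intervals for RMSSD")
  sqrt(mean(diff(ibis)^2))
}

#' Estimate respiratory rate from PPG beat-amplitude modulation
#'
#' Respiration modulates the amplitude of successive pulses. The detected
#' peak heights are interpolated onto a uniform 4 Hz grid, and the dominant
#' frequency of the mean-removed series in the respiratory band
#' (0.1-0.5 Hz) is taken, times 60. The ratio of the dominant spectral line
#' to total in-band power is attached as attribute `"confidence"`; when it
#' falls below 0.2 (no coherent modulation) the result carries
#' `attr(, "low_confidence") = TRUE`.
#'
#' @param signal A [synthesize_ppg()] object.
#' @param beats Optional [detect_peaks()] result for `signal`; detected if
#'   missing.
#' @param min_duration Minimum signal length in seconds for a stable
#'   estimate.
#' @return Respiratory rate in breaths/min, with attributes `confidence`
#'   and `low_confidence`.
#' @export
estimate_rr <- function(signal, beats = NULL, min_duration = 30) {
  dur <- length(signal$ir) / signal$fs
  if (dur < min_duration)
    stop("insufficient data: need at least ", min_duration,
         " s of signal to estimate respiratory rate")
  if (is.null(beats)) beats <- detect_peaks(signal)
  fs_i <- 4
  grid <- seq(min(beats$peak_times), max(beats$peak_times), by = 1 / fs_i)
  if (length(grid) < 16) stop("insufficient data: too few beats")
  amp <- stats::approx(beats$peak_times, beats$peak_height, xout = grid)$y
  amp <- amp - mean(amp)
  nfft <- 2^ceiling(log2(length(amp) * 4))      # zero-pad for resolution
  p <- Mod(stats::fft(c(amp, numeric(nfft - length(amp)))))^2
  freq <- (seq_len(nfft) - 1) * fs_i / nfft
  band <- freq >= 0.1 & freq <= 0.5
  pb <- p[band]; fb <- freq[band]
  conf <- max(pb) / sum(pb)
  out <- fb[which.max(pb)] * 60
  attr(out, "confidence") <- conf
  attr(out, "low_confidence") <- conf < 0.2
  out
}

#' SpO2 from a calibration line
#'
#' Maps the ratio-of-ratios `R = (AC/DC)_red / (AC/DC)_IR` through the
#' linear pulse-oximetry calibration `spo2 = intercept + slope * R`
#' (default `110 - 25 R`), clipped to `[0, 100]`.
#'
#' @param ratio Ratio-of-ratios value(s).
#' @param calibration Numeric `c(intercept, slope)`.
#' @return SpO2 in percent.
#' @examples
#' spo2_from_ratio(0.4)  # 100 (clipped)
#' spo2_from_ratio(1.0)  # 85
#' @export
spo2_from_ratio <- function(ratio, calibration = c(110, -25)) {
  pmin(100, pmax(0, calibration[1] + calibration[2] * ratio))
}

#' Estimate SpO2 from the red/IR ratio-of-ratios
#'
#' AC is measured as the standard deviation of each channel and DC as its
#' mean over the window; the ratio-of-ratios is mapped through
#' [spo2_from_ratio()].
#'
#' @param signal A two-channel [synthesize_ppg()] object.
#' @param beats Unused placeholder for API symmetry (windowing is done by
#'   the caller).
#' @param calibration Passed to [spo2_from_ratio()].
#' @return SpO2 in percent.
#' @export
estimate_spo2 <- function(signal, beats = NULL, calibration = c(110, -25)) {
  dc_ir <- mean(signal$ir); dc_red <- mean(signal$red)
  if (abs(dc_ir) < 1e-9 || abs(dc_red) < 1e-9)
    stop("invalid signal: zero DC component")
  ac_ir <- stats::sd(signal$ir); ac_red <- stats::sd(signal$red)
  if (ac_ir < 1e-9) stop("invalid signal: no pulsatile component")
  ratio <- (ac_red / dc_red) / (ac_ir / dc_ir)
  spo2_from_ratio(ratio, calibration)
}

window_signal <- function(signal, from, to) {
  i <- signal$t >= from & signal$t < to
  structure(list(fs = signal$fs, t = signal$t[i], ir = signal$ir[i],
                 red = signal$red[i], start_time = signal$start_time),
            class = "ppg_signal")
}

#' Windowed vital-sign extraction at the hardware cadence
#'
#' Runs the HR / PRV / SpO2 estimators on a sliding window (default 8 s,
#' hop 0.5 s, i.e. two estimates per second of signal, matching an embedded
#' front end that reports each parameter twice a second) and the respiratory
#' rate on a longer trailing window.
#'
#' @param signal A [synthesize_ppg()] object.
#' @param window Window length for HR/PRV/SpO2, seconds.
#' @param hop Hop between successive windows, seconds.
#' @param rr_window Trailing window for the respiratory estimate, seconds;
#'   `NA` is reported until that much signal has accumulated.
#' @return Data frame with columns `t` (window end, s), `hr`, `prv_rmssd`,
#'   `rr`, `spo2`.
#' @export
extract_vitals <- function(signal, window = 8, hop = 0.5, rr_window = 32) {
  dur <- length(signal$ir) / signal$fs
  if (dur < window) stop("insufficient data: signal shorter than one window")
  ends <- seq(window, dur, by = hop)
  rows <- lapply(ends, function(e) {
    seg <- window_signal(signal, e - window, e)
    hr <- prv <- spo2 <- rr <- NA_real_
    b <- tryCatch(detect_peaks(seg), error = function(err) NULL)
    if (!is.null(b) && length(b$ibis) >= 2) {
      hr <- estimate_hr(b)
      prv <- estimate_prv_rmssd(b)
      spo2 <- estimate_spo2(seg)
    }
    if (e >= rr_window) {
      rseg <- window_signal(signal, e - rr_window, e)
      rr <- tryCatch(as.numeric(estimate_rr(rseg, min_duration = rr_window - 1)),
                     error = function(err) NA_real_)
    }
    data.frame(t = e, hr = hr, prv_rmssd = prv, rr = rr, spo2 = spo2)
  })
  do.call(rbind, rows)
}
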