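#' Spectral analysis parameters
#'
#' Defaults give the conventional telemetry-EEG grid: 500 samples/s, a 10-s
#' epoch (5000 samples) zero-padded to an 8192-point FFT, hence frequency
#' bins of 500/8192 = 0.0610 Hz. The analysis range is 0.5-60 Hz.
#'
#' @param fs Sampling rate in samples/s.
#' @param nfft FFT length; must be at least the epoch sample count
#'   (zero-padding is applied).
#' @param window `"hann"` (default) or `"rectangular"`.
#' @param f_min,f_max Analysis range in Hz.
#' @return An object of class `"spectral_params"`.
#' @export
spectral_params <- function(fs = 500, nfft = 8192, window = c("hann", "rectangular"),
                            f_min = 0.5, f_max = 60) {
  window <- match.arg(window)
  if (fs <= 0 || nfft <= 0) stop("fs and nfft must be positive")
  if (f_min < 0 || f_max <= f_min) stop("need 0 <= f_min < f_max")
  if (f_max > fs / 2) stop("f_max exceeds the Nyquist frequency fs/2")
  structure(list(fs = fs, nfft = nfft, window = window,
                 f_min = f_min, f_max = f_max, bin_hz = fs / nfft),
            class = "spectral_params")
}

# periodic Hann window (sums cleanly over full cycles)
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' One-sided power spectrum of a single epoch
#'
#' Scaling is energy-consistent: the sum of the one-sided bin powers equals
#' the time-domain energy of the (windowed) epoch exactly (Parseval), so
#' multiplying the signal by `c` multiplies every bin by `c^2`.
#'
#' @param samples Numeric vector of EEG samples for one epoch; all finite.
#' @param params A [spectral_params()]; `nfft` must be >= `length(samples)`.
#' @return An object of class `"epoch_spectrum"`: list with `freq` (Hz, from
#'   0 to Nyquist), `power` (nonnegative, one value per bin), `bin_hz`.
#' @export
epoch_psd <- function(samples, params = spectral_params()) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("samples must be a nonempty numeric vector")
  if (any(!is.finite(samples))) {
    bad <- which(!is.finite(samples))[1]
    stop("non-finite sample at position ", bad)
  }
  n <- length(samples)
  if (params$nfft < n) stop("nfft (", params$nfft, ") < epoch length (", n, ")")
  w <- if (params$window == "hann") hann_window(n) else rep(1, n)
  x <- c(w * samples, rep(0, params$nfft - n))
  X <- stats::fft(x)
  half <- params$nfft %/% 2
  p2 <- Mod(X)^2 / params$nfft
  power <- p2[seq_len(half + 1L)]
  if (half >= 2L) power[2:half] <- 2 * power[2:half]
  structure(list(freq = (0:half) * params$bin_hz, power = power,
                 bin_hz = params$bin_hz, n_bins = half + 1L),
            class = "epoch_spectrum")
}

# epochs included for spectral analysis: all epochs of each bout of `state`
# except the first `exclusion` (transition) epochs. Returns 1-based indices.
included_epochs <- function(h, state, exclusion = 2L) {
  b <- detect_bouts(h)
  b <- b[b$state == state & b$n_epochs > exclusion, , drop = FALSE]
  if (nrow(b) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(b)), function(i) {
    (b$onset_epoch[i] + exclusion + 1L):(b$onset_epoch[i] + b$n_epochs[i])
  }))
}

epoch_samples <- function(eeg, h, epoch_1based, params) {
  spe <- round(h$epoch_s * params$fs)
  i0 <- (epoch_1based - 1L) * spe
  eeg[(i0 + 1L):(i0 + spe)]
}

#' State-conditioned mean EEG spectrum
#'
#' Averages [epoch_psd()] over all epochs of the given state, excluding the
#' first `exclusion` (transition) epochs of every bout; bouts no longer than
#' `exclusion` epochs contribute nothing. With the default `exclusion = 2`,
#' the included-epoch count satisfies `sum(pmax(0, bout_len - 2))`.
#'
#' @param eeg Numeric vector of EEG samples covering the hypnogram
#'   (`n_epochs * epoch_s * fs` samples or more).
#' @param h A [hypnogram()] aligned to `eeg` on the same epoch grid.
#' @param state `"W"`, `"N"` or `"R"`.
#' @param params A [spectral_params()].
#' @param exclusion Number of leading transition epochs excluded per bout.
#' @param epoch_mask Optional logical vector (per epoch) restricting the
#'   analysis window, e.g. to specific ZT hours.
#' @return An object of class `"state_spectrum"`: `state`, `freq`, `power`
#'   (per-bin means, `NA` when nothing is included), `n_epochs_included`,
#'   `exclusion`, `bin_hz`.
#' @export
state_spectrum <- function(eeg, h, state, params = spectral_params(),
                           exclusion = 2L, epoch_mask = NULL) {
  spe <- round(h$epoch_s * params$fs)
  if (length(eeg) < n_epochs(h) * spe)
    stop("eeg shorter than the hypnogram epoch grid")
  idx <- included_epochs(h, state, exclusion)
  if (!is.null(epoch_mask)) idx <- idx[epoch_mask[idx]]
  half <- params$nfft %/% 2
  freq <- (0:half) * params$bin_hz
  if (length(idx) == 0L) {
    warning("no included ", state, " epochs; state spectrum is missing")
    power <- rep(NA_real_, half + 1L)
  } else {
    acc <- numeric(half + 1L)
    for (e in idx) acc <- acc + epoch_psd(epoch_samples(eeg, h, e, params), params)$power
    power <- acc / length(idx)
  }
  structure(list(state = state, freq = freq, power = power,
                 n_epochs_included = length(idx), exclusion = as.integer(exclusion),
                 bin_hz = params$bin_hz),
            class = "state_spectrum")
}

#' Standard EEG frequency bands
#'
#' delta 0.5-4, theta 6-9, alpha 9-12, beta 12-30 and low gamma 30-60 Hz
#' (band membership is half-open, `[lo, hi)`, so touching edges such as
#' theta/alpha at 9 Hz are never double-counted; 4-6 Hz is unassigned).
#'
#' @return Data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "low_gamma"),
             lo_hz = c(0.5, 6, 9, 12, 30),
             hi_hz = c(4, 9, 12, 30, 60),
             stringsAsFactors = FALSE)
}

resolve_band <- function(band) {
  if (is.character(band) && length(band) == 1L) {
    tab <- default_bands()
    i <- match(band, tab$name)
    if (is.na(i)) stop("unknown band name: ", band)
    return(c(tab$lo_hz[i], tab$hi_hz[i]))
  }
  if (is.numeric(band) && length(band) == 2L && band[1] < band[2]) return(band)
  stop("band must be a band name or c(lo_hz, hi_hz) with lo < hi")
}

#' Band power of a spectrum
#'
#' Sums the bins with `lo_hz <= f < hi_hz` (half-open).
#'
#' @param spec An `"epoch_spectrum"` or `"state_spectrum"`.
#' @param band Band name (see [default_bands()]) or numeric `c(lo_hz, hi_hz)`.
#' @return Nonnegative scalar; `NA` if the spectrum is missing.
#' @export
band_power <- function(spec, band) {
  b <- resolve_band(band)
  if (all(is.na(spec$power))) return(NA_real_)
  sum(spec$power[spec$freq >= b[1] & spec$freq < b[2]])
}

#' Ratio of two band powers
#'
#' @param spec A spectrum object.
#' @param num_band,den_band Bands as in [band_power()].
#' @return `num/den`; `NA` when the denominator power is 0 or missing.
#' @export
band_ratio <- function(spec, num_band, den_band) {
  num <- band_power(spec, num_band)
  den <- band_power(spec, den_band)
  if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
  num / den
}

#' Hourly NREM delta-power (slow-wave activity) time course
#'
#' For each requested ZT hour, the mean delta-band power over the included
#' NREM epochs of that hour (transition-epoch exclusion as in
#' [state_spectrum()]). Hours without included NREM epochs are `NA`.
#'
#' @param eeg,h,params,exclusion As in [state_spectrum()].
#' @param hours Integer ZT hours (default `0:23`).
#' @param state State to condition on (default `"N"`).
#' @param band Band for the power summary (default `"delta"`).
#' @return Data frame `zt_hour`, `n_epochs`, `power`.
#' @export
nrem_delta_timecourse <- function(eeg, h, params = spectral_params(),
                                  hours = 0:23, state = "N", band = "delta",
                                  exclusion = 2L) {
  b <- resolve_band(band)
  idx <- included_epochs(h, state, exclusion)
  hr <- floor(epoch_zt_s(h) / 3600)
  out <- data.frame(zt_hour = hours, n_epochs = 0L, power = NA_real_)
  for (k in seq_along(hours)) {
    sel <- idx[hr[idx] == hours[k]]
    out$n_epochs[k] <- length(sel)
    if (length(sel)) {
      p <- vapply(sel, function(e) {
        sp <- epoch_psd(epoch_samples(eeg, h, e, params), params)
        sum(sp$power[sp$freq >= b[1] & sp$freq < b[2]])
      }, numeric(1))
      out$power[k] <- mean(p)
    }
  }
  out
}

#' Per-animal slow-wave-activity baseline
#'
#' Mean NREM delta power over the included NREM epochs of the baseline day's
#' light phase (the normalization window is configurable via `epoch_mask`).
#'
#' @param eeg,h,params,exclusion As in [state_spectrum()].
#' @param window Window over which baseline NREM epochs are taken
#'   (default `"LIGHT"`).
#' @return Scalar mean delta power (`NA` if no epochs included).
#' @export
swa_baseline <- function(eeg, h, params = spectral_params(), window = "LIGHT",
                         exclusion = 2L) {
  mask <- window_mask(h, window)
  sp <- suppressWarnings(
    state_spectrum(eeg, h, "N", params, exclusion, epoch_mask = mask))
  if (sp$n_epochs_included == 0L) return(NA_real_)
  # recompute as mean of per-epoch delta power (equals delta of mean spectrum)
  band_power(sp, "delta")
}

#' Normalize a power series to a baseline value
#'
#' @param series Numeric vector (e.g. hourly SWA).
#' @param baseline_value Positive scalar baseline power.
#' @return `100 * series / baseline_value` (percent of baseline).
#' @export
normalize_to_baseline <- function(series, baseline_value) {
  if (!is.numeric(baseline_value) || length(baseline_value) != 1L ||
      is.na(baseline_value) || baseline_value <= 0)
    stop("baseline_value must be a single positive number")
  100 * series / baseline_value
}
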