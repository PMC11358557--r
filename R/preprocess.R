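#' EEG rhythm band table
#'
#' The band edges used throughout: theta 4-7 Hz, alpha 8-15 Hz, beta
#' 16-31 Hz, gamma 32-55 Hz and the full recorded range 0-75 Hz. The delta
#' band is deliberately absent (deep-sleep activity, outside the scope of
#' emotion features).
#'
#' @param bands Optional character vector selecting a subset, in any order.
#' @return Tibble with columns `band`, `low_hz`, `high_hz`.
#' @export
default_bands <- function(bands = NULL) {
  tab <- tibble::tibble(
    band    = c("theta", "alpha", "beta", "gamma", "full"),
    low_hz  = c(4, 8, 16, 32, 0),
    high_hz = c(7, 15, 31, 55, 75)
  )
  if (is.null(bands)) return(tab)
  missing <- setdiff(bands, tab$band)
  if (length(missing) > 0) {
    abort(paste0("unknown band(s): ", paste(missing, collapse = ", ")))
  }
  tab[match(bands, tab$band), ]
}

#' Resample a trial to a lower rate
#'
#' Applies an anti-aliasing low-pass (zero-phase FIR, cutoff at the target
#' Nyquist frequency) and then samples the filtered signal on the new time
#' grid by linear interpolation, so arbitrary rate ratios are supported.
#' Upsampling is refused. When `target_rate` equals the current rate the
#' trial is returned unchanged.
#'
#' @param trial An [eeg_trial()].
#' @param target_rate Target sampling rate in Hz; must not exceed the
#'   trial's rate.
#' @return The resampled `eeg_trial`.
#' @export
resample_trial <- function(trial, target_rate) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (target_rate > trial$rate) {
    abort("target_rate exceeds the trial's rate; upsampling is not supported")
  }
  if (target_rate == trial$rate) return(trial)
  # anti-alias: low-pass with pass edge at 0.8x and stop edge at the target
  # Nyquist, applied forward-backward
  nyq_new <- target_rate / 2
  spec <- design_bandpass(
    band = "antialias", low_hz = 0, high_hz = 0.9 * nyq_new,
    rate = trial$rate, transition_hz = 0.2 * nyq_new
  )
  filtered <- apply_filter(trial, spec)$data
  n_in <- ncol(filtered)
  t_in <- (seq_len(n_in) - 1) / trial$rate
  n_out <- floor((n_in - 1) * target_rate / trial$rate) + 1
  t_out <- (seq_len(n_out) - 1) / target_rate
  out <- t(apply(filtered, 1, function(ch) approx(t_in, ch, xout = t_out)$y))
  with_data(trial, out, rate = target_rate)
}

#' Extract the central segment of a trial
#'
#' Returns the centred window of `round(duration_s * rate)` samples; the
#' start index is `floor((n - out_len) / 2)` (0-based). Used to take the
#' one-minute core out of each roughly four-minute film-clip trial.
#'
#' @param trial An [eeg_trial()].
#' @param duration_s Desired duration in seconds.
#' @return The cropped `eeg_trial`.
#' @export
crop_middle <- function(trial, duration_s) {
  stopifnot(inherits(trial, "eeg_trial"))
  out_len <- round(duration_s * trial$rate)
  n <- n_samples(trial)
  if (out_len > n) abort("trial is shorter than the requested duration")
  start0 <- floor((n - out_len) / 2) # 0-based
  with_data(trial, trial$data[, (start0 + 1):(start0 + out_len), drop = FALSE])
}

#' Design a linear-phase FIR band-pass filter
#'
#' Windowed (Hamming) FIR design. A band with `low_hz = 0` becomes a
#' low-pass. The order is chosen from the transition width
#' (`order ~ 3.3 / (transition / rate)`, rounded up to even), giving at
#' least ~40 dB stop-band attenuation 2 Hz beyond each band edge at the
#' default transition width.
#'
#' @param band Band name, or a row of [default_bands()]; when a bare name
#'   is given `low_hz`/`high_hz` are looked up in the default table.
#' @param low_hz,high_hz Band edges in Hz (overriding the lookup).
#' @param rate Sampling rate the filter is designed for.
#' @param transition_hz Transition band width in Hz (default 2).
#' @return A `filter_spec`: list with the tap sequence `coefficients`,
#'   the band, `rate` and design metadata.
#' @export
design_bandpass <- function(band, rate, low_hz = NULL, high_hz = NULL,
                            transition_hz = 2) {
  if (is.null(low_hz) || is.null(high_hz)) {
    row <- default_bands(band)
    low_hz <- row$low_hz
    high_hz <- row$high_hz
  }
  nyq <- rate / 2
  if (high_hz >= nyq) abort("high_hz must be below the Nyquist frequency")
  if (low_hz < 0 || low_hz >= high_hz) abort("band edges must satisfy 0 <= low < high")
  order <- ceiling(3.3 / (transition_hz / rate))
  if (order %% 2 == 1) order <- order + 1 # even order -> odd, symmetric taps
  if (low_hz == 0) {
    taps <- signal::fir1(order, high_hz / nyq, type = "low")
  } else {
    taps <- signal::fir1(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  structure(
    list(
      band = as.character(band), low_hz = low_hz, high_hz = high_hz,
      rate = rate, coefficients = as.numeric(taps),
      order = order, window = "hamming", transition_hz = transition_hz
    ),
    class = "filter_spec"
  )
}

#' Apply a zero-phase FIR filter to a trial
#'
#' Each channel is filtered forward and backward, so the net phase is
#' zero and window-local amplitude distributions are not smeared by group
#' delay. The two passes are carried out as a single FFT convolution with
#' the filter's zero-phase autocorrelation kernel (exactly equivalent to
#' forward-backward filtering with zero-padded edges), vectorised over
#' channels. Output length equals input length.
#'
#' @param trial An [eeg_trial()].
#' @param spec A `filter_spec` from [design_bandpass()]; its design rate
#'   must equal the trial's rate.
#' @return The filtered `eeg_trial`, with `band` set from the spec.
#' @export
apply_filter <- function(trial, spec) {
  stopifnot(inherits(trial, "eeg_trial"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(spec$rate, trial$rate))) {
    abort(sprintf(
      "filter designed for %g Hz but trial is sampled at %g Hz",
      spec$rate, trial$rate
    ))
  }
  taps <- spec$coefficients
  nt <- length(taps)
  n <- ncol(trial$data)
  # forward-backward FIR = convolution with conv(taps, rev(taps)), a
  # symmetric kernel of length 2*nt - 1 centred at index nt (zero phase)
  g <- stats::convolve(taps, taps, type = "open")
  nf <- 2^ceiling(log2(n + 2 * nt))
  gpad <- c(g, numeric(nf - length(g)))
  xpad <- rbind(t(trial$data), matrix(0, nf - n, nrow(trial$data)))
  yfull <- Re(mvfft(mvfft(xpad) * fft(gpad), inverse = TRUE)) / nf
  out <- t(yfull[nt:(nt + n - 1), , drop = FALSE])
  with_data(trial, out, band = spec$band)
}

#' Z-score normalise a trial per channel
#'
#' Standardises every channel to mean 0 and unit sample standard deviation
#' (n-1 denominator). Used to remove per-subject and per-channel amplitude
#' bias before feature extraction.
#'
#' @param trial An [eeg_trial()].
#' @return List with `trial` (the normalised `eeg_trial`) and `params`
#'   (tibble of per-channel `mean` and `sd`).
#' @export
zscore_trial <- function(trial) {
  stopifnot(inherits(trial, "eeg_trial"))
  mu <- rowMeans(trial$data)
  sdev <- apply(trial$data, 1, sd)
  if (any(sdev == 0 | !is.finite(sdev))) {
    bad <- trial$channels[sdev == 0 | !is.finite(sdev)]
    abort(paste0("constant channel(s) cannot be z-scored: ",
                 paste(bad, collapse = ", ")))
  }
  out <- (trial$data - mu) / sdev
  list(
    trial = with_data(trial, out),
    params = tibble::tibble(channel = trial$channels, mean = mu, sd = sdev)
  )
}

#' Decompose a trial into rhythm bands
#'
#' Runs the fixed preprocessing order resample -> crop -> band filter ->
#' z-score and returns one standardised trial per requested band. Resampling
#' and cropping are skipped when `target_rate`/`crop_seconds` are `NULL`
#' (recordings may already be downsampled and cropped upstream).
#'
#' @param trial An [eeg_trial()].
#' @param bands Character vector of band names (see [default_bands()]), or
#'   a data frame with columns `band`, `low_hz`, `high_hz`.
#' @param target_rate Optional rate to resample to first (default `NULL`).
#' @param crop_seconds Optional central-segment duration (default `NULL`).
#' @param transition_hz FIR transition width passed to [design_bandpass()].
#' @return Named list of z-scored `eeg_trial`s, one per band.
#' @export
extract_bands <- function(trial, bands = default_bands(),
                          target_rate = NULL, crop_seconds = NULL,
                          transition_hz = 2) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (is.character(bands)) bands <- default_bands(bands)
  if (!is.null(target_rate)) trial <- resample_trial(trial, target_rate)
  if (!is.null(crop_seconds)) trial <- crop_middle(trial, crop_seconds)
  out <- vector("list", nrow(bands))
  names(out) <- bands$band
  for (i in seq_len(nrow(bands))) {
    spec <- design_bandpass(
      band = bands$band[i], rate = trial$rate,
      low_hz = bands$low_hz[i], high_hz = bands$high_hz[i],
      transition_hz = transition_hz
    )
    out[[i]] <- zscore_trial(apply_filter(trial, spec))$trial
  }
  out
}
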