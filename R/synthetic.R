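#' Class profile for synthetic EEG generation
#'
#' Describes how one emotion class's signals are synthesised. Every
#' channel is a per-rhythm mixture of a narrowband deterministic tone
#' (low amplitude-distribution entropy) and band-limited Gaussian noise
#' (high entropy), blended by the complexity parameter `c` in `[0, 1]`:
#' `c = 0` is a pure tone, `c = 1` pure noise. A designated set of
#' carrier channels may use a different complexity, which is how a class
#' difference is planted on known channels and rhythms while the rest of
#' the scalp stays identical between classes.
#'
#' @param label Class label, `"positive"` or `"negative"`.
#' @param band_amps Named amplitudes (arbitrary units) of the rhythm
#'   components; names from [default_bands()] excluding `full`.
#' @param complexity Default tone/noise mix `c` for all channels.
#' @param carrier_complexity Mix used on the carrier channels (defaults
#'   to `complexity`, i.e. no planted difference).
#' @param carriers Channel labels that carry the class difference.
#' @param carrier_bands Rhythms on which the carrier complexity applies
#'   (default `"gamma"`); other rhythms use the default complexity
#'   everywhere.
#' @param floor_noise Broadband white-noise floor amplitude relative to
#'   the rhythm components.
#' @return A `class_profile`.
#' @export
class_profile <- function(label,
                          band_amps = c(theta = 1, alpha = 1, beta = 1, gamma = 1),
                          complexity = 0.6,
                          carrier_complexity = complexity,
                          carriers = character(0),
                          carrier_bands = "gamma",
                          floor_noise = 0.05) {
  if (complexity < 0 || complexity > 1 ||
      carrier_complexity < 0 || carrier_complexity > 1) {
    abort("complexity parameters must lie in [0, 1]")
  }
  if (any(band_amps < 0)) abort("band amplitudes must be nonnegative")
  bad <- setdiff(names(band_amps), c("theta", "alpha", "beta", "gamma"))
  if (length(bad) > 0) abort(paste0("unknown rhythm(s): ", paste(bad, collapse = ", ")))
  structure(
    list(
      label = label, band_amps = band_amps, complexity = complexity,
      carrier_complexity = carrier_complexity, carriers = carriers,
      carrier_bands = carrier_bands, floor_noise = floor_noise
    ),
    class = "class_profile"
  )
}

# band-limited unit-variance Gaussian noise, one row per channel,
# synthesised in the frequency domain (exactly band-limited)
band_noise <- function(n_channels, n, rate, low_hz, high_hz) {
  white <- matrix(stats::rnorm(n_channels * n), n, n_channels)
  freqs <- (seq_len(n) - 1) * rate / n
  freqs <- pmin(freqs, rate - freqs) # two-sided
  mask <- as.numeric(freqs >= low_hz & freqs <= high_hz)
  shaped <- Re(mvfft(mvfft(white) * mask, inverse = TRUE)) / n
  s <- apply(shaped, 2, sd)
  s[s == 0] <- 1
  t(sweep(shaped, 2, s, "/"))
}

sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483629)
}

#' Generate one synthetic EEG trial
#'
#' Synthesises a channels-by-samples trial from a [class_profile()]:
#' per rhythm, each channel is `(1 - c) * tone + c * band-limited noise`
#' (both unit variance) scaled by the rhythm amplitude, summed across
#' rhythms, plus a broadband noise floor. Tone frequencies sit near each
#' rhythm's centre with small per-channel jitter. Deterministic given the
#' seed.
#'
#' @param profile A [class_profile()].
#' @param channels Channel labels (or a channel count).
#' @param rate Sampling rate in Hz (default 200, the working rate).
#' @param duration_s Trial duration in seconds (default 60, the central
#'   one-minute segment).
#' @param seed Integer seed.
#' @param subject,session,trial Metadata for the resulting trial.
#' @param complexity_jitter Optional additive perturbation of the
#'   complexity (used for inter-subject variability).
#' @param gain Per-channel multiplicative gain (recycled).
#' @return An [eeg_trial()] labelled with the profile's class.
#' @export
generate_trial <- function(profile, channels, rate = 200, duration_s = 60,
                           seed = 1, subject = "s01", session = "1",
                           trial = "1", complexity_jitter = 0, gain = 1) {
  stopifnot(inherits(profile, "class_profile"))
  if (is.numeric(channels)) channels <- sprintf("CH%02d", seq_len(channels))
  n <- round(duration_s * rate)
  if (n < 1) abort("duration times rate must be at least one sample")
  nch <- length(channels)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  bands <- default_bands(names(profile$band_amps))
  tt <- (seq_len(n) - 1) / rate
  out <- matrix(0, nch, n)
  is_carrier <- channels %in% profile$carriers
  for (i in seq_len(nrow(bands))) {
    bname <- bands$band[i]
    amp <- profile$band_amps[[bname]]
    if (amp == 0) next
    centre <- (bands$low_hz[i] + bands$high_hz[i]) / 2
    bw <- bands$high_hz[i] - bands$low_hz[i]
    f <- centre + stats::runif(nch, -0.1, 0.1) * bw
    phase <- stats::runif(nch, 0, 2 * pi)
    tone <- sqrt(2) * sin(outer(2 * pi * f, tt) + phase) # unit variance
    noise <- band_noise(nch, n, rate, bands$low_hz[i], bands$high_hz[i])
    cc <- ifelse(is_carrier & bname %in% profile$carrier_bands,
                 profile$carrier_complexity, profile$complexity)
    cc <- pmin(1, pmax(0, cc + complexity_jitter))
    out <- out + amp * ((1 - cc) * tone + cc * noise)
  }
  out <- out + profile$floor_noise * matrix(stats::rnorm(nch * n), nch, n)
  out <- out * rep(gain, length.out = nch) * 10 # ~tens of microvolts
  eeg_trial(out, rate = rate, channels = channels, subject = subject,
            session = session, trial = trial, label = profile$label)
}

dataset_manifest <- function(positive, negative, n_subjects, trials_per_class,
                             channels, rate, duration_s, seed) {
  grid <- tidyr::expand_grid(
    subject = sprintf("s%02d", seq_len(n_subjects)),
    label = c(positive$label, negative$label),
    rep = seq_len(trials_per_class)
  )
  grid$trial <- as.character(seq_len(nrow(grid)))
  grid$session <- "1"
  grid$seed <- vapply(seq_len(nrow(grid)), function(i) sub_seed(seed, i), 1L)
  sj <- vapply(seq_len(n_subjects), function(s) {
    set.seed(sub_seed(seed, 900000 + s))
    stats::rnorm(1, 0, 0.03)
  }, numeric(1))
  grid$complexity_jitter <- sj[as.integer(sub("^s", "", grid$subject))]
  gj <- lapply(seq_len(n_subjects), function(s) {
    set.seed(sub_seed(seed, 950000 + s))
    exp(stats::rnorm(length(channels), 0, 0.1))
  })
  grid$gain <- gj[as.integer(sub("^s", "", grid$subject))]
  grid
}

manifest_trial <- function(row, profiles, channels, rate, duration_s) {
  profile <- if (row$label == profiles[[1]]$label) profiles[[1]] else profiles[[2]]
  generate_trial(
    profile, channels = channels, rate = rate, duration_s = duration_s,
    seed = row$seed, subject = row$subject, session = row$session,
    trial = row$trial, complexity_jitter = row$complexity_jitter,
    gain = row$gain[[1]]
  )
}

#' Generate a labelled synthetic dataset
#'
#' Emulates the shape of the SEED emotion recordings: `n_subjects`
#' subjects each contribute `trials_per_class` trials per class
#' (mirroring the five film clips per emotion), with per-subject gain
#' jitter and a small per-subject complexity offset as inter-subject
#' variability, all sub-seeded from the master seed so regeneration is
#' bit-identical.
#'
#' @param positive,negative [class_profile()]s for the two classes.
#' @param n_subjects Number of subjects (default 15).
#' @param trials_per_class Trials per class per subject (default 5).
#' @param channels Channel labels; default the full 62-channel montage.
#' @param rate,duration_s Sampling rate and trial duration (defaults 200
#'   Hz, 60 s).
#' @param seed Master seed.
#' @return A `synthetic_dataset`: list with `trials` (list of
#'   [eeg_trial()]) and `manifest` (generation parameters and per-trial
#'   seeds).
#' @export
generate_dataset <- function(positive, negative, n_subjects = 15,
                             trials_per_class = 5,
                             channels = load_montage()$channels,
                             rate = 200, duration_s = 60, seed = 1) {
  stopifnot(inherits(positive, "class_profile"), inherits(negative, "class_profile"))
  if (identical(positive$label, negative$label)) {
    abort("the two class profiles must use distinct labels")
  }
  if (n_subjects < 1 || trials_per_class < 1) abort("need at least one subject and trial")
  grid <- dataset_manifest(positive, negative, n_subjects, trials_per_class,
                           channels, rate, duration_s, seed)
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    manifest_trial(grid[i, ], list(positive, negative), channels, rate, duration_s)
  })
  structure(
    list(
      trials = trials,
      manifest = list(
        grid = grid[c("subject", "session", "trial", "label", "seed")],
        n_subjects = n_subjects, trials_per_class = trials_per_class,
        channels = channels, rate = rate, duration_s = duration_s, seed = seed
      )
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d trials, %d channels @ %g Hz, %g s\n",
    length(x$trials), length(x$manifest$channels),
    x$manifest$rate, x$manifest$duration_s
  ))
  invisible(x)
}

#' Canonical class-profile pairs for the packaged study conditions
#'
#' Three fixed pairs of [class_profile()]s used throughout the package's
#' experiments and examples:
#'
#' * `"gamma_discriminative"` — the classes differ only in gamma-band
#'   complexity on four bilateral temporal carrier channels (positive
#'   c = 0.9, negative c = 0.15, everything else c = 0.6): the planted
#'   structure the pipeline is expected to recover in the gamma band and
#'   on those channels, and nowhere else.
#' * `"null"` — identical generation for both classes; classification
#'   must sit at chance.
#' * `"power_only"` — the classes differ only in gamma-band amplitude
#'   (not complexity); per-channel z-scoring removes amplitude scale, so
#'   entropy features are expected to be blind to this difference. A
#'   control documenting what the features do not use.
#'
#' @param kind Which pair to return.
#' @param carriers Carrier channels for the discriminative pair (default
#'   the bilateral temporal sites FT7, FT8, T7, T8).
#' @return List with elements `positive` and `negative`.
#' @export
emotion_profiles <- function(kind = c("gamma_discriminative", "null",
                                      "power_only"),
                             carriers = c("FT7", "FT8", "T7", "T8")) {
  kind <- match.arg(kind)
  switch(kind,
    gamma_discriminative = list(
      positive = class_profile("positive", carriers = carriers,
                               complexity = 0.6, carrier_complexity = 0.9),
      negative = class_profile("negative", carriers = carriers,
                               complexity = 0.6, carrier_complexity = 0.15)
    ),
    null = list(
      positive = class_profile("positive"),
      negative = class_profile("negative")
    ),
    power_only = list(
      positive = class_profile(
        "positive", band_amps = c(theta = 1, alpha = 1, beta = 1, gamma = 1.6)
      ),
      negative = class_profile("negative")
    )
  )
}

#' Stream a synthetic dataset straight into a feature table
#'
#' Generates each trial in turn, band-decomposes it, extracts the sliding
#' Tsallis entropy features and discards the raw signal, so full-size
#' datasets (62 channels, one-minute trials) never sit in memory at once.
#' The result is identical to running [generate_dataset()],
#' [extract_bands()] and [build_feature_table()] by hand.
#'
#' @inheritParams generate_dataset
#' @param bands Band names to extract (default all five).
#' @param config An [entropy_config()]; may carry several `q` values.
#' @return Feature tibble as from [build_feature_table()].
#' @export
generate_features <- function(positive, negative, n_subjects = 15,
                              trials_per_class = 5,
                              channels = load_montage()$channels,
                              rate = 200, duration_s = 60, seed = 1,
                              bands = default_bands()$band,
                              config = entropy_config()) {
  grid <- dataset_manifest(positive, negative, n_subjects, trials_per_class,
                           channels, rate, duration_s, seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- manifest_trial(grid[i, ], list(positive, negative), channels,
                         rate, duration_s)
    banded <- extract_bands(tr, bands)
    build_feature_table(list(banded), config)
  })
  dplyr::bind_rows(rows)
}
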