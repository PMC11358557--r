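#' Entropy engine configuration
#'
#' Governs the sliding-window Tsallis feature engine: the nonextensive
#' index `q`, the window width `window` and step `step` (both in samples,
#' with `1 <= step <= window`), and the histogram bin rule. Defaults are
#' one-second windows with 50% overlap at the 200 Hz working rate and the
#' square-root bin rule `ceiling(sqrt(window))`; all three are exposed
#' because entropy estimates depend on them.
#'
#' @param q Nonextensive parameter(s), each > 0. `q = 1` selects the
#'   Shannon limit. Several values may be given; feature tables then carry
#'   a `q` column.
#' @param window Window width in samples (>= 2).
#' @param step Sliding step in samples, between 1 and `window`.
#' @param bins `"sqrt"` or a fixed integer number of histogram bins.
#' @return An `entropy_config` list.
#' @export
entropy_config <- function(q = 3, window = 200, step = window / 2,
                           bins = "sqrt") {
  if (any(q <= 0)) abort("q must be positive (use q = 1 for the Shannon limit)")
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 2) abort("window must be at least 2 samples")
  if (step < 1 || step > window) abort("step must satisfy 1 <= step <= window")
  if (!(identical(bins, "sqrt") || (is.numeric(bins) && bins >= 1))) {
    abort("bins must be \"sqrt\" or an integer >= 1")
  }
  structure(
    list(q = as.numeric(q), window = window, step = step, bins = bins),
    class = "entropy_config"
  )
}

resolve_bins <- function(bins, window) {
  if (identical(bins, "sqrt")) as.integer(ceiling(sqrt(window))) else as.integer(bins)
}

#' Amplitude distribution of a signal window
#'
#' Equal-width histogram over `[min, max]` of the window; the probability
#' of bin i is its count divided by the window length. A constant window
#' yields a single degenerate bin with probability 1. This is the discrete
#' distribution the entropy measures operate on.
#'
#' @param x Numeric vector (one window of samples), length >= 2, finite.
#' @param bins `"sqrt"` or a fixed bin count.
#' @return List with `p` (probabilities, summing to 1) and `breaks`
#'   (bin edges in amplitude units).
#' @export
amplitude_distribution <- function(x, bins = "sqrt") {
  if (length(x) < 2) abort("window must contain at least 2 samples")
  if (any(!is.finite(x))) abort("window contains non-finite samples")
  n_bins <- resolve_bins(bins, length(x))
  mn <- min(x)
  mx <- max(x)
  if (mx == mn) {
    return(list(p = 1, breaks = c(mn, mx)))
  }
  idx <- pmin(floor((x - mn) * (n_bins / (mx - mn))), n_bins - 1)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  list(
    p = counts / length(x),
    breaks = seq(mn, mx, length.out = n_bins + 1)
  )
}

check_distribution <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("probabilities must be nonnegative and sum to 1")
  }
}

#' Tsallis entropy of a discrete distribution
#'
#' The nonextensive entropy `(1 - sum(p^q)) / (q - 1)`. For independent
#' subsystems it composes pseudo-additively:
#' `E(XY) = E(X) + E(Y) + (1 - q) E(X) E(Y)`, so `q > 1` is subextensive
#' and `q < 1` superextensive. As `q -> 1` it converges to
#' [shannon_entropy()].
#'
#' @param p Probability vector (nonnegative, sums to 1). Zero-probability
#'   bins contribute nothing.
#' @param q Nonextensive parameter, > 0 and != 1.
#' @return Entropy value (dimensionless).
#' @export
tsallis_entropy <- function(p, q) {
  check_distribution(p)
  if (length(q) != 1 || q <= 0) abort("q must be a single positive number")
  if (q == 1) abort("q = 1 is the Shannon limit; use shannon_entropy()")
  (1 - sum(p[p > 0]^q)) / (q - 1)
}

#' Shannon entropy of a discrete distribution
#'
#' `-sum(p * log(p))` in nats, with `0 * log(0)` taken as 0.
#'
#' @inheritParams tsallis_entropy
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  check_distribution(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sliding-window entropy series of a single channel
#'
#' Slides a window of `config$window` samples in steps of `config$step`
#' over the signal (trailing samples that do not fill a window are
#' discarded), computes the amplitude distribution in each window, and
#' evaluates the Tsallis entropy at each configured `q` (Shannon when
#' `q = 1`). The series length is `floor((L - w) / step) + 1`.
#'
#' @param x Numeric vector, a single channel.
#' @param config An [entropy_config()].
#' @return An `entropy_series`: tibble with columns `start` (0-based
#'   window start), `q` and `entropy`, with the config attached as an
#'   attribute.
#' @export
sliding_entropy <- function(x, config = entropy_config()) {
  stopifnot(inherits(config, "entropy_config"))
  if (length(x) < config$window) {
    abort("signal shorter than one window")
  }
  n_bins <- resolve_bins(config$bins, config$window)
  mat <- .sliding_entropy_cpp(as.numeric(x), config$window, config$step,
                              n_bins, config$q)
  starts <- (seq_len(nrow(mat)) - 1L) * config$step
  out <- tibble::tibble(
    q = rep(config$q, each = nrow(mat)),
    start = rep(starts, times = length(config$q)),
    entropy = as.vector(mat)
  )
  attr(out, "config") <- config
  class(out) <- c("entropy_series", class(out))
  out
}

#' Mean and variance of an entropy series
#'
#' The summary statistics used as classification features: the mean and
#' the sample variance (n-1 denominator; 0 for a single window) of the
#' per-window entropies, per `q`.
#'
#' @param series An `entropy_series` from [sliding_entropy()], or a bare
#'   numeric vector of entropies.
#' @return Tibble with columns `q` (if available), `mean`, `variance`.
#' @export
entropy_features <- function(series) {
  if (is.numeric(series)) {
    if (length(series) == 0) abort("empty entropy series")
    v <- if (length(series) > 1) var(series) else 0
    return(tibble::tibble(mean = mean(series), variance = v))
  }
  if (nrow(series) == 0) abort("empty entropy series")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(series), .data$q),
    mean = mean(.data$entropy),
    variance = if (dplyr::n() > 1) var(.data$entropy) else 0,
    .groups = "drop"
  )
}

# features for one banded trial: named numeric row per q
trial_feature_rows <- function(banded, channels, config) {
  n_bins <- resolve_bins(config$bins, config$window)
  n_q <- length(config$q)
  cols <- character(0)
  vals <- vector("list", length(banded))
  for (bi in seq_along(banded)) {
    bt <- banded[[bi]]
    band <- names(banded)[bi]
    m <- matrix(NA_real_, n_q, 2 * length(channels))
    for (ci in seq_along(channels)) {
      ent <- .sliding_entropy_cpp(bt$data[ci, ], config$window, config$step,
                                  n_bins, config$q)
      mu <- colMeans(ent)
      vv <- if (nrow(ent) > 1) apply(ent, 2, var) else rep(0, n_q)
      m[, 2 * ci - 1] <- mu
      m[, 2 * ci] <- vv
    }
    colnames(m) <- as.vector(rbind(
      paste0(channels, "_", band, "_mean"),
      paste0(channels, "_", band, "_var")
    ))
    vals[[bi]] <- m
  }
  do.call(cbind, vals)
}

#' Build a feature table from banded trials
#'
#' Turns a set of band-decomposed trials into the table the classifier
#' consumes: one row per (subject, session, trial) and per configured `q`,
#' with a column `<channel>_<band>_<mean|var>` for every channel, band and
#' statistic.
#'
#' @param banded_trials List; each element is a named list of band-filtered
#'   [eeg_trial()]s for one trial (as produced by [extract_bands()]), all
#'   sharing the same channel set.
#' @param config An [entropy_config()].
#' @return A tibble with id columns `subject`, `session`, `trial`,
#'   `label`, `q`, followed by the numeric feature columns.
#' @export
build_feature_table <- function(banded_trials, config = entropy_config()) {
  stopifnot(inherits(config, "entropy_config"))
  if (length(banded_trials) == 0) {
    return(tibble::tibble(
      subject = character(), session = character(), trial = character(),
      label = character(), q = numeric()
    ))
  }
  ref <- banded_trials[[1]][[1]]$channels
  rows <- purrr::map(banded_trials, function(banded) {
    t1 <- banded[[1]]
    if (!identical(t1$channels, ref)) {
      abort(paste0(
        "inconsistent channel sets; trial ", t1$trial, " of subject ",
        t1$subject, " differs from the first trial"
      ))
    }
    feats <- trial_feature_rows(banded, ref, config)
    dplyr::bind_cols(
      tibble::tibble(
        subject = t1$subject, session = t1$session, trial = t1$trial,
        label = t1$label, q = config$q
      ),
      tibble::as_tibble(feats)
    )
  })
  dplyr::bind_rows(rows)
}
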