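#' Construct an EEG trial
#'
#' The unit the pipeline transforms: one trial's channels-by-samples matrix
#' together with its sampling rate, channel labels and identifying metadata.
#'
#' @param data Numeric matrix, channels in rows, samples in columns
#'   (microvolts before normalisation).
#' @param rate Sampling rate in samples per second.
#' @param channels Ordered character vector of channel labels, one per row.
#' @param subject,session,trial Identifiers (coerced to character).
#' @param label Class label, `"positive"`, `"negative"` or `NA` when
#'   unlabeled.
#' @param band Name of the rhythm this trial has been filtered to, or
#'   `"raw"` before filtering.
#' @return An `eeg_trial` object.
#' @export
eeg_trial <- function(data, rate, channels,
                      subject = NA, session = NA, trial = NA,
                      label = NA_character_, band = "raw") {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("trial data must be numeric")
  if (nrow(data) != length(channels)) {
    abort("number of data rows must equal number of channel labels")
  }
  if (ncol(data) < 1) abort("trial must contain at least one sample")
  if (rate <= 0) abort("sampling rate must be positive")
  if (!is.na(label) && !label %in% c("positive", "negative")) {
    abort("label must be 'positive', 'negative' or NA")
  }
  rownames(data) <- channels
  structure(
    list(
      data = data, rate = as.numeric(rate), channels = as.character(channels),
      subject = as.character(subject), session = as.character(session),
      trial = as.character(trial), label = label, band = band
    ),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf(
    "<eeg_trial> %d ch x %d samples @ %g Hz  subject=%s trial=%s label=%s band=%s\n",
    nrow(x$data), ncol(x$data), x$rate, x$subject, x$trial, x$label, x$band
  ))
  invisible(x)
}

n_samples <- function(trial) ncol(trial$data)

# rebuild a trial around a new data matrix, keeping metadata
with_data <- function(trial, data, rate = trial$rate, band = trial$band) {
  trial$data <- data
  trial$rate <- rate
  trial$band <- band
  rownames(trial$data) <- trial$channels
  trial
}
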