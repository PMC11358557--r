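#' Write a dataset as delimited matrices plus a JSON manifest
#'
#' Each trial becomes a tab-separated channels-by-samples matrix (no
#' header); a single `manifest.json` records the sampling rate, channel
#' order and per-trial metadata. The format round-trips losslessly
#' through [read_fixture()].
#'
#' @param dataset A `synthetic_dataset`, or a bare list of
#'   [eeg_trial()]s.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  trials <- if (inherits(dataset, "synthetic_dataset")) dataset$trials else dataset
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    file <- sprintf("trial_%04d.tsv", i)
    utils::write.table(
      tr$data, file.path(dir, file),
      sep = "\t", row.names = FALSE, col.names = FALSE
    )
    list(
      file = file, subject = tr$subject, session = tr$session,
      trial = tr$trial, label = tr$label, rate = tr$rate,
      channels = tr$channels, band = tr$band
    )
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(trials = entries), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a delimited-matrix dataset written by [write_fixture()]
#'
#' @param dir Directory containing `manifest.json` and the trial
#'   matrices (or a path to the manifest itself).
#' @return List of [eeg_trial()]s.
#' @export
read_fixture <- function(dir) {
  manifest <- if (dir.exists(dir)) file.path(dir, "manifest.json") else dir
  if (!file.exists(manifest)) abort(paste0("no manifest at ", manifest))
  raw <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  base <- dirname(manifest)
  lapply(raw$trials, function(e) {
    mat <- as.matrix(utils::read.table(file.path(base, e$file), sep = "\t"))
    dimnames(mat) <- NULL
    eeg_trial(
      mat, rate = e$rate, channels = unlist(e$channels),
      subject = e$subject, session = e$session, trial = e$trial,
      label = if (is.null(e$label)) NA_character_ else e$label,
      band = if (is.null(e$band)) "raw" else e$band
    )
  })
}

#' Read a European Data Format (EDF) recording
#'
#' Minimal reader for classic continuous EDF: parses the ASCII header and
#' per-signal subheaders, decodes the 2-byte little-endian samples and
#' rescales them to physical units with each signal's calibration
#' (`physical` range over `digital` range). Annotation channels
#' (`EDF Annotations`) are dropped. All retained signals must share one
#' sampling rate.
#'
#' @param path Path to an `.edf` file.
#' @param subject,session,trial,label Metadata attached to the resulting
#'   trial (EDF itself carries none of the experimental structure).
#' @return An [eeg_trial()].
#' @export
read_edf <- function(path, subject = NA, session = NA, trial = NA,
                     label = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_txt(8)
  hdr_txt(80) # patient id
  hdr_txt(80) # recording id
  hdr_txt(8)  # start date
  hdr_txt(8)  # start time
  n_header <- as.integer(hdr_txt(8))
  hdr_txt(44) # reserved
  n_records <- as.integer(hdr_txt(8))
  record_dur <- as.numeric(hdr_txt(8))
  ns <- as.integer(hdr_txt(4))
  if (is.na(ns) || ns < 1) abort("malformed EDF header")
  field <- function(w) vapply(seq_len(ns), function(i) hdr_txt(w), "")
  labels <- field(16)
  field(80) # transducer
  field(8)  # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80) # prefiltering
  spr <- as.integer(field(8)) # samples per record
  field(32) # reserved
  keep <- labels != "EDF Annotations"
  if (!any(keep)) abort("EDF file contains no signal channels")
  if (length(unique(spr[keep])) != 1) {
    abort("signals with mixed sampling rates are not supported")
  }
  rate <- spr[keep][1] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  data <- matrix(0, sum(keep), n_records * spr[keep][1])
  for (r in seq_len(n_records)) {
    ki <- 0
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2,
                      signed = TRUE, endian = "little")
      if (keep[s]) {
        ki <- ki + 1
        cols <- ((r - 1) * spr[s] + 1):(r * spr[s])
        data[ki, cols] <- gain[s] * vals + offset[s]
      }
    }
  }
  eeg_trial(data, rate = rate, channels = labels[keep], subject = subject,
            session = session, trial = trial, label = label)
}

#' Write a feature table to CSV with a provenance sidecar
#'
#' @param features Feature tibble from [build_feature_table()].
#' @param path Output CSV path; the entropy configuration is echoed to
#'   `<path>.json`.
#' @param config The [entropy_config()] used (optional).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, config = NULL) {
  readr::write_csv(features, path)
  if (!is.null(config)) {
    jsonlite::write_json(
      unclass(config), paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      subject = "c", session = "c", trial = "c", label = "c",
      .default = "d"
    )
  )
}
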