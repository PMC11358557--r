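#' Load a scalp montage
#'
#' Reads a montage description (channel labels, 2-D scalp positions on the
#' unit-circle convention with the nose at the top, and named region
#' partitions). The bundled default is the 62-channel extended 10-20 montage
#' used by the SEED recordings, partitioned into hemispheres, an
#' anterior/posterior split at the central electrode row, and the four
#' quadrants with the boundary rows excluded.
#'
#' @param path Path to a montage JSON file with fields `channels` (ordered
#'   labels), `positions` (label -> `[x, y]`) and `regions`
#'   (region id -> labels). Defaults to the bundled SEED montage.
#' @return A `montage` object: list with `channels` (character), `positions`
#'   (tibble with `label`, `x`, `y`) and `regions` (named list of character
#'   vectors).
#' @examples
#' m <- load_montage()
#' length(m$channels)
#' @export
load_montage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "seed_montage.json", package = "tseeg")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- as.character(raw$channels)
  if (anyDuplicated(channels)) {
    abort("montage channel labels must be unique")
  }
  pos <- tibble::tibble(
    label = names(raw$positions),
    x = vapply(raw$positions, function(p) p[[1]], numeric(1)),
    y = vapply(raw$positions, function(p) p[[2]], numeric(1))
  )
  regions <- lapply(raw$regions, as.character)
  bad <- unlist(regions)[!unlist(regions) %in% channels]
  if (length(bad) > 0) {
    abort(paste0("region labels not in montage: ", paste(unique(bad), collapse = ", ")))
  }
  structure(
    list(channels = channels, positions = pos, regions = regions),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channels), " channels, ",
      length(x$regions), " regions\n", sep = "")
  invisible(x)
}

#' Channels belonging to a scalp region
#'
#' @param montage A `montage` from [load_montage()].
#' @param region A region id; one of `names(montage$regions)` (the bundled
#'   montage defines `left_hemisphere`, `right_hemisphere`, `anterior`,
#'   `posterior` and the four quadrants).
#' @return Character vector of channel labels, in montage order.
#' @export
region_members <- function(montage, region) {
  stopifnot(inherits(montage, "montage"))
  if (length(region) != 1 || !region %in% names(montage$regions)) {
    abort(paste0(
      "unknown region '", region, "'; valid regions: ",
      paste(names(montage$regions), collapse = ", ")
    ))
  }
  members <- montage$regions[[region]]
  montage$channels[montage$channels %in% members]
}

#' Top-performing channels by classification accuracy
#'
#' Selects the best `floor(n * fraction)` channels from a per-channel result
#' table, ranked by mean accuracy with ties broken by mean F-score and then
#' alphabetically by label. With the 62-channel montage and the default
#' fraction this marks the top quarter, 15 channels.
#'
#' @param results A data frame with one row per channel and columns `unit`
#'   (channel label), `mean_accuracy` and `mean_f_score`.
#' @param fraction Proportion of channels to keep, in (0, 1].
#' @return Character vector of channel labels, best first.
#' @export
top_quartile_channels <- function(results, fraction = 0.25) {
  if (nrow(results) == 0) abort("empty result table")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  ord <- order(-results$mean_accuracy, -results$mean_f_score, results$unit)
  n_keep <- max(1L, floor(nrow(results) * fraction))
  results$unit[ord][seq_len(n_keep)]
}
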