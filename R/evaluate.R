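#' Plan a channel / rhythm / region experiment
#'
#' Describes the full analysis: which nonextensive parameters to compare
#' (default q = 2, 3, 4), which rhythms, and which analysis axes. The
#' per-channel and per-region axes classify within a single rhythm
#' (`analysis_band`, default gamma — the band the per-channel and
#' quadrant analyses concentrate on); the band axis classifies each
#' rhythm with all channels pooled.
#'
#' @param q_values Nonextensive parameters (default `c(2, 3, 4)`). Values
#'   outside that set are accepted with a warning: they are untested
#'   territory.
#' @param bands Rhythm names for the band axis.
#' @param axes Subset of `c("channel", "band", "region")`.
#' @param analysis_band The rhythm used by the channel and region axes.
#' @param split A [split_spec()].
#' @param k,metric KNN settings (defaults k = 10, Euclidean).
#' @param statistics Feature statistics to use, subset of
#'   `c("mean", "var")`; both by default.
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(q_values = c(2, 3, 4),
                            bands = default_bands()$band,
                            axes = c("channel", "band", "region"),
                            analysis_band = "gamma",
                            split = split_spec(),
                            k = 10, metric = "euclidean",
                            statistics = c("mean", "var")) {
  if (length(q_values) == 0 || length(bands) == 0 || length(axes) == 0) {
    abort("q_values, bands and axes must all be nonempty")
  }
  axes <- match.arg(axes, c("channel", "band", "region"), several.ok = TRUE)
  statistics <- match.arg(statistics, c("mean", "var"), several.ok = TRUE)
  if (any(!q_values %in% c(2, 3, 4))) {
    warn("q values outside {2, 3, 4} are untested territory")
  }
  structure(
    list(q_values = q_values, bands = bands, axes = axes,
         analysis_band = analysis_band, split = split, k = k,
         metric = metric, statistics = statistics),
    class = "experiment_plan"
  )
}

unit_columns <- function(features, channels, bands, statistics) {
  wanted <- as.vector(outer(
    channels,
    as.vector(outer(bands, statistics, paste, sep = "_")),
    paste, sep = "_"
  ))
  intersect(wanted, names(features))
}

#' Run the full channel / rhythm / region experiment
#'
#' For every combination of q, axis and experimental unit in the plan,
#' selects that unit's feature columns, runs [repeated_holdout()] and
#' records the aggregate scores. A unit contributing no feature columns
#' (e.g. an empty region) is kept as a flagged row rather than silently
#' dropped. Deterministic given the split seed.
#'
#' @param features Feature tibble from [build_feature_table()] or
#'   [generate_features()], carrying a `q` column that covers the plan's
#'   `q_values`.
#' @param plan An [experiment_plan()].
#' @param montage A [load_montage()] montage (needed for the channel and
#'   region axes).
#' @return A `ts_result` tibble: one row per (q, axis, band, unit) with
#'   mean/max accuracy and F-score, mean sensitivity/specificity,
#'   repetition count and a `flagged` column.
#' @export
run_experiment <- function(features, plan = experiment_plan(),
                           montage = load_montage()) {
  stopifnot(inherits(plan, "experiment_plan"))
  missing_q <- setdiff(plan$q_values, unique(features$q))
  if (length(missing_q) > 0) {
    abort(paste0("feature table lacks q = ", paste(missing_q, collapse = ", ")))
  }
  units <- list()
  if ("channel" %in% plan$axes) {
    units <- c(units, lapply(montage$channels, function(ch) {
      list(axis = "channel", band = plan$analysis_band, unit = ch, channels = ch)
    }))
  }
  if ("band" %in% plan$axes) {
    units <- c(units, lapply(plan$bands, function(b) {
      list(axis = "band", band = b, unit = b, channels = montage$channels)
    }))
  }
  if ("region" %in% plan$axes) {
    units <- c(units, lapply(names(montage$regions), function(r) {
      list(axis = "region", band = plan$analysis_band, unit = r,
           channels = region_members(montage, r))
    }))
  }
  rows <- list()
  for (qv in plan$q_values) {
    fq <- features[features$q == qv, , drop = FALSE]
    for (u in units) {
      cols <- unit_columns(fq, u$channels, u$band, plan$statistics)
      if (length(cols) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          q = qv, axis = u$axis, band = u$band, unit = u$unit,
          mean_accuracy = NA_real_, max_accuracy = NA_real_,
          mean_f_score = NA_real_, max_f_score = NA_real_,
          mean_sensitivity = NA_real_, mean_specificity = NA_real_,
          n_reps = 0L, flagged = TRUE
        )
        next
      }
      sub <- fq[c("subject", "session", "trial", "label", cols)]
      ev <- repeated_holdout(sub, spec = plan$split, k = plan$k,
                             metric = plan$metric)
      rows[[length(rows) + 1]] <- tibble::tibble(
        q = qv, axis = u$axis, band = u$band, unit = u$unit,
        mean_accuracy = ev$mean_accuracy, max_accuracy = ev$max_accuracy,
        mean_f_score = ev$mean_f_score, max_f_score = ev$max_f_score,
        mean_sensitivity = ev$mean_sensitivity,
        mean_specificity = ev$mean_specificity,
        n_reps = nrow(ev$scores), flagged = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ts_result", class(out))
  out
}

#' Rank experimental units by classification performance
#'
#' Orders one (q, band, axis) stratum of a result table by descending
#' mean accuracy, ties broken by mean F-score and then unit label.
#'
#' @param table A `ts_result` from [run_experiment()].
#' @param q,band The stratum to rank.
#' @param axis Axis to rank within (default `"channel"`).
#' @return The stratum's rows, best first.
#' @export
rank_units <- function(table, q, band, axis = "channel") {
  sub <- table[table$q == q & table$band == band & table$axis == axis, ,
               drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("no rows for q = %s, band = %s, axis = %s", q, band, axis))
  }
  sub[order(-sub$mean_accuracy, -sub$mean_f_score, sub$unit), , drop = FALSE]
}

#' Channels performing well at every q
#'
#' Intersects the top-quartile channel sets across all q values in a
#' result table — the electrode positions that consistently separate the
#' classes regardless of the nonextensive parameter.
#'
#' @param table A `ts_result` with channel-axis rows (or a list of such
#'   tables, one per q).
#' @param fraction Top fraction per q (default 0.25).
#' @param band Band of the channel axis (default the table's own).
#' @return Character vector of channel labels.
#' @export
consensus_channels <- function(table, fraction = 0.25, band = NULL) {
  if (is.list(table) && !is.data.frame(table)) {
    table <- dplyr::bind_rows(table)
  }
  chan <- table[table$axis == "channel", , drop = FALSE]
  if (!is.null(band)) chan <- chan[chan$band == band, , drop = FALSE]
  if (nrow(chan) == 0) abort("no channel-axis rows to intersect")
  qs <- unique(chan$q)
  sets <- lapply(qs, function(qv) {
    top_quartile_channels(chan[chan$q == qv, , drop = FALSE], fraction)
  })
  Reduce(intersect, sets)
}

#' Export a scalp topology document
#'
#' Produces a plotting-ready table of every montage channel with its 2-D
#' scalp position and a `marked` flag for the selected set (e.g. the
#' consensus electrodes).
#'
#' @param selected Channel labels to mark; must all belong to the
#'   montage.
#' @param montage A [load_montage()] montage.
#' @param path Optional JSON output path.
#' @return Tibble with `label`, `x`, `y`, `marked` (class
#'   `ts_topology`).
#' @export
export_topology <- function(selected, montage = load_montage(), path = NULL) {
  unknown <- setdiff(selected, montage$channels)
  if (length(unknown) > 0) {
    abort(paste0("labels not in montage: ", paste(unknown, collapse = ", ")))
  }
  out <- montage$positions
  out$marked <- out$label %in% selected
  class(out) <- c("ts_topology", class(out))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  out
}
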