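# a small montage and a hand-built feature table keep these tests fast:
# run_experiment only needs labelled rows and <channel>_<band>_<stat> columns
toy_montage <- function(channels = c("A1", "A2", "B1", "B2")) {
  structure(
    list(
      channels = channels,
      positions = tibble::tibble(label = channels,
                                 x = seq(-1, 1, length.out = length(channels)),
                                 y = 0),
      regions = list(front = channels[1:2], back = channels[3:4],
                     nothing = character(0))
    ),
    class = "montage"
  )
}

# signal planted in `informative` channels of the gamma band only
toy_experiment_features <- function(informative = c("A1", "A2"),
                                    channels = c("A1", "A2", "B1", "B2"),
                                    n_per_class = 20, q_values = 3, seed = 1,
                                    sep = 4) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("positive", "negative"), each = n_per_class)
  base <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:4), length.out = n),
    session = "1", trial = as.character(seq_len(n)), label = lab
  )
  purrr::map_dfr(q_values, function(qv) {
    out <- base
    out$q <- qv
    for (ch in channels) {
      for (band in c("gamma", "theta")) {
        shift <- if (ch %in% informative && band == "gamma") {
          ifelse(lab == "positive", sep, 0)
        } else 0
        out[[paste0(ch, "_", band, "_mean")]] <- rnorm(n) + shift
        out[[paste0(ch, "_", band, "_var")]] <- abs(rnorm(n))
      }
    }
    out
  })
}

test_that("experiments produce one row per q, axis and unit", {
  feats <- toy_experiment_features(q_values = c(2, 3))
  plan <- experiment_plan(q_values = c(2, 3), bands = c("gamma", "theta"),
                          axes = c("channel", "band", "region"),
                          split = split_spec(repetitions = 3, seed = 1), k = 3)
  res <- run_experiment(feats, plan, toy_montage())
  expect_equal(nrow(res), 2 * (4 + 2 + 3))
  expect_setequal(unique(res$axis), c("channel", "band", "region"))
  expect_true(all(res$mean_accuracy[!res$flagged] >= 0 &
                    res$mean_accuracy[!res$flagged] <= 1))
  # empty region flagged, not dropped
  empty_row <- res[res$unit == "nothing", ]
  expect_equal(nrow(empty_row), 2)
  expect_true(all(empty_row$flagged))
  # determinism
  res2 <- run_experiment(feats, plan, toy_montage())
  expect_identical(as.data.frame(res), as.data.frame(res2))
  expect_error(run_experiment(feats[feats$q == 2, ], plan, toy_montage()),
               "q = 3")
})

test_that("informative channels rank at the top and form the consensus", {
  feats <- toy_experiment_features(informative = c("A1", "A2", "B1"),
                                   q_values = c(2, 3, 4), sep = 6)
  plan <- experiment_plan(q_values = c(2, 3, 4), bands = "gamma",
                          axes = "channel",
                          split = split_spec(repetitions = 5, seed = 2), k = 3)
  res <- run_experiment(feats, plan, toy_montage())
  for (qv in c(2, 3, 4)) {
    ranked <- rank_units(res, qv, "gamma")
    expect_setequal(ranked$unit[1:3], c("A1", "A2", "B1"))
  }
  cons <- consensus_channels(res, fraction = 0.75)
  expect_setequal(cons, c("A1", "A2", "B1"))
  # identical rankings across q give the full quartile set; ordering of
  # ranked rows is strict on distinct accuracies
  expect_error(rank_units(res, 5, "gamma"), "no rows")
  expect_error(consensus_channels(res[res$axis == "band", ]), "channel-axis")
})

test_that("tie-breaking in ranking uses F-score then unit label", {
  tab <- tibble::tibble(
    q = 3, axis = "channel", band = "gamma",
    unit = c("C2", "C1", "C3"),
    mean_accuracy = c(0.8, 0.8, 0.9),
    mean_f_score = c(0.7, 0.75, 0.5),
    flagged = FALSE
  )
  class(tab) <- c("ts_result", class(tab))
  ranked <- rank_units(tab, 3, "gamma")
  expect_equal(ranked$unit, c("C3", "C1", "C2"))
})

test_that("per-channel rows are unaffected by adding a pure-noise channel", {
  feats <- toy_experiment_features(channels = c("A1", "A2", "B1", "B2"))
  plan <- experiment_plan(q_values = 3, bands = "gamma", axes = "channel",
                          split = split_spec(repetitions = 4, seed = 9), k = 3)
  res4 <- run_experiment(feats, plan, toy_montage())
  set.seed(77)
  feats$Z9_gamma_mean <- rnorm(nrow(feats))
  feats$Z9_gamma_var <- abs(rnorm(nrow(feats)))
  res5 <- run_experiment(feats, plan, toy_montage(c("A1", "A2", "B1", "B2", "Z9")))
  for (ch in c("A1", "A2", "B1", "B2")) {
    expect_identical(as.data.frame(res4[res4$unit == ch, ]),
                     as.data.frame(res5[res5$unit == ch, ]))
  }
})

test_that("experiment tables are invariant to trial input order", {
  feats <- toy_experiment_features()
  plan <- experiment_plan(q_values = 3, bands = "gamma",
                          axes = c("channel", "band"),
                          split = split_spec(repetitions = 4, seed = 5), k = 3)
  r1 <- run_experiment(feats, plan, toy_montage())
  set.seed(1)
  r2 <- run_experiment(feats[sample(nrow(feats)), ], plan, toy_montage())
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("topology export marks exactly the selected montage labels", {
  m <- load_montage()
  consensus_named <- c("FT7", "FT8", "T7", "C5", "C6", "T8", "TP7", "CP5",
                       "TP8", "P7", "P8")
  topo <- export_topology(consensus_named, m)
  expect_equal(nrow(topo), 62)
  expect_equal(sum(topo$marked), 11)
  expect_setequal(topo$label[topo$marked], consensus_named)
  one <- export_topology("FT7", m)
  expect_equal(one$x[one$marked], m$positions$x[m$positions$label == "FT7"])
  expect_equal(sum(export_topology(character(0), m)$marked), 0)
  expect_error(export_topology("XX9", m), "XX9")
  # JSON round-trips
  path <- withr::local_tempfile(fileext = ".json")
  export_topology("FT7", m, path = path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sum(back$marked), 1)
})
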