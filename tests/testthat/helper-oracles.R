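# Independent oracles, written naively on purpose: they recompute results
# from first principles and must not share code paths with the package
# internals they check.

# sliding-window entropy, recomputing every window from scratch through the
# scalar R entropy functions (the compiled kernel never runs here)
naive_sliding_entropy <- function(x, w, delta, bins, q) {
  starts <- seq(0, length(x) - w, by = delta)
  vapply(starts, function(s) {
    win <- x[(s + 1):(s + w)]
    p <- amplitude_distribution(win, bins)$p
    if (q == 1) shannon_entropy(p) else tsallis_entropy(p, q)
  }, numeric(1))
}

# brute-force KNN: all-pairs scalar distances, explicit sort, the documented
# tie-breaks applied literally
naive_knn <- function(train_x, train_y, query, k) {
  d <- vapply(seq_len(nrow(train_x)), function(j) {
    sqrt(sum((query - train_x[j, ])^2))
  }, numeric(1))
  nn <- order(d)[seq_len(k)] # order() is stable: distance ties -> row order
  votes <- table(train_y[nn])
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) == 1) winners else train_y[nn[1]]
}

# 99% normal-approximation binomial interval around 0.5; n is the number of
# independent units (distinct trials), since holdout repetitions reuse them
chance_interval <- function(n, level = 0.99) {
  half <- stats::qnorm(1 - (1 - level) / 2) * sqrt(0.25 / n)
  c(0.5 - half, 0.5 + half)
}

random_distribution <- function(n_bins) {
  p <- stats::runif(n_bins)
  p / sum(p)
}

# small labelled feature table with planted separation in given columns
toy_feature_table <- function(n_per_class = 20, d = 4, sep = 3, seed = 1,
                              subjects = 4) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(stats::rnorm(n * d), n, d)
  lab <- rep(c("positive", "negative"), each = n_per_class)
  x[lab == "positive", 1] <- x[lab == "positive", 1] + sep
  colnames(x) <- paste0("f", seq_len(d))
  tibble::tibble(
    subject = rep(sprintf("s%02d", seq_len(subjects)), length.out = n),
    session = "1",
    trial = as.character(seq_len(n)),
    label = lab
  ) |> dplyr::bind_cols(tibble::as_tibble(x))
}

# tiny synthetic banded trial set for feature-table tests
tiny_banded_trials <- function(n_trials = 3, n_channels = 4, seed = 5,
                               bands = c("gamma", "theta"),
                               duration_s = 5) {
  prof <- class_profile("positive")
  lapply(seq_len(n_trials), function(i) {
    tr <- generate_trial(prof, channels = n_channels, rate = 200,
                         duration_s = duration_s, seed = seed + i,
                         subject = sprintf("s%02d", i), trial = as.character(i))
    extract_bands(tr, bands)
  })
}
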