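#' Euclidean distance between two feature vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) abort("feature vectors differ in length")
  sqrt(sum((x - y)^2))
}

# pairwise distances between rows of query (m x d) and train (n x d).
# Names follow the conventional KNN distance menu.
distance_matrix <- function(query, train, metric = "euclidean",
                            train_stats = NULL) {
  metric <- match.arg(metric, c(
    "euclidean", "cityblock", "chebyshev", "minkowski", "cosine",
    "correlation", "hamming", "jaccard", "seuclidean", "spearman",
    "mahalanobis"
  ))
  q <- as.matrix(query)
  tr <- as.matrix(train)
  d <- ncol(tr)
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(q^2), rowSums(tr^2), "+") - 2 * tcrossprod(q, tr)
      sqrt(pmax(d2, 0))
    },
    seuclidean = {
      s <- if (is.null(train_stats)) apply(tr, 2, sd) else train_stats
      s[s == 0] <- 1
      qs <- sweep(q, 2, s, "/")
      ts <- sweep(tr, 2, s, "/")
      d2 <- outer(rowSums(qs^2), rowSums(ts^2), "+") - 2 * tcrossprod(qs, ts)
      sqrt(pmax(d2, 0))
    },
    cityblock = rowwise_dist(q, tr, function(a, b) sum(abs(a - b))),
    chebyshev = rowwise_dist(q, tr, function(a, b) max(abs(a - b))),
    minkowski = rowwise_dist(q, tr, function(a, b) sum(abs(a - b)^3)^(1 / 3)),
    hamming = rowwise_dist(q, tr, function(a, b) mean(a != b)),
    jaccard = rowwise_dist(q, tr, function(a, b) {
      nz <- (a != 0) | (b != 0)
      if (!any(nz)) 0 else sum(a[nz] != b[nz]) / sum(nz)
    }),
    cosine = {
      qn <- q / pmax(sqrt(rowSums(q^2)), .Machine$double.eps)
      tn <- tr / pmax(sqrt(rowSums(tr^2)), .Machine$double.eps)
      1 - tcrossprod(qn, tn)
    },
    correlation = {
      qc <- q - rowMeans(q)
      tc <- tr - rowMeans(tr)
      qn <- qc / pmax(sqrt(rowSums(qc^2)), .Machine$double.eps)
      tn <- tc / pmax(sqrt(rowSums(tc^2)), .Machine$double.eps)
      1 - tcrossprod(qn, tn)
    },
    spearman = {
      qr <- t(apply(q, 1, rank))
      tre <- t(apply(tr, 1, rank))
      if (d == 1) { qr <- matrix(qr, ncol = 1); tre <- matrix(tre, ncol = 1) }
      qc <- qr - rowMeans(qr)
      tc <- tre - rowMeans(tre)
      qn <- qc / pmax(sqrt(rowSums(qc^2)), .Machine$double.eps)
      tn <- tc / pmax(sqrt(rowSums(tc^2)), .Machine$double.eps)
      1 - tcrossprod(qn, tn)
    },
    mahalanobis = {
      cv <- stats::cov(tr)
      # ridge degenerate covariances so the metric stays defined
      diag(cv) <- diag(cv) + 1e-8 * max(diag(cv), 1)
      ci <- solve(cv)
      rowwise_dist(q, tr, function(a, b) {
        v <- a - b
        sqrt(drop(v %*% ci %*% v))
      })
    }
  )
}

rowwise_dist <- function(q, tr, f) {
  out <- matrix(0, nrow(q), nrow(tr))
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(tr))) out[i, j] <- f(q[i, ], tr[j, ])
  }
  out
}

#' Fit a k-nearest-neighbour model
#'
#' A lazy learner: stores the training rows and labels. Prediction takes
#' the majority label among the `k` nearest training rows; a majority tie
#' is broken by the label of the single nearest neighbour, and neighbours
#' at exactly equal distance are taken in training-row order, so
#' prediction is fully deterministic.
#'
#' @param features Numeric matrix or data frame of training rows.
#' @param labels Vector of class labels, one per row.
#' @param k Number of neighbours (default 10, must not exceed the number
#'   of training rows).
#' @param metric Distance name; one of euclidean, cityblock, chebyshev,
#'   minkowski (p = 3), cosine, correlation, spearman, hamming, jaccard,
#'   seuclidean, mahalanobis.
#' @return A `knn_model`.
#' @export
knn_fit <- function(features, labels, k = 10, metric = "euclidean") {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) abort("one label per training row required")
  if (k < 1 || k > nrow(features)) abort("k must be between 1 and the number of training rows")
  structure(
    list(features = features, labels = as.character(labels),
         k = as.integer(k), metric = metric),
    class = "knn_model"
  )
}

#' Predict classes with a fitted KNN model
#'
#' @param object A `knn_model` from [knn_fit()].
#' @param newdata Numeric matrix or data frame of query rows (same number
#'   of columns as the training features).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$features)) {
    abort("query feature count does not match the training features")
  }
  dm <- distance_matrix(newdata, object$features, object$metric)
  apply(dm, 1, function(dr) {
    # stable order: equal distances resolved by training-row index
    nn <- order(dr)[seq_len(object$k)]
    votes <- table(object$labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else object$labels[nn[1]]
  })
}

#' Repeated stratified holdout specification
#'
#' @param fraction Test fraction in (0, 1); default 0.2 (80% train / 20%
#'   test).
#' @param repetitions Number of independent splits to average over
#'   (default 10).
#' @param seed Master seed; repetition `r` uses sub-seed `seed + r`.
#' @param stratify Columns defining strata; default `c("label",
#'   "subject")` so every subject contributes to both sets with a roughly
#'   constant class percentage. Use `"label"` for pure class
#'   stratification.
#' @return A `split_spec`.
#' @export
split_spec <- function(fraction = 0.2, repetitions = 10, seed = 1,
                       stratify = c("label", "subject")) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  if (repetitions < 1) abort("repetitions must be >= 1")
  structure(
    list(fraction = fraction, repetitions = as.integer(repetitions),
         seed = as.integer(seed), stratify = stratify),
    class = "split_spec"
  )
}

#' Split a feature table into train and test sets
#'
#' Samples approximately `spec$fraction` of the rows of every stratum into
#' the test set (rounded to nearest, at least one test row per stratum);
#' the rest train. Deterministic given `(spec$seed, repetition)`.
#'
#' @param table Feature tibble with the stratification columns present.
#' @param spec A [split_spec()].
#' @param repetition Repetition index (1-based), which selects the
#'   sub-seed.
#' @return List with `train` and `test` tibbles.
#' @export
holdout_split <- function(table, spec, repetition = 1) {
  stopifnot(inherits(spec, "split_spec"))
  if (nrow(table) == 0) abort("empty feature table")
  keys <- do.call(paste, c(table[spec$stratify], sep = "\r"))
  # canonical row order (stratum, then trial identity) so the split is
  # invariant to the input order of the rows
  idcols <- intersect(c("subject", "session", "trial"), names(table))
  within_key <- if (length(idcols) > 0) {
    do.call(paste, c(table[idcols], sep = "\r"))
  } else {
    seq_len(nrow(table))
  }
  canon <- order(keys, within_key)
  table <- table[canon, , drop = FALSE]
  keys <- keys[canon]
  strata <- split(seq_len(nrow(table)), keys)
  small <- names(strata)[lengths(strata) < 2]
  if (length(small) > 0) {
    abort(paste0("stratum too small to split: ", gsub("\r", "/", small[1])))
  }
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed((spec$seed + repetition) %% .Machine$integer.max)
  test_idx <- unlist(lapply(strata, function(idx) {
    n_test <- max(1L, round(length(idx) * spec$fraction))
    n_test <- min(n_test, length(idx) - 1L)
    sample(idx, n_test)
  }), use.names = FALSE)
  list(
    train = table[-test_idx, , drop = FALSE],
    test = table[sort(test_idx), , drop = FALSE]
  )
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject", "session", "trial", "label", "q"))
}

#' Train on one split and tally the confusion matrix
#'
#' Fits KNN on the training rows and predicts every test row; counts are
#' tallied with `"positive"` as the positive class by default.
#'
#' @param train,test Feature tibbles with a `label` column and numeric
#'   feature columns (all non-id columns are used).
#' @param k,metric Passed to [knn_fit()].
#' @param positive_class Label counted as positive (default
#'   `"positive"`).
#' @return A `confusion_matrix` (see [confusion()]).
#' @export
evaluate_once <- function(train, test, k = 10, metric = "euclidean",
                          positive_class = "positive") {
  cols <- feature_columns(train)
  model <- knn_fit(train[cols], train$label, k = k, metric = metric)
  pred <- predict(model, test[cols])
  confusion(test$label, pred, positive_class = positive_class)
}

#' Repeated stratified holdout evaluation
#'
#' Runs [evaluate_once()] for each repetition of the split specification
#' (repetition `r` uses sub-seed `seed + r`) and aggregates the resulting
#' confusion matrices into mean and maximum accuracy and F-score (plus
#' mean sensitivity and specificity).
#'
#' @inheritParams evaluate_once
#' @param table Feature tibble for one experimental unit.
#' @param spec A [split_spec()].
#' @return An `eeg_eval` object; see [summarize_evaluations()], [tidy()]
#'   and [glance()].
#' @export
repeated_holdout <- function(table, spec = split_spec(), k = 10,
                             metric = "euclidean",
                             positive_class = "positive") {
  cms <- lapply(seq_len(spec$repetitions), function(r) {
    parts <- holdout_split(table, spec, repetition = r)
    evaluate_once(parts$train, parts$test, k = k, metric = metric,
                  positive_class = positive_class)
  })
  summarize_evaluations(cms, spec = spec, k = k, metric = metric)
}
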