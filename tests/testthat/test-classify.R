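test_that("euclidean distance follows the root-sum-of-squares definition", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 6, 3)), 5)
  expect_error(euclidean_distance(1:2, 1:3), "length")
})

test_that("KNN predicts by majority with documented tie-breaks", {
  m1 <- knn_fit(matrix(c(0, 10), ncol = 1), c("A", "B"), k = 1)
  expect_equal(predict(m1, matrix(1)), "A")
  m3 <- knn_fit(matrix(c(0, 1, 10, 11), ncol = 1), c("A", "A", "B", "B"), k = 3)
  expect_equal(predict(m3, matrix(0.5)), "A")
  # query on a training point
  expect_equal(predict(m1, matrix(10)), "B")
  # even k, 1-1 majority tie -> label of the single nearest neighbour
  m2 <- knn_fit(matrix(c(0, 3), ncol = 1), c("A", "B"), k = 2)
  expect_equal(predict(m2, matrix(1)), "A")
  expect_equal(predict(m2, matrix(2.5)), "B")
  # equal distances -> training-row order decides the nearest
  meq <- knn_fit(matrix(c(-1, 1), ncol = 1), c("B", "A"), k = 1)
  expect_equal(predict(meq, matrix(0)), "B")
  expect_error(knn_fit(matrix(1:4, 2), c("A", "B"), k = 5), "k must be")
})

test_that("predictions match the brute-force distance sort on random tables", {
  set.seed(23)
  for (i in 1:12) {
    n <- sample(30:120, 1)
    d <- sample(2:20, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(c("positive", "negative"), n, replace = TRUE)
    q <- matrix(rnorm(15 * d), 15, d)
    for (k in c(1, 3, 10)) {
      model <- knn_fit(x, y, k = k)
      fast <- predict(model, q)
      slow <- vapply(seq_len(nrow(q)), function(j) naive_knn(x, y, q[j, ], k),
                     character(1))
      expect_identical(fast, slow)
    }
  }
})

test_that("prediction is invariant to training-row permutation away from ties", {
  set.seed(4)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- sample(c("positive", "negative"), 40, replace = TRUE)
  q <- matrix(rnorm(10 * 3), 10, 3)
  p1 <- predict(knn_fit(x, y, k = 3), q)
  perm <- sample(40)
  p2 <- predict(knn_fit(x[perm, ], y[perm], k = 3), q)
  expect_identical(p1, p2)
})

test_that("alternative metrics plug into the same evaluation plumbing", {
  set.seed(6)
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(c("positive", "negative"), 15)
  q <- matrix(rnorm(5 * 4), 5, 4)
  for (metric in c("cityblock", "chebyshev", "cosine", "correlation",
                   "minkowski", "seuclidean", "spearman", "mahalanobis",
                   "hamming", "jaccard")) {
    p <- predict(knn_fit(x, y, k = 3, metric = metric), q)
    expect_length(p, 5)
    expect_true(all(p %in% y))
  }
  # spot-check definitions against naive formulas
  dm <- tseeg:::distance_matrix(matrix(c(1, 2), 1), matrix(c(4, 6), 1), "cityblock")
  expect_equal(dm[1, 1], 7)
  dm <- tseeg:::distance_matrix(matrix(c(1, 2), 1), matrix(c(4, 6), 1), "chebyshev")
  expect_equal(dm[1, 1], 4)
  dm <- tseeg:::distance_matrix(matrix(c(1, 0), 1), matrix(c(0, 1), 1), "cosine")
  expect_equal(dm[1, 1], 1)
})

test_that("stratified holdout keeps per-stratum class fractions", {
  tab <- toy_feature_table(n_per_class = 50, subjects = 5)
  spec <- split_spec(fraction = 0.2, seed = 3, stratify = "label")
  parts <- holdout_split(tab, spec)
  expect_equal(nrow(parts$train), 80)
  expect_equal(nrow(parts$test), 20)
  expect_equal(sum(parts$test$label == "positive"), 10)
  expect_length(intersect(parts$train$trial, parts$test$trial), 0)
  expect_setequal(c(parts$train$trial, parts$test$trial), tab$trial)
  # deterministic given (seed, repetition)
  parts2 <- holdout_split(tab, spec)
  expect_identical(parts$test$trial, parts2$test$trial)
  expect_false(identical(
    holdout_split(tab, spec, repetition = 2)$test$trial,
    parts$test$trial
  ))
  # per-stratum rounding: 4 rows, 2 per class, fraction 0.5 -> 1 test each
  small <- toy_feature_table(n_per_class = 2, subjects = 1)
  p <- holdout_split(small, split_spec(fraction = 0.5, stratify = "label"))
  expect_equal(sum(p$test$label == "positive"), 1)
  expect_equal(sum(p$test$label == "negative"), 1)
  one <- toy_feature_table(n_per_class = 1, subjects = 1)
  expect_error(holdout_split(one, split_spec(stratify = "label")), "stratum")
})

test_that("splits are invariant to the input order of rows", {
  tab <- toy_feature_table(n_per_class = 30, subjects = 6, seed = 8)
  spec <- split_spec(seed = 5)
  p1 <- holdout_split(tab, spec, repetition = 3)
  set.seed(99)
  p2 <- holdout_split(tab[sample(nrow(tab)), ], spec, repetition = 3)
  expect_setequal(p1$test$trial, p2$test$trial)
})

test_that("single-split evaluation separates separable clusters", {
  tab <- toy_feature_table(n_per_class = 30, sep = 8, seed = 12)
  parts <- holdout_split(tab, split_spec(seed = 2))
  cm <- evaluate_once(parts$train, parts$test, k = 5)
  expect_s3_class(cm, "confusion_matrix")
  expect_equal(cm$fp + cm$fn, 0)
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, nrow(parts$test))
})

test_that("label-permuted data classifies at chance", {
  set.seed(31)
  tab <- toy_feature_table(n_per_class = 100, sep = 0, seed = 31, subjects = 4)
  ev <- repeated_holdout(tab, split_spec(repetitions = 25, seed = 7), k = 10)
  n_pred <- sum(ev$scores$tp + ev$scores$fp + ev$scores$tn + ev$scores$fn)
  # mean accuracy within 3 binomial sigma of 0.5 (n = distinct rows)
  expect_lt(abs(ev$mean_accuracy - 0.5), 3 * sqrt(0.25 / nrow(tab)))
  expect_gt(n_pred, 0)
})

test_that("repeated holdout records one confusion matrix per repetition", {
  tab <- toy_feature_table(n_per_class = 20, sep = 8, seed = 2)
  ev <- repeated_holdout(tab, split_spec(repetitions = 10, seed = 1), k = 3)
  expect_equal(nrow(tidy(ev)), 10)
  expect_equal(ev$mean_accuracy, 1)
  expect_equal(ev$max_accuracy, 1)
  # same master seed twice -> identical summaries
  ev2 <- repeated_holdout(tab, split_spec(repetitions = 10, seed = 1), k = 3)
  expect_identical(tidy(ev), tidy(ev2))
  g <- glance(ev)
  expect_equal(g$n_reps, 10)
  expect_named(g, c("n_reps", "mean_accuracy", "max_accuracy", "mean_f_score",
                    "max_f_score", "mean_sensitivity", "mean_specificity"))
})
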