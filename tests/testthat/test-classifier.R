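small_spec <- function(seed = 1L) {
  classifier_spec(hidden = 4L, max_iter = 120L, seed = seed)
}

test_that("training sampling is uniform without replacement and reproducible", {
  items <- make_training_items(2000, seed = 77)
  full <- sample_training(items, n = 2000, seed = 1)
  expect_equal(nrow(full), 2000L)
  expect_setequal(full$text, items$text)

  s1 <- sample_training(items, n = 500, seed = 9)
  s2 <- sample_training(items, n = 500, seed = 9)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_error(sample_training(items, n = 2001, seed = 1),
               class = "mdaudit_input_error")

  # hypergeometric-CDF oracle: per-category draw counts in the 99% band
  pop <- table(items$truth_category)
  got <- table(factor(s1$truth_category, levels = names(pop)))
  for (cc in names(pop)) {
    m <- pop[[cc]]
    lo <- qhyper(0.005, m, 2000 - m, 500)
    hi <- qhyper(0.995, m, 2000 - m, 500)
    expect_gte(got[[cc]], lo)
    expect_lte(got[[cc]], hi)
  }
})

test_that("noiseless distinct-vocabulary categories are learned exactly", {
  items <- make_training_items(200, categories = separable_categories[1:4],
                               noise = 0, seed = 31)
  model <- train_classifier(items, small_spec())
  pred <- predict(model, items)
  expect_equal(mean(pred$core == items$core), 1)          # 100% training acc
  expect_equal(mean(pred$discretionary == items$discretionary), 1)

  # determinism: same data and seed give identical held-out predictions
  held <- make_training_items(60, categories = separable_categories[1:4],
                              noise = 0, seed = 32)
  m2 <- train_classifier(items, small_spec())
  expect_identical(predict(model, held), predict(m2, held))

  one_class <- dplyr::mutate(items, core = 1L)
  expect_error(train_classifier(one_class, small_spec()),
               class = "mdaudit_input_error")
})

test_that("prediction maps scores through the healthiness invariants", {
  items <- make_training_items(200, categories = separable_categories[1:4],
                               noise = 0, seed = 31)
  model <- train_classifier(items, small_spec())
  expect_equal(nrow(predict(model, tibble::tibble(name = character(),
                                                  description = character()))),
               0L)
  pred <- predict(model, items)
  expect_equal(pred$overall, pred$core - pred$discretionary)
  expect_equal(pred$binary, ifelse(pred$overall >= 1, "healthy", "unhealthy"))
})

test_that("k-fold cross-validation partitions the data into near-equal folds", {
  items <- make_training_items(2000, seed = 77)
  cv <- kfold_cv(items, classifier_spec(hidden = 2L, max_iter = 5L), k = 5,
                 seed = 4)
  expect_equal(cv$per_fold$n_test, rep(400L, 5))          # 2000/5 exactly
  # partition property: every record in exactly one test fold
  expect_equal(nrow(cv$assignments), 2000L)
  expect_setequal(unique(cv$assignments$fold), 1:5)
  expect_equal(sort(cv$assignments$text), sort(items$text))

  expect_error(kfold_cv(items[1:4, ], small_spec(), k = 5),
               class = "mdaudit_input_error")

  # sizes differ by <= 1 when k does not divide n
  cv7 <- kfold_cv(make_training_items(61, seed = 5),
                  classifier_spec(hidden = 2L, max_iter = 5L), k = 3, seed = 4)
  expect_lte(diff(range(cv7$per_fold$n_test)), 1L)
})

test_that("leave-group-out accuracy is perfect on separable data", {
  items <- make_training_items(120, categories = separable_categories[1:4],
                               noise = 0, seed = 55)
  cv <- kfold_cv(items, small_spec(), k = 4, seed = 6)
  expect_equal(cv$mean_core_accuracy, 100)
  expect_equal(cv$mean_discretionary_accuracy, 100)
})

test_that("record order does not change the CV report for a fixed seed", {
  items <- make_training_items(150, noise = 0.2, seed = 56)
  cv1 <- kfold_cv(items, small_spec(), k = 3, seed = 8)
  cv2 <- kfold_cv(items[sample.int(nrow(items)), ], small_spec(), k = 3,
                  seed = 8)
  expect_equal(cv1$per_fold, cv2$per_fold)
})

test_that("label permutation drops CV accuracy to chance levels", {
  items <- make_training_items(400, noise = 0, seed = 99)
  sh <- items
  withr::with_seed(7, {
    sh$core <- sample(sh$core)
    sh$discretionary <- sample(sh$discretionary)
  })
  cv <- kfold_cv(sh, small_spec(), k = 5, seed = 3)

  # chance bound from the label marginal: a model without signal can at best
  # memorise the plurality label of duplicated texts; Monte Carlo oracle for
  # the expected plurality share over the observed text-group sizes
  null_bound <- function(labels, texts) {
    sizes <- as.integer(table(texts))
    p <- as.numeric(table(labels) / length(labels))
    sim <- withr::with_seed(123, replicate(200, {
      mean(unlist(lapply(sizes, function(s) {
        draw <- table(sample(seq_along(p), s, TRUE, prob = p))
        rep(max(draw) / s, s)
      })))
    }))
    100 * (mean(sim) + 3 * stats::sd(sim) + 3 * sqrt(0.25 / length(labels)))
  }
  expect_lt(cv$mean_core_accuracy, null_bound(sh$core, sh$text))
  expect_lt(cv$mean_discretionary_accuracy,
            null_bound(sh$discretionary, sh$text))
  expect_lt(cv$mean_core_accuracy, 100)
})

test_that("accuracy degrades with text noise but stays above chance", {
  accs <- vapply(c(0, 0.35, 0.7), function(nz) {
    reps <- vapply(1:10, function(r) {
      items <- make_training_items(150, noise = nz,
                                   seed = 1000L + r)
      cv <- kfold_cv(items, classifier_spec(hidden = 3L, max_iter = 80L),
                     k = 3, seed = r)
      (cv$mean_core_accuracy + cv$mean_discretionary_accuracy) / 2
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  # monotone non-increasing on average (small tolerance for replicate noise)
  expect_lte(accs[2], accs[1] + 1)
  expect_lte(accs[3], accs[2] + 1)
  expect_lte(accs[3], accs[1])
  expect_equal(accs[1], 100)          # noise-0 limit
  expect_gt(accs[3], 50)              # far above the ~1/3-per-target null
})
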