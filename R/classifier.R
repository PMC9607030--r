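#' Classifier specification
#'
#' Configuration for the supervised scorer: a bag-of-words featuriser
#' (lowercasing, word tokenisation, minimum token frequency) feeding two
#' independent 3-class feed-forward neural networks (one hidden layer,
#' softmax output) predicting the core and the discretionary score. The
#' architecture is deliberately small and pluggable: the workflow (manual
#' sample, train, cross-validate, predict) is the point, not the network.
#'
#' @param hidden Hidden-layer size.
#' @param max_iter Optimiser iteration cap.
#' @param decay Weight decay (regularisation).
#' @param min_token_freq Tokens seen fewer times than this in the training
#'   corpus are dropped from the vocabulary.
#' @param seed Integer seed; a fixed seed gives a deterministic fit.
#'
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(hidden = 8L, max_iter = 200L, decay = 1e-3,
                            min_token_freq = 2L, seed = 1L) {
  structure(
    list(hidden = assert_count(hidden, "hidden"),
         max_iter = assert_count(max_iter, "max_iter"),
         decay = decay,
         min_token_freq = assert_count(min_token_freq, "min_token_freq"),
         seed = assert_count(seed, "seed", min = 0L)),
    class = "classifier_spec"
  )
}

#' Draw a manual-scoring training sample
#'
#' Uniform sample without replacement of `n` items, emulating the audit step
#' where a random subset of the scraped items is hand-scored to train the
#' model. Items are sorted by a stable key before the draw so the sample
#' depends only on (items, n, seed).
#'
#' @param items Scored item tibble (needs `name`, `description`, `core`,
#'   `discretionary`).
#' @param n Sample size (default 2000).
#' @param seed Integer seed.
#'
#' @return A tibble of class `mda_training` with a `text` column
#'   (name + description) and the two score columns.
#' @export
sample_training <- function(items, n = 2000L, seed = 1L) {
  assert_cols(items, c("name", "description", "core", "discretionary"), "items")
  n <- assert_count(n, "n")
  if (n > nrow(items)) {
    abort(sprintf("Cannot sample %d items from %d available.", n, nrow(items)),
          class = "mdaudit_input_error")
  }
  items <- items %>%
    mutate(text = stringr::str_squish(paste(.data$name, .data$description))) %>%
    arrange(.data$text, .data$core, .data$discretionary)
  picked <- withr::with_seed(assert_count(seed, "seed", min = 0L),
                             sample.int(nrow(items), n))
  out <- items[sort(picked), ]
  class(out) <- c("mda_training", class(out))
  out
}

# --- featuriser --------------------------------------------------------------

tokenize_text <- function(text) {
  stringr::str_split(stringr::str_to_lower(text), "[^a-z0-9]+")
}

build_vocab <- function(text, min_freq) {
  tok <- unlist(tokenize_text(text))
  tok <- tok[nzchar(tok)]
  tab <- table(tok)
  sort(names(tab)[tab >= min_freq])
}

featurize <- function(text, vocab) {
  toks <- tokenize_text(text)
  m <- matrix(0L, nrow = length(text), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(toks)) {
    t <- toks[[i]][toks[[i]] %in% vocab]
    if (length(t)) {
      tt <- table(t)
      m[i, names(tt)] <- as.integer(tt)
    }
  }
  m
}

# --- training ----------------------------------------------------------------

fit_target <- function(x, y, spec) {
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    abort("Target has a single class; supply more (or more varied) training data.",
          class = "mdaudit_input_error")
  }
  y_ind <- nnet::class.ind(factor(y, levels = classes))
  set.seed(spec$seed)
  net <- nnet::nnet(x = x, y = y_ind, size = spec$hidden, softmax = TRUE,
                    maxit = spec$max_iter, decay = spec$decay,
                    MaxNWts = 100000L, trace = FALSE)
  list(net = net, classes = classes)
}

#' Train the menu-item score classifier
#'
#' Fits two independent 3-class networks predicting the core and the
#' discretionary score from bag-of-words counts of the item text.
#'
#' @param ts An `mda_training` from [sample_training()] (or any tibble with
#'   `text`, `core`, `discretionary`).
#' @param spec A [classifier_spec()].
#'
#' @return An object of class `mda_classifier`.
#' @export
train_classifier <- function(ts, spec = classifier_spec()) {
  assert_cols(ts, c("text", "core", "discretionary"), "ts")
  if (nrow(ts) == 0L) {
    abort("Training set is empty.", class = "mdaudit_input_error")
  }
  vocab <- build_vocab(ts$text, spec$min_token_freq)
  if (!length(vocab)) {
    abort("Empty vocabulary; lower `min_token_freq` or supply more text.",
          class = "mdaudit_input_error")
  }
  x <- featurize(ts$text, vocab)
  structure(
    list(vocab = vocab, spec = spec, n_train = nrow(ts),
         core = fit_target(x, ts$core, spec),
         discretionary = fit_target(x, ts$discretionary, spec)),
    class = "mda_classifier"
  )
}

#' @export
print.mda_classifier <- function(x, ...) {
  cat(sprintf(
    "<mda_classifier> %d training items, %d-token vocabulary, hidden size %d\n",
    x$n_train, length(x$vocab), x$spec$hidden))
  invisible(x)
}

predict_target <- function(fit, x) {
  p <- predict(fit$net, x)
  fit$classes[max.col(p, ties.method = "first")]
}

#' Predict healthiness scores for menu items
#'
#' @param object An `mda_classifier`.
#' @param items Tibble with `name` and `description` (or a `text` column).
#' @param ... Unused.
#'
#' @return `items` with predicted `core`, `discretionary`, `overall`,
#'   `binary` columns.
#' @export
predict.mda_classifier <- function(object, items, ...) {
  if (!"text" %in% names(items)) {
    assert_cols(items, c("name", "description"), "items")
    items <- mutate(items,
                    text = stringr::str_squish(paste(.data$name,
                                                     .data$description)))
  }
  if (nrow(items) == 0L) {
    return(mutate(items, core = integer(), discretionary = integer(),
                  overall = integer(), binary = character()))
  }
  x <- featurize(items$text, object$vocab)
  items$core <- as.integer(predict_target(object$core, x))
  items$discretionary <- as.integer(predict_target(object$discretionary, x))
  items$overall <- items$core - items$discretionary
  items$binary <- ifelse(items$overall >= 1L, "healthy", "unhealthy")
  items
}

#' k-fold cross-validation of the classifier
#'
#' Records are randomly partitioned into `k` folds of as-equal-as-possible
#' size (each record in exactly one test fold); the model is fitted on k-1
#' folds and exact-match accuracy measured on the held-out fold, separately
#' for the core and the discretionary target. Records are pre-sorted by a
#' stable key so the report is invariant to input row order given the seed.
#'
#' @param ts An `mda_training`.
#' @param spec A [classifier_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#'
#' @return An object of class `mda_cv`: list with `k`, `per_fold` (tibble
#'   `fold`, `n_test`, `core_accuracy`, `discretionary_accuracy`, in %),
#'   `assignments` (tibble `text`, `fold`: the test-fold partition, one row
#'   per record in stable sort order) and the two mean accuracies.
#' @export
kfold_cv <- function(ts, spec = classifier_spec(), k = 5L, seed = 1L) {
  assert_cols(ts, c("text", "core", "discretionary"), "ts")
  k <- assert_count(k, "k", min = 2L)
  if (k > nrow(ts)) {
    abort(sprintf("k = %d exceeds the %d training records.", k, nrow(ts)),
          class = "mdaudit_input_error")
  }
  ts <- arrange(ts, .data$text, .data$core, .data$discretionary)
  n <- nrow(ts)
  fold <- withr::with_seed(assert_count(seed, "seed", min = 0L),
                           sample(rep(seq_len(k), length.out = n)))
  per_fold <- purrr::map(seq_len(k), function(f) {
    train <- ts[fold != f, ]
    test <- ts[fold == f, ]
    model <- train_classifier(train, spec)
    pred <- predict(model, test)
    tibble(fold = f, n_test = nrow(test),
           core_accuracy = 100 * mean(pred$core == test$core),
           discretionary_accuracy =
             100 * mean(pred$discretionary == test$discretionary))
  }) %>% bind_rows()
  structure(
    list(k = k, per_fold = per_fold,
         assignments = tibble(text = ts$text, fold = fold),
         mean_core_accuracy = mean(per_fold$core_accuracy),
         mean_discretionary_accuracy = mean(per_fold$discretionary_accuracy)),
    class = "mda_cv"
  )
}

#' @export
print.mda_cv <- function(x, ...) {
  cat(sprintf(
    "<mda_cv> %d folds; mean accuracy core %.1f%%, discretionary %.1f%%\n",
    x$k, x$mean_core_accuracy, x$mean_discretionary_accuracy))
  invisible(x)
}
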