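#' Tidy a contingency table
#'
#' @param x An `mda_contingency`.
#' @param ... Unused.
#' @return A long tibble: `binary`, `level`, `n`.
#' @export
tidy.mda_contingency <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)) %>%
    rlang::set_names(c("binary", "level", "n")) %>%
    mutate(n = as.integer(.data$n))
}

#' Tidy / glance a chi-square result
#'
#' @param x An `mda_chisq`.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p_value` (and, for
#'   `glance()`, the factor and service labels when present).
#' @export
tidy.mda_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @rdname tidy.mda_chisq
#' @export
glance.mda_chisq <- function(x, ...) {
  tidy(x) %>%
    mutate(factor = x$table$factor_name,
           service = x$table$service %||% NA_character_)
}

#' Tidy / glance a cross-validation report
#'
#' @param x An `mda_cv`.
#' @param ... Unused.
#' @return `tidy()`: the per-fold accuracy tibble; `glance()`: one row with
#'   `k` and the two mean accuracies (%).
#' @export
tidy.mda_cv <- function(x, ...) x$per_fold

#' @rdname tidy.mda_cv
#' @export
glance.mda_cv <- function(x, ...) {
  tibble(k = x$k, mean_core_accuracy = x$mean_core_accuracy,
         mean_discretionary_accuracy = x$mean_discretionary_accuracy)
}

#' Glance at a fitted classifier
#'
#' @param x An `mda_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: `n_train`, `vocab_size`, `hidden`.
#' @export
glance.mda_classifier <- function(x, ...) {
  tibble(n_train = x$n_train, vocab_size = length(x$vocab),
         hidden = x$spec$hidden)
}

#' Plot a contingency table as stacked proportions
#'
#' @param object An `mda_contingency`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mda_contingency <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$level, y = .data$n,
                                 fill = .data$binary)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = object$factor_name, y = "share of menu items",
                  fill = NULL,
                  title = object$service %||% "Healthy vs unhealthy items") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object An `mda_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mda_cv <- function(object, ...) {
  tidy(object) %>%
    tidyr::pivot_longer(c("core_accuracy", "discretionary_accuracy"),
                        names_to = "target", values_to = "accuracy") %>%
    mutate(target = sub("_accuracy", "", .data$target)) %>%
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$fold), y = .data$accuracy,
                                 colour = .data$target, group = .data$target)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fold", y = "exact-match accuracy (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-service score distributions
#'
#' @param dist A tibble from [score_distribution()].
#' @return A ggplot.
#' @export
plot_score_distribution <- function(dist) {
  assert_cols(dist, c("service", "score", "pct"), "dist")
  ggplot2::ggplot(dist, ggplot2::aes(x = factor(.data$score), y = .data$pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~service) +
    ggplot2::labs(x = "overall healthiness score", y = "% of menu items") +
    ggplot2::theme_minimal()
}
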