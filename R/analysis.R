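#' Score distribution per service
#'
#' Counts and percentages of items at each overall score (-2..2), one row per
#' (service, score) with all five score levels present.
#'
#' @param scored Scored item tibble with `service` and `overall` columns.
#' @param by Grouping column (default `"service"`).
#'
#' @return A tibble `service` (or other grouping), `score`, `n`, `pct`. An
#'   empty input gives an empty table.
#' @export
score_distribution <- function(scored, by = "service") {
  assert_cols(scored, c(by, "overall"), "scored")
  if (nrow(scored) == 0L) {
    return(tibble(!!by := character(), score = integer(), n = integer(),
                  pct = numeric()))
  }
  scored %>%
    mutate(score = factor(.data$overall, levels = -2:2)) %>%
    count(.data[[by]], .data$score, .drop = FALSE, name = "n") %>%
    group_by(.data[[by]]) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    mutate(score = as.integer(as.character(.data$score)))
}

#' Share of unhealthy items per service
#'
#' The unhealthy total: percentage of items scoring 0, -1 or -2.
#'
#' @inheritParams score_distribution
#' @return A tibble `service`, `n_unhealthy`, `total`, `unhealthy_pct`.
#' @export
unhealthy_share <- function(scored, by = "service") {
  assert_cols(scored, c(by, "overall"), "scored")
  scored %>%
    group_by(.data[[by]]) %>%
    summarise(n_unhealthy = sum(.data$overall <= 0L),
              total = n(),
              unhealthy_pct = 100 * .data$n_unhealthy / .data$total,
              .groups = "drop")
}

#' Construct a healthy/unhealthy contingency table
#'
#' @param counts A 2 x k matrix of non-negative counts, rows healthy then
#'   unhealthy, columns the factor levels.
#' @param factor_name Which stratification factor the columns represent.
#' @param service Optional service label.
#'
#' @return An object of class `mda_contingency`.
#' @export
contingency_table <- function(counts, factor_name = "factor", service = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || ncol(counts) < 2L) {
    abort("`counts` must be a 2 x k matrix with k >= 2.",
          class = "mdaudit_input_error")
  }
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("`counts` must be non-negative with a positive grand total.",
          class = "mdaudit_input_error")
  }
  rownames(counts) <- c("healthy", "unhealthy")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("L", seq_len(ncol(counts)))
  }
  structure(list(counts = counts, factor_name = factor_name,
                 service = service),
            class = "mda_contingency")
}

#' @export
print.mda_contingency <- function(x, ...) {
  cat(sprintf("<mda_contingency> %s%s\n",
              if (!is.null(x$service)) paste0(x$service, " x ") else "",
              x$factor_name))
  print(x$counts)
  invisible(x)
}

#' Build a contingency table from scored items and a sampling frame
#'
#' Cross-tabulates the binary healthy/unhealthy class against one
#' stratification factor, after mapping each item's address to its stratum
#' via the frame. Items with `binary = "unlabelled"` are excluded (they carry
#' no class); items whose address is not in the frame raise an error.
#'
#' @param scored Scored item tibble with `address_id` and `binary`.
#' @param frame An `mda_frame`.
#' @param factor One of `"deprivation"`, `"access"`, `"maori"`.
#' @param service Optional service label stored on the result.
#'
#' @return An `mda_contingency`.
#' @export
build_contingency <- function(scored, frame,
                              factor = c("deprivation", "access", "maori"),
                              service = NULL) {
  factor <- match.arg(factor)
  assert_cols(scored, c("address_id", "binary"), "scored")
  joined <- join_frame(scored, frame) %>%
    filter(.data$binary %in% c("healthy", "unhealthy"))
  level <- switch(factor,
    deprivation = paste0("T", joined$deprivation_tertile),
    access = paste0("T", joined$access_tertile),
    maori = ifelse(joined$high_maori, "higher_maori", "other"))
  lev_order <- switch(factor,
                      deprivation = , access = c("T1", "T2", "T3"),
                      maori = c("higher_maori", "other"))
  counts <- table(factor(joined$binary, levels = c("healthy", "unhealthy")),
                  factor(level, levels = lev_order))
  contingency_table(unclass(counts),
                    factor_name = switch(factor,
                                         deprivation = "NZDep",
                                         access = "physical density",
                                         maori = "Maori population"),
                    service = service)
}

#' Pearson chi-square test of independence
#'
#' The uncorrected Pearson statistic sum((O - E)^2 / E) with expected counts
#' E = row total x column total / N, degrees of freedom
#' (rows - 1) x (cols - 1), and the p-value from the upper tail of the
#' chi-square distribution. No continuity correction is applied for 2 x 2
#' tables.
#'
#' @param x An `mda_contingency` or a count matrix.
#'
#' @return An object of class `mda_chisq`: `statistic`, `df`, `p_value`, plus
#'   the table it was computed from.
#' @export
#' @examples
#' tab <- contingency_table(rbind(c(448, 1070), c(2250, 4308)),
#'                          factor_name = "Maori population")
#' chi_square(tab)
chi_square <- function(x) {
  if (!inherits(x, "mda_contingency")) {
    x <- contingency_table(x)
  }
  o <- x$counts
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
    abort("Zero row or column margin: expected counts are undefined.",
          class = "mdaudit_input_error")
  }
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  stat <- sum((o - e)^2 / e)
  df <- (nrow(o) - 1L) * (ncol(o) - 1L)
  structure(
    list(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         table = x),
    class = "mda_chisq"
  )
}

#' @export
print.mda_chisq <- function(x, ...) {
  cat(sprintf("<mda_chisq> X-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Quartile summary of outlet availability by stratum
#'
#' Median, first and third quartile of open-outlet counts per factor level
#' plus an overall row. The default quartile rule is Tukey hinges
#' ([stats::fivenum()]): for even-sized groups the median is the midpoint of
#' the two central order statistics (half-integer medians arise naturally).
#' `rule = "linear"` switches to [stats::quantile()] type 7.
#'
#' @param open_counts Tibble with `address_id` and `n_open` (one row per
#'   address), e.g. from [count_open_outlets()].
#' @param frame An `mda_frame`.
#' @param factor One of `"deprivation"`, `"access"`, `"maori"`.
#' @param rule Quartile interpolation rule.
#'
#' @return A tibble `level`, `n`, `q1`, `median`, `q3`; empty levels keep
#'   `n = 0` with `NA` quartiles.
#' @export
availability_summary <- function(open_counts, frame,
                                 factor = c("deprivation", "access", "maori"),
                                 rule = c("hinges", "linear")) {
  factor <- match.arg(factor)
  rule <- match.arg(rule)
  assert_cols(open_counts, c("address_id", "n_open"), "open_counts")
  if (any(open_counts$n_open < 0)) {
    abort("`n_open` must be non-negative.", class = "mdaudit_input_error")
  }
  joined <- join_frame(open_counts, frame)
  level <- switch(factor,
    deprivation = paste0("T", joined$deprivation_tertile),
    access = paste0("T", joined$access_tertile),
    maori = ifelse(joined$high_maori, "higher_maori", "other"))
  lev_order <- switch(factor,
                      deprivation = , access = c("T1", "T2", "T3"),
                      maori = c("higher_maori", "other"))
  one <- function(v) {
    if (!length(v)) return(tibble(n = 0L, q1 = NA_real_, median = NA_real_,
                                  q3 = NA_real_))
    q <- if (rule == "hinges") fivenum(v)[2:4] else
      unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    tibble(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }
  per_level <- purrr::map(rlang::set_names(lev_order), function(l) {
    one(joined$n_open[level == l])
  }) %>% bind_rows(.id = "level")
  bind_rows(per_level, mutate(one(joined$n_open), level = "overall"))
}
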