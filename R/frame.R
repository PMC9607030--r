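#' Count unhealthy outlets within a buffer of each SA1 centroid
#'
#' Physical access to unhealthy food is measured as the number of outlet
#' points within a closed Euclidean ball of radius `radius_m` around each
#' unit's centroid ("within" is read inclusively: distance <= radius).
#'
#' @param sa1 Tibble with `sa1_id`, `centroid_x`, `centroid_y`.
#' @param outlets Tibble with `x`, `y` (may have zero rows).
#' @param radius_m Buffer radius in metres (> 0); default 800.
#'
#' @return `sa1` with an `outlet_count` column appended.
#' @export
count_outlets_in_buffer <- function(sa1, outlets, radius_m = 800) {
  assert_cols(sa1, c("sa1_id", "centroid_x", "centroid_y"), "sa1")
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0) {
    abort("`radius_m` must be a single positive number.",
          class = "mdaudit_config_error")
  }
  r2 <- radius_m^2
  if (nrow(outlets) == 0L) {
    return(mutate(sa1, outlet_count = 0L))
  }
  assert_cols(outlets, c("x", "y"), "outlets")
  counts <- purrr::map2_int(sa1$centroid_x, sa1$centroid_y, function(cx, cy) {
    sum((outlets$x - cx)^2 + (outlets$y - cy)^2 <= r2)
  })
  mutate(sa1, outlet_count = counts)
}

#' Assign within-city tertiles of a numeric variable
#'
#' Units are ranked within each city by `value` (ties broken by id, so the
#' assignment is stable under input reordering) and split into three
#' contiguous rank groups with sizes as equal as possible; when the count is
#' not divisible by three the lower tertiles take the extra units. Tertile 1
#' holds the lowest values.
#'
#' @param df Tibble with an id column, a city column and a value column.
#' @param value Name of the numeric column to split on.
#' @param id Name of the unique id column (default `"sa1_id"`).
#' @param city Name of the city column (default `"city"`).
#' @param into Name of the new tertile column.
#'
#' @return `df` with an integer tertile column (1-3) appended, original row
#'   order preserved.
#' @export
assign_tertiles <- function(df, value, id = "sa1_id", city = "city",
                            into = paste0(value, "_tertile")) {
  assert_cols(df, c(value, id, city), "df")
  sizes <- df %>% count(.data[[city]])
  bad <- sizes$n < 3L
  if (any(bad)) {
    abort(sprintf("Cities with fewer than 3 units cannot be split into tertiles: %s.",
                  paste(sizes[[city]][bad], collapse = ", ")),
          class = "mdaudit_input_error")
  }
  df %>%
    group_by(.data[[city]]) %>%
    mutate(!!into := tertile_of_rank(order(order(.data[[value]], .data[[id]])),
                                     n())) %>%
    ungroup()
}

# rank r of n -> tertile index, lower groups take remainders
tertile_of_rank <- function(rank, n) {
  sizes <- rep(n %/% 3L, 3L) + (seq_len(3L) <= n %% 3L)
  findInterval(rank, cumsum(c(1L, sizes[1:2])))
}

#' Flag SA1s with a higher proportion of Maori population
#'
#' True for units whose Maori population proportion falls in the top fifth by
#' within-city rank. Boundary ties are resolved toward inclusion: every unit
#' whose proportion equals the k-th largest value (k = floor(n/5)) is flagged,
#' so a full tie flags the whole city.
#'
#' @param df Tibble with id, city and `maori_proportion` columns.
#' @param id,city Column names as in [assign_tertiles()].
#'
#' @return `df` with a logical `high_maori` column appended.
#' @export
flag_high_maori <- function(df, id = "sa1_id", city = "city") {
  assert_cols(df, c("maori_proportion", id, city), "df")
  sizes <- df %>% count(.data[[city]])
  bad <- sizes$n < 5L
  if (any(bad)) {
    abort(sprintf("Cities with fewer than 5 units cannot be split into quintiles: %s.",
                  paste(sizes[[city]][bad], collapse = ", ")),
          class = "mdaudit_input_error")
  }
  df %>%
    group_by(.data[[city]]) %>%
    mutate(high_maori = {
      k <- max(1L, n() %/% 5L)
      cutoff <- sort(.data$maori_proportion, decreasing = TRUE)[k]
      .data$maori_proportion >= cutoff
    }) %>%
    ungroup()
}

#' Classify a geography into the stratification variables
#'
#' Convenience wrapper: computes 800 m buffer outlet counts, within-city
#' access and deprivation tertiles, and the higher-Maori flag.
#'
#' @param geo An `mda_geography` (or a list with `sa1` and `outlets` tibbles).
#' @param radius_m Buffer radius passed to [count_outlets_in_buffer()].
#'
#' @return The `sa1` tibble with `outlet_count`, `access_tertile`,
#'   `deprivation_tertile` and `high_maori` columns.
#' @export
classify_sa1s <- function(geo, radius_m = 800) {
  count_outlets_in_buffer(geo$sa1, geo$outlets, radius_m) %>%
    assign_tertiles("outlet_count", into = "access_tertile") %>%
    assign_tertiles("deprivation", into = "deprivation_tertile") %>%
    flag_high_maori()
}

#' Build the stratification cells
#'
#' Forms the complete city x access-tertile x deprivation-tertile x
#' ethnicity-class grid (18 cells per city; 54 for three cities) and assigns
#' every classified SA1 to exactly one cell. The sampling target is 2 SA1s for
#' "other" cells and 1 for higher-Maori cells. Cells with no members are kept
#' (with a warning) so the caller can decide to regenerate the geography.
#'
#' @param sa1s Classified SA1 tibble from [classify_sa1s()].
#'
#' @return Tibble of class `mda_cells`: one row per cell with `cell_id`,
#'   `city`, `access_tertile`, `deprivation_tertile`, `high_maori`,
#'   `target_n`, `n_members` and a `members` list-column of SA1 ids.
#' @export
build_cells <- function(sa1s) {
  assert_cols(sa1s, c("sa1_id", "city", "access_tertile",
                      "deprivation_tertile", "high_maori"), "sa1s")
  uncl <- sa1s %>%
    filter(is.na(.data$access_tertile) | is.na(.data$deprivation_tertile) |
             is.na(.data$high_maori))
  if (nrow(uncl)) {
    abort(sprintf("Unclassified SA1(s): %s.",
                  paste(uncl$sa1_id, collapse = ", ")),
          class = "mdaudit_input_error")
  }
  grid <- tidyr::expand_grid(
    city = unique(sa1s$city),
    access_tertile = 1:3,
    deprivation_tertile = 1:3,
    high_maori = c(FALSE, TRUE)
  ) %>%
    mutate(
      cell_id = sprintf("%s/acc%d/dep%d/%s", .data$city, .data$access_tertile,
                        .data$deprivation_tertile,
                        ifelse(.data$high_maori, "maori", "other")),
      target_n = ifelse(.data$high_maori, 1L, 2L)
    )
  members <- sa1s %>%
    arrange(.data$sa1_id) %>%
    group_by(.data$city, .data$access_tertile, .data$deprivation_tertile,
             .data$high_maori) %>%
    summarise(members = list(.data$sa1_id), .groups = "drop")
  cells <- grid %>%
    left_join(members, by = c("city", "access_tertile",
                              "deprivation_tertile", "high_maori")) %>%
    mutate(
      members = purrr::map(.data$members, function(m) m %||% character()),
      n_members = lengths(.data$members)
    ) %>%
    select("cell_id", "city", "access_tertile", "deprivation_tertile",
           "high_maori", "target_n", "n_members", "members") %>%
    arrange(.data$cell_id)
  empty <- cells$cell_id[cells$n_members == 0L]
  if (length(empty)) {
    warn(sprintf("%d empty stratification cell(s): %s.",
                 length(empty), paste(empty, collapse = ", ")))
  }
  class(cells) <- c("mda_cells", class(cells))
  cells
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample the address frame from stratification cells
#'
#' Uniform sampling without replacement of `target_n` SA1s per cell, then one
#' uniform address per sampled SA1. Members and addresses are sorted by id
#' before any draw, so the result depends only on (cells, addresses, seed),
#' never on input row order.
#'
#' @param cells An `mda_cells` tibble from [build_cells()].
#' @param addresses Address tibble with `address_id`, `sa1_id`.
#' @param seed Integer seed for the draws.
#'
#' @return Tibble of class `mda_frame`: one row per sampled SA1 with the cell
#'   descriptors, `sa1_id` and `address_id`; the seed is kept as an attribute.
#' @export
sample_frame <- function(cells, addresses, seed = 1L) {
  assert_cols(cells, c("cell_id", "target_n", "members"), "cells")
  assert_cols(addresses, c("address_id", "sa1_id"), "addresses")
  short <- cells$n_members < cells$target_n
  if (any(short)) {
    abort(sprintf(
      "Cell(s) with fewer members than their sampling target: %s. Regenerate the geography or merge cells.",
      paste(cells$cell_id[short], collapse = ", ")),
      class = "mdaudit_empty_cell_error")
  }
  seed <- assert_count(seed, "seed", min = 0L)
  cells <- arrange(cells, .data$cell_id)
  withr::with_seed(seed, {
    sampled <- cells %>%
      mutate(sa1_id = purrr::map2(.data$members, .data$target_n, function(m, k) {
        m <- sort(m)
        m[sample.int(length(m), k)]
      })) %>%
      select(-"members", -"n_members") %>%
      tidyr::unnest("sa1_id")
    addr <- addresses %>%
      arrange(.data$sa1_id, .data$address_id) %>%
      group_by(.data$sa1_id) %>%
      summarise(all_addr = list(.data$address_id), .groups = "drop")
    sampled <- left_join(sampled, addr, by = "sa1_id")
    no_addr <- sampled$sa1_id[purrr::map_lgl(sampled$all_addr, is.null)]
    if (length(no_addr)) {
      abort(sprintf("Sampled SA1(s) without any address: %s.",
                    paste(no_addr, collapse = ", ")),
            class = "mdaudit_input_error")
    }
    sampled <- sampled %>%
      mutate(address_id = purrr::map_chr(
        .data$all_addr, function(a) a[sample.int(length(a), 1L)])) %>%
      select(-"all_addr")
  })
  attr(sampled, "seed") <- seed
  class(sampled) <- c("mda_frame", class(sampled))
  sampled
}

#' Attach city/stratum information from a frame to per-address data
#'
#' @param df Tibble with an `address_id` column.
#' @param frame An `mda_frame`.
#' @return `df` joined to the frame's stratum columns; addresses absent from
#'   the frame raise an error listing them.
#' @export
join_frame <- function(df, frame) {
  assert_cols(df, "address_id", "df")
  out <- left_join(
    df,
    select(as_tibble(frame), "address_id", "sa1_id", "city",
           "access_tertile", "deprivation_tertile", "high_maori"),
    by = "address_id")
  unmapped <- unique(out$address_id[is.na(out$city)])
  if (length(unmapped)) {
    abort(sprintf("Address(es) not present in the sampling frame: %s.",
                  paste(unmapped, collapse = ", ")),
          class = "mdaudit_input_error")
  }
  out
}
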