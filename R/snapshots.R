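#' Menu snapshot collection
#'
#' A `menu_snapshots` object holds what each delivery service displayed to
#' each queried address at one time, in display order, as three linked
#' tibbles:
#' \describe{
#'   \item{snapshots}{one row per (service, address): `service`, `address_id`,
#'     `query_time`.}
#'   \item{outlets}{one row per listed outlet: `service`, `address_id`,
#'     `outlet_id`, `outlet_name`, `display_rank`, `open`.}
#'   \item{items}{one row per menu item: `service`, `address_id`, `outlet_id`,
#'     `outlet_rank`, `item_rank`, `name`, `description` and (for synthetic
#'     data) `truth_category`.}
#' }
#'
#' @param snapshots,outlets,items Tibbles as described above.
#' @param validate Run [validate_snapshots()] on construction?
#'
#' @return A `menu_snapshots` object.
#' @export
menu_snapshots <- function(snapshots, outlets, items, validate = TRUE) {
  x <- structure(
    list(snapshots = as_tibble(snapshots), outlets = as_tibble(outlets),
         items = as_tibble(items)),
    class = "menu_snapshots"
  )
  if (validate) validate_snapshots(x)
  x
}

#' @export
print.menu_snapshots <- function(x, ...) {
  cat(sprintf("<menu_snapshots> %d snapshots, %d outlets, %d items\n",
              nrow(x$snapshots), nrow(x$outlets), nrow(x$items)))
  invisible(x)
}

#' Validate snapshot invariants
#'
#' Checks: non-empty address ids and item names; outlet display ranks
#' strictly increasing (hence unique) within each snapshot; item ranks
#' strictly increasing within each outlet listing; ranks >= 1. A duplicate
#' outlet listed twice in one view violates the rank rule and is rejected.
#'
#' @param x A `menu_snapshots`.
#' @param context Optional character vector, parallel to `x$snapshots`, used
#'   to label errors (e.g. source line numbers).
#' @return `x` invisibly; aborts with a `mdaudit_validation_error` listing
#'   every violation otherwise.
#' @export
validate_snapshots <- function(x, context = NULL) {
  assert_cols(x$snapshots, c("service", "address_id", "query_time"), "snapshots")
  assert_cols(x$outlets, c("service", "address_id", "outlet_id", "outlet_name",
                           "display_rank", "open"), "outlets")
  assert_cols(x$items, c("service", "address_id", "outlet_id", "item_rank",
                         "name"), "items")
  probs <- character()
  label <- function(service, address_id) {
    key <- paste(service, address_id)
    if (is.null(context)) return(key)
    i <- match(key, paste(x$snapshots$service, x$snapshots$address_id))
    if (is.na(i)) key else paste0(context[i], " (", key, ")")
  }
  bad_addr <- !nzchar(x$snapshots$address_id) | is.na(x$snapshots$address_id)
  if (any(bad_addr)) {
    probs <- c(probs, sprintf("snapshot %d: field address_id is empty",
                              which(bad_addr)))
  }
  bad_name <- !nzchar(x$items$name) | is.na(x$items$name)
  if (any(bad_name)) {
    probs <- c(probs, sprintf("item %d: field name is empty", which(bad_name)))
  }
  rank_probs <- function(df, rank_col, keys, what) {
    df %>%
      group_by(across(all_of(keys))) %>%
      summarise(ok = all(.data[[rank_col]] >= 1L) &&
                  all(diff(.data[[rank_col]]) > 0), .groups = "drop") %>%
      filter(!.data$ok) %>%
      mutate(msg = sprintf("%s: field %s not strictly increasing from >= 1 in %s",
                           purrr::map2_chr(.data$service, .data$address_id, label),
                           rank_col, what)) %>%
      pull("msg")
  }
  if (nrow(x$outlets)) {
    probs <- c(probs, rank_probs(x$outlets, "display_rank",
                                 c("service", "address_id"), "outlet list"))
  }
  if (nrow(x$items)) {
    probs <- c(probs, rank_probs(x$items, "item_rank",
                                 c("service", "address_id", "outlet_id"),
                                 "item list"))
  }
  if (length(probs)) {
    abort(c("Invalid menu snapshots:", probs),
          class = "mdaudit_validation_error")
  }
  invisible(x)
}

#' Write snapshots as JSON Lines
#'
#' One JSON object per line per snapshot, with nested display-ordered
#' `outlets` and `items` arrays, UTF-8.
#'
#' @param x A `menu_snapshots`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(x, path) {
  keys <- paste(x$snapshots$service, x$snapshots$address_id)
  out_split <- split(x$outlets, factor(paste(x$outlets$service, x$outlets$address_id),
                                       levels = keys))
  it_split <- split(x$items, factor(paste(x$items$service, x$items$address_id),
                                    levels = keys))
  lines <- purrr::map_chr(seq_along(keys), function(i) {
    snap <- x$snapshots[i, ]
    outs <- out_split[[i]]
    its <- it_split[[i]]
    outlets <- purrr::map(seq_len(nrow(outs)), function(j) {
      o <- outs[j, ]
      oi <- its[its$outlet_id == o$outlet_id, ]
      items <- purrr::map(seq_len(nrow(oi)), function(k) {
        rec <- list(name = oi$name[k],
                    description = oi$description[k] %||% "",
                    display_rank = oi$item_rank[k])
        if (!is.null(oi$truth_category) && !is.na(oi$truth_category[k])) {
          rec$truth_category <- oi$truth_category[k]
        }
        rec
      })
      list(id = o$outlet_id, name = o$outlet_name,
           display_rank = o$display_rank, open = o$open, items = items)
    })
    jsonlite::toJSON(list(service = snap$service, address_id = snap$address_id,
                          query_time = snap$query_time, outlets = outlets),
                     auto_unbox = TRUE, digits = NA)
  })
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read snapshots from JSON Lines
#'
#' Every record is validated against the snapshot invariants; violations are
#' reported with their source line number and field.
#'
#' @param path Path to a JSONL file (an empty file yields an empty
#'   collection).
#' @return A validated `menu_snapshots`.
#' @export
read_snapshots <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Snapshot file not found: '%s'.", path),
          class = "mdaudit_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_idx <- which(nzchar(trimws(lines)))
  parsed <- purrr::map(lines_idx, function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) {
               abort(sprintf("line %d: malformed JSON (%s)", i,
                             conditionMessage(e)),
                     class = "mdaudit_validation_error")
             })
  })
  snaps <- purrr::map2(parsed, lines_idx, parse_snapshot_record)
  x <- menu_snapshots(
    snapshots = bind_rows(purrr::map(snaps, "snapshot")) %||% empty_snaps()$snapshots,
    outlets = bind_rows(purrr::map(snaps, "outlets")),
    items = bind_rows(purrr::map(snaps, "items")),
    validate = FALSE
  )
  if (nrow(x$snapshots) == 0L) return(empty_snaps())
  if (nrow(x$outlets) == 0L) x$outlets <- empty_snaps()$outlets
  if (nrow(x$items) == 0L) x$items <- empty_snaps()$items
  validate_snapshots(x, context = sprintf("line %d", lines_idx))
  x
}

empty_snaps <- function() {
  menu_snapshots(
    snapshots = tibble(service = character(), address_id = character(),
                       query_time = character()),
    outlets = tibble(service = character(), address_id = character(),
                     outlet_id = character(), outlet_name = character(),
                     display_rank = integer(), open = logical()),
    items = tibble(service = character(), address_id = character(),
                   outlet_id = character(), outlet_rank = integer(),
                   item_rank = integer(), name = character(),
                   description = character(), truth_category = character()),
    validate = FALSE
  )
}

parse_snapshot_record <- function(rec, line) {
  need <- function(x, field) {
    if (is.null(x)) {
      abort(sprintf("line %d: missing field %s", line, field),
            class = "mdaudit_validation_error")
    }
    x
  }
  service <- need(rec$service, "service")
  address_id <- need(rec$address_id, "address_id")
  outlets <- purrr::map(rec$outlets %||% list(), function(o) {
    tibble(service = service, address_id = address_id,
           outlet_id = need(o$id, "outlets.id"),
           outlet_name = need(o$name, "outlets.name"),
           display_rank = as.integer(need(o$display_rank, "outlets.display_rank")),
           open = isTRUE(o$open))
  })
  items <- purrr::map(rec$outlets %||% list(), function(o) {
    bind_rows(purrr::map(o$items %||% list(), function(it) {
      tibble(service = service, address_id = address_id,
             outlet_id = o$id, outlet_rank = as.integer(o$display_rank),
             item_rank = as.integer(need(it$display_rank, "items.display_rank")),
             name = need(it$name, "items.name"),
             description = it$description %||% "",
             truth_category = it$truth_category %||% NA_character_)
    }))
  })
  list(
    snapshot = tibble(service = service, address_id = address_id,
                      query_time = need(rec$query_time, "query_time")),
    outlets = bind_rows(outlets),
    items = bind_rows(items)
  )
}

#' Truncate snapshots to the first-N-outlets, first-N-items window
#'
#' Keeps the first `max_outlets` outlets of each snapshot and the first
#' `max_items` items of each retained outlet, "first" meaning lowest display
#' rank. Order is preserved and the operation is idempotent; under-capacity
#' snapshots pass through unchanged. With the 81-address design and the
#' default 10 x 10 window, at most 8100 items per service remain.
#'
#' @param x A `menu_snapshots`.
#' @param max_outlets,max_items Window sizes (default 10 each).
#' @return A truncated `menu_snapshots`.
#' @export
truncate_window <- function(x, max_outlets = 10L, max_items = 10L) {
  kept_outlets <- x$outlets %>%
    group_by(.data$service, .data$address_id) %>%
    arrange(.data$display_rank, .by_group = TRUE) %>%
    filter(row_number() <= max_outlets) %>%
    ungroup()
  kept_items <- x$items %>%
    inner_join(select(kept_outlets, "service", "address_id", "outlet_id"),
               by = c("service", "address_id", "outlet_id")) %>%
    group_by(.data$service, .data$address_id, .data$outlet_id) %>%
    arrange(.data$item_rank, .by_group = TRUE) %>%
    filter(row_number() <= max_items) %>%
    ungroup()
  menu_snapshots(x$snapshots, kept_outlets, kept_items, validate = FALSE)
}

#' Count open outlets per snapshot
#'
#' Counts every outlet flagged open, before any window truncation (services
#' typically list far more than ten outlets).
#'
#' @param x A `menu_snapshots`.
#' @return Tibble with `service`, `address_id`, `n_open`.
#' @export
count_open_outlets <- function(x) {
  counts <- x$outlets %>%
    group_by(.data$service, .data$address_id) %>%
    summarise(n_open = sum(.data$open), .groups = "drop")
  x$snapshots %>%
    select("service", "address_id") %>%
    left_join(counts, by = c("service", "address_id")) %>%
    mutate(n_open = as.integer(tidyr::replace_na(.data$n_open, 0L)))
}
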