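#' Load a menu-item classification manual
#'
#' The manual maps intermediate menu-item categories to a core score and a
#' discretionary score, each 0-2, following the core/discretionary distinction
#' of national dietary guidelines: the core score rewards everyday-food
#' components (variety, fruit/veg, whole grains, dairy, protein) and the
#' discretionary score penalises saturated fat, salt, sugar and heavy
#' processing. Component columns are rationale metadata; the category-level
#' integers are authoritative. Alcoholic-drink categories must carry core 0
#' and discretionary 2.
#'
#' The bundled default manual has 36 categories. Its `source` column marks
#' which entries reproduce externally documented category scores ("printed")
#' and which are this package's own reconstructions ("reconstructed") filling
#' out the category space; edit the CSV to supply a different manual.
#'
#' @param path Path to a manual CSV; `NULL` loads the bundled default.
#'
#' @return A tibble of class `mda_manual`, one row per category, with columns
#'   `name`, `core`, `discretionary`, `is_alcohol`, the nine component
#'   columns and `source`.
#' @export
#' @examples
#' manual <- load_manual()
#' nrow(manual)
load_manual <- function(path = NULL) {
  path <- path %||% system.file("extdata", "classification_manual.csv",
                                package = "mdaudit")
  if (!file.exists(path) || !nzchar(path)) {
    abort(sprintf("Manual file not found: '%s'.", path),
          class = "mdaudit_io_error")
  }
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(m) == 0L) {
    abort("Manual file is empty: a manual must define at least one category.",
          class = "mdaudit_validation_error")
  }
  assert_cols(m, c("name", "core", "discretionary", "is_alcohol"), "manual")
  for (col in c("core", "discretionary")) {
    bad <- !m[[col]] %in% 0:2
    if (any(bad)) {
      abort(sprintf("Column `%s` out of range {0,1,2} for category(ies): %s.",
                    col, paste(m$name[bad], collapse = ", ")),
            class = "mdaudit_validation_error")
    }
  }
  dup <- m$name[duplicated(m$name)]
  if (length(dup)) {
    abort(sprintf("Duplicate category name(s): %s.",
                  paste(unique(dup), collapse = ", ")),
          class = "mdaudit_validation_error")
  }
  m$core <- as.integer(m$core)
  m$discretionary <- as.integer(m$discretionary)
  bad_alc <- m$is_alcohol & !(m$core == 0L & m$discretionary == 2L)
  if (any(bad_alc)) {
    abort(sprintf("Alcohol categories must score core 0, discretionary 2: %s.",
                  paste(m$name[bad_alc], collapse = ", ")),
          class = "mdaudit_validation_error")
  }
  class(m) <- c("mda_manual", class(m))
  m
}

#' Healthiness score from core and discretionary components
#'
#' The overall score is core minus discretionary, ranging -2 (least healthy)
#' to 2 (most healthy); items scoring 1 or 2 are classed "healthy", items
#' scoring 0, -1 or -2 "unhealthy".
#'
#' @param core,discretionary Integer vectors with values in {0, 1, 2}.
#'
#' @return A tibble with columns `core`, `discretionary`, `overall`, `binary`.
#' @export
#' @examples
#' healthiness_score(2, 0)  # e.g. a salad: overall 2, healthy
#' healthiness_score(0, 2)  # e.g. a pizza meal deal: overall -2, unhealthy
healthiness_score <- function(core, discretionary) {
  if (!all(core %in% 0:2) || !all(discretionary %in% 0:2)) {
    abort("`core` and `discretionary` must take values in {0, 1, 2}.",
          class = "mdaudit_validation_error")
  }
  overall <- as.integer(core) - as.integer(discretionary)
  tibble(
    core = as.integer(core),
    discretionary = as.integer(discretionary),
    overall = overall,
    binary = ifelse(overall >= 1L, "healthy", "unhealthy")
  )
}

#' Score a single manual category
#'
#' @param cat One row of an `mda_manual` (or any list with `core` and
#'   `discretionary`).
#' @return A one-row tibble as in [healthiness_score()].
#' @export
score_category <- function(cat) {
  healthiness_score(cat$core, cat$discretionary)
}

#' Score menu items against a classification manual
#'
#' Each item's category label is looked up in the manual and the healthiness
#' score derived. Labels absent from the manual are an error (they indicate a
#' manual/labelling mismatch); items with a missing (`NA`) label are never
#' silently dropped -- they are retained with `binary = "unlabelled"`.
#'
#' @param items Tibble of menu items with a category-label column.
#' @param manual An `mda_manual` from [load_manual()].
#' @param category_col Name of the label column (default `"truth_category"`).
#'
#' @return `items` with `core`, `discretionary`, `overall`, `binary` appended.
#' @export
score_items <- function(items, manual, category_col = "truth_category") {
  assert_cols(items, category_col, "items")
  if (nrow(items) == 0L) {
    return(mutate(items, core = integer(), discretionary = integer(),
                  overall = integer(), binary = character()))
  }
  labels <- items[[category_col]]
  unknown <- setdiff(labels[!is.na(labels)], manual$name)
  if (length(unknown)) {
    abort(sprintf("Category label(s) not in the manual: %s.",
                  paste(unknown, collapse = ", ")),
          class = "mdaudit_validation_error")
  }
  idx <- match(labels, manual$name)
  out <- items
  out$core <- manual$core[idx]
  out$discretionary <- manual$discretionary[idx]
  out$overall <- out$core - out$discretionary
  out$binary <- dplyr::case_when(
    is.na(labels) ~ "unlabelled",
    out$overall >= 1L ~ "healthy",
    TRUE ~ "unhealthy"
  )
  out
}

#' Percent agreement between two parallel score lists
#'
#' Position-by-position exact agreement, reported separately for the core and
#' discretionary components, as used to compare independent human coders.
#'
#' @param a,b Tibbles of equal length with `core` and `discretionary` columns.
#'
#' @return A tibble with columns `component` and `agreement_pct` (0-100).
#' @export
agreement <- function(a, b) {
  assert_cols(a, c("core", "discretionary"), "a")
  assert_cols(b, c("core", "discretionary"), "b")
  if (nrow(a) != nrow(b) || nrow(a) == 0L) {
    abort("`a` and `b` must have equal, non-zero length.",
          class = "mdaudit_input_error")
  }
  tibble(
    component = c("core", "discretionary"),
    agreement_pct = c(100 * mean(a$core == b$core),
                      100 * mean(a$discretionary == b$discretionary))
  )
}
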