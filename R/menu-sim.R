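#' Service profile for the snapshot simulator
#'
#' Describes one delivery service: per-city availability (coverage gaps are
#' Bernoulli per address within a city, so a low-coverage city reproduces the
#' "most misses in one city" pattern of a partial market rollout), the
#' distribution of listed outlets per covered address, the probability an
#' outlet is open, items per outlet, the category mixture items are drawn
#' from, and the text noise rate.
#'
#' @param name Service name.
#' @param coverage Named vector of per-city coverage probabilities, or a
#'   single probability applied to every city.
#' @param outlet_mean Poisson mean of listed outlets per covered address.
#' @param open_prob Probability an outlet is flagged open.
#' @param items_mean Poisson mean of items per outlet.
#' @param item_depth Item lists are generated only for the first `item_depth`
#'   outlets by display rank (deeper outlets are listed with an empty item
#'   list). This mirrors observation: only items near the top of the outlet
#'   list are ever recorded, while open-outlet counting uses the full list.
#'   Keep `item_depth` at least as large as the analysis window (10).
#' @param category_mixture Named non-negative weights over manual categories
#'   (normalised to sum 1), or a function of the address row returning such
#'   weights (stratum-varying mixtures); `NULL` uses
#'   [default_category_mixture()].
#' @param text_noise_rate Per-token corruption probability in \[0, 1\].
#'
#' @return A `service_profile` list.
#' @export
service_profile <- function(name, coverage = 1, outlet_mean = 20,
                            open_prob = 0.8, items_mean = 8,
                            item_depth = 12L, category_mixture = NULL,
                            text_noise_rate = 0.1) {
  assert_prob(coverage, "coverage")
  assert_prob(open_prob, "open_prob")
  assert_prob(text_noise_rate, "text_noise_rate")
  structure(
    list(name = name, coverage = coverage, outlet_mean = outlet_mean,
         open_prob = open_prob, items_mean = items_mean,
         item_depth = assert_count(item_depth, "item_depth", min = 0L),
         category_mixture = category_mixture,
         text_noise_rate = text_noise_rate),
    class = "service_profile"
  )
}

#' Default category mixture
#'
#' Weights over the bundled manual's categories chosen so the implied
#' distribution of overall scores matches the strong unhealthy skew observed
#' in audited New Zealand delivery platforms (mass per score: -2: 0.30,
#' -1: 0.31, 0: 0.16, 1: 0.20, 2: 0.03), split uniformly among the categories
#' sharing a score.
#'
#' @param manual An `mda_manual`; default the bundled manual.
#' @return A named numeric vector of weights summing to 1.
#' @export
default_category_mixture <- function(manual = load_manual()) {
  mass <- c(`-2` = 0.30, `-1` = 0.31, `0` = 0.16, `1` = 0.20, `2` = 0.03)
  overall <- manual$core - manual$discretionary
  w <- mass[as.character(overall)] / table(overall)[as.character(overall)]
  rlang::set_names(as.numeric(w), manual$name)
}

#' Configuration for the snapshot simulator
#'
#' @param seed Integer seed.
#' @param services List of [service_profile()]s. The defaults emulate a
#'   three-service market: two full-coverage services and one domestic
#'   service with a large coverage gap in Auckland.
#' @param query_time Timestamp string stamped on every snapshot (collection
#'   is simulated at a single dinner-time query).
#' @param templates Text template table from [category_templates()].
#'
#' @return A `menu_config` list.
#' @export
menu_config <- function(seed = 1L,
                        services = default_services(),
                        query_time = "2022-05-10T18:00:00+12:00",
                        templates = category_templates()) {
  if (inherits(services, "service_profile")) services <- list(services)
  stopifnot(length(services) >= 1L)
  structure(
    list(seed = assert_count(seed, "seed", min = 0L), services = services,
         query_time = query_time, templates = templates),
    class = "menu_config"
  )
}

#' @rdname menu_config
#' @export
default_services <- function() {
  list(
    service_profile("ubereats-like", coverage = 1, outlet_mean = 160),
    service_profile("menulog-like", coverage = 1, outlet_mean = 95),
    service_profile("delivereasy-like",
                    coverage = c(Auckland = 0.3, Wellington = 0.95,
                                 Christchurch = 0.95),
                    outlet_mean = 55)
  )
}

#' Simulate MDA snapshots for a sampled address frame
#'
#' For each service and each frame address, coverage is drawn Bernoulli with
#' the city's coverage probability; uncovered addresses produce no snapshot
#' and are logged in the `coverage_gaps` attribute. Covered addresses get a
#' display-ordered outlet list (ranks contiguous from 1) with open flags and
#' item lists whose texts come from category templates, each item carrying
#' its ground-truth category label.
#'
#' @param frame An `mda_frame` (needs `address_id` and `city` columns).
#' @param config A [menu_config()].
#'
#' @return A `menu_snapshots` with a `coverage_gaps` attribute (tibble
#'   `service`, `address_id`, `city`). Deterministic given `config$seed`.
#' @export
simulate_snapshots <- function(frame, config = menu_config()) {
  assert_cols(frame, c("address_id", "city"), "frame")
  if (nrow(frame) == 0L) {
    abort("`frame` must contain at least one address.",
          class = "mdaudit_input_error")
  }
  manual_names <- config$templates$category
  for (sv in config$services) {
    mix <- sv$category_mixture
    if (is.numeric(mix)) check_mixture(mix, manual_names, sv$name)
  }
  withr::with_seed(config$seed, simulate_snapshots_impl(frame, config))
}

check_mixture <- function(mix, known, service) {
  if (is.null(names(mix)) || any(!nzchar(names(mix)))) {
    abort(sprintf("Service '%s': category_mixture must be named.", service),
          class = "mdaudit_config_error")
  }
  unknown <- setdiff(names(mix), known)
  if (length(unknown)) {
    abort(sprintf("Service '%s': unknown category(ies) in mixture: %s.",
                  service, paste(unknown, collapse = ", ")),
          class = "mdaudit_config_error")
  }
  if (any(mix < 0) || sum(mix) <= 0) {
    abort(sprintf("Service '%s': mixture weights must be non-negative with positive sum.",
                  service), class = "mdaudit_config_error")
  }
  invisible(mix)
}

simulate_snapshots_impl <- function(frame, config) {
  frame <- arrange(as_tibble(frame), .data$address_id)
  default_mix <- NULL
  snap_rows <- list(); outlet_rows <- list(); item_rows <- list()
  gaps <- list()
  for (sv in config$services) {
    for (a in seq_len(nrow(frame))) {
      addr <- frame[a, ]
      cov <- if (length(sv$coverage) == 1L && is.null(names(sv$coverage))) {
        sv$coverage
      } else {
        p <- sv$coverage[addr$city]
        if (is.na(p)) 1 else unname(p)
      }
      if (runif(1) >= cov && cov < 1) {
        gaps[[length(gaps) + 1L]] <- tibble(service = sv$name,
                                            address_id = addr$address_id,
                                            city = addr$city)
        next
      }
      mix <- sv$category_mixture
      if (is.function(mix)) {
        mix <- check_mixture(mix(addr), config$templates$category, sv$name)
      } else if (is.null(mix)) {
        if (is.null(default_mix)) default_mix <- default_category_mixture()
        mix <- default_mix[names(default_mix) %in% config$templates$category]
      }
      mix <- mix / sum(mix)
      n_out <- rpois(1, sv$outlet_mean)
      snap_rows[[length(snap_rows) + 1L]] <-
        tibble(service = sv$name, address_id = addr$address_id,
               query_time = config$query_time)
      if (n_out == 0L) next
      ids <- sprintf("%s-%s-O%03d", sv$name, addr$address_id, seq_len(n_out))
      outlet_rows[[length(outlet_rows) + 1L]] <-
        tibble(service = sv$name, address_id = addr$address_id,
               outlet_id = ids,
               outlet_name = sprintf("outlet %03d", seq_len(n_out)),
               display_rank = seq_len(n_out),
               open = runif(n_out) < sv$open_prob)
      with_items <- seq_len(min(n_out, sv$item_depth))
      n_items <- rpois(length(with_items), sv$items_mean)
      for (j in with_items[n_items > 0L]) {
        k <- n_items[match(j, with_items)]
        cats <- sample(names(mix), k, replace = TRUE, prob = mix)
        texts <- generate_item_texts(cats, sv$text_noise_rate,
                                     config$templates)
        item_rows[[length(item_rows) + 1L]] <-
          tibble(service = sv$name, address_id = addr$address_id,
                 outlet_id = ids[j], outlet_rank = j,
                 item_rank = seq_len(k),
                 name = texts$name, description = texts$description,
                 truth_category = texts$truth_category)
      }
    }
  }
  base <- empty_snaps()
  x <- menu_snapshots(
    snapshots = bind_rows(base$snapshots, !!!snap_rows),
    outlets = bind_rows(base$outlets, !!!outlet_rows),
    items = bind_rows(base$items, !!!item_rows),
    validate = FALSE
  )
  attr(x, "coverage_gaps") <- bind_rows(
    tibble(service = character(), address_id = character(), city = character()),
    !!!gaps)
  x
}
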