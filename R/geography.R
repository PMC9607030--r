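#' Configuration for the synthetic geography generator
#'
#' Describes a set of cities, each a regular grid of square small-area units
#' (SA1-like census areas), with a continuous deprivation index (higher = more
#' deprived, mirroring NZDep), a bounded Maori population proportion, street
#' addresses inside each unit, and point locations of unhealthy-food outlets
#' (dairy/convenience, fast food, takeaway) whose density can be concentrated
#' in high-deprivation areas.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param cities Character vector of city names.
#' @param sa1_per_city Number of small-area units per city (>= 1). The
#'   default (400) makes every stratification cell populated with high
#'   probability: the higher-Maori flag marks the top fifth within a city, so
#'   each of the 9 access x deprivation combinations expects about
#'   `sa1_per_city/45` flagged members, and small counts risk empty cells
#'   (callers can regenerate with a fresh seed if [sample_frame()] reports
#'   one).
#' @param deprivation_range Length-2 numeric bounds of the deprivation index.
#' @param maori_shape Length-2 shape parameters of the Beta distribution used
#'   for the Maori population proportion (default mean 0.2).
#' @param outlet_intensity Expected number of outlets per square kilometre.
#' @param outlet_clustering Non-negative coefficient concentrating outlets in
#'   high-deprivation units; 0 gives spatially homogeneous intensity.
#' @param addresses_per_sa1 Street addresses generated inside each unit (>= 1).
#' @param sa1_size_m Side length of each square unit, in metres.
#'
#' @return An object of class `geo_config`.
#' @export
geo_config <- function(seed = 1L,
                       cities = c("Auckland", "Wellington", "Christchurch"),
                       sa1_per_city = 400L,
                       deprivation_range = c(1, 10),
                       maori_shape = c(2, 8),
                       outlet_intensity = 12,
                       outlet_clustering = 1,
                       addresses_per_sa1 = 5L,
                       sa1_size_m = 500) {
  if (!is.character(cities) || !length(cities) || anyDuplicated(cities)) {
    abort("`cities` must be a non-empty character vector of distinct names.",
          class = "mdaudit_config_error")
  }
  if (!is.numeric(deprivation_range) || length(deprivation_range) != 2L ||
      diff(deprivation_range) <= 0) {
    abort("`deprivation_range` must be increasing numeric bounds of length 2.",
          class = "mdaudit_config_error")
  }
  if (!is.numeric(outlet_intensity) || outlet_intensity < 0) {
    abort("`outlet_intensity` must be >= 0.", class = "mdaudit_config_error")
  }
  if (!is.numeric(outlet_clustering) || outlet_clustering < 0) {
    abort("`outlet_clustering` must be >= 0.", class = "mdaudit_config_error")
  }
  structure(
    list(
      seed = assert_count(seed, "seed", min = 0L),
      cities = cities,
      sa1_per_city = assert_count(sa1_per_city, "sa1_per_city"),
      deprivation_range = as.numeric(deprivation_range),
      maori_shape = as.numeric(maori_shape),
      outlet_intensity = as.numeric(outlet_intensity),
      outlet_clustering = as.numeric(outlet_clustering),
      addresses_per_sa1 = assert_count(addresses_per_sa1, "addresses_per_sa1"),
      sa1_size_m = as.numeric(sa1_size_m)
    ),
    class = "geo_config"
  )
}

#' Generate a synthetic geography bundle
#'
#' Lays each city out as a grid of non-overlapping square small-area units
#' (cities are offset far apart so buffers never cross city boundaries), then
#' draws deprivation, ethnicity, population, addresses and outlet locations.
#' Outlet counts per unit are Poisson with intensity proportional to
#' `exp(outlet_clustering * z)` where `z` is the within-city standardised
#' deprivation, normalised so the city-wide expected count matches
#' `outlet_intensity` per km^2; a positive clustering coefficient therefore
#' induces a positive association between deprivation and nearby outlet
#' density.
#'
#' @param config A [geo_config()].
#'
#' @return An object of class `mda_geography`: a list with tibbles `sa1`
#'   (`sa1_id`, `city`, `centroid_x`, `centroid_y`, `deprivation`,
#'   `maori_proportion`, `population`), `outlets` (`outlet_id`, `city`, `x`,
#'   `y`, `kind`), `addresses` (`address_id`, `sa1_id`, `x`, `y`) and the
#'   config. Deterministic given `config$seed`.
#' @export
#' @examples
#' geo <- simulate_geography(geo_config(seed = 1, sa1_per_city = 9))
#' nrow(geo$sa1)
simulate_geography <- function(config = geo_config()) {
  if (!inherits(config, "geo_config")) {
    abort("`config` must be created by geo_config().",
          class = "mdaudit_config_error")
  }
  withr::with_seed(config$seed, simulate_geography_impl(config))
}

simulate_geography_impl <- function(config) {
  n <- config$sa1_per_city
  side <- config$sa1_size_m
  ncol_grid <- ceiling(sqrt(n))
  kinds <- c("dairy/convenience", "fast food", "takeaway")
  area_km2 <- (side / 1000)^2

  bundles <- purrr::imap(
    rlang::set_names(config$cities),
    function(city, .) {
      # cities spaced 10^6 m apart: an 800 m buffer can never span two cities
      origin_x <- (match(city, config$cities) - 1) * 1e6
      idx <- seq_len(n) - 1L
      sa1 <- tibble(
        sa1_id = sprintf("%s-%04d", toupper(substr(city, 1, 3)), idx + 1L),
        city = city,
        xmin = origin_x + (idx %% ncol_grid) * side,
        ymin = (idx %/% ncol_grid) * side
      ) %>%
        mutate(
          centroid_x = .data$xmin + side / 2,
          centroid_y = .data$ymin + side / 2,
          deprivation = runif(n, config$deprivation_range[1],
                              config$deprivation_range[2]),
          maori_proportion = rbeta(n, config$maori_shape[1],
                                   config$maori_shape[2]),
          population = 50L + rpois(n, 130)
        )

      addresses <- sa1 %>%
        tidyr::uncount(config$addresses_per_sa1, .id = "addr_no") %>%
        mutate(
          address_id = sprintf("%s-A%02d", .data$sa1_id, .data$addr_no),
          x = .data$xmin + runif(n()) * side,
          y = .data$ymin + runif(n()) * side
        ) %>%
        select("address_id", "sa1_id", "x", "y")

      # expected outlets per unit, tilted toward deprived units
      base <- config$outlet_intensity * area_km2
      z <- as.numeric(scale(sa1$deprivation))
      if (anyNA(z)) z <- rep(0, n)  # constant deprivation degenerates to flat
      w <- exp(config$outlet_clustering * z)
      lambda <- base * n * w / sum(w)
      n_out <- rpois(n, lambda)
      outlets <- sa1[rep(seq_len(n), n_out), c("city", "xmin", "ymin")] %>%
        mutate(
          x = .data$xmin + runif(n()) * side,
          y = .data$ymin + runif(n()) * side,
          kind = sample(kinds, n(), replace = TRUE)
        ) %>%
        select("city", "x", "y", "kind")

      list(sa1 = select(sa1, -"xmin", -"ymin"), addresses = addresses,
           outlets = outlets)
    }
  )

  outlets <- bind_rows(purrr::map(bundles, "outlets"))
  if (nrow(outlets)) {
    outlets <- mutate(outlets,
                      outlet_id = sprintf("OUT-%06d", row_number()),
                      .before = 1)
  } else {
    outlets <- tibble(outlet_id = character(), city = character(),
                      x = numeric(), y = numeric(), kind = character())
  }

  structure(
    list(
      sa1 = bind_rows(purrr::map(bundles, "sa1")),
      outlets = outlets,
      addresses = bind_rows(purrr::map(bundles, "addresses")),
      config = config
    ),
    class = "mda_geography"
  )
}

#' @export
print.mda_geography <- function(x, ...) {
  cat(sprintf(
    "<mda_geography> %d cities, %d SA1s, %d addresses, %d outlets (seed %d)\n",
    length(x$config$cities), nrow(x$sa1), nrow(x$addresses), nrow(x$outlets),
    x$config$seed))
  invisible(x)
}

#' Write or read a geography bundle as CSV files
#'
#' One UTF-8 CSV per entity: `sa1.csv`, `outlets.csv`, `addresses.csv`.
#'
#' @param geo An `mda_geography`.
#' @param dir Directory to write into (created if needed).
#' @return `write_geography()` returns `dir` invisibly; `read_geography()`
#'   returns a list of the three tibbles.
#' @export
write_geography <- function(geo, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(geo$sa1, file.path(dir, "sa1.csv"))
  readr::write_csv(geo$outlets, file.path(dir, "outlets.csv"))
  readr::write_csv(geo$addresses, file.path(dir, "addresses.csv"))
  invisible(dir)
}

#' @rdname write_geography
#' @export
read_geography <- function(dir) {
  read1 <- function(f) readr::read_csv(file.path(dir, f),
                                       show_col_types = FALSE, progress = FALSE)
  list(sa1 = read1("sa1.csv"), outlets = read1("outlets.csv"),
       addresses = read1("addresses.csv"))
}
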