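# Shared fixture builders. Everything is generated in code; no binary data.

# A classified SA1 table with every stratification cell populated by
# construction (bypasses the geography generator so cell-level behaviour can
# be tested deterministically).
make_classified <- function(cities = c("A", "B", "C"), n_per_cell = 3L) {
  tidyr::expand_grid(
    city = cities,
    access_tertile = 1:3,
    deprivation_tertile = 1:3,
    high_maori = c(FALSE, TRUE),
    member = seq_len(n_per_cell)
  ) |>
    dplyr::mutate(sa1_id = sprintf("%s-a%dd%d%s-%02d", city, access_tertile,
                                   deprivation_tertile,
                                   ifelse(high_maori, "m", "o"), member)) |>
    dplyr::select(-member)
}

make_addresses <- function(sa1_ids, per = 2L) {
  tidyr::expand_grid(sa1_id = sa1_ids, k = seq_len(per)) |>
    dplyr::mutate(address_id = sprintf("%s-A%02d", sa1_id, k),
                  x = 0, y = 0) |>
    dplyr::select(address_id, sa1_id, x, y)
}

# Small geography for integration-style tests.
small_geo <- function(seed = 42L, per_city = 45L) {
  simulate_geography(geo_config(seed = seed, sa1_per_city = per_city,
                                addresses_per_sa1 = 2L))
}

# A minimal single-service frame + snapshot config for fast end-to-end runs.
fast_menu_config <- function(seed = 5L, services = NULL, noise = 0) {
  services <- services %||% list(
    service_profile("svc-a", coverage = 1, outlet_mean = 6, items_mean = 4,
                    text_noise_rate = noise),
    service_profile("svc-b",
                    coverage = c(A = 0.3, B = 1, C = 1),
                    outlet_mean = 5, items_mean = 3, text_noise_rate = noise)
  )
  menu_config(seed = seed, services = services)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable labelled item set for classifier tests: categories with fully
# distinct vocabularies at noise 0.
separable_categories <- c(
  "Salad (+ or - dressing or meat)", "Pizza meal deal",
  "Alcoholic drink", "Sushi roll or bowl", "Fried chicken meal",
  "Energy drink"
)

make_training_items <- function(n, categories = separable_categories,
                                noise = 0, seed = 99L) {
  manual <- load_manual()
  withr::with_seed(seed, {
    cats <- sample(categories, n, replace = TRUE)
    txt <- mdaudit:::generate_item_texts(cats, noise_rate = noise)
  })
  scored <- score_items(txt, manual)
  dplyr::mutate(scored,
                text = stringr::str_squish(paste(name, description)))
}
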