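test_that("buffer counts match the pairwise-distance oracle", {
  sa1 <- tibble::tibble(sa1_id = "S1", centroid_x = 0, centroid_y = 0)
  expect_equal(count_outlets_in_buffer(
    sa1, tibble::tibble(x = numeric(), y = numeric()))$outlet_count, 0L)
  expect_equal(count_outlets_in_buffer(
    sa1, tibble::tibble(x = 0, y = 0))$outlet_count, 1L)
  # boundary is inclusive: distance exactly 800 counts
  expect_equal(count_outlets_in_buffer(
    sa1, tibble::tibble(x = 800, y = 0))$outlet_count, 1L)

  withr::with_seed(21, {
    sa1s <- tibble::tibble(sa1_id = sprintf("S%02d", 1:20),
                           centroid_x = runif(20, 0, 5000),
                           centroid_y = runif(20, 0, 5000))
    outlets <- tibble::tibble(x = runif(500, 0, 5000),
                              y = runif(500, 0, 5000))
  })
  got <- count_outlets_in_buffer(sa1s, outlets, radius_m = 800)$outlet_count
  ref <- integer(20)
  for (i in 1:20) {
    for (j in 1:500) {
      d <- sqrt((outlets$x[j] - sa1s$centroid_x[i])^2 +
                  (outlets$y[j] - sa1s$centroid_y[i])^2)
      if (d <= 800) ref[i] <- ref[i] + 1L
    }
  }
  expect_equal(got, ref)
})

test_that("tertiles split each city into thirds with stable tie handling", {
  df <- tibble::tibble(sa1_id = sprintf("S%d", 1:9), city = "X", v = 1:9)
  t <- assign_tertiles(df, "v", into = "tert")
  expect_equal(t$tert, rep(1:3, each = 3))

  # full tie: sizes as equal as possible, invariant to input order
  tie <- tibble::tibble(sa1_id = sprintf("S%02d", 1:10), city = "X", v = 5)
  t1 <- assign_tertiles(tie, "v", into = "tert")
  t2 <- assign_tertiles(tie[sample.int(10), ], "v", into = "tert") |>
    dplyr::arrange(sa1_id)
  expect_equal(dplyr::arrange(t1, sa1_id)$tert, t2$tert)
  expect_equal(sort(as.integer(table(t1$tert))), c(3L, 3L, 4L))

  # sort-and-split oracle on random values across cities
  withr::with_seed(31, {
    big <- tibble::tibble(sa1_id = sprintf("S%04d", 1:1000),
                          city = sample(c("X", "Y"), 1000, replace = TRUE),
                          v = round(runif(1000), 2))
  })
  got <- assign_tertiles(big, "v", into = "tert")
  for (ct in c("X", "Y")) {
    sub <- big[big$city == ct, ]
    ord <- sub$sa1_id[order(sub$v, sub$sa1_id)]
    n <- length(ord)
    sizes <- rep(n %/% 3, 3) + (1:3 <= n %% 3)
    oracle <- rep(1:3, times = sizes)
    names(oracle) <- ord
    expect_equal(got$tert[got$city == ct],
                 unname(oracle[got$sa1_id[got$city == ct]]))
  }

  expect_error(assign_tertiles(df[1:2, ], "v"), "X",
               class = "mdaudit_input_error")
})

test_that("higher-Maori flag marks the within-city top fifth, ties included", {
  df <- tibble::tibble(sa1_id = sprintf("S%02d", 1:10), city = "X",
                       maori_proportion = seq(0, 0.9, by = 0.1))
  f <- flag_high_maori(df)
  expect_equal(f$sa1_id[f$high_maori], c("S09", "S10"))

  tie <- tibble::tibble(sa1_id = sprintf("S%02d", 1:8), city = "X",
                        maori_proportion = 0.25)
  expect_true(all(flag_high_maori(tie)$high_maori))

  withr::with_seed(41, {
    big <- tibble::tibble(sa1_id = sprintf("S%03d", 1:500),
                          city = sample(c("X", "Y"), 500, replace = TRUE),
                          maori_proportion = round(runif(500), 2))
  })
  got <- flag_high_maori(big)
  for (ct in c("X", "Y")) {
    sub <- big[big$city == ct, ]
    k <- nrow(sub) %/% 5
    cutoff <- sort(sub$maori_proportion, decreasing = TRUE)[k]
    expect_equal(got$high_maori[got$city == ct],
                 sub$maori_proportion >= cutoff)
  }

  expect_error(flag_high_maori(df[1:4, ]), class = "mdaudit_input_error")
})

test_that("cell building forms the complete partition", {
  cls3 <- make_classified(c("A", "B", "C"))
  cells3 <- build_cells(cls3)
  expect_equal(nrow(cells3), 54L)
  cls1 <- make_classified("A")
  expect_equal(nrow(build_cells(cls1)), 18L)

  members <- unlist(cells3$members)
  expect_equal(sort(members), sort(cls3$sa1_id))  # union = all, no overlap
  expect_equal(anyDuplicated(members), 0L)
  expect_equal(cells3$target_n, ifelse(cells3$high_maori, 1L, 2L))

  bad <- cls3
  bad$access_tertile[3] <- NA
  expect_error(build_cells(bad), bad$sa1_id[3],
               class = "mdaudit_input_error")
})

test_that("empty cells are warned about and block sampling with a named error", {
  cls <- make_classified("A") |>
    dplyr::filter(!(high_maori & access_tertile == 2 & deprivation_tertile == 2))
  expect_warning(cells <- build_cells(cls), "A/acc2/dep2/maori")
  addr <- make_addresses(cls$sa1_id)
  expect_error(sample_frame(cells, addr, seed = 1), "A/acc2/dep2/maori",
               class = "mdaudit_empty_cell_error")
})

test_that("the complete stratified design samples 2+1 per cell pair", {
  cls <- make_classified(c("A", "B", "C"))
  cells <- build_cells(cls)
  addr <- make_addresses(cls$sa1_id)
  frame <- sample_frame(cells, addr, seed = 9)
  expect_s3_class(frame, "mda_frame")
  expect_equal(nrow(frame), 81L)                       # 54 + 27
  expect_equal(dplyr::n_distinct(frame$address_id), 81L)
  expect_equal(sum(!frame$high_maori), 54L)
  expect_equal(sum(frame$high_maori), 27L)
  # sampled addresses belong to their sampled SA1
  expect_true(all(startsWith(frame$address_id, frame$sa1_id)))
  # membership consistency: each sampled SA1 is in its cell
  chk <- dplyr::inner_join(
    frame, cls, by = c("sa1_id", "city", "access_tertile",
                       "deprivation_tertile", "high_maori"))
  expect_equal(nrow(chk), 81L)

  one <- sample_frame(build_cells(make_classified("A")),
                      make_addresses(make_classified("A")$sa1_id), seed = 9)
  expect_equal(nrow(one), 27L)                         # 9 x 2 + 9 x 1
})

test_that("sampling is deterministic and order-invariant", {
  cls <- make_classified(c("A", "B"))
  cells <- build_cells(cls)
  addr <- make_addresses(cls$sa1_id)
  f1 <- sample_frame(cells, addr, seed = 5)
  f2 <- sample_frame(cells[sample.int(nrow(cells)), ],
                     addr[sample.int(nrow(addr)), ], seed = 5)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
  f3 <- sample_frame(cells, addr, seed = 6)
  expect_false(identical(f1$sa1_id, f3$sa1_id))
})

test_that("cells holding exactly their target are sampled with certainty", {
  cls <- make_classified("A", n_per_cell = 2L) |>
    dplyr::group_by(city, access_tertile, deprivation_tertile, high_maori) |>
    dplyr::filter(!high_maori | dplyr::row_number() == 1L) |>
    dplyr::ungroup()
  cells <- build_cells(cls)
  addr <- make_addresses(cls$sa1_id)
  for (s in 1:100) {
    frame <- sample_frame(cells, addr, seed = s)
    expect_setequal(frame$sa1_id, cls$sa1_id)
  }
})
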