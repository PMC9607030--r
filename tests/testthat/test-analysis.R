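# expand per-score counts into one row per item
uncount_scores <- function(counts) {
  tidyr::uncount(counts, n) |>
    dplyr::mutate(overall = score, binary = ifelse(score >= 1, "healthy",
                                                   "unhealthy"))
}

reference_scores <- function() {
  readr::read_csv(system.file("extdata", "nz_audit_score_counts.csv",
                              package = "mdaudit"),
                  show_col_types = FALSE)
}

test_that("score distributions and unhealthy totals are recovered from counts", {
  scored <- uncount_scores(reference_scores())
  dist <- score_distribution(scored)
  expect_equal(nrow(dist), 15L)  # 3 services x 5 score levels
  ue <- dist[dist$service == "Uber Eats", ]
  expect_equal(ue$n, c(2361L, 2277L, 1114L, 1568L, 138L))
  expect_equal(round(ue$pct, 1), c(31.7, 30.5, 14.9, 21.0, 1.9))

  u <- unhealthy_share(scored)
  expect_equal(round(u$unhealthy_pct[u$service == "Uber Eats"], 1), 77.1)
  expect_equal(round(u$unhealthy_pct[u$service == "Menulog"], 1), 81.2)
  expect_equal(round(u$unhealthy_pct[u$service == "delivereasy"], 1), 72.8)

  all2 <- tibble::tibble(service = "x", overall = rep(2L, 10))
  expect_equal(unhealthy_share(all2)$unhealthy_pct, 0)
  empty <- score_distribution(tibble::tibble(service = character(),
                                             overall = integer()))
  expect_equal(nrow(empty), 0L)
})

test_that("contingency tables from synthetic data match a brute-force recount", {
  cls <- make_classified(c("A", "B"))
  frame <- sample_frame(build_cells(cls), make_addresses(cls$sa1_id), seed = 4)
  withr::with_seed(51, {
    scored <- tibble::tibble(
      address_id = sample(frame$address_id, 400, replace = TRUE),
      binary = sample(c("healthy", "unhealthy"), 400, replace = TRUE))
  })
  ct <- build_contingency(scored, frame, "deprivation")
  expect_equal(sum(ct$counts), 400)
  joined <- dplyr::left_join(scored, as.data.frame(frame), by = "address_id")
  for (b in c("healthy", "unhealthy")) {
    for (t in 1:3) {
      expect_equal(ct$counts[b, paste0("T", t)],
                   sum(joined$binary == b & joined$deprivation_tertile == t),
                   ignore_attr = TRUE)
    }
  }
  # single-level concentration
  one <- tibble::tibble(address_id = frame$address_id[1], binary = "healthy")
  ct1 <- build_contingency(one, frame, "maori")
  expect_equal(sum(ct1$counts), 1)
  expect_equal(sum(ct1$counts["healthy", ]), 1)

  expect_error(build_contingency(
    tibble::tibble(address_id = "nope", binary = "healthy"), frame, "maori"),
    "nope", class = "mdaudit_input_error")
})

test_that("the Pearson statistic matches oracles and reference results", {
  # 2x2 reference: higher-Maori vs other healthy/unhealthy split
  res <- chi_square(contingency_table(rbind(c(448, 1070), c(2250, 4308))))
  expect_equal(round(res$statistic, 4), 12.7487)
  expect_equal(round(res$p_value, 4), 4e-04)
  expect_equal(res$df, 1L)

  # proportional rows: statistic exactly 0, p = 1
  ind <- chi_square(contingency_table(rbind(c(10, 20), c(30, 60))))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)

  withr::with_seed(61, {
    for (rep in 1:20) {
      m <- matrix(rpois(6, 40) + 1L, nrow = 2)
      got <- chi_square(contingency_table(m))
      # cell-loop oracle
      e <- outer(rowSums(m), colSums(m)) / sum(m)
      stat <- 0
      for (i in 1:2) for (j in 1:3) stat <- stat + (m[i, j] - e[i, j])^2 / e[i, j]
      expect_equal(got$statistic, stat)
      expect_equal(got$df, 2L)
      # independent implementation cross-check
      ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, ref$p.value)
      # invariance under row/column permutation
      perm <- m[2:1, c(2, 3, 1)]
      expect_equal(chi_square(contingency_table(perm))$statistic, got$statistic)

      # 2x2 closed form N(ad - bc)^2 / (r1 r2 c1 c2)
      m2 <- matrix(rpois(4, 30) + 1L, nrow = 2)
      got2 <- chi_square(contingency_table(m2))
      closed <- sum(m2) * (m2[1, 1] * m2[2, 2] - m2[1, 2] * m2[2, 1])^2 /
        prod(rowSums(m2)) / prod(colSums(m2))
      expect_equal(got2$statistic, closed)
    }
  })

  expect_error(chi_square(contingency_table(rbind(c(0, 0), c(3, 4)))),
               class = "mdaudit_input_error")
  expect_error(contingency_table(rbind(c(-1, 2), c(3, 4))),
               class = "mdaudit_input_error")
})

test_that("availability quartiles follow the hinge rule and a sort oracle", {
  cls <- make_classified("A", 1L)
  frame <- sample_frame(
    build_cells(dplyr::mutate(cls, sa1_id = paste0(sa1_id, "x")) |>
                  dplyr::bind_rows(cls)),
    make_addresses(c(cls$sa1_id, paste0(cls$sa1_id, "x"))), seed = 2)

  two <- tibble::tibble(address_id = frame$address_id[1:2], n_open = c(1L, 2L))
  s <- availability_summary(two, frame, "maori")
  expect_equal(s$median[s$level == "overall"], 1.5)  # even-n midpoint rule

  const <- tibble::tibble(address_id = frame$address_id[1:4], n_open = 5L)
  sc <- availability_summary(const, frame, "deprivation")
  ov <- sc[sc$level == "overall", ]
  expect_equal(c(ov$q1, ov$median, ov$q3), c(5, 5, 5))

  withr::with_seed(71, {
    counts <- tibble::tibble(address_id = sample(frame$address_id, 200,
                                                 replace = TRUE),
                             n_open = rpois(200, 30))
  })
  counts <- dplyr::distinct(counts, address_id, .keep_all = TRUE)
  got <- availability_summary(counts, frame, "access")
  joined <- dplyr::left_join(counts, as.data.frame(frame), by = "address_id")
  hinge_oracle <- function(v) {
    # Tukey hinges by explicit sort arithmetic
    v <- sort(v); n <- length(v)
    med <- if (n %% 2) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
    half <- ceiling(n / 2)
    lower <- v[1:half]; upper <- v[(n - half + 1):n]
    mid <- function(u) {
      m <- length(u)
      if (m %% 2) u[(m + 1) / 2] else mean(u[m / 2 + 0:1])
    }
    c(mid(lower), med, mid(upper))
  }
  for (t in 1:3) {
    v <- joined$n_open[joined$access_tertile == t]
    row <- got[got$level == paste0("T", t), ]
    expect_equal(c(row$q1, row$median, row$q3), hinge_oracle(v))
    expect_equal(row$n, length(v))
    expect_true(row$q1 <= row$median && row$median <= row$q3)
  }

  # empty level: n = 0, null quartiles
  sub <- dplyr::filter(counts,
                       address_id %in% joined$address_id[
                         joined$access_tertile != 2])
  se <- availability_summary(sub, frame, "access")
  expect_equal(se$n[se$level == "T2"], 0L)
  expect_true(is.na(se$median[se$level == "T2"]))

  # linear interpolation override matches quantile type 7
  lin <- availability_summary(counts, frame, "access", rule = "linear")
  ovl <- lin[lin$level == "overall", ]
  expect_equal(c(ovl$q1, ovl$median, ovl$q3),
               unname(quantile(joined$n_open, c(0.25, 0.5, 0.75), type = 7)))
})
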