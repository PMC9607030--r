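#' Configuration for an end-to-end audit run
#'
#' Bundles the stage configurations and derives per-stage seeds from one
#' master seed (geography: seed; frame sampling: seed + 1; snapshots:
#' seed + 2; classifier: seed + 3).
#'
#' @param seed Master integer seed.
#' @param geo A [geo_config()]; its seed is overridden by `seed`.
#' @param menu A [menu_config()]; its seed is overridden by `seed + 2`.
#' @param manual_path Path to a classification-manual CSV; `NULL` for the
#'   bundled manual. Checked up front so a bad path fails before any compute.
#' @param scorer `"truth"` scores items through their ground-truth category
#'   labels and the manual; `"classifier"` additionally trains the text
#'   classifier on a manual-scored sample and scores items from text.
#' @param training_n Training-sample size for the classifier path.
#' @param classifier A [classifier_spec()] for the classifier path.
#' @param max_outlets,max_items Observation window for [truncate_window()].
#'
#' @return An `audit_config` list.
#' @export
audit_config <- function(seed = 1L,
                         geo = geo_config(),
                         menu = menu_config(),
                         manual_path = NULL,
                         scorer = c("truth", "classifier"),
                         training_n = 2000L,
                         classifier = classifier_spec(),
                         max_outlets = 10L, max_items = 10L) {
  seed <- assert_count(seed, "seed", min = 0L)
  if (seed > 2^31 - 10) {
    abort("`seed` too large; stage seeds are derived as seed + 0..3.",
          class = "mdaudit_config_error")
  }
  if (!is.null(manual_path) && !file.exists(manual_path)) {
    abort(sprintf("Manual path does not exist: '%s'.", manual_path),
          class = "mdaudit_config_error")
  }
  geo$seed <- seed
  menu$seed <- seed + 2L
  structure(
    list(seed = seed, geo = geo, menu = menu, manual_path = manual_path,
         scorer = match.arg(scorer), training_n = training_n,
         classifier = classifier,
         max_outlets = assert_count(max_outlets, "max_outlets"),
         max_items = assert_count(max_items, "max_items")),
    class = "audit_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "mdaudit_stage_error", parent = e)
  })
}

#' Run the full audit pipeline
#'
#' simulate geography -> classify and build cells -> sample the address
#' frame -> simulate snapshots -> truncate the observation window -> score
#' items (ground-truth manual lookup, or trained text classifier) -> analyse
#' (score distributions, chi-square tests of healthy/unhealthy proportions by
#' stratum, outlet-availability quartiles). Identical configs give identical
#' result bundles; the manifest records seeds, record counts and content
#' hashes of the key tables.
#'
#' @param config An [audit_config()].
#'
#' @return An object of class `mda_audit`: a list with the frame, snapshots,
#'   scored items, result surfaces (`distribution`, `unhealthy`,
#'   `chi_tests`, `availability`), coverage gaps, and `manifest`.
#' @export
run_audit <- function(config = audit_config()) {
  if (!inherits(config, "audit_config")) {
    abort("`config` must come from audit_config().",
          class = "mdaudit_config_error")
  }
  manual <- run_stage("load-manual", load_manual(config$manual_path))
  geo <- run_stage("simulate-geography", simulate_geography(config$geo))
  classified <- run_stage("classify-sa1s", classify_sa1s(geo))
  cells <- run_stage("build-cells", build_cells(classified))
  frame <- run_stage("sample-frame",
                     sample_frame(cells, geo$addresses, seed = config$seed + 1L))
  snapshots <- run_stage("simulate-snapshots",
                         simulate_snapshots(frame, config$menu))
  open_counts <- run_stage("count-open-outlets", count_open_outlets(snapshots))
  window <- run_stage("truncate-window",
                      truncate_window(snapshots, config$max_outlets,
                                      config$max_items))
  scored <- run_stage("score-items", {
    truth_scored <- score_items(window$items, manual)
    if (config$scorer == "classifier") {
      ts <- sample_training(truth_scored, n = min(config$training_n,
                                                  nrow(truth_scored)),
                            seed = config$seed + 3L)
      model <- train_classifier(ts, config$classifier)
      pred <- predict(model, window$items)
      attr(pred, "model") <- model
      pred
    } else {
      truth_scored
    }
  })

  chi_tests <- run_stage("chi-square-tests", {
    tidyr::expand_grid(service = unique(scored$service),
                       factor = c("deprivation", "access", "maori")) %>%
      purrr::pmap(function(service, factor) {
        ct <- build_contingency(filter(scored, .data$service == !!service),
                                frame, factor, service = service)
        res <- chi_square(ct)
        tibble(service = service, factor = ct$factor_name,
               statistic = res$statistic, df = res$df,
               p_value = res$p_value,
               significant = res$p_value < 0.05)
      }) %>% bind_rows()
  })
  availability <- run_stage("availability-summary", {
    tidyr::expand_grid(service = unique(open_counts$service),
                       factor = c("deprivation", "access", "maori")) %>%
      purrr::pmap(function(service, factor) {
        availability_summary(filter(open_counts, .data$service == !!service),
                             frame, factor) %>%
          mutate(service = service, factor = factor, .before = 1)
      }) %>% bind_rows()
  })
  gaps <- attr(snapshots, "coverage_gaps")

  manifest <- list(
    package_version = as.character(utils::packageVersion("mdaudit")),
    seed = config$seed,
    stage_seeds = c(geography = config$seed, frame = config$seed + 1L,
                    snapshots = config$seed + 2L,
                    classifier = config$seed + 3L),
    scorer = config$scorer,
    n = c(sa1 = nrow(geo$sa1), cells = nrow(cells), sampled_sa1 = nrow(frame),
          snapshots = nrow(snapshots$snapshots),
          coverage_gaps = nrow(gaps), items_scored = nrow(scored)),
    digests = c(frame = rlang::hash(as_tibble(frame)),
                items = rlang::hash(window$items),
                scored = rlang::hash(scored))
  )

  structure(
    list(config = config, cells = cells, frame = frame,
         snapshots = snapshots, window = window, open_counts = open_counts,
         scored = scored,
         distribution = score_distribution(scored),
         unhealthy = unhealthy_share(scored),
         chi_tests = chi_tests, availability = availability,
         coverage_gaps = gaps, manifest = manifest),
    class = "mda_audit"
  )
}

#' @export
print.mda_audit <- function(x, ...) {
  cat(sprintf(
    "<mda_audit> seed %d: %d sampled SA1s, %d snapshots (%d coverage gaps), %d scored items\n",
    x$manifest$seed, nrow(x$frame), nrow(x$snapshots$snapshots),
    nrow(x$coverage_gaps), nrow(x$scored)))
  invisible(x)
}

#' Render an audit bundle as a markdown report
#'
#' Three result surfaces -- the per-service score distribution, the
#' outlet-availability quartiles and the chi-square tests (statistic, df,
#' p-value and the alpha = 0.05 decision as a labelled column) -- as a
#' markdown character vector.
#'
#' @param results An `mda_audit` from [run_audit()].
#' @return Character vector of markdown lines, invisibly printable with
#'   `cat(..., sep = "\n")`.
#' @export
report_markdown <- function(results) {
  needed <- c("distribution", "unhealthy", "chi_tests", "availability")
  missing <- needed[!purrr::map_lgl(results[needed],
                                    function(x) !is.null(x) && nrow(x) > 0)]
  if (length(missing)) {
    abort(sprintf("Incomplete results bundle; missing surface(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "mdaudit_input_error")
  }
  md <- c("# MDA audit report", "")
  md <- c(md, "## Menu items by healthiness score", "",
          "| service | score | n | % |", "|---|---|---|---|",
          sprintf("| %s | %d | %d | %.1f |",
                  results$distribution$service, results$distribution$score,
                  results$distribution$n, results$distribution$pct),
          "",
          sprintf("* Unhealthy total (score <= 0): %s",
                  paste(sprintf("%s %.1f%%", results$unhealthy$service,
                                results$unhealthy$unhealthy_pct),
                        collapse = "; ")),
          "")
  md <- c(md, "## Available outlets by stratum (median, Q1, Q3)", "",
          "| service | factor | level | n | Q1 | median | Q3 |",
          "|---|---|---|---|---|---|---|",
          sprintf("| %s | %s | %s | %d | %.2f | %.2f | %.2f |",
                  results$availability$service, results$availability$factor,
                  results$availability$level, results$availability$n,
                  results$availability$q1, results$availability$median,
                  results$availability$q3),
          "")
  md <- c(md, "## Chi-square tests of healthy/unhealthy proportions", "",
          "| service | factor | statistic | df | p | significant (alpha = 0.05) |",
          "|---|---|---|---|---|---|",
          sprintf("| %s | %s | %.4f | %d | %.4g | %s |",
                  results$chi_tests$service, results$chi_tests$factor,
                  results$chi_tests$statistic, results$chi_tests$df,
                  results$chi_tests$p_value,
                  ifelse(results$chi_tests$significant, "yes", "no")))
  md
}

#' Write the result surfaces of an audit bundle to disk
#'
#' CSV mirrors of the three table surfaces plus a JSON manifest.
#'
#' @param results An `mda_audit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(results$distribution, file.path(dir, "score_distribution.csv"))
  readr::write_csv(results$unhealthy, file.path(dir, "unhealthy_share.csv"))
  readr::write_csv(results$chi_tests, file.path(dir, "chi_square_tests.csv"))
  readr::write_csv(results$availability, file.path(dir, "availability.csv"))
  readr::write_csv(results$coverage_gaps, file.path(dir, "coverage_gaps.csv"))
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report_markdown(results), file.path(dir, "report.md"))
  invisible(dir)
}
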