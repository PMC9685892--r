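fake_rules <- function(n = 10, orders = NULL, seed = 1) {
  set.seed(seed)
  orders <- orders %||% sample(1:4, n, TRUE)
  items <- lapply(seq_len(n), function(i)
    sort(sprintf("cm_Item%02d", sample(50, orders[i]))))
  df <- data.frame(order = orders,
                   antecedent = vapply(items, paste, character(1),
                                       collapse = " & "),
                   n_antecedent = sample(25:500, n, TRUE),
                   stringsAsFactors = FALSE)
  df$items <- I(items)
  df$n_both <- rbinom(n, df$n_antecedent, 0.3)
  df$coverage <- df$n_antecedent / 1000
  df$confidence <- df$n_both / df$n_antecedent
  df$aor <- exp(rnorm(n))
  structure(df, N = 1000, D = 120, baseline = 0.12,
            class = c("rule_set", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rules rank descending by the key within each order", {
  df <- fake_rules(2, orders = c(1, 1))
  df$aor <- c(13.09, 13.01)
  df$antecedent <- c("pdx_Cardiac.Arrest", "dx_Encounter.for.counseling")
  ranked <- rank_rules(df, report_spec("aor"))
  expect_equal(ranked$aor, c(13.09, 13.01))

  one <- rank_rules(df[1, ], report_spec("aor"))
  expect_equal(nrow(one), 1)

  big <- fake_rules(100, seed = 12)
  ranked <- rank_rules(big, report_spec("confidence", top_k = 1000))
  for (k in unique(big$order)) {
    keyed <- big$confidence[big$order == k]
    expect_equal(ranked$confidence[ranked$order == k],
                 sort(keyed, decreasing = TRUE))
  }
  expect_error(rank_rules(big[, setdiff(names(big), "aor")],
                          report_spec("aor")), "not present")
})

test_that("report rows never exceed top_k per order and ties break lexicographically", {
  df <- fake_rules(60, seed = 3)
  ranked <- rank_rules(df, report_spec("antecedent_count", top_k = 5))
  expect_lte(nrow(ranked), 5 * 4)
  expect_true(all(table(ranked$order) <= 5))

  tie <- fake_rules(3, orders = c(1, 1, 1), seed = 4)
  tie$n_antecedent <- c(100L, 100L, 100L)
  tie$antecedent <- c("b", "a", "c")
  ranked <- rank_rules(tie, report_spec("antecedent_count"))
  expect_equal(ranked$antecedent, c("a", "b", "c"))
})

test_that("written reports round-trip at the declared display precision", {
  df <- fake_rules(8, seed = 6)
  ranked <- rank_rules(df, report_spec("confidence", top_k = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(ranked, path, "csv", report_spec("confidence"),
               meta = list(seed = 1))
  back <- read_report_csv(path)
  expect_equal(nrow(back), nrow(ranked))
  expect_equal(back$confidence_pct, round(100 * ranked$confidence, 1))
  expect_equal(back$antecedent, ranked$antecedent)
  expect_true(any(grepl("seed", attr(back, "meta"))))
  # full-precision companion carries unrounded values
  full <- jsonlite::fromJSON(paste0(path, ".full.json"))
  expect_equal(full$rows$confidence, ranked$confidence, tolerance = 1e-12)
})

test_that("markdown and empty reports are well-formed", {
  df <- fake_rules(3, orders = c(1, 2, 3), seed = 8)
  path <- withr::local_tempfile(fileext = ".md")
  write_report(rank_rules(df, report_spec("confidence")), path, "markdown")
  lines <- readLines(path)
  body <- grep("^\\| ", lines, value = TRUE)
  expect_equal(length(body), 3 + 1)   # header row + 3 rules

  empty <- df[0, ]
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(empty, csv, "csv")
  back <- read_report_csv(csv)
  expect_equal(nrow(back), 0)
})

test_that("published totals give the 11.7% baseline and the lift identity holds", {
  tb <- published_tables()
  bm <- baseline_mortality(tb)
  expect_equal(bm$deaths, 1041)
  expect_equal(bm$patients, 8893)
  expect_equal(bm$percent, 11.7)

  li <- check_lift_identity(tb)
  expect_true(all(li$status %in% c("match", "boundary", "mismatch")))
  expect_gt(mean(li$status == "match"), 0.5)
})

test_that("the pipeline runs end to end, deterministically, from a config list", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(simulate = list(n_patients = 700, seed = 202),
              mining = list(min_count = 10, max_order = 3),
              filter = list(min_improvement = 10),
              report = list(top_k = 5, estimate_top = 3))
  res1 <- suppressMessages(run_pipeline(cfg, out1))
  res2 <- suppressMessages(run_pipeline(cfg, out2))
  expect_true(file.exists(res1$paths$rules))
  expect_true(file.exists(res1$paths$prevalence))
  expect_true(file.exists(res1$paths$mortality))
  expect_identical(readLines(res1$paths$rules), readLines(res2$paths$rules))
  expect_identical(readLines(res1$paths$mortality),
                   readLines(res2$paths$mortality))
  expect_lte(nrow(res1$ranked_aor), 5 * 4)
  # mined rules all meet the support floor
  expect_true(all(res1$rules$n_antecedent >= 10))
})

test_that("pipeline configuration errors are stage-labeled", {
  expect_error(suppressMessages(run_pipeline(list(), withr::local_tempdir())),
               "stage 'map'")
  bad <- list(simulate = list(n_patients = 50, seed = 1,
                              config = "/nonexistent.yaml"))
  expect_error(
    suppressWarnings(suppressMessages(run_pipeline(bad,
                                                   withr::local_tempdir()))),
    "stage 'simulate'")
})

test_that("mine-only mode consumes a provided indicator CSV", {
  set.seed(77)
  m <- random_indicator_matrix(300, 6, 0.4, 0.25)
  m$covariates <- data.frame(age = sample(21:90, 300, TRUE),
                             sex = sample(c("Male", "Female"), 300, TRUE),
                             race = "White")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_indicators(m, csv)
  res <- suppressMessages(run_pipeline(
    list(indicators = csv,
         mining = list(min_count = 10, max_order = 2),
         filter = list(min_improvement = 0),
         report = list(top_k = 3, estimate_top = 2)),
    withr::local_tempdir()))
  expect_gt(nrow(res$rules), 0)
  expect_equal(res$matrix$N, 300)
})
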