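test_that("mapping tables validate their closed vocabularies", {
  df <- data.frame(code = "I10", code_system = "icd10",
                   concept = "Essential.Hypertension", subcategory = "cm")
  expect_s3_class(mapping_table(df), "mapping_table")

  bad <- df; bad$subcategory <- "comorbid"
  expect_error(mapping_table(bad), "comorbid")
  expect_error(mapping_table(bad), "pdx, pl, dx, cm, hx, ddx")

  dup <- rbind(df, df)
  expect_error(mapping_table(dup), "duplicate")

  expect_error(mapping_table(df[, -1]), "missing required column")
})

test_that("load_mapping reads a generated file and keeps all unique rows", {
  n <- 1000
  df <- data.frame(code = sprintf("Z%04d", seq_len(n)),
                   code_system = rep(c("icd9", "icd10"), length.out = n),
                   concept = sprintf("Concept%04d", seq_len(n)),
                   subcategory = rep(c("pdx", "pl", "dx", "cm", "hx", "ddx"),
                                     length.out = n))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tab <- load_mapping(path)
  expect_equal(nrow(tab), n)
  expect_false(anyDuplicated(paste(tab$code, tab$code_system,
                                   tab$subcategory)) > 0)
})

test_that("records map to prefixed items with set semantics", {
  mapping <- mapping_table(data.frame(
    code = c("I10", "I48.91", "I48.91"),
    code_system = "icd10",
    concept = c("Essential.Hypertension", "Atrial.Fibrillation",
                "Atrial.Fibrillation"),
    subcategory = c("cm", "pl", "cm")))
  records <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2"),
    code = c("I10", "i10 ", "I48.91", "I48.91"),
    code_system = "icd10",
    source = c("clinical", "administrative", "clinical", "clinical"),
    phase = c("referring", "receiving", "receiving", "receiving"))
  res <- map_records(records, mapping)
  # duplicate I10 collapses; the dual-subcategory code emits two items
  expect_equal(res$items$p1, sort(c("cm_Essential.Hypertension",
                                    "cm_Atrial.Fibrillation",
                                    "pl_Atrial.Fibrillation")))
  expect_equal(res$items$p2, sort(c("cm_Atrial.Fibrillation",
                                    "pl_Atrial.Fibrillation")))
  expect_equal(res$n_unmapped, 0)
})

test_that("empty record streams yield empty item sets and report", {
  res <- map_records(data.frame(patient_id = character(0),
                                code = character(0),
                                code_system = character(0)),
                     tiny_mapping())
  expect_length(res$items, 0)
  expect_equal(nrow(res$report), 0)
  expect_equal(res$n_records, 0)
})

test_that("unmapped records are counted, reported and warned about", {
  mapping <- tiny_mapping()
  records <- data.frame(patient_id = c("p1", "p1", "p2"),
                        code = c("T01.1", "QQQ", "QQQ"),
                        code_system = "icd10")
  expect_warning(res <- map_records(records, mapping), "matched no mapping row")
  expect_equal(res$n_mapped + res$n_unmapped, nrow(records))
  expect_equal(res$report$code, "QQQ")
  expect_equal(res$report$n_records, 2)
  # under a permissive threshold no warning is raised
  expect_no_warning(map_records(records, mapping,
                                unmapped_warn_threshold = 0.9))
})

test_that("single-category mode honors precedence", {
  mapping <- mapping_table(data.frame(
    code = "I48.91", code_system = "icd10",
    concept = "Atrial.Fibrillation",
    subcategory = c("pl", "cm"), precedence = c(2, 1)))
  records <- data.frame(patient_id = "p1", code = "I48.91",
                        code_system = "icd10")
  both <- map_records(records, mapping)
  expect_length(both$items$p1, 2)
  one <- map_records(records, mapping, single_category = TRUE)
  expect_equal(one$items$p1, "cm_Atrial.Fibrillation")
})

test_that("indicator matrices are built with lexicographic columns and cached totals", {
  demo <- data.frame(patient_id = c("p1", "p2"), died = c(1, 0),
                     age = c(70, 50), sex = c("Male", "Female"),
                     race = c("White", "Black"))
  m <- build_indicators(list(p1 = "A", p2 = c("B", "A")), demo)
  expect_equal(unname(m$items), matrix(c(1L, 1L, 0L, 1L), 2))
  expect_equal(colnames(m$items), c("A", "B"))
  expect_equal(m$N, 2)
  expect_equal(m$D, 1)

  # item-free patients are retained with all-zero rows
  m0 <- build_indicators(structure(list(), names = character(0)), demo)
  expect_equal(ncol(m0$items), 0)
  expect_equal(m0$N, 2)
  expect_equal(m0$D, 1)

  expect_error(build_indicators(list(p3 = "A"), demo), "p3")
})

test_that("mapping is idempotent and conserves record counts", {
  mapping <- tiny_mapping()
  set.seed(5)
  codes <- c(mapping$code, "NOPE1", "NOPE2")
  records <- data.frame(
    patient_id = sample(sprintf("p%02d", 1:20), 200, TRUE),
    code = sample(codes, 200, TRUE),
    code_system = "icd10")
  demo <- data.frame(patient_id = sprintf("p%02d", 1:20),
                     died = rbinom(20, 1, 0.2))
  r1 <- suppressWarnings(map_records(records, mapping))
  r2 <- suppressWarnings(map_records(records, mapping))
  expect_identical(r1, r2)
  expect_equal(r1$n_mapped + r1$n_unmapped, 200)
  m1 <- build_indicators(r1$items, demo)
  m2 <- build_indicators(r2$items, demo)
  expect_identical(m1$items, m2$items)
})

test_that("the same concept in two subcategories yields two distinct columns", {
  mapping <- mapping_table(data.frame(
    code = c("J96.0", "J96.0"), code_system = "icd10",
    concept = "Acute.respiratory.failure", subcategory = c("pl", "ddx")))
  records <- data.frame(patient_id = "p1", code = "J96.0",
                        code_system = "icd10")
  res <- map_records(records, mapping)
  demo <- data.frame(patient_id = "p1", died = 0)
  m <- build_indicators(res$items, demo)
  expect_equal(colnames(m$items),
               c("ddx_Acute.respiratory.failure",
                 "pl_Acute.respiratory.failure"))
})

test_that("indicator CSV round trip preserves the matrix", {
  set.seed(9)
  m <- random_indicator_matrix(30, 5)
  m$covariates <- data.frame(age = sample(21:90, 30, TRUE),
                             sex = sample(c("Male", "Female"), 30, TRUE),
                             race = sample(c("White", "Black"), 30, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_indicators(m, path)
  m2 <- read_indicators(path)
  expect_equal(unname(m2$items), unname(m$items))
  expect_equal(m2$died, m$died)
  expect_equal(m2$covariates$age, m$covariates$age)
})
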