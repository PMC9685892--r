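test_that("configuration invariants are enforced", {
  expect_error(tiny_config(sex_probs = c(Male = 0.6, Female = 0.5)),
               "sum to 1")
  bad_cat <- tiny_catalog()
  bad_cat$subcategory[1] <- "primary"
  expect_error(sim_config(10, 1, item_catalog = bad_cat), "one of")
  dup_cat <- rbind(tiny_catalog(), tiny_catalog()[1, ])
  expect_error(sim_config(10, 1, item_catalog = dup_cat), "unique")
  expect_error(
    tiny_config(planted_interactions = list(list(items = "cm_Acidosis",
                                                 gamma = 1))),
    "size 2-4")
  expect_error(
    tiny_config(planted_interactions = list(list(items = c("cm_Nope",
                                                           "pdx_Cardiac.Arrest"),
                                                 gamma = 1))),
    "unknown item")
  expect_error(sim_config(10, 1, item_catalog = tiny_catalog()[0, ]),
               "empty")
})

test_that("intercept calibration recovers closed-form logits with null effects", {
  cat0 <- tiny_catalog()
  cat0$outcome_effect <- 0
  cfg50 <- sim_config(10, 1, item_catalog = cat0, target_mortality = 0.5)
  b0 <- calibrate_intercept(cfg50, n_probe = 10000)
  expect_equal(as.numeric(b0), 0, tolerance = 1e-6)

  cfg117 <- sim_config(10, 1, item_catalog = cat0, target_mortality = 0.117)
  b1 <- calibrate_intercept(cfg117, n_probe = 10000)
  expect_equal(as.numeric(b1), log(0.117 / 0.883), tolerance = 1e-6)
  expect_equal(attr(b1, "achieved_rate"), 0.117, tolerance = 1e-9)

  expect_error(calibrate_intercept(cfg117, n_probe = 100), "10,000")
})

test_that("cohorts are bit-identical under the same config and seed", {
  cfg <- tiny_config(n = 800, seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(tiny_config(n = 800, seed = 124))
  expect_false(identical(c1$demographics$died, c3$demographics$died))
})

test_that("cohort structure honors its invariants", {
  cfg <- tiny_config(n = 3000, seed = 5)
  co <- generate_cohort(cfg)
  d <- co$demographics
  expect_true(all(d$age >= 21 & d$age <= 90))
  expect_true(all(d$disposition[d$died == 1] == "Died"))
  expect_true(all(d$disposition[d$died == 0] != "Died"))
  expect_true(all(co$items %in% c(0L, 1L)))
  expect_equal(colnames(co$items), cfg$catalog$item)
  expect_match(co$config_hash, "^[0-9a-f]{16}$")
})

test_that("an empty cohort is valid and a zero-item patient keeps demographics", {
  cfg0 <- tiny_config(n = 0)
  co0 <- generate_cohort(cfg0)
  expect_equal(nrow(co0$demographics), 0)
  expect_equal(nrow(co0$items), 0)

  cfg <- tiny_config(n = 300, seed = 9)
  co <- generate_cohort(cfg)
  rt <- cohort_to_records(co, tiny_mapping())
  zero_item <- rownames(co$items)[rowSums(co$items) == 0]
  if (length(zero_item)) {
    expect_false(any(rt$records$patient_id %in% zero_item))
    expect_true(all(zero_item %in% rt$demographics$patient_id))
  }
  expect_equal(nrow(rt$records), sum(co$items))
})

test_that("record emission round-trips to the exact cohort item matrix", {
  cfg <- tiny_config(n = 1200, seed = 31)
  co <- generate_cohort(cfg)
  mapping <- tiny_mapping()
  rt <- cohort_to_records(co, mapping)
  expect_true(all(rt$records$source %in% c("clinical", "administrative")))
  expect_true(all(rt$records$phase %in% c("referring", "receiving")))
  mapped <- map_records(rt$records, mapping)
  m <- build_indicators(mapped$items, rt$demographics)
  expect_equal(m$items[rownames(co$items), colnames(co$items)],
               co$items)
  expect_equal(m$D, sum(co$demographics$died))
})

test_that("a single-item patient round-trips through one record", {
  cfg <- tiny_config(n = 50, seed = 2)
  co <- generate_cohort(cfg)
  one <- which(rowSums(co$items) == 1)[1]
  expect_false(is.na(one))   # this draw contains a single-item patient
  pid <- rownames(co$items)[one]
  rt <- cohort_to_records(co, tiny_mapping())
  rec <- rt$records[rt$records$patient_id == pid, ]
  expect_equal(nrow(rec), 1)
  mapped <- map_records(rec, tiny_mapping())
  expect_equal(mapped$items[[pid]],
               colnames(co$items)[co$items[one, ] == 1])
})

test_that("unmapped catalog concepts abort record emission with a listing", {
  cfg <- tiny_config(n = 100, seed = 3)
  co <- generate_cohort(cfg)
  partial <- tiny_mapping(tiny_catalog()[-1, ])
  expect_error(cohort_to_records(co, partial), "pdx_Cardiac.Arrest")
})

test_that("mortality calibration and age skew hold in a large cohort", {
  cfg <- tiny_config(n = 50000, seed = 40)
  co <- generate_cohort(cfg)
  d <- co$demographics
  expect_lt(abs(mean(d$died) - 0.117), 0.01)
  # positive per-decade age effect implies the dead skew older
  expect_gt(mean(d$age[d$died == 1]), mean(d$age[d$died == 0]))
  # model-implied and empirical mortality agree
  expect_equal(mean(co$p_death), 0.117, tolerance = 1e-6)
})

test_that("planted interactions hit their target carrier mortality", {
  cfg <- tiny_config(
    n = 50000, seed = 88,
    planted_interactions = list(list(
      items = c("cm_Acidosis", "pdx_Cardiac.Arrest"),
      target_carrier_mortality = 0.72)))
  co <- generate_cohort(cfg)
  carrier <- rowSums(co$items[, c("cm_Acidosis", "pdx_Cardiac.Arrest")]) == 2
  expect_gt(sum(carrier), 50)
  model_mean <- mean(co$p_death[carrier])
  expect_equal(model_mean, 0.72, tolerance = 0.01)
  emp <- mean(co$demographics$died[carrier])
  mc_se <- sqrt(model_mean * (1 - model_mean) / sum(carrier))
  expect_lt(abs(emp - model_mean), 3 * mc_se + 1e-12)
})

test_that("shared burden loadings induce positive co-occurrence", {
  cfg <- tiny_config(n = 50000, seed = 61)
  co <- generate_cohort(cfg)
  x <- co$items
  prev <- colMeans(x)
  pairs <- list(c("cm_Acidosis", "pl_Acute.respiratory.failure"),
                c("pl_Hypotension", "pl_Acute.respiratory.failure"),
                c("cm_Acidosis", "pdx_Cardiac.Arrest"))
  for (p in pairs) {
    obs <- mean(x[, p[1]] == 1 & x[, p[2]] == 1)
    expect_gt(obs / (prev[[p[1]]] * prev[[p[2]]]), 1)
  }
})

test_that("calibrated defaults track the published subcategory mean counts", {
  cfg <- default_sim_config(n_patients = 20000, seed = 15)
  co <- generate_cohort(cfg)
  counts <- tapply(colSums(co$items) / nrow(co$items),
                   sub("_.*", "", colnames(co$items)), sum)
  target <- c(pdx = 3, pl = 5, dx = 8, cm = 6, hx = 2, ddx = 1)
  for (s in names(target))
    expect_lt(abs(counts[[s]] - target[[s]]) / target[[s]], 0.15)
})
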