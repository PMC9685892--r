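# shared in-code fixtures: tiny catalogs, matrices and mapping tables

tiny_catalog <- function() {
  data.frame(
    name = c("Cardiac.Arrest", "Hypotension", "Acute.respiratory.failure",
             "Essential.Hypertension", "Acidosis", "Coagulopathy",
             "Atrial.Fibrillation", "DNR"),
    subcategory = c("pdx", "pl", "pl", "cm", "cm", "hx", "ddx", "ddx"),
    prevalence = c(0.05, 0.10, 0.15, 0.50, 0.20, 0.05, 0.08, 0.03),
    loading = c(0.8, 0.5, 0.6, 0.4, 0.8, 0.3, 0.4, 0.2),
    age_loading = c(0, 0, 0, 0.3, 0, 0, 0.2, 0),
    outcome_effect = c(2.0, 0.6, 0.9, 0.1, 0.6, 0.8, 0.2, 2.5),
    stringsAsFactors = FALSE)
}

tiny_config <- function(n = 2000, seed = 11, catalog = tiny_catalog(),
                        covariate_effects = list(
                          age_per_decade = 0.4,
                          sex = c(Male = 0, Female = 0.15),
                          race = c(White = 0, Black = 0, Other = 0)), ...) {
  sim_config(n_patients = n, seed = seed,
             item_catalog = catalog,
             covariate_effects = covariate_effects,
             target_mortality = 0.117, ...)
}

tiny_mapping <- function(catalog = tiny_catalog()) {
  mapping_table(data.frame(
    code = sprintf("T%02d.1", seq_len(nrow(catalog))),
    code_system = "icd10",
    concept = catalog$name,
    subcategory = catalog$subcategory,
    stringsAsFactors = FALSE))
}

random_indicator_matrix <- function(n, m, p = 0.3, death_p = 0.2) {
  x <- matrix(rbinom(n * m, 1, p), n, m,
              dimnames = list(NULL, sprintf("it%02d", seq_len(m))))
  indicator_matrix(x, rbinom(n, 1, death_p))
}

# independent re-evaluation of the minimum-improvement criterion by direct
# enumeration of the full subset lattice (test oracle)
brute_force_improvement <- function(rules, baseline) {
  key <- vapply(rules$items, function(v) paste(sort(v), collapse = "|"),
                character(1))
  out <- numeric(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    its <- rules$items[[i]]
    best <- baseline
    if (length(its) > 1) {
      for (s in seq_len(length(its) - 1)) {
        for (cc in as.data.frame(combn(its, s), stringsAsFactors = FALSE)) {
          j <- match(paste(sort(cc), collapse = "|"), key)
          if (!is.na(j)) best <- max(best, rules$confidence[j])
        }
      }
    }
    out[i] <- 100 * (rules$confidence[i] - best)
  }
  out
}

expect_same_itemsets <- function(a, b) {
  expect_equal(a$antecedent, b$antecedent)
  expect_equal(a$n_antecedent, b$n_antecedent)
  expect_equal(a$n_both, b$n_both)
}
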