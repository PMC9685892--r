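#' Simulation configuration for synthetic transfer cohorts
#'
#' Defines a seeded generative model for an adult interhospital-transfer
#' cohort: demographics with published-table-like marginals, a catalog of
#' diagnosis indicator items spread over the six subcategories, a logistic
#' in-hospital mortality model with item main effects, age/sex/race
#' effects and planted high-risk item interactions.
#'
#' Item presence is Bernoulli with log-odds
#' `base + loading * burden + age_loading * (age - age_mean)/10`, where
#' `burden` is a single standard-normal latent severity factor per patient.
#' Positive loadings induce the positive co-occurrence of comorbid
#' conditions seen in real cohorts; age loadings let comorbidities
#' accumulate with age. `base` is solved numerically at construction so
#' each item's marginal prevalence matches its configured target.
#'
#' Planted interactions add `gamma` to the death log-odds of patients
#' carrying all items of the set; alternatively a
#' `target_carrier_mortality` may be given, in which case `gamma` is solved
#' at generation time (jointly with the intercept) so that the
#' model-implied mortality among carriers equals the target.
#'
#' @param n_patients cohort size (>= 0).
#' @param seed integer RNG seed.
#' @param age list with `mean`, `sd` (years), `min` (default 21) and
#'   `top_code` (default 90; ages are top-coded there, mirroring
#'   deidentified data releases).
#' @param sex_probs,race_probs named probability vectors (must sum to 1
#'   within 1e-9).
#' @param item_catalog data frame with columns `name`, `subcategory`
#'   (one of pdx/pl/dx/cm/hx/ddx), `prevalence` (0-1), `loading` (>= 0),
#'   and optionally `age_loading` (log-odds per decade) and
#'   `outcome_effect` (log-odds increment on death).
#' @param covariate_effects list with `age_per_decade` and named numeric
#'   vectors `sex` and `race` (log-odds offsets; reference levels 0).
#' @param planted_interactions list of lists, each with `items` (2-4
#'   prefixed item names from the catalog) and either `gamma` or
#'   `target_carrier_mortality`.
#' @param target_mortality overall in-hospital mortality proportion the
#'   intercept is calibrated to.
#' @param disposition_survivors named non-negative weights for survivor
#'   discharge dispositions (renormalized internally).
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_patients, seed,
                       age = list(mean = 63.5, sd = 14.3, min = 21,
                                  top_code = 90),
                       sex_probs = c(Male = 0.5347, Female = 0.4653),
                       race_probs = c(White = 0.7344, Black = 0.2219,
                                      Other = 0.0437),
                       item_catalog,
                       covariate_effects = list(age_per_decade = 0,
                                                sex = NULL, race = NULL),
                       planted_interactions = list(),
                       target_mortality = 0.117,
                       disposition_survivors = c(Home = 4683,
                                                 `Home care` = 828,
                                                 `Nursing facility` = 1566,
                                                 `Other facility` = 677,
                                                 Other = 98)) {
  assert_that(is.numeric(n_patients) && n_patients >= 0 &&
                n_patients == round(n_patients),
              "n_patients must be a non-negative integer")
  assert_that(target_mortality > 0 && target_mortality < 1,
              "target_mortality must be in (0, 1)")
  for (nm in c("sex_probs", "race_probs")) {
    p <- get(nm)
    assert_that(abs(sum(p) - 1) < 1e-9,
                paste(nm, "must sum to 1 within 1e-9"))
    assert_that(all(p >= 0), paste(nm, "must be non-negative"))
  }
  cat <- as.data.frame(item_catalog, stringsAsFactors = FALSE)
  assert_that(nrow(cat) > 0, "item catalog must not be empty")
  assert_that(all(c("name", "subcategory", "prevalence", "loading") %in%
                    names(cat)),
              "item catalog needs columns name, subcategory, prevalence, loading")
  assert_that(all(cat$subcategory %in% SUBCATEGORIES),
              paste("item subcategory must be one of:",
                    paste(SUBCATEGORIES, collapse = ", ")))
  if (is.null(cat$age_loading)) cat$age_loading <- 0
  if (is.null(cat$outcome_effect)) cat$outcome_effect <- 0
  cat$item <- paste0(cat$subcategory, "_", cat$name)
  assert_that(!anyDuplicated(cat$item),
              "item names must be unique within the catalog")
  assert_that(all(cat$prevalence > 0 & cat$prevalence < 1),
              "item prevalences must be in (0, 1)")
  assert_that(all(cat$loading >= 0), "burden loadings must be >= 0")

  sd_dec <- age$sd / 10
  cat$base_logodds <- mapply(function(p, lam, al)
    prevalence_to_base_logodds(p, sqrt(lam^2 + (al * sd_dec)^2)),
    cat$prevalence, cat$loading, cat$age_loading)

  for (pi in planted_interactions) {
    assert_that(length(pi$items) >= 2 && length(pi$items) <= 4,
                "planted interaction sets must have size 2-4")
    assert_that(all(pi$items %in% cat$item),
                paste("planted interaction references unknown item(s):",
                      paste(setdiff(pi$items, cat$item), collapse = ", ")))
    assert_that(!is.null(pi$gamma) || !is.null(pi$target_carrier_mortality),
                "planted interactions need gamma or target_carrier_mortality")
  }
  ce <- covariate_effects
  ce$age_per_decade <- ce$age_per_decade %||% 0
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 age = age, sex_probs = sex_probs, race_probs = race_probs,
                 catalog = cat, covariate_effects = ce,
                 planted_interactions = planted_interactions,
                 target_mortality = target_mortality,
                 disposition_survivors =
                   disposition_survivors / sum(disposition_survivors)),
            class = "sim_config")
}

# solve b so that E_Z[plogis(b + s Z)] = p for standard-normal Z
prevalence_to_base_logodds <- function(p, s) {
  if (s < 1e-12) return(qlogis(p))
  f <- function(b)
    stats::integrate(function(z) plogis(b + s * z) * dnorm(z),
                     -Inf, Inf)$value - p
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Load a simulation configuration from a YAML file
#'
#' @param path YAML file laid out like the packaged default
#'   (`system.file("extdata", "default_cohort_config.yaml",
#'   package = "ihtrules")`).
#' @param n_patients,seed optional overrides of the file's values.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path, n_patients = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  cat <- do.call(rbind, lapply(y$items, function(it)
    data.frame(name = it$name, subcategory = it$subcategory,
               prevalence = it$prevalence, loading = it$loading,
               age_loading = it$age_loading %||% 0,
               outcome_effect = it$outcome_effect %||% 0,
               stringsAsFactors = FALSE)))
  sim_config(
    n_patients = n_patients %||% y$n_patients,
    seed = seed %||% y$seed,
    age = y$age,
    sex_probs = unlist(y$sex),
    race_probs = unlist(y$race),
    item_catalog = cat,
    covariate_effects = list(
      age_per_decade = y$covariate_effects$age_per_decade %||% 0,
      sex = unlist(y$covariate_effects$sex),
      race = unlist(y$covariate_effects$race)),
    planted_interactions = y$planted_interactions %||% list(),
    target_mortality = y$target_mortality,
    disposition_survivors = unlist(y$disposition_survivors))
}

#' The packaged default cohort configuration
#'
#' Loads the versioned default configuration shipped with the package:
#' a 70-item catalog over the six subcategories with per-subcategory mean
#' counts near the published cohort's, published-table demographic
#' marginals, 11.7% target mortality, and one planted high-risk pair
#' (comorbid acidosis with an admitting diagnosis of cardiac arrest,
#' target carrier mortality 72.6%).
#'
#' @inheritParams read_sim_config
#' @return a `sim_config`.
#' @export
default_sim_config <- function(n_patients = NULL, seed = NULL) {
  read_sim_config(system.file("extdata", "default_cohort_config.yaml",
                              package = "ihtrules", mustWork = TRUE),
                  n_patients = n_patients, seed = seed)
}

# draw demographics, latent burden and item presences (everything except
# the outcome) in a fixed order under the given seed
draw_population <- function(config, n, seed) {
  cat <- config$catalog
  m <- nrow(cat)
  with_seed(seed, {
    amin <- config$age$min %||% 21
    atop <- config$age$top_code %||% 90
    lo <- stats::pnorm(amin - 0.5, config$age$mean, config$age$sd)
    hi <- stats::pnorm(atop + 0.5, config$age$mean, config$age$sd)
    age <- round(qnorm(runif(n, lo, hi), config$age$mean, config$age$sd))
    age <- pmin(pmax(age, amin), atop)
    sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
    race <- sample(names(config$race_probs), n, TRUE, config$race_probs)
    burden <- rnorm(n)
    age_dec <- (age - config$age$mean) / 10
    eta_items <- outer(burden, cat$loading) +
      outer(age_dec, cat$age_loading) +
      matrix(cat$base_logodds, n, m, byrow = TRUE)
    x <- matrix(as.integer(matrix(runif(n * m), n, m) < plogis(eta_items)),
                n, m, dimnames = list(NULL, cat$item))
    u_death <- runif(n)
    u_disp <- runif(n)
    list(age = age, sex = sex, race = race, burden = burden, items = x,
         u_death = u_death, u_disp = u_disp)
  })
}

# death log-odds without the intercept and without planted interactions
fixed_linear_predictor <- function(config, pop) {
  ce <- config$covariate_effects
  eta <- drop(pop$items %*% config$catalog$outcome_effect)
  eta <- eta + (ce$age_per_decade %||% 0) * (pop$age - config$age$mean) / 10
  if (!is.null(ce$sex)) eta <- eta + unname(ce$sex[pop$sex])
  if (!is.null(ce$race)) eta <- eta + unname(ce$race[pop$race])
  eta
}

bisect_offset <- function(eta, target, max_iter = 100L, what = "intercept") {
  lo <- -30; hi <- 30
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (mean(plogis(mid + eta)) < target) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  achieved <- mean(plogis(mid + eta))
  if (abs(achieved - target) > 0.002)
    stop(sprintf("calibration of the %s did not converge within %d iterations (achieved rate %.4f, target %.4f)",
                 what, max_iter, achieved, target))
  mid
}

# joint calibration of the intercept and any target-specified interaction
# gammas by alternating bisections (carriers are a small fraction of the
# cohort, so the fixed point settles in a few sweeps)
calibrate_on_sample <- function(config, pop, eta_fixed) {
  ints <- config$planted_interactions
  carrier <- lapply(ints, function(pi)
    rowSums(pop$items[, pi$items, drop = FALSE]) == length(pi$items))
  gamma <- vapply(ints, function(pi) pi$gamma %||% 0, numeric(1))
  solve_g <- vapply(ints, function(pi)
    !is.null(pi$target_carrier_mortality), logical(1))
  beta0 <- 0
  for (sweep in 1:4) {
    eta_int <- rep(0, length(eta_fixed))
    for (j in seq_along(ints)) eta_int <- eta_int + gamma[j] * carrier[[j]]
    beta0 <- bisect_offset(eta_fixed + eta_int, config$target_mortality)
    for (j in seq_along(ints)) {
      if (!solve_g[j]) next
      idx <- carrier[[j]]
      if (!any(idx)) {
        warning("planted interaction ",
                paste(ints[[j]]$items, collapse = " & "),
                " has no carriers in the sample; gamma left at 0")
        next
      }
      others <- rep(0, sum(idx))
      for (k in seq_along(ints))
        if (k != j) others <- others + gamma[k] * carrier[[k]][idx]
      gamma[j] <- bisect_offset(beta0 + eta_fixed[idx] + others,
                                ints[[j]]$target_carrier_mortality,
                                what = "interaction gamma")
    }
    if (!any(solve_g)) break
  }
  names(gamma) <- vapply(ints, function(pi)
    paste(sort(pi$items), collapse = " & "), character(1))
  list(beta0 = beta0, gamma = gamma, carrier = carrier)
}

#' Calibrate the mortality-model intercept
#'
#' Finds the intercept `beta0` such that the mean simulated death
#' probability over a probe sample of covariates and items equals the
#' configured target mortality, by bisection (derivative-free and
#' deterministic given the configuration seed).
#'
#' @param config a `sim_config`.
#' @param n_probe probe sample size (>= 10,000).
#' @return the log-odds intercept, with the achieved probe rate and any
#'   solved interaction gammas as attributes.
#' @export
calibrate_intercept <- function(config, n_probe = 50000) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(config$target_mortality > 0.001 &&
                config$target_mortality < 0.999,
              "target_mortality must be in (0.001, 0.999)")
  assert_that(n_probe >= 10000, "n_probe must be at least 10,000")
  pop <- draw_population(config, n_probe, derive_seed(config$seed, 97))
  eta_fixed <- fixed_linear_predictor(config, pop)
  cal <- calibrate_on_sample(config, pop, eta_fixed)
  eta_int <- rep(0, n_probe)
  for (j in seq_along(cal$carrier))
    eta_int <- eta_int + cal$gamma[j] * cal$carrier[[j]]
  structure(cal$beta0,
            achieved_rate = mean(plogis(cal$beta0 + eta_fixed + eta_int)),
            gamma = cal$gamma)
}

#' Generate a synthetic transfer-episode cohort
#'
#' Draws demographics, the latent burden factor, item presences, and then
#' in-hospital deaths from the logistic outcome model with the intercept
#' (and any target-specified interaction gammas) calibrated on the
#' generated sample itself, so the model-implied mean death probability
#' equals the configured target exactly. Survivor discharge dispositions
#' are sampled from the configured weights; death implies disposition
#' `"Died"`. Bit-identical under an identical configuration and seed.
#'
#' @param config a `sim_config`.
#' @return a `synthetic_cohort`: list with `demographics` (data frame:
#'   `patient_id`, `age`, `sex`, `race`, `died`, `disposition`), `items`
#'   (0/1 matrix, prefix-named columns), `p_death` (model-implied
#'   per-patient probabilities), `model` (`beta0`, `gamma`), `seed` and
#'   `config_hash`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  cat <- config$catalog
  if (n == 0) {
    demo <- data.frame(patient_id = character(0), age = integer(0),
                       sex = character(0), race = character(0),
                       died = integer(0), disposition = character(0),
                       stringsAsFactors = FALSE)
    return(structure(list(demographics = demo,
                          items = matrix(0L, 0, nrow(cat),
                                         dimnames = list(NULL, cat$item)),
                          p_death = numeric(0),
                          model = list(beta0 = NA_real_, gamma = numeric(0)),
                          seed = config$seed,
                          config_hash = config_hash(unclass(config))),
                     class = "synthetic_cohort"))
  }
  pop <- draw_population(config, n, config$seed)
  eta_fixed <- fixed_linear_predictor(config, pop)
  cal <- calibrate_on_sample(config, pop, eta_fixed)
  eta <- cal$beta0 + eta_fixed
  for (j in seq_along(cal$carrier))
    eta <- eta + cal$gamma[j] * cal$carrier[[j]]
  p <- plogis(eta)
  died <- as.integer(pop$u_death < p)

  disp <- rep("Died", n)
  surv_probs <- config$disposition_survivors
  cuts <- cumsum(surv_probs)
  alive <- died == 0L
  disp[alive] <- names(surv_probs)[
    findInterval(pop$u_disp[alive], c(0, cuts), rightmost.closed = TRUE)]

  ids <- sprintf("P%06d", seq_len(n))
  demo <- data.frame(patient_id = ids, age = pop$age, sex = pop$sex,
                     race = pop$race, died = died, disposition = disp,
                     stringsAsFactors = FALSE)
  items <- pop$items
  rownames(items) <- ids
  structure(list(demographics = demo, items = items, p_death = p,
                 model = list(beta0 = cal$beta0, gamma = cal$gamma),
                 seed = config$seed,
                 config_hash = config_hash(unclass(config))),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$demographics)
  cat(sprintf("<synthetic_cohort> %d patients, %d items; deaths %d (%.1f%%); seed %d, config %s\n",
              n, ncol(x$items), sum(x$demographics$died),
              if (n) 100 * mean(x$demographics$died) else NA_real_,
              x$seed, x$config_hash))
  invisible(x)
}

#' Emit diagnosis records (and demographics) from a synthetic cohort
#'
#' The inverse of the mapping stage, used as a round-trip fixture: every
#' present item becomes one coded diagnosis record using the mapping
#' table's code for that item, so that [map_records()] +
#' [build_indicators()] reproduce the cohort's item matrix exactly.
#' Record `source` and `phase` are assigned deterministically (they carry
#' no information in the synthetic model). Patients with zero items emit
#' no records but stay in the demographics table.
#'
#' @param cohort a `synthetic_cohort`.
#' @param mapping a `mapping_table` covering every catalog item.
#' @return list with `records` and `demographics` data frames.
#' @export
cohort_to_records <- function(cohort, mapping) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(mapping, "mapping_table"))
  cohort_items <- colnames(cohort$items)
  hit <- match(cohort_items, mapping$item)
  if (anyNA(hit)) {
    missing_items <- cohort_items[is.na(hit)]
    stop("no mapping row for cohort item(s): ",
         paste(missing_items, collapse = ", "))
  }
  pos <- which(cohort$items == 1L, arr.ind = TRUE)
  if (nrow(pos)) {
    records <- data.frame(
      patient_id = rownames(cohort$items)[pos[, 1]],
      code = mapping$code[hit[pos[, 2]]],
      code_system = mapping$code_system[hit[pos[, 2]]],
      source = ifelse((pos[, 1] + pos[, 2]) %% 2 == 0,
                      "clinical", "administrative"),
      phase = ifelse(pos[, 2] %% 2 == 0, "referring", "receiving"),
      stringsAsFactors = FALSE)
    records <- records[order(records$patient_id, records$code), , drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- data.frame(patient_id = character(0), code = character(0),
                          code_system = character(0), source = character(0),
                          phase = character(0), stringsAsFactors = FALSE)
  }
  demographics <- cohort$demographics[, c("patient_id", "age", "sex",
                                          "race", "died")]
  list(records = records, demographics = demographics)
}

#' Indicator matrix straight from a synthetic cohort
#'
#' Shortcut that skips the record round trip (which [cohort_to_records()]
#' plus [map_records()] reproduces exactly).
#'
#' @param cohort a `synthetic_cohort`.
#' @return an [indicator_matrix()].
#' @export
cohort_indicators <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  demo <- cohort$demographics
  cov <- demo[, intersect(c("age", "sex", "race"), names(demo)), drop = FALSE]
  rownames(cov) <- demo$patient_id
  indicator_matrix(cohort$items, demo$died, cov)
}
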