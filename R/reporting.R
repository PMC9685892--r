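#' Report ranking and rounding options
#'
#' @param rank_by ranking key: `"antecedent_count"` (prevalence-style
#'   tables), `"confidence"`, or `"aor"` (mortality-impact tables).
#' @param top_k rules kept per antecedent order (default 10).
#' @param rounding named list of display decimals (`coverage`,
#'   `confidence`, `lift`, `or`); applied only at write time.
#' @return a `report_spec` list.
#' @export
report_spec <- function(rank_by = c("antecedent_count", "confidence", "aor"),
                        top_k = 10,
                        rounding = list(coverage = 1, confidence = 1,
                                        lift = 2, or = 2)) {
  rank_by <- match.arg(rank_by)
  if (!is.numeric(top_k) || top_k < 1) stop("top_k must be >= 1")
  structure(list(rank_by = rank_by, top_k = as.integer(top_k),
                 rounding = rounding),
            class = "report_spec")
}

#' Rank rules within each antecedent order
#'
#' Within each order (1-4) rules are sorted descending by the ranking key,
#' ties broken lexicographically by antecedent, and the top `top_k`
#' retained. All values stay at full precision; rounding is applied by
#' [write_report()].
#'
#' @param rules a rule data frame (with effect columns when ranking by
#'   `aor`).
#' @param spec a [report_spec()].
#' @return the ranked and truncated rows, with a `rank_in_order` column.
#' @export
rank_rules <- function(rules, spec = report_spec()) {
  stopifnot(inherits(spec, "report_spec"))
  key <- switch(spec$rank_by,
                antecedent_count = "n_antecedent",
                confidence = "confidence",
                aor = "aor")
  if (is.null(rules[[key]]))
    stop("ranking key ", dQuote(key), " is not present on the rules")
  parts <- lapply(sort(unique(rules$order)), function(k) {
    rk <- rules[rules$order == k, , drop = FALSE]
    rk <- rk[order(-rk[[key]], rk$antecedent), , drop = FALSE]
    rk <- head(rk, spec$top_k)
    rk$rank_in_order <- seq_len(nrow(rk))
    rk
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- rules[0, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("N", "D", "baseline")) attr(out, a) <- attr(rules, a)
  out
}

round_for_display <- function(rows, rounding) {
  r <- function(nm, d) {
    for (n in intersect(nm, names(rows))) rows[[n]] <<- round(rows[[n]], d)
  }
  rows$coverage_pct <- 100 * rows$coverage
  rows$confidence_pct <- 100 * rows$confidence
  r(c("coverage_pct"), rounding$coverage %||% 1)
  r(c("confidence_pct"), rounding$confidence %||% 1)
  r(c("lift_outcome", "lift_cooccurrence"), rounding$lift %||% 2)
  r(c("or", "or_ci_low", "or_ci_high", "aor", "aor_ci_low", "aor_ci_high"),
    rounding$or %||% 2)
  r(c("improvement"), 1)
  rows$coverage <- NULL
  rows$confidence <- NULL
  rows
}

#' Write a report table with a run-metadata header
#'
#' Display rounding is applied only at write time; a full-precision JSON
#' companion (same path with extension `.full.json`) is always written
#' alongside CSV/markdown output. Files start with a metadata header
#' (package version, seed, config hash) so every table is traceable to
#' its run.
#'
#' @param rows ranked report rows (from [rank_rules()]).
#' @param path output file path.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param spec the [report_spec()] (for display rounding).
#' @param meta named list of run metadata (e.g. `seed`, `config_hash`).
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = c("csv", "json", "markdown"),
                         spec = report_spec(), meta = list()) {
  format <- match.arg(format)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  meta <- c(list(package = "ihtrules",
                 version = as.character(utils::packageVersion("ihtrules"))),
            meta)
  df <- as.data.frame(rows)
  df$items <- NULL
  full <- df
  disp <- round_for_display(df, spec$rounding)

  if (format == "json") {
    jsonlite::write_json(list(meta = meta, rows = full), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  # full-precision companion for lossy display formats
  jsonlite::write_json(list(meta = meta, rows = full),
                       paste0(path, ".full.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  header <- sprintf("# %s: %s", names(meta),
                    vapply(meta, function(v) paste(format(v), collapse = " "),
                           character(1)))
  con <- file(path, "wt")
  on.exit(close(con))
  if (format == "csv") {
    writeLines(header, con)
    write.csv(disp, con, row.names = FALSE)
  } else {
    writeLines(c(header, ""), con)
    cols <- names(disp)
    fmt <- function(v) ifelse(is.na(v), "", format(v, trim = TRUE))
    writeLines(paste0("| ", paste(cols, collapse = " | "), " |"), con)
    writeLines(paste0("|", paste(rep("---", length(cols)), collapse = "|"),
                      "|"), con)
    for (i in seq_len(nrow(disp)))
      writeLines(paste0("| ", paste(vapply(disp[i, ], fmt, character(1)),
                                    collapse = " | "), " |"), con)
  }
  invisible(path)
}

#' Read back a CSV report written by [write_report()]
#'
#' @param path report path.
#' @return a data frame (metadata header lines are skipped and attached
#'   as attribute `"meta"`).
#' @export
read_report_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  df <- read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                              collapse = "\n"),
                 stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- sub("^# ", "", lines[hdr])
  df
}

#' Run the full pipeline from a configuration file
#'
#' Orchestrates simulate (optional) -> map -> mine -> filter -> estimate ->
#' report. The YAML configuration has sections:
#' \describe{
#'   \item{simulate}{`n_patients`, `seed`, optional `config` (cohort YAML
#'     path; defaults to the packaged one). Omit the section (and supply
#'     `indicators`) to mine a provided indicator CSV instead.}
#'   \item{mapping}{path to the mapping CSV (required in simulate mode for
#'     the record round trip; ignored in indicator mode).}
#'   \item{indicators}{path to an indicator-matrix CSV (mine-only mode).}
#'   \item{mining}{`min_count` (default 25), `max_order` (default 4).}
#'   \item{filter}{`min_improvement` (default 10).}
#'   \item{report}{`top_k` (default 10), `estimate_top` (how many retained
#'     rules per order get adjusted odds ratios; default `top_k`).}
#' }
#' Every stage logs its input/output sizes; any stage error aborts with a
#' stage-labeled message. Deterministic given the seed.
#'
#' @param config path to the pipeline YAML configuration, or an equivalent
#'   named list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the rule set, retained rules, ranked
#'   report tables and paths of the written artifacts.
#' @export
run_pipeline <- function(config, out_dir = "results") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "wt")
  on.exit(close(log_con))
  logf <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    writeLines(line, log_con)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  meta <- list(config_hash = config_hash(cfg))
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    meta$seed <- sim$seed
    scfg <- stage("simulate", {
      if (is.null(sim$config)) default_sim_config(sim$n_patients, sim$seed)
      else read_sim_config(sim$config, sim$n_patients, sim$seed)
    })
    logf("simulate", "n_patients=%d seed=%d config=%s",
         scfg$n_patients, scfg$seed, config_hash(unclass(scfg)))
    cohort <- stage("simulate", generate_cohort(scfg))
    logf("simulate", "generated %d patients, %d items, %d deaths",
         nrow(cohort$demographics), ncol(cohort$items),
         sum(cohort$demographics$died))
    mapping_path <- cfg$mapping %||%
      system.file("extdata", "synthetic_mapping.csv", package = "ihtrules",
                  mustWork = TRUE)
    mapping <- stage("map", load_mapping(mapping_path))
    rt <- stage("map", cohort_to_records(cohort, mapping))
    mapped <- stage("map", map_records(rt$records, mapping))
    matrix <- stage("map", build_indicators(mapped$items, rt$demographics))
    logf("map", "%d records -> %d mapped, %d unmapped; matrix %d x %d",
         mapped$n_records, mapped$n_mapped, mapped$n_unmapped,
         matrix$N, ncol(matrix$items))
  } else if (!is.null(cfg$indicators)) {
    matrix <- stage("map", read_indicators(cfg$indicators))
    logf("map", "loaded indicator matrix %d x %d (skipping simulation and mapping)",
         matrix$N, ncol(matrix$items))
  } else {
    stop("pipeline stage 'map' failed: configuration must provide either a 'simulate' section or an 'indicators' path",
         call. = FALSE)
  }

  mcfg <- mining_config(
    min_antecedent_count = cfg$mining$min_count %||% 25,
    max_order = cfg$mining$max_order %||% 4)
  itemsets <- stage("mine", mine_frequent_antecedents(matrix, mcfg))
  rules <- stage("mine", generate_rules(itemsets, matrix, mcfg))
  logf("mine", "%d frequent antecedents at min count %d, max order %d",
       nrow(rules), mcfg$min_antecedent_count, mcfg$max_order)

  min_imp <- cfg$filter$min_improvement %||% 10
  retained <- stage("filter", apply_improvement_filter(rules, min_imp))
  logf("filter", "%d of %d rules retained at %.1f-pp minimum improvement",
       nrow(retained), nrow(rules), min_imp)

  top_k <- cfg$report$top_k %||% 10
  spec_conf <- report_spec("confidence", top_k = top_k)
  ranked_conf <- stage("report", rank_rules(retained, spec_conf))
  est_top <- cfg$report$estimate_top %||% top_k
  est_rows <- stage("estimate", {
    sel <- rank_rules(retained, report_spec("confidence", top_k = est_top))
    estimate_rule_effects(sel, matrix)
  })
  logf("estimate", "adjusted odds ratios fitted for %d rules", nrow(est_rows))
  ranked_aor <- stage("report", rank_rules(est_rows, report_spec("aor",
                                                                 top_k = top_k)))

  paths <- list(
    rules = file.path(out_dir, "rules.jsonl"),
    prevalence = file.path(out_dir, "report_prevalence.csv"),
    mortality = file.path(out_dir, "report_mortality_impact.csv"),
    log = log_path)
  stage("report", {
    write_rules_jsonl(retained, paths$rules)
    write_report(rank_rules(retained,
                            report_spec("antecedent_count", top_k = top_k)),
                 paths$prevalence, "csv",
                 report_spec("antecedent_count", top_k = top_k), meta)
    write_report(ranked_aor, paths$mortality, "csv",
                 report_spec("aor", top_k = top_k), meta)
  })
  logf("report", "wrote %s", paste(unlist(paths), collapse = ", "))
  invisible(list(matrix = matrix, rules = rules, retained = retained,
                 ranked_confidence = ranked_conf, ranked_aor = ranked_aor,
                 effects = est_rows, paths = paths))
}
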