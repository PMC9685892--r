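#' Load and validate a diagnosis code mapping table
#'
#' The mapping table realizes the code-to-concept-to-subcategory step that
#' turns raw billing codes into prefix-named indicator items. Each row maps
#' one `(code, code_system)` pair to a concept name placed in one of the six
#' diagnosis subcategories (`pdx`, `pl`, `dx`, `cm`, `hx`, `ddx`); the same
#' code may legitimately map into several subcategories (e.g. atrial
#' fibrillation as both an acute problem and an existing comorbidity), and
#' every such row produces a distinct indicator item.
#'
#' @param path path to a CSV with header columns `code`, `code_system`,
#'   `concept`, `subcategory` and optionally `precedence` (smaller = higher
#'   priority, used only in single-category mode).
#' @return a `mapping_table` data frame.
#' @export
load_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  mapping_table(df)
}

#' Construct a mapping table from a data frame
#'
#' @param df data frame with columns `code`, `code_system`, `concept`,
#'   `subcategory` and optionally `precedence`.
#' @return a validated `mapping_table`.
#' @export
mapping_table <- function(df) {
  req <- c("code", "code_system", "concept", "subcategory")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("mapping table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$code <- trimws(as.character(df$code))
  df$code_system <- trimws(as.character(df$code_system))
  df$concept <- trimws(as.character(df$concept))
  df$subcategory <- trimws(as.character(df$subcategory))
  if (any(!nzchar(df$code)))
    stop("mapping row(s) with empty code: row ",
         paste(which(!nzchar(df$code)), collapse = ", "))
  bad <- which(!df$subcategory %in% SUBCATEGORIES)
  if (length(bad))
    stop("unknown subcategory ", dQuote(df$subcategory[bad[1]]), " in mapping row ",
         bad[1], "; allowed values are: ", paste(SUBCATEGORIES, collapse = ", "))
  bad_cs <- which(!df$code_system %in% CODE_SYSTEMS)
  if (length(bad_cs))
    stop("unknown code_system ", dQuote(df$code_system[bad_cs[1]]),
         " in mapping row ", bad_cs[1], "; allowed values are: ",
         paste(CODE_SYSTEMS, collapse = ", "))
  key <- paste(df$code, df$code_system, df$subcategory, sep = "\x1f")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))
    stop("duplicate (code, code_system, subcategory) triple in mapping row(s): ",
         paste(d, collapse = ", "))
  }
  if (is.null(df$precedence)) df$precedence <- NA_integer_
  df$item <- paste0(df$subcategory, "_", df$concept)
  class(df) <- c("mapping_table", "data.frame")
  df
}

normalize_codes <- function(code, strip_dots = FALSE) {
  code <- toupper(trimws(code))
  if (strip_dots) code <- gsub(".", "", code, fixed = TRUE)
  code
}

validate_records <- function(records) {
  req <- c("patient_id", "code", "code_system")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("diagnosis records are missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(records)) {
    if (any(!nzchar(trimws(as.character(records$code)))))
      stop("diagnosis record(s) with empty code")
    if (!is.null(records$source) &&
        any(!records$source %in% RECORD_SOURCES))
      stop("record source must be one of: ",
           paste(RECORD_SOURCES, collapse = ", "))
    if (!is.null(records$phase) &&
        any(!records$phase %in% RECORD_PHASES))
      stop("record phase must be one of: ",
           paste(RECORD_PHASES, collapse = ", "))
  }
  invisible(records)
}

#' Map diagnosis records to per-patient indicator item sets
#'
#' Every record contributes the item `<subcategory>_<Concept>` for each
#' mapping row matching its `(code, code_system)`; duplicates collapse (set
#' semantics). Records matching no mapping row are never silently dropped:
#' they are tallied into an unmapped-record report, and a warning is raised
#' when the unmapped rate exceeds `unmapped_warn_threshold`.
#'
#' @param records data frame of diagnosis records with columns `patient_id`,
#'   `code`, `code_system` and optionally `source`
#'   (`clinical`/`administrative`) and `phase` (`referring`/`receiving`).
#' @param mapping a `mapping_table`.
#' @param strip_dots normalize codes by removing dots (ICD dialects differ);
#'   codes are always upper-cased and whitespace-trimmed.
#' @param single_category if `TRUE`, a code mapping into several
#'   subcategories contributes only the row with the best (smallest)
#'   `precedence` rank; the default emits all of them.
#' @param unmapped_warn_threshold proportion of unmapped records above which
#'   a warning is emitted (default 0.05).
#' @return a list with elements `items` (named list: patient id ->
#'   sorted character vector of items), `report` (data frame of unmapped
#'   `(code, code_system)` pairs with record counts), `n_records`,
#'   `n_mapped`, `n_unmapped`.
#' @export
map_records <- function(records, mapping, strip_dots = FALSE,
                        single_category = FALSE,
                        unmapped_warn_threshold = 0.05) {
  stopifnot(inherits(mapping, "mapping_table"))
  validate_records(records)
  if (nrow(records) == 0) {
    return(list(items = structure(list(), names = character(0)),
                report = data.frame(code = character(0),
                                    code_system = character(0),
                                    n_records = integer(0)),
                n_records = 0L, n_mapped = 0L, n_unmapped = 0L))
  }
  map <- mapping
  map$code <- normalize_codes(map$code, strip_dots)
  if (single_category) {
    ckey <- paste(map$code, map$code_system, sep = "\x1f")
    prec <- ifelse(is.na(map$precedence), .Machine$integer.max, map$precedence)
    ord <- order(ckey, prec)
    map <- map[ord[!duplicated(ckey[ord])], , drop = FALSE]
  }

  rec_code <- normalize_codes(as.character(records$code), strip_dots)
  rec_key <- paste(rec_code, records$code_system, sep = "\x1f")
  map_key <- paste(map$code, map$code_system, sep = "\x1f")

  # one record can match several mapping rows; expand via the key index
  idx_by_key <- split(seq_len(nrow(map)), map_key)
  hits <- idx_by_key[rec_key]
  n_hits <- lengths(hits)
  mapped <- n_hits > 0

  pid <- rep(as.character(records$patient_id)[mapped], n_hits[mapped])
  item <- map$item[unlist(hits[mapped], use.names = FALSE)]
  items <- lapply(split(item, pid), function(v) sort(unique(v)))

  unm <- which(!mapped)
  if (length(unm)) {
    tab <- as.data.frame(table(code = rec_code[unm],
                               code_system = records$code_system[unm]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    report <- data.frame(code = tab$code, code_system = tab$code_system,
                         n_records = tab$Freq, stringsAsFactors = FALSE)
    report <- report[order(-report$n_records, report$code), , drop = FALSE]
    rownames(report) <- NULL
  } else {
    report <- data.frame(code = character(0), code_system = character(0),
                         n_records = integer(0))
  }
  n_unmapped <- length(unm)
  if (n_unmapped / nrow(records) > unmapped_warn_threshold)
    warning(sprintf("%d of %d diagnosis records (%.1f%%) matched no mapping row",
                    n_unmapped, nrow(records),
                    100 * n_unmapped / nrow(records)))
  list(items = items, report = report, n_records = nrow(records),
       n_mapped = nrow(records) - n_unmapped, n_unmapped = n_unmapped)
}

#' Build a patients-by-items binary indicator matrix
#'
#' Assembles the analysis-ready representation: one 0/1 column per observed
#' item (lexicographic order), the in-hospital death outcome, and the age,
#' sex and race covariates. Patients with zero mapped diagnoses are retained
#' with all-zero rows: the denominators of every downstream rate are all
#' transferred patients.
#'
#' @param item_sets named list mapping patient id to a character vector of
#'   items (as from [map_records()]).
#' @param demographics data frame with columns `patient_id`, `died` (0/1)
#'   and optionally `age`, `sex`, `race`.
#' @return an `indicator_matrix` object.
#' @export
build_indicators <- function(item_sets, demographics) {
  stopifnot(is.data.frame(demographics),
            all(c("patient_id", "died") %in% names(demographics)))
  pid <- as.character(demographics$patient_id)
  if (anyDuplicated(pid))
    stop("duplicate patient_id in demographics: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  extra <- setdiff(names(item_sets), pid)
  if (length(extra))
    stop("patient(s) present in item sets but missing from demographics: ",
         paste(extra, collapse = ", "))
  items <- sort(unique(unlist(item_sets, use.names = FALSE)))
  mat <- matrix(0L, nrow = length(pid), ncol = length(items),
                dimnames = list(pid, items))
  if (length(items) && length(item_sets)) {
    row_idx <- rep(match(names(item_sets), pid), lengths(item_sets))
    col_idx <- match(unlist(item_sets, use.names = FALSE), items)
    mat[cbind(row_idx, col_idx)] <- 1L
  }
  cov_cols <- intersect(c("age", "sex", "race"), names(demographics))
  covariates <- demographics[, cov_cols, drop = FALSE]
  rownames(covariates) <- pid
  indicator_matrix(mat, as.integer(demographics$died), covariates)
}

#' Construct an indicator matrix object
#'
#' @param items integer (0/1) matrix, patients in rows (rownames = ids),
#'   items in columns; columns are re-sorted lexicographically.
#' @param died integer 0/1 outcome vector, one per row.
#' @param covariates optional data frame of per-patient covariates
#'   (`age`, `sex`, `race`).
#' @return an `indicator_matrix`: list with `items`, `died`, `covariates`,
#'   and cached totals `N` (patients) and `D` (deaths).
#' @export
indicator_matrix <- function(items, died, covariates = NULL) {
  items <- as.matrix(items)
  storage.mode(items) <- "integer"
  if (is.null(colnames(items)) && ncol(items) > 0)
    colnames(items) <- sprintf("item%03d", seq_len(ncol(items)))
  if (is.null(rownames(items)) && nrow(items) > 0)
    rownames(items) <- sprintf("p%06d", seq_len(nrow(items)))
  if (anyDuplicated(colnames(items)))
    stop("duplicate item names in indicator matrix")
  if (length(items) && !all(items %in% c(0L, 1L)))
    stop("indicator cells must be 0 or 1")
  died <- as.integer(died)
  if (length(died) != nrow(items))
    stop("outcome vector length (", length(died),
         ") does not match patient count (", nrow(items), ")")
  if (length(died) && !all(died %in% c(0L, 1L)))
    stop("died must be coded 0/1")
  if (ncol(items) > 1)
    items <- items[, order(colnames(items)), drop = FALSE]
  structure(list(items = items, died = died,
                 covariates = covariates,
                 N = nrow(items), D = sum(died)),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("<indicator_matrix> %d patients x %d items; deaths %d (%.1f%%)\n",
              x$N, ncol(x$items), x$D,
              if (x$N) 100 * x$D / x$N else NA_real_))
  invisible(x)
}

#' Write / read an indicator matrix as CSV
#'
#' Layout: `patient_id`, one 0/1 column per item, then `died`, `age`,
#' `sex`, `race`.
#' @param x an `indicator_matrix`
#' @param path file path
#' @return `path`, invisibly (writer); an `indicator_matrix` (reader).
#' @export
write_indicators <- function(x, path) {
  stopifnot(inherits(x, "indicator_matrix"))
  df <- data.frame(patient_id = rownames(x$items),
                   x$items, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$died <- x$died
  for (cc in c("age", "sex", "race"))
    if (!is.null(x$covariates[[cc]])) df[[cc]] <- x$covariates[[cc]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- intersect(c("patient_id", "died", "age", "sex", "race"), names(df))
  item_cols <- setdiff(names(df), meta)
  mat <- as.matrix(df[, item_cols, drop = FALSE])
  rownames(mat) <- as.character(df$patient_id)
  cov_cols <- intersect(c("age", "sex", "race"), names(df))
  indicator_matrix(mat, df$died,
                   if (length(cov_cols)) df[, cov_cols, drop = FALSE])
}
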