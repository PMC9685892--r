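#' Mining configuration
#'
#' Constraints for the antecedent search: an absolute left-hand support
#' floor expressed in subjects (carriers of the antecedent, regardless of
#' outcome) and a maximum antecedent order. The defaults — 25 subjects and
#' four-way combinations — are the constraints the pipeline is designed
#' around.
#'
#' @param min_antecedent_count minimum number of carriers (default 25).
#' @param max_order largest antecedent size searched, 1-4 by default.
#' @param lift_mode which lift variant(s) to report: `"outcome"`
#'   (confidence over baseline mortality), `"cooccurrence"` (observed over
#'   expected carrier count under item independence), or `"both"`.
#' @return a `mining_config` list.
#' @export
mining_config <- function(min_antecedent_count = 25, max_order = 4,
                          lift_mode = c("both", "outcome", "cooccurrence")) {
  lift_mode <- match.arg(lift_mode)
  if (!is.numeric(min_antecedent_count) || min_antecedent_count < 1)
    stop("min_antecedent_count must be a positive integer")
  if (!is.numeric(max_order) || max_order < 1)
    stop("max_order must be at least 1")
  structure(list(min_antecedent_count = as.integer(min_antecedent_count),
                 max_order = as.integer(max_order),
                 lift_mode = lift_mode),
            class = "mining_config")
}

as_item_matrix <- function(matrix) {
  if (inherits(matrix, "indicator_matrix")) return(matrix$items)
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  m
}

matrix_died <- function(matrix) {
  if (inherits(matrix, "indicator_matrix")) return(matrix$died)
  integer(nrow(as.matrix(matrix)))
}

itemset_df <- function(idx_list, item_names) {
  parts <- lapply(seq_along(idx_list), function(k) {
    lev <- idx_list[[k]]
    nr <- nrow(lev$items)
    if (nr == 0) return(NULL)
    nm <- matrix(item_names[lev$items], nrow = nr)
    data.frame(order = k,
               antecedent = apply(nm, 1, paste, collapse = " & "),
               items = I(lapply(seq_len(nr), function(r) nm[r, ])),
               n_antecedent = lev$count,
               n_both = lev$count_died,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(order = integer(0), antecedent = character(0),
                      items = I(list()), n_antecedent = integer(0),
                      n_both = integer(0))
  out <- out[order(out$order, out$antecedent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine frequent antecedents with the Apriori algorithm
#'
#' Levelwise search over antecedents of size 1..`max_order` carried by at
#' least `min_antecedent_count` patients. Candidate generation uses the
#' standard prefix join with full subset pruning (support is anti-monotone),
#' and carrier counting intersects per-item patient bitsets. Deaths among
#' carriers are counted in the same pass so rule metrics need no second scan.
#'
#' Items are put in lexicographic name order before mining, so itemsets and
#' the output ordering are reproducible regardless of input column order.
#'
#' @param matrix an [indicator_matrix()] (or plain 0/1 matrix, in which case
#'   all outcomes are taken as 0).
#' @param config a [mining_config()].
#' @return data frame with one row per frequent itemset: `order`,
#'   `antecedent` (names joined by `" & "`), `items` (list column),
#'   `n_antecedent`, `n_both` (carriers who died).
#' @export
mine_frequent_antecedents <- function(matrix, config = mining_config()) {
  stopifnot(inherits(config, "mining_config"))
  m <- as_item_matrix(matrix)
  if (nrow(m) == 0 || ncol(m) == 0)
    return(itemset_df(list(), character(0)))
  m <- m[, order(colnames(m)), drop = FALSE]
  res <- .apriori_mine(m, matrix_died(matrix),
                       config$min_antecedent_count, config$max_order)
  itemset_df(res, colnames(m))
}

#' Exhaustively enumerate antecedents (reference oracle)
#'
#' Counts every subset of size 1..`max_order` directly, with no pruning.
#' Reference semantics for [mine_frequent_antecedents()]; guarded to at
#' most 16 items.
#'
#' @inheritParams mine_frequent_antecedents
#' @return data frame in the same layout as [mine_frequent_antecedents()].
#' @export
brute_force_mine <- function(matrix, config = mining_config()) {
  stopifnot(inherits(config, "mining_config"))
  m <- as_item_matrix(matrix)
  if (ncol(m) > 16)
    stop("brute_force_mine refuses matrices with more than 16 items (got ",
         ncol(m), ")")
  if (nrow(m) == 0 || ncol(m) == 0)
    return(itemset_df(list(), character(0)))
  m <- m[, order(colnames(m)), drop = FALSE]
  died <- matrix_died(matrix)
  levels <- lapply(seq_len(min(config$max_order, ncol(m))), function(k) {
    combs <- combn(ncol(m), k)
    carrier <- apply(combs, 2, function(js)
      rowSums(m[, js, drop = FALSE]) == k)
    if (is.null(dim(carrier)))
      carrier <- matrix(carrier, ncol = ncol(combs))
    cnt <- colSums(carrier)
    keep <- cnt >= config$min_antecedent_count
    list(items = t(combs[, keep, drop = FALSE]),
         count = as.integer(cnt[keep]),
         count_died = as.integer(colSums(carrier[, keep, drop = FALSE] * died)))
  })
  out <- itemset_df(levels, colnames(m))
  if (config$max_order > ncol(m)) out  # orders beyond item count are empty
  out
}

#' Turn frequent antecedents into mortality rules
#'
#' The consequent is fixed: in-hospital death. For each antecedent X the
#' rule X => death gets exact-count metrics:
#' coverage = carriers / N, confidence = carrier deaths / carriers,
#' `lift_outcome` = confidence / (D / N), and `lift_cooccurrence` =
#' observed carriers / expected carriers under independence of the items.
#' No minimum-confidence cutoff is applied; ranking happens downstream.
#'
#' Two lift variants are reported deliberately: the co-occurrence form
#' follows the textbook definition on the antecedent itemset, while the
#' outcome form (confidence over baseline mortality) is the quantity that
#' published rule tables in this setting actually print.
#'
#' @param itemsets output of [mine_frequent_antecedents()] (or the oracle).
#' @param matrix the same `indicator_matrix` they were mined from.
#' @param config a [mining_config()].
#' @return a `rule_set` data frame with metric columns and attributes
#'   `N`, `D`, `baseline` (= D/N).
#' @export
generate_rules <- function(itemsets, matrix, config = mining_config()) {
  stopifnot(inherits(matrix, "indicator_matrix"))
  N <- matrix$N
  D <- matrix$D
  if (N == 0) stop("cannot generate rules from an empty cohort")
  baseline <- D / N
  zero <- itemsets$n_antecedent == 0
  if (any(zero)) {
    warning(sum(zero), " itemset(s) with zero carriers excluded")
    itemsets <- itemsets[!zero, , drop = FALSE]
  }
  rules <- itemsets
  rules$coverage <- rules$n_antecedent / N
  rules$confidence <- rules$n_both / rules$n_antecedent
  rules$lift_outcome <- if (baseline > 0) rules$confidence / baseline else NA_real_
  prev <- colMeans(matrix$items)
  expected <- N * vapply(rules$items, function(it) prod(prev[it]), numeric(1))
  rules$lift_cooccurrence <- rules$n_antecedent / expected
  rownames(rules) <- NULL
  structure(rules, N = N, D = D, baseline = baseline,
            class = c("rule_set", "data.frame"))
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rules (orders %s); N = %d, deaths = %d (baseline %.3f)\n",
              nrow(x),
              if (nrow(x)) paste(range(x$order), collapse = "-") else "-",
              attr(x, "N"), attr(x, "D"), attr(x, "baseline")))
  if (nrow(x)) print(head(as.data.frame(x)[, setdiff(names(x), "items")], 10))
  invisible(x)
}

#' Serialize / read rules as JSON lines
#'
#' One JSON object per line with the antecedent as an array and all metrics
#' at full precision; display rounding belongs to the reporting layer.
#'
#' @param rules a `rule_set` (or filtered rule data frame).
#' @param path file path.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_rules_jsonl <- function(rules, path) {
  df <- as.data.frame(rules)
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- list(N = attr(rules, "N"), D = attr(rules, "D"),
               baseline = attr(rules, "baseline"))
  writeLines(jsonlite::toJSON(c(list(header = TRUE), meta),
                              auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, setdiff(names(df), c("items", "antecedent"))])
    rec$antecedent <- df$items[[i]]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_rules_jsonl
#' @export
read_rules_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  hdr <- recs[[1]]
  recs <- recs[-1]
  df <- do.call(rbind, lapply(recs, function(r) {
    items <- r$antecedent
    r$antecedent <- NULL
    d <- as.data.frame(r[!vapply(r, is.null, logical(1))])
    d$antecedent <- paste(items, collapse = " & ")
    d$items <- I(list(items))
    d
  }))
  structure(df, N = hdr$N, D = hdr$D, baseline = hdr$baseline,
            class = c("rule_set", "data.frame"))
}
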