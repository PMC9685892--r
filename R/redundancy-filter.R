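#' Minimum-improvement margin of a rule over its sub-combinations
#'
#' A combination only carries new prognostic information if mortality among
#' its carriers is meaningfully higher than what any smaller combination
#' already achieves. The improvement of a rule is the percentage-point
#' margin of its confidence over the best confidence in its comparison set:
#' every proper non-empty sub-antecedent that met the support floor, plus
#' the cohort baseline mortality (so single-item rules are compared against
#' baseline alone). Sub-antecedents absent from the mined rule collection
#' (below the support floor, so their confidence is unknown under the
#' mining constraints) are skipped and tallied, never imputed.
#'
#' @param rule a single-row rule (one row of a `rule_set`), or a rule set to
#'   evaluate in bulk.
#' @param all_rules the indexed rule collection the sub-antecedents live in
#'   (defaults to `rule` itself when that is a whole rule set).
#' @param baseline cohort baseline mortality as a proportion; defaults to
#'   the `baseline` attribute of `all_rules`.
#' @return for a single rule, a numeric percentage-point margin; for a rule
#'   set, the rule set with columns `improvement`, `binding_subrule` (the
#'   sub-antecedent — or `"<baseline>"` — whose confidence binds the margin)
#'   and `n_subsets_below_floor`.
#' @export
compute_improvement <- function(rule, all_rules = rule, baseline = NULL) {
  baseline <- baseline %||% attr(all_rules, "baseline")
  if (is.null(baseline))
    stop("baseline mortality must be supplied (or present as an attribute)")
  single <- nrow(rule) == 1 && !identical(rule, all_rules)
  res <- improvement_table(all_rules, baseline,
                           query = if (single) rule else NULL)
  if (single) res$improvement[1] else res
}

key_of <- function(items_list) {
  vapply(items_list, function(v) paste(sort(v), collapse = "\x1f"), character(1))
}

improvement_table <- function(rules, baseline, query = NULL) {
  df <- if (is.null(query)) rules else query
  all_key <- key_of(rules$items)
  conf_of <- rules$confidence
  n <- nrow(df)
  best <- rep(baseline, n)
  binding <- rep("<baseline>", n)
  missing_subs <- integer(n)

  for (k in sort(unique(df$order))) {
    if (k < 2) next
    rows <- which(df$order == k)
    nm <- matrix(unlist(df$items[rows]), ncol = k, byrow = TRUE)
    # item names arrive sorted within each antecedent, so column subsets
    # of nm are themselves sorted item tuples
    for (s in seq_len(k - 1)) {
      pats <- combn(k, s)
      for (p in seq_len(ncol(pats))) {
        sub <- nm[, pats[, p], drop = FALSE]
        skey <- do.call(paste, c(split(sub, col(sub)), sep = "\x1f"))
        hit <- match(skey, all_key)
        found <- !is.na(hit)
        missing_subs[rows] <- missing_subs[rows] + !found
        if (any(found)) {
          cf <- conf_of[hit[found]]
          rr <- rows[found]
          better <- cf > best[rr]
          if (any(better)) {
            best[rr[better]] <- cf[better]
            subf <- sub[found, , drop = FALSE][better, , drop = FALSE]
            binding[rr[better]] <- apply(subf, 1, paste, collapse = " & ")
          }
        }
      }
    }
  }
  df$improvement <- 100 * (df$confidence - best)
  df$binding_subrule <- binding
  df$n_subsets_below_floor <- missing_subs
  total_missing <- sum(missing_subs)
  if (total_missing > 0 && is.null(query))
    message(total_missing,
            " sub-antecedent lookup(s) were below the support floor and skipped")
  df
}

#' Apply the minimum-improvement redundancy filter
#'
#' Retains exactly the rules whose improvement margin is at least
#' `min_improvement`. The default margin of 10 is read as an absolute
#' margin of 10 percentage points of mortality; a relative mode (confidence
#' at least `(1 + min_improvement/100)` times the best sub-combination's)
#' is available behind the `mode` flag.
#'
#' @param rules a `rule_set`; improvements are computed if absent.
#' @param min_improvement non-negative margin, percentage points (absolute
#'   mode) or percent (relative mode). Default 10.
#' @param baseline baseline mortality proportion; defaults to the rule
#'   set's attribute.
#' @param mode `"absolute"` (default) or `"relative"`.
#' @return the retained subset, each rule carrying its `improvement` and
#'   `binding_subrule`; the full annotated collection (with a `retained`
#'   flag) is attached as attribute `"annotated"`.
#' @export
apply_improvement_filter <- function(rules, min_improvement = 10,
                                     baseline = NULL,
                                     mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (!is.numeric(min_improvement) || min_improvement < 0)
    stop("min_improvement must be non-negative")
  baseline <- baseline %||% attr(rules, "baseline")
  if (is.null(rules$improvement) || mode == "relative")
    rules <- compute_improvement(rules, rules, baseline)
  if (mode == "absolute") {
    keep <- rules$improvement >= min_improvement
  } else {
    best <- rules$confidence - rules$improvement / 100
    keep <- rules$confidence >= best * (1 + min_improvement / 100)
  }
  rules$retained <- keep
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "annotated") <- rules
  for (a in c("N", "D", "baseline"))
    attr(out, a) <- attr(rules, a)
  class(out) <- class(rules)
  out
}
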