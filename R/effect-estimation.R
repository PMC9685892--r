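#' Construct a 2x2 combination-by-death contingency table
#'
#' @param a carriers who died
#' @param b carriers who survived
#' @param c non-carriers who died
#' @param d non-carriers who survived
#' @return a `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers")
  cells <- round(cells)
  storage.mode(cells) <- "integer"
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("carrier", "non-carrier"),
                              c("died", "survived")))
  print(m)
  invisible(x)
}

#' Cross-tabulate antecedent carriage against death
#'
#' @param matrix an [indicator_matrix()].
#' @param antecedent character vector of item names (the antecedent X).
#' @return a `contingency_table` with `a + c` = total deaths and
#'   `a + b + c + d` = total patients.
#' @export
contingency_from_indicators <- function(matrix, antecedent) {
  stopifnot(inherits(matrix, "indicator_matrix"))
  unknown <- setdiff(antecedent, colnames(matrix$items))
  if (length(unknown))
    stop("unknown item name(s): ", paste(unknown, collapse = ", "))
  carrier <- rowSums(matrix$items[, antecedent, drop = FALSE]) ==
    length(antecedent)
  a <- sum(carrier & matrix$died == 1L)
  b <- sum(carrier & matrix$died == 0L)
  c_ <- sum(!carrier & matrix$died == 1L)
  d <- sum(!carrier & matrix$died == 0L)
  contingency_table(a, b, c_, d)
}

#' Reconstruct a 2x2 table from printed summary percentages
#'
#' Published rule tables report only cohort size, total deaths, coverage
#' (percent of patients with the combination) and confidence (percent of
#' carriers who died in hospital). Those four numbers determine the full
#' 2x2 table up to rounding of the printed percentages:
#' `n1 = round(coverage * N / 100)`, `a = round(confidence * n1 / 100)`,
#' `b = n1 - a`, `c = D - a`, `d = N - n1 - c`.
#'
#' @param N cohort size
#' @param D total deaths
#' @param coverage percent of patients carrying the combination, in `(0, 100]`
#' @param confidence percent mortality among carriers, in `[0, 100]`
#' @return a `contingency_table`.
#' @export
reconstruct_table <- function(N, D, coverage, confidence) {
  if (coverage <= 0 || coverage > 100)
    stop("coverage must be in (0, 100]")
  if (confidence < 0 || confidence > 100)
    stop("confidence must be in [0, 100]")
  n1 <- round(coverage * N / 100)
  a <- round(confidence * n1 / 100)
  b <- n1 - a
  c_ <- D - a
  d <- N - n1 - c_
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(cells < 0))
    stop("printed percentages imply a negative cell: ",
         paste(names(cells)[cells < 0], collapse = ", "))
  contingency_table(a, b, c_, d)
}

#' Unadjusted odds ratio with a Wald 95% confidence interval
#'
#' `OR = (a d) / (b c)`; the interval is Wald on the log scale,
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. A table containing a
#' zero cell gets the Haldane-Anscombe correction (0.5 added to every cell)
#' and is flagged; a table with two zeros in the same row or column has no
#' defined odds ratio and is an error.
#'
#' @param table a `contingency_table`.
#' @return list with `or`, `ci` (length-2), `log_or`, `se_log_or`,
#'   `corrected` (logical flag).
#' @export
estimate_or <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(a = table$a, b = table$b, c = table$c, d = table$d)
  pairs <- list(c("a", "b"), c("c", "d"), c("a", "c"), c("b", "d"))
  for (p in pairs)
    if (all(cells[p] == 0))
      stop("odds ratio undefined: cells ", paste(p, collapse = " and "),
           " are both zero")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(0.975)
  list(or = unname(exp(log_or)),
       ci = unname(exp(log_or + c(-1, 1) * z * se)),
       log_or = unname(log_or), se_log_or = unname(se),
       corrected = corrected)
}

#' Maximum-likelihood logistic regression via IRLS
#'
#' Self-contained iteratively reweighted least squares fit of a binomial
#' GLM with logit link. Each iteration solves the weighted least squares
#' normal equations through a QR decomposition of `sqrt(W) X`; convergence
#' is declared when the deviance changes by less than `tol` (default 1e-8)
#' or after `max_iter` (default 50) iterations. Standard errors come from
#' the inverse of the observed information `X' W X`. Any coefficient with
#' absolute value above 15 on the logit scale trips a separation warning
#' flag (a carrier group with no survivors, say, has no finite MLE).
#'
#' @param design numeric design matrix including the intercept column.
#' @param outcome 0/1 response vector.
#' @param tol deviance-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `coefficients`, `se`, `vcov`, `deviance`,
#'   `iterations`, `converged`, `separation` (logical flag),
#'   `fitted` (probabilities).
#' @export
fit_logistic <- function(design, outcome, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  y <- as.numeric(outcome)
  if (length(y) != nrow(X))
    stop("outcome length does not match design rows")
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (nrow(X) <= ncol(X))
    stop("more parameters than observations")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  dev_of <- function(mu) -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  clamp <- function(mu) pmin(pmax(mu, 1e-10), 1 - 1e-10)
  # per-observation start, as in the classic binomial IRLS: keeps the first
  # Newton step well-scaled even when carriers are rare
  mu <- (y + 0.5) / 2
  eta <- qlogis(mu)
  dev <- dev_of(mu)
  beta <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X * sw), z * sw)
    # step-halve if the deviance worsens (Newton overshoot)
    for (h in 0:30) {
      beta_try <- if (is.null(beta) || h == 0) beta_new
                  else beta + (beta_new - beta) / 2^h
      eta_try <- drop(X %*% beta_try)
      mu_try <- clamp(plogis(eta_try))
      dev_try <- dev_of(mu_try)
      if (is.null(beta) || dev_try <= dev + 1e-8) break
    }
    eta <- eta_try
    mu <- mu_try
    beta <- beta_try
    if (abs(dev_try - dev) < tol) {
      dev <- dev_try
      converged <- TRUE
      break
    }
    dev <- dev_try
  }
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(info)),
                   error = function(e)
                     stop("observed information is singular near the optimum"))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)
  list(coefficients = beta, se = se, vcov = vcov,
       deviance = dev, iterations = iter, converged = converged,
       separation = any(abs(beta) > 15), fitted = mu)
}

#' Build the covariate design for an adjusted model
#'
#' Age enters linearly in years; sex is coded with male as reference and
#' race with white as reference (levels black, other). Missing covariate
#' columns are simply omitted.
#' @noRd
adjustment_design <- function(covariates, n) {
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(covariates)) return(X)
  if (!is.null(covariates$age))
    X <- cbind(X, age = as.numeric(covariates$age))
  if (!is.null(covariates$sex)) {
    sex <- factor(covariates$sex)
    if ("Male" %in% levels(sex)) sex <- stats::relevel(sex, "Male")
    if (nlevels(sex) > 1)
      X <- cbind(X, stats::model.matrix(~sex)[, -1, drop = FALSE])
  }
  if (!is.null(covariates$race)) {
    race <- factor(covariates$race)
    if ("White" %in% levels(race)) race <- stats::relevel(race, "White")
    if (nlevels(race) > 1)
      X <- cbind(X, stats::model.matrix(~race)[, -1, drop = FALSE])
  }
  X
}

#' Unadjusted and covariate-adjusted odds ratio for one combination
#'
#' Fits `death ~ carrier + age + sex + race` by maximum likelihood (one
#' regression per combination, with the combination as the main independent
#' variable) and bundles the unadjusted odds ratio computed from the same
#' matrix. Confidence intervals are Wald at 95%.
#'
#' @param matrix an [indicator_matrix()] with covariates.
#' @param antecedent character vector of item names.
#' @return an `effect_estimate`: list with `antecedent`, `or_unadjusted`,
#'   `or_ci`, `aor`, `aor_ci`, `coefficients` (estimate/se table) and
#'   `convergence_info`.
#' @export
estimate_adjusted_or <- function(matrix, antecedent) {
  stopifnot(inherits(matrix, "indicator_matrix"))
  tab <- contingency_from_indicators(matrix, antecedent)
  if (tab$a + tab$b == 0)
    stop("no patient carries the antecedent: ",
         paste(antecedent, collapse = " & "))
  carrier <- as.numeric(
    rowSums(matrix$items[, antecedent, drop = FALSE]) == length(antecedent))
  X <- adjustment_design(matrix$covariates, matrix$N)
  X <- cbind(X[, 1, drop = FALSE], carrier = carrier,
             X[, -1, drop = FALSE])
  fit <- fit_logistic(X, matrix$died)
  z <- qnorm(0.975)
  b <- fit$coefficients["carrier"]
  s <- fit$se["carrier"]
  unadj <- estimate_or(tab)
  structure(list(
    antecedent = antecedent,
    table = tab,
    or_unadjusted = unadj$or,
    or_ci = unadj$ci,
    or_corrected = unadj$corrected,
    aor = unname(exp(b)),
    aor_ci = unname(exp(b + c(-1, 1) * z * s)),
    coefficients = data.frame(term = names(fit$coefficients),
                              estimate = unname(fit$coefficients),
                              se = unname(fit$se)),
    convergence_info = list(iterations = fit$iterations,
                            converged = fit$converged,
                            deviance = fit$deviance,
                            separation = fit$separation)),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s\n  OR  %.2f (95%% CI %.2f-%.2f)%s\n  aOR %.2f (95%% CI %.2f-%.2f)%s\n",
              paste(x$antecedent, collapse = " & "),
              x$or_unadjusted, x$or_ci[1], x$or_ci[2],
              if (x$or_corrected) " [Haldane-Anscombe corrected]" else "",
              x$aor, x$aor_ci[1], x$aor_ci[2],
              if (x$convergence_info$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Attach effect estimates to a set of rules
#'
#' Convenience wrapper running [estimate_adjusted_or()] for each rule and
#' appending `or`, `or_ci_low/high`, `aor`, `aor_ci_low/high` columns, plus
#' a Benjamini-Hochberg adjusted p-value column for the carrier coefficient
#' (an extension beyond the exploratory unadjusted framing, clearly
#' labeled as such in reports).
#'
#' @param rules a `rule_set` (possibly filtered).
#' @param matrix the `indicator_matrix` the rules were mined from.
#' @return `rules` with effect-estimate columns.
#' @export
estimate_rule_effects <- function(rules, matrix) {
  n <- nrow(rules)
  cols <- c("or", "or_ci_low", "or_ci_high", "aor", "aor_ci_low",
            "aor_ci_high", "aor_p")
  for (cc in cols) rules[[cc]] <- NA_real_
  rules$separation <- NA
  for (i in seq_len(n)) {
    est <- estimate_adjusted_or(matrix, rules$items[[i]])
    rules$or[i] <- est$or_unadjusted
    rules$or_ci_low[i] <- est$or_ci[1]
    rules$or_ci_high[i] <- est$or_ci[2]
    rules$aor[i] <- est$aor
    rules$aor_ci_low[i] <- est$aor_ci[1]
    rules$aor_ci_high[i] <- est$aor_ci[2]
    co <- est$coefficients
    zval <- co$estimate[co$term == "carrier"] / co$se[co$term == "carrier"]
    rules$aor_p[i] <- 2 * stats::pnorm(-abs(zval))
    rules$separation[i] <- est$convergence_info$separation
  }
  rules$aor_p_bh <- stats::p.adjust(rules$aor_p, method = "BH")
  rules
}
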