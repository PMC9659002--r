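#' Construct the 2x5 observed table for one variable
#'
#' Cross-classifies one risk factor against the five outcome (LCM) risk
#' levels. The "variable" row at outcome level l is the sum, over
#' observations at that level, of the variable's share of the observation's
#' total crude rate across all risk factors; the complement row is the level
#' count minus that share mass. Column totals therefore equal the outcome
#' level frequencies and the grand total equals the number of observations.
#' Entries are real-valued by construction.
#'
#' @param rates Rate matrix from [crude_rates()].
#' @param levels Level matrix from [quintile_classify()].
#' @param variable Risk-factor name.
#' @param outcome Outcome column name (default the matrix attribute, else "LCM").
#' @return An `observed_table`.
#' @export
build_observed <- function(rates, levels, variable,
                           outcome = attr(levels, "outcome") %||% "LCM") {
  if (!variable %in% colnames(rates)) stop("unknown variable: ", variable)
  if (!outcome %in% colnames(levels)) stop("outcome levels not available")
  factors <- setdiff(colnames(rates), outcome)
  denom <- rowSums(rates[, factors, drop = FALSE])
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " observation(s) with all-zero rates dropped",
            call. = FALSE)
    rates <- rates[!zero, , drop = FALSE]
    levels <- levels[!zero, , drop = FALSE]
    denom <- denom[!zero]
  }
  share <- rates[, variable] / denom
  lcm <- factor(levels[, outcome], levels = 1:5)
  v_row <- as.vector(tapply(share, lcm, sum, default = 0))
  counts <- tabulate(levels[, outcome], nbins = 5L)
  observed_table(rbind(v_row, counts - v_row), variable = variable)
}

#' Create an observed_table from a 2x5 matrix
#'
#' @param m Numeric 2x5 matrix: first row the variable of interest, second its
#'   complement; columns are the five risk levels.
#' @param variable Label for the first row.
#' @return An `observed_table` (list with the matrix and its margins).
#' @export
observed_table <- function(m, variable = "variable") {
  m <- as.matrix(m)
  if (!identical(dim(m), c(2L, 5L))) stop("observed table must be 2x5")
  if (any(m < 0)) stop("observed entries must be non-negative")
  dimnames(m) <- list(c(variable, paste0("non-", variable)),
                      c("very_low", "low", "medium", "high", "very_high"))
  grand <- sum(m)
  if (grand <= 0) stop("grand total must be positive")
  structure(list(observed = m, row_totals = rowSums(m),
                 col_totals = colSums(m), grand_total = grand,
                 variable = variable),
            class = "observed_table")
}

#' Expected table under row/column independence
#'
#' `expected(i, j) = row_total_i * col_total_j / grand_total`; a zero row or
#' column margin yields zero expected entries there.
#'
#' @param observed An `observed_table`.
#' @return Numeric 2x5 matrix with the same margins as the observed table.
#' @export
expected_under_independence <- function(observed) {
  stopifnot(inherits(observed, "observed_table"))
  outer(observed$row_totals, observed$col_totals) / observed$grand_total
}

#' Pearson chi-square statistic for an observed table
#'
#' Per-cell contributions `(O - E)^2 / E` (0 where E = 0), their total, and
#' the p-value from the chi-square distribution with 4 degrees of freedom
#' (a 2x5 table). No continuity correction is applied; real-valued entries
#' are permitted and the formula is applied as-is.
#'
#' @param observed An `observed_table`.
#' @return A `chisq_result` list: `observed`, `expected`, `contributions`,
#'   `statistic`, `df`, `p_value`.
#' @export
pearson_chisq <- function(observed) {
  stopifnot(inherits(observed, "observed_table"))
  E <- expected_under_independence(observed)
  O <- observed$observed
  contrib <- ifelse(E > 0, (O - E)^2 / E, 0)
  stat <- sum(contrib)
  structure(list(observed = O, expected = E, contributions = contrib,
                 statistic = stat, df = 4L,
                 p_value = stats::pchisq(stat, df = 4L, lower.tail = FALSE),
                 variable = observed$variable),
            class = "chisq_result")
}

#' Normalize chi-square statistics into a weight vector
#'
#' `weight_v = statistic_v / sum(statistics)`: non-negative weights summing
#' to 1 (weight group A1).
#'
#' @param stats Named numeric vector of per-variable chi-square statistics.
#' @return Named weight vector summing to 1.
#' @export
chisq_weights <- function(stats) {
  if (!length(stats)) stop("need at least one variable")
  if (any(stats < 0)) stop("chi-square statistics must be non-negative")
  total <- sum(stats)
  if (total == 0) stop("all chi-square statistics are zero: no information")
  stats / total
}

#' Chi-square weighting stage over all risk factors
#'
#' For each risk factor, builds the 2x5 rate-share observed table against the
#' outcome levels and computes the Pearson chi-square statistic; weights are
#' the normalized statistics. The per-variable association p-value is taken
#' from the standard count-based contingency test of the factor's quintile
#' level against the outcome level (5x5 table, [stats::chisq.test()] without
#' continuity correction), the usual test of the independence null.
#'
#' @inheritParams build_observed
#' @return Data frame with one row per risk factor: `variable`, `statistic`,
#'   `p_value`, `weight` (weights sum to 1).
#' @export
chisq_stage <- function(rates, levels,
                        outcome = attr(levels, "outcome") %||% "LCM") {
  factors <- setdiff(colnames(rates), outcome)
  stat <- vapply(factors, function(v)
    pearson_chisq(build_observed(rates, levels, v, outcome))$statistic,
    numeric(1))
  pval <- vapply(factors, function(v) {
    tab <- table(factor(levels[, v], levels = 1:5),
                 factor(levels[, outcome], levels = 1:5))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (min(dim(tab)) < 2L) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  data.frame(variable = factors, statistic = unname(stat),
             p_value = unname(pval), weight = unname(chisq_weights(stat)),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
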