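#' RIDIT values of ordered risk levels
#'
#' Mid-rank (Bross) RIDIT of each ordered level against its own frequency
#' distribution: `ridit_l = (count below l + frequency_l / 2) / total`. The
#' frequency-weighted mean of the ridits is exactly 0.5.
#'
#' @param frequencies Non-negative counts per ordered level (typically 5).
#' @return A `ridit_levels` data frame with columns `level`, `frequency`,
#'   `average` (half the frequency), `cumulative` (count below), `sum`
#'   (cumulative + average) and `ridit`.
#' @export
level_ridits <- function(frequencies) {
  if (any(frequencies < 0)) stop("frequencies must be non-negative")
  total <- sum(frequencies)
  if (total <= 0) stop("total frequency must be positive")
  below <- cumsum(frequencies) - frequencies
  half <- frequencies / 2
  structure(data.frame(level = seq_along(frequencies),
                       frequency = frequencies, average = half,
                       cumulative = below, sum = below + half,
                       ridit = (below + half) / total),
            class = c("ridit_levels", "data.frame"), total = total)
}

#' RIDIT-based association score for one risk factor
#'
#' Each observation carries the reference ridit of its outcome level. Within
#' each level group of the risk factor the mean reference ridit is computed;
#' the score is the frequency-weighted mean absolute deviation of these group
#' means from 0.5. It is 0 when the factor is independent of the outcome and
#' at most 0.5; empty level groups are skipped. The score depends only on the
#' grouping, not the labels of the factor's levels.
#'
#' @param levels Level matrix from [quintile_classify()].
#' @param variable Risk-factor name.
#' @param lcm_ridits A `ridit_levels` built from the outcome level
#'   frequencies (the reference distribution).
#' @param outcome Outcome column name.
#' @return Non-negative scalar score in `[0, 0.5]`.
#' @export
variable_ridit_score <- function(levels, variable, lcm_ridits,
                                 outcome = attr(levels, "outcome") %||% "LCM") {
  if (!variable %in% colnames(levels)) stop("unknown variable: ", variable)
  obs_ridit <- lcm_ridits$ridit[levels[, outcome]]
  g <- levels[, variable]
  n <- length(g)
  means <- tapply(obs_ridit, g, mean)
  sizes <- tapply(obs_ridit, g, length)
  sum(sizes / n * abs(means - 0.5))
}

#' Normalize RIDIT scores into a weight vector
#'
#' @param scores Named non-negative per-variable scores, not all zero.
#' @return Named weight vector summing to 1 (weight group A2).
#' @export
ridit_weights <- function(scores) {
  if (!length(scores)) stop("need at least one variable")
  if (any(scores < 0)) stop("scores must be non-negative")
  total <- sum(scores)
  if (total == 0) stop("all RIDIT scores are zero: no information")
  scores / total
}

#' RIDIT weighting stage over all risk factors
#'
#' The reference distribution is the pooled outcome level frequencies; each
#' factor's score is its [variable_ridit_score()] and weights are the
#' normalized scores.
#'
#' @inheritParams variable_ridit_score
#' @return Data frame with `variable`, `score`, `weight` per risk factor.
#' @export
ridit_stage <- function(levels,
                        outcome = attr(levels, "outcome") %||% "LCM") {
  ref <- level_ridits(level_frequencies(levels, outcome))
  factors <- setdiff(colnames(levels), outcome)
  score <- vapply(factors, function(v)
    variable_ridit_score(levels, v, ref, outcome), numeric(1))
  data.frame(variable = factors, score = unname(score),
             weight = unname(ridit_weights(score)), row.names = NULL)
}
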