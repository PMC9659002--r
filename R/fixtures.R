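#' Packaged worked-example fixtures
#'
#' Small plain-text tables shipped with the package: the published worked
#' examples of each analysis stage (observed 2x5 chi-square table, the 30
#' per-variable chi-square statistics and weights, the pooled outcome level
#' frequencies, the per-variable RIDIT values and weights, the 30x30 expert
#' pairwise-comparison matrix, the published AHP priorities, the nearness
#' table, and the method-comparison rankings).
#'
#' @param name One of `"table2_observed"`, `"table3_chisq"`,
#'   `"table4_frequencies"`, `"table5_ridit"`, `"table6_pairwise"`,
#'   `"table7_ahp"`, `"table8_nearness"`, `"table9_comparison"`.
#' @return A data frame, except `"table6_pairwise"` which returns a
#'   `pairwise_matrix`.
#' @export
fim_fixture <- function(name = c("table2_observed", "table3_chisq",
                                 "table4_frequencies", "table5_ridit",
                                 "table6_pairwise", "table7_ahp",
                                 "table8_nearness", "table9_comparison")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "fimrisk")
  if (path == "") stop("fixture not installed: ", name)
  if (name == "table6_pairwise") return(read_pairwise_matrix(path))
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Reconstruct a composed membership vector from the nearness fixture
#'
#' The published nearness table prints, for each weighting method, the
#' elementwise inner (min with C) and outer (max with C) rows rather than the
#' composed vector B itself. B is recovered elementwise: at each level B is
#' whichever of the inner and outer entries differs from C (when both equal
#' C, B equals C there).
#'
#' @param method `"chisq"`, `"ridit"` or `"ahp"`.
#' @param fixture The nearness fixture data frame (default: the packaged one).
#' @return List with membership vectors `C` and `B` (proportions, not
#'   percent).
#' @export
reconstruct_membership <- function(method = c("chisq", "ridit", "ahp"),
                                   fixture = fim_fixture("table8_nearness")) {
  method <- match.arg(method)
  value_cols <- c("very_low", "low", "medium", "high", "very_high")
  row_of <- function(m, q)
    as.numeric(fixture[fixture$method == m & fixture$quantity == q,
                       value_cols]) / 100
  C <- row_of("reference", "C")
  inner <- row_of(method, "inner")
  outer <- row_of(method, "outer")
  B <- ifelse(abs(inner - C) > 1e-9, inner,
              ifelse(abs(outer - C) > 1e-9, outer, C))
  list(C = stats::setNames(C, value_cols), B = stats::setNames(B, value_cols))
}
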