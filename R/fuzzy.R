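#' Empirical fuzzy membership matrix R
#'
#' One row per risk factor, one column per risk class (1..5). The entry for
#' factor v and class l is the fraction of observations at level l of v whose
#' outcome level is also l — the class-wise agreement of the factor with the
#' outcome — renormalized so each row sums to 1. Empty level groups
#' contribute 0; a factor with no agreement anywhere gets a uniform row with
#' a warning.
#'
#' @param levels Level matrix from [quintile_classify()].
#' @param outcome Outcome column name.
#' @param n_classes Number of risk classes (default 5).
#' @return Numeric matrix (factors x classes), rows summing to 1.
#' @export
membership_matrix <- function(levels,
                              outcome = attr(levels, "outcome") %||% "LCM",
                              n_classes = 5L) {
  if (!outcome %in% colnames(levels)) stop("outcome levels not available")
  factors <- setdiff(colnames(levels), outcome)
  lcm <- levels[, outcome]
  R <- t(vapply(factors, function(v) {
    lv <- levels[, v]
    row <- vapply(seq_len(n_classes), function(l) {
      n_l <- sum(lv == l)
      if (n_l == 0L) 0 else sum(lv == l & lcm == l) / n_l
    }, numeric(1))
    if (all(row == 0)) {
      warning("no class agreement for ", v, ": uniform membership row",
              call. = FALSE)
      row <- rep(1, n_classes)
    }
    row / sum(row)
  }, numeric(n_classes)))
  colnames(R) <- c("very_low", "low", "medium", "high", "very_high")[seq_len(n_classes)]
  R
}

#' Compose a weight vector with the membership matrix
#'
#' `B = A %*% R` followed by normalization to sum 1: the composed membership
#' vector of a weight group.
#'
#' @param weights Named weight vector (a weight group A).
#' @param R Membership matrix from [membership_matrix()]; its rows must cover
#'   the names of `weights`.
#' @return Membership vector of length `ncol(R)` summing to 1.
#' @export
fuzzy_compose <- function(weights, R) {
  if (is.null(names(weights)) || !all(names(weights) %in% rownames(R)))
    stop("weight names must match membership matrix rows")
  if (length(weights) != nrow(R))
    stop("dimension mismatch: ", length(weights), " weights vs ",
         nrow(R), " membership rows")
  B <- as.vector(weights %*% R[names(weights), , drop = FALSE])
  s <- sum(B)
  if (s <= 0) stop("composed vector has zero mass")
  stats::setNames(B / s, colnames(R))
}

#' Inner (max-min) composition of two membership vectors
#'
#' @param B,C Membership vectors of equal length.
#' @return `max_l min(B_l, C_l)`.
#' @export
inner_composition <- function(B, C) {
  stopifnot(length(B) == length(C))
  max(pmin(B, C))
}

#' Outer (min-max) composition of two membership vectors
#'
#' @param B,C Membership vectors of equal length.
#' @return `min_l max(B_l, C_l)`.
#' @export
outer_composition <- function(B, C) {
  stopifnot(length(B) == length(C))
  min(pmax(B, C))
}

#' Lattice degree of nearness between two membership vectors
#'
#' `sigma = 0.5 * ((B inner C) + 1 - (B outer C))`, a similarity in `[0, 1]`;
#' symmetric in its arguments.
#'
#' @param B,C Membership vectors of equal length.
#' @return Scalar sigma in `[0, 1]`.
#' @export
lattice_nearness <- function(B, C) {
  0.5 * (inner_composition(B, C) + 1 - outer_composition(B, C))
}

#' Select the weight group with maximal nearness
#'
#' Ties are broken by the fixed method order chisq, ridit, ahp (then by
#' name), with a message when a tie occurs.
#'
#' @param sigmas Named numeric vector of lattice degrees of nearness.
#' @return Name of the selected method.
#' @export
select_optimal <- function(sigmas) {
  if (!length(sigmas)) stop("no nearness values supplied")
  if (is.null(names(sigmas))) stop("sigmas must be named by method")
  best <- names(sigmas)[sigmas == max(sigmas)]
  if (length(best) > 1L) {
    message("nearness tie between ", paste(best, collapse = ", "),
            "; fixed method order applied")
    pref <- c("chisq", "ridit", "ahp")
    ordered <- c(intersect(pref, best), sort(setdiff(best, pref)))
    best <- ordered[1L]
  }
  best
}

#' Reference membership vector C from the outcome's rate mass
#'
#' `C_l` is the share of the total outcome crude rate carried by observations
#' at outcome level l. For equal rates and balanced quintiles this is
#' uniform; for a monotone rate-to-level assignment it increases with level.
#'
#' @param rates Rate matrix from [crude_rates()].
#' @param levels Level matrix from [quintile_classify()].
#' @param outcome Outcome column name.
#' @return Membership vector of length 5 summing to 1.
#' @export
reference_membership <- function(rates, levels,
                                 outcome = attr(levels, "outcome") %||% "LCM") {
  r <- rates[, outcome]
  total <- sum(r)
  if (total <= 0) stop("total outcome rate is zero")
  lv <- factor(levels[, outcome], levels = 1:5)
  C <- as.vector(tapply(r, lv, sum, default = 0)) / total
  stats::setNames(C, c("very_low", "low", "medium", "high", "very_high"))
}

#' Nearness comparison of several weight groups
#'
#' Composes each weight group with the membership matrix, computes inner and
#' outer compositions and the lattice degree of nearness against the
#' reference vector, and selects the optimal group.
#'
#' @param weight_groups Named list of weight vectors (e.g. `chisq`, `ridit`,
#'   `ahp`).
#' @param R Membership matrix.
#' @param C Reference membership vector.
#' @return A `nearness_result`: per-method data frame (`method`, `inner`,
#'   `outer`, `sigma`), the composed vectors, and `selected`.
#' @export
nearness_comparison <- function(weight_groups, R, C) {
  stopifnot(is.list(weight_groups), length(weight_groups) >= 1L)
  composed <- lapply(weight_groups, fuzzy_compose, R = R)
  tab <- data.frame(method = names(weight_groups),
                    inner = vapply(composed, inner_composition, numeric(1), C = C),
                    outer = vapply(composed, outer_composition, numeric(1), C = C),
                    row.names = NULL)
  tab$sigma <- 0.5 * (tab$inner + 1 - tab$outer)
  sigmas <- stats::setNames(tab$sigma, tab$method)
  structure(list(table = tab, composed = composed, reference = C,
                 selected = select_optimal(sigmas)),
            class = "nearness_result")
}

#' @export
print.nearness_result <- function(x, ...) {
  cat("Lattice degree of nearness\n")
  tab <- x$table
  tab$inner <- sprintf("%.2f%%", 100 * tab$inner)
  tab$outer <- sprintf("%.2f%%", 100 * tab$outer)
  tab$sigma <- sprintf("%.2f%%", 100 * tab$sigma)
  print(tab, row.names = FALSE)
  cat("selected weight group:", x$selected, "\n")
  invisible(x)
}
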