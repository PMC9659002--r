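#' Read a pairwise-comparison matrix
#'
#' Reads an n x n positive comparison matrix (entry a(i, j) = importance of
#' variable i over variable j) from a CSV whose first column holds the row
#' names and whose header holds the column names. Entries must be positive
#' and the diagonal 1. Reciprocity (a(i, j) * a(j, i) = 1) is checked and the
#' violating pairs reported in the `"reciprocity_violations"` attribute, but
#' not enforced: expert-elicited matrices are consumed as given.
#'
#' @param path CSV path.
#' @param reciprocity_tol Relative tolerance on `a(i,j) * a(j,i) - 1` before a
#'   pair is flagged (default 0.05, accommodating rounded judgements such as
#'   3.33 vs 0.30).
#' @return A `pairwise_matrix` (numeric matrix subclass).
#' @export
read_pairwise_matrix <- function(path, reciprocity_tol = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  as_pairwise_matrix(m, reciprocity_tol = reciprocity_tol)
}

#' Validate a pairwise-comparison matrix
#'
#' @param m Square positive numeric matrix with dimnames.
#' @inheritParams read_pairwise_matrix
#' @return A `pairwise_matrix`.
#' @export
as_pairwise_matrix <- function(m, reciprocity_tol = 0.05) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop("pairwise matrix must be square and numeric")
  if (anyNA(m) || any(m <= 0))
    stop("pairwise matrix entries must be positive")
  if (any(abs(diag(m) - 1) > 1e-8))
    stop("pairwise matrix diagonal must be 1")
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  prod <- m * t(m)
  viol <- which(upper.tri(prod) & abs(prod - 1) > reciprocity_tol,
                arr.ind = TRUE)
  violations <- data.frame(i = rownames(m)[viol[, 1]],
                           j = colnames(m)[viol[, 2]],
                           a_ij = m[viol], a_ji = t(m)[viol],
                           product = prod[viol])
  if (nrow(violations))
    message("pairwise matrix: ", nrow(violations),
            " reciprocity violation(s) detected (reported, not enforced)")
  structure(m, class = c("pairwise_matrix", class(m)),
            reciprocity_violations = violations)
}

#' AHP priority vector from a pairwise-comparison matrix
#'
#' Derives the normalized priority (weight) vector — weight group A3 — by one
#' of three standard prioritization methods:
#' * `column_norm_mean` (default): normalize each column to sum 1 and average
#'   across columns (the variant whose signature intermediate is the vector of
#'   column sums);
#' * `geometric_mean`: normalized row geometric means;
#' * `eigenvector`: principal right eigenvector by power iteration
#'   (`tol` on the max absolute change per iteration, at most `max_iter`
#'   iterations).
#'
#' The principal eigenvalue is estimated as the mean of `(A w)_i / w_i`, from
#' which the consistency index CI = (lambda_max - n) / (n - 1) and the
#' consistency ratio CR = CI / RI(n) follow.
#'
#' @param matrix A `pairwise_matrix` (or plain positive square matrix).
#' @param method Prioritization method (see above).
#' @param tol,max_iter Power-iteration controls (eigenvector method).
#' @return An `ahp_result`: `weights` (named, sums to 1), `lambda_max`, `ci`,
#'   `cr`, `method`, `n`.
#' @export
priority_vector <- function(matrix,
                            method = c("column_norm_mean", "geometric_mean",
                                       "eigenvector"),
                            tol = 1e-10, max_iter = 10000L) {
  method <- match.arg(method)
  if (!inherits(matrix, "pairwise_matrix"))
    matrix <- as_pairwise_matrix(as.matrix(matrix))
  A <- unclass(matrix)
  n <- nrow(A)
  w <- switch(method,
    column_norm_mean = rowMeans(sweep(A, 2L, colSums(A), "/")),
    geometric_mean = {
      g <- exp(rowMeans(log(A)))
      g / sum(g)
    },
    eigenvector = {
      v <- rep(1 / n, n)
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        v_new <- as.vector(A %*% v)
        v_new <- v_new / sum(v_new)
        if (max(abs(v_new - v)) < tol) {
          v <- v_new
          converged <- TRUE
          break
        }
        v <- v_new
      }
      if (!converged)
        stop("power iteration did not converge; residual ",
             format(max(abs(as.vector(A %*% v) / sum(A %*% v) - v))))
      v
    })
  w <- w / sum(w)
  names(w) <- rownames(A)
  lambda <- mean(as.vector(A %*% w) / w)
  ci <- if (n > 1) (lambda - n) / (n - 1) else 0
  res <- structure(list(weights = w, lambda_max = lambda, ci = ci,
                        cr = NA_real_, method = method, n = n),
                   class = "ahp_result")
  res$cr <- consistency_ratio(res)
  res
}

#' AHP consistency ratio
#'
#' CR = CI / RI(n), with Saaty's random consistency indices for n <= 15 and a
#' linear extrapolation (slope 0.02 per step, with a warning) beyond. For
#' n < 3 inconsistency is undefined and CR is 0.
#'
#' @param result An `ahp_result`, or a numeric consistency index CI.
#' @param n Matrix order (taken from `result` when it is an `ahp_result`).
#' @return Scalar consistency ratio.
#' @export
consistency_ratio <- function(result, n = NULL) {
  if (inherits(result, "ahp_result")) {
    ci <- result$ci
    if (is.null(n)) n <- result$n
  } else {
    ci <- result
    if (is.null(n)) stop("n is required when passing a bare CI")
  }
  if (n < 3) return(0)
  ri_table <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
                1.51, 1.48, 1.56, 1.57, 1.59)
  if (n <= 15) {
    ri <- ri_table[n]
  } else {
    warning("random index extrapolated linearly beyond n = 15", call. = FALSE)
    ri <- ri_table[15] + 0.02 * (n - 15)
  }
  ci / ri
}

#' @export
print.ahp_result <- function(x, ...) {
  cat("AHP priority vector (", x$method, "), n = ", x$n, "\n", sep = "")
  cat("  lambda_max = ", format(x$lambda_max, digits = 6),
      ", CI = ", format(x$ci, digits = 4),
      ", CR = ", format(x$cr, digits = 4), "\n", sep = "")
  top <- sort(x$weights, decreasing = TRUE)
  cat("  top weights:\n")
  print(round(utils::head(top, 5L), 4))
  invisible(x)
}
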