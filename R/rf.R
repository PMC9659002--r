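#' Random-forest stage configuration
#'
#' Defaults mirror the motivating study design: maximum tree depth 5, at
#' least 10 cases in a node before it may be split, at least 5 cases in any
#' child node, and a 663/1097 train fraction.
#'
#' @param max_depth Maximum tree depth (>= 1).
#' @param min_parent Minimum node size to attempt a split (default 10).
#' @param min_child Minimum terminal-node size (default 5; at most `min_parent`).
#' @param n_trees Number of trees (default 100).
#' @param train_fraction Fraction of observations used for training
#'   (default 663/1097).
#' @param seed Integer seed controlling the split and the forest.
#' @return An `rf_config` list.
#' @export
rf_config <- function(max_depth = 5L, min_parent = 10L, min_child = 5L,
                      n_trees = 100L, train_fraction = 663 / 1097, seed = 1L) {
  if (max_depth < 1L) stop("max_depth must be at least 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (min_child > min_parent) stop("min_child must not exceed min_parent")
  if (n_trees < 1L) stop("need at least one tree")
  structure(list(max_depth = as.integer(max_depth),
                 min_parent = as.integer(min_parent),
                 min_child = as.integer(min_child),
                 n_trees = as.integer(n_trees),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "rf_config")
}

#' Stratified train/test split by outcome level
#'
#' Deterministic given the seed: within each outcome level a proportional
#' share of observations is sampled for training (largest-remainder rounding
#' so the total training size equals `round(n * train_fraction)`); the rest
#' form the test set. Warns if any outcome class is absent from the training
#' set.
#'
#' @param levels Level matrix from [quintile_classify()].
#' @param config An [rf_config()].
#' @param outcome Outcome column name.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
rf_split <- function(levels, config = rf_config(),
                     outcome = attr(levels, "outcome") %||% "LCM") {
  n <- nrow(levels)
  if (n < 10L) stop("need at least 10 observations to split")
  y <- levels[, outcome]
  n_train <- round(n * config$train_fraction)
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(k) sum(y == k), integer(1))
  exact <- sizes * config$train_fraction
  take <- floor(exact)
  shortfall <- n_train - sum(take)
  if (shortfall > 0) {
    extra <- order(exact - take, decreasing = TRUE)[seq_len(shortfall)]
    take[extra] <- take[extra] + 1L
  } else if (shortfall < 0) {
    cut <- order(exact - take)[seq_len(-shortfall)]
    take[cut] <- take[cut] - 1L
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  train <- unlist(lapply(seq_along(classes), function(i) {
    idx <- which(y == classes[i])
    if (take[i] >= length(idx)) idx else sort(sample(idx, take[i]))
  }), use.names = FALSE)
  train <- sort(train)
  if (length(setdiff(classes, y[train])))
    warning("outcome class absent from training set", call. = FALSE)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit the random forest and report accuracy and importance
#'
#' Classifies the outcome risk level (5 classes) from the risk factors'
#' quintile levels with a Gini-impurity forest (via \pkg{ranger}) honouring
#' the depth and node-size limits of the configuration. Variable importance
#' is mean impurity decrease, normalized to sum 1; the ranking orders factors
#' by decreasing importance with alphabetical tie-break.
#'
#' @param levels Level matrix from [quintile_classify()].
#' @param config An [rf_config()].
#' @param outcome Outcome column name.
#' @param split Optional split from [rf_split()]; computed from `config` if
#'   omitted.
#' @return An `rf_report`: `accuracy` (fraction correct on the test set),
#'   `importance` (named, sums to 1), `ranking`, `n_train`, `n_test`,
#'   `config`.
#' @export
rf_fit_and_report <- function(levels, config = rf_config(),
                              outcome = attr(levels, "outcome") %||% "LCM",
                              split = NULL) {
  if (is.null(split)) split <- rf_split(levels, config, outcome)
  factors <- setdiff(colnames(levels), outcome)
  df <- as.data.frame(levels[, factors, drop = FALSE])
  df$.outcome <- factor(levels[, outcome], levels = 1:5)
  train <- df[split$train, , drop = FALSE]
  test <- df[split$test, , drop = FALSE]
  if (nrow(train) == 0L) stop("empty training set")
  if (length(unique(train$.outcome)) < 2L)
    stop("training data has a single outcome class")
  fit <- ranger::ranger(
    .outcome ~ ., data = train,
    num.trees = config$n_trees, max.depth = config$max_depth,
    min.node.size = config$min_parent, min.bucket = config$min_child,
    importance = "impurity", seed = config$seed,
    num.threads = 1L, verbose = FALSE)
  # predict() breaks tied votes with the RNG; seed it for reproducibility
  pred <- stats::predict(fit, data = test, seed = config$seed,
                         num.threads = 1L)$predictions
  imp <- fit$variable.importance[factors]
  imp[is.na(imp) | imp < 0] <- 0
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / length(factors), length(factors)), factors)
  ranking <- factors[order(-imp, factors)]
  structure(list(accuracy = mean(pred == test$.outcome),
                 importance = imp, ranking = ranking,
                 n_train = nrow(train), n_test = nrow(test),
                 config = config),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat("Random-forest report: ", x$n_train, " train / ", x$n_test,
      " test, accuracy ", sprintf("%.2f%%", 100 * x$accuracy), "\n", sep = "")
  cat("top importance:\n")
  print(round(utils::head(sort(x$importance, decreasing = TRUE), 5L), 4))
  invisible(x)
}
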