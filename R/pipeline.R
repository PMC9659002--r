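#' Overlap of the top k entries of two rankings
#'
#' @param ranking_a,ranking_b Character vectors ranking the same variable set.
#' @param k Head size (at most the number of variables).
#' @return List with `count` and `members` (the intersection of the two
#'   top-k sets).
#' @export
topk_overlap <- function(ranking_a, ranking_b, k) {
  if (!setequal(ranking_a, ranking_b) ||
      length(ranking_a) != length(ranking_b))
    stop("rankings must cover the same variable set")
  if (k > length(ranking_a) || k < 1L)
    stop("k must be in 1..", length(ranking_a))
  members <- intersect(utils::head(ranking_a, k), utils::head(ranking_b, k))
  list(count = length(members), members = members)
}

rank_of_weights <- function(weights) {
  # higher weight => better (smaller) rank; ties broken by name
  ord <- order(-weights, names(weights))
  stats::setNames(match(names(weights), names(weights)[ord]), names(weights))
}

#' Method-comparison report
#'
#' Tabulates, per risk factor, the random-forest importance rank and the
#' weight and rank under each weighting method, plus the pairwise top-k
#' overlap between all rankings.
#'
#' @param weight_groups Named list of weight vectors (chisq, ridit, ahp).
#' @param rf An `rf_report`.
#' @param k Top-k size for the overlap summary (default 10).
#' @return A `comparison_report`: `table` (one row per factor), `overlaps`
#'   (named list of [topk_overlap()] results), `k`.
#' @export
comparison_report <- function(weight_groups, rf, k = 10L) {
  vars <- rf$ranking
  tab <- data.frame(variable = vars,
                    rf_rank = stats::setNames(seq_along(vars), vars)[vars],
                    row.names = NULL)
  rankings <- list(rf = vars)
  for (m in names(weight_groups)) {
    w <- weight_groups[[m]][vars]
    r <- rank_of_weights(w)
    tab[[paste0(m, "_weight")]] <- unname(w)
    tab[[paste0(m, "_rank")]] <- unname(r[vars])
    rankings[[m]] <- vars[order(r[vars])]
  }
  pairs <- utils::combn(names(rankings), 2L, simplify = FALSE)
  overlaps <- lapply(pairs, function(p)
    topk_overlap(rankings[[p[1]]], rankings[[p[2]]], k))
  names(overlaps) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  structure(list(table = tab[order(tab$rf_rank), ], overlaps = overlaps,
                 rankings = rankings, k = as.integer(k)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Method comparison (top ", x$k, " overlap counts):\n", sep = "")
  for (nm in names(x$overlaps))
    cat("  ", nm, ": ", x$overlaps[[nm]]$count, "\n", sep = "")
  print(utils::head(x$table, x$k), row.names = FALSE)
  invisible(x)
}

#' Run the full weighting pipeline
#'
#' Executes ingestion (or synthetic generation), quintile classification, the
#' three weighting stages, fuzzy composition with lattice-nearness selection,
#' the random-forest stage, and the method-comparison report. Deterministic
#' given the seed. When `out_dir` is given, every stage artifact is written
#' (CSV/JSON) together with a `manifest.json` listing them.
#'
#' @param config Either a YAML file path or a list with (all optional)
#'   entries:
#'   * `simulate`: arguments for [synthetic_config()] (used when no `data`);
#'   * `data`: path of a long-format CSV to ingest (with optional `schema`);
#'   * `unit`: observation unit for [crude_rates()];
#'   * `pairwise_matrix`: CSV path for the AHP stage (default: the packaged
#'     expert matrix);
#'   * `ahp_method`: prioritization method (default `column_norm_mean`);
#'   * `rf`: arguments for [rf_config()];
#'   * `top_k`: comparison head size (default 10);
#'   * `seed`: master seed (default 1), used for simulation and the forest
#'     unless those blocks set their own.
#' @param out_dir Optional output directory for stage artifacts.
#' @return A `fim_pipeline` list with `rates`, `levels`, `weights` (list of
#'   the three groups), `stages` (full stage outputs), `nearness`, `rf`,
#'   `comparison`, `truth` (if simulated), and `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  unit <- config$unit %||% "country-year"
  top_k <- config$top_k %||% 10L

  truth <- NULL
  if (!is.null(config$data)) {
    table <- read_mortality_table(config$data,
                                  schema = config$schema,
                                  variables = config$variables %||% fim_variables())
  } else {
    sim_args <- config$simulate %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- generate_mortality_data(do.call(synthetic_config, sim_args))
    table <- sim$table
    truth <- sim$truth
  }

  rates <- crude_rates(table, unit = unit)
  levels <- quintile_classify(rates)

  a1 <- chisq_stage(rates, levels)
  a2 <- ridit_stage(levels)
  matrix_path <- config$pairwise_matrix %||%
    system.file("extdata", "table6_pairwise.csv", package = "fimrisk")
  pm <- read_pairwise_matrix(matrix_path)
  factors <- setdiff(colnames(levels), attr(levels, "outcome") %||% "LCM")
  if (!all(factors %in% rownames(pm)))
    stop("pairwise matrix does not cover the risk-factor set: missing ",
         paste(utils::head(setdiff(factors, rownames(pm)), 5), collapse = ", "))
  a3 <- priority_vector(pm[factors, factors],
                        method = config$ahp_method %||% "column_norm_mean")

  weights <- list(chisq = stats::setNames(a1$weight, a1$variable),
                  ridit = stats::setNames(a2$weight, a2$variable),
                  ahp = a3$weights[factors])

  R <- membership_matrix(levels)
  C <- if (!is.null(config$reference)) {
    ref <- as.numeric(config$reference)
    ref / sum(ref)
  } else reference_membership(rates, levels)
  nearness <- nearness_comparison(weights, R, C)

  rf_args <- config$rf %||% list()
  if (is.null(rf_args$seed)) rf_args$seed <- seed
  rfc <- do.call(rf_config, rf_args)
  rf <- rf_fit_and_report(levels, rfc)

  comparison <- comparison_report(weights, rf, k = top_k)

  manifest <- c("data", "levels", "a1", "a2", "a3", "nearness", "rf_report",
                "comparison")
  result <- structure(list(table = table, rates = rates, levels = levels,
                           stages = list(chisq = a1, ridit = a2, ahp = a3),
                           weights = weights, membership = R, reference = C,
                           nearness = nearness, rf = rf,
                           comparison = comparison, truth = truth,
                           seed = seed, manifest = manifest),
                      class = "fim_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_mortality_table(result$table, p("data.csv"))
  utils::write.csv(data.frame(observation = rownames(result$levels),
                              result$levels, check.names = FALSE),
                   p("levels.csv"), row.names = FALSE)
  utils::write.csv(result$stages$chisq, p("a1.csv"), row.names = FALSE)
  utils::write.csv(result$stages$ridit, p("a2.csv"), row.names = FALSE)
  utils::write.csv(data.frame(variable = names(result$weights$ahp),
                              weight = unname(result$weights$ahp)),
                   p("a3.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(table = result$nearness$table, selected = result$nearness$selected,
         reference = result$reference),
    p("nearness.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(accuracy = result$rf$accuracy,
         importance = as.list(result$rf$importance),
         ranking = result$rf$ranking,
         n_train = result$rf$n_train, n_test = result$rf$n_test),
    p("rf_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$comparison$table, p("comparison.csv"),
                   row.names = FALSE)
  files <- c(data = "data.csv", levels = "levels.csv", a1 = "a1.csv",
             a2 = "a2.csv", a3 = "a3.csv", nearness = "nearness.json",
             rf_report = "rf_report.json", comparison = "comparison.csv")
  jsonlite::write_json(list(seed = result$seed, artifacts = as.list(files)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.fim_pipeline <- function(x, ...) {
  cat("fimrisk pipeline: ", nrow(x$levels), " observations x ",
      ncol(x$levels) - 1L, " risk factors (seed ", x$seed, ")\n", sep = "")
  print(x$nearness)
  cat("\n")
  print(x$rf)
  invisible(x)
}
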