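#' Configuration for the synthetic mortality-table generator
#'
#' Describes a GBD-like study: `n_countries` observed over `years`, with crude
#' mortality rates for each variable and the outcome. Each country has a
#' latent severity score z ~ N(0, 1); an informative variable v has
#' log-rate = baseline_v + effect_v * z + noise, a non-informative variable
#' omits the z term, and the outcome has log-rate = baseline + z + noise, so
#' informative variables are monotonically associated with the outcome on the
#' rate scale.
#'
#' @param n_countries Number of countries (default 100; at least 5).
#' @param years Integer vector of calendar years (default 2006:2016).
#' @param variables Risk-factor names (default [fim_variables()]).
#' @param informative Subset of `variables` with a planted outcome
#'   association (default the five factors Smoking, LPA, CW, LBW, IDY).
#' @param effect_sizes Positive association coefficients for the informative
#'   variables; scalar recycled (default 1).
#' @param baseline_log_mean,baseline_log_sd Log-scale mean and sd from which
#'   each variable's baseline log crude rate is drawn (defaults log(1e-4), 0.5 —
#'   crude rates of order 10 per 100,000).
#' @param noise_sd Standard deviation of the lognormal observation noise on
#'   the log-rate scale (default 0.5).
#' @param population_log_mean,population_log_sd Lognormal parameters for
#'   country-year population (defaults log(1e7), 0.5).
#' @param missing_rows Number of country-year observations deleted at random
#'   (all variables for that unit; default 3, so the default design yields
#'   100 x 11 - 3 = 1097 observations).
#' @param outcome Outcome variable name (default `"LCM"`).
#' @param seed Integer seed; the same config (including seed) reproduces the
#'   table exactly.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_countries = 100L, years = 2006:2016,
                             variables = fim_variables(),
                             informative = c("Smoking", "LPA", "CW", "LBW", "IDY"),
                             effect_sizes = 1,
                             baseline_log_mean = log(1e-4),
                             baseline_log_sd = 0.5,
                             noise_sd = 0.5,
                             population_log_mean = log(1e7),
                             population_log_sd = 0.5,
                             missing_rows = 3L,
                             outcome = "LCM", seed = 1L) {
  if (n_countries < 5L) stop("n_countries must be at least 5")
  if (!length(years)) stop("years must be non-empty")
  if (anyDuplicated(variables)) stop("duplicate variable names")
  if (!all(informative %in% variables))
    stop("informative set must be a subset of variables")
  effect_sizes <- rep_len(effect_sizes, length(informative))
  names(effect_sizes) <- informative
  if (length(informative) && any(effect_sizes <= 0))
    stop("effect sizes must be positive")
  if (missing_rows < 0L || missing_rows >= n_countries * length(years))
    stop("missing_rows must be in [0, n_countries * n_years)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_countries = as.integer(n_countries),
                 years = as.integer(years), variables = variables,
                 informative = informative, effect_sizes = effect_sizes,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, noise_sd = noise_sd,
                 population_log_mean = population_log_mean,
                 population_log_sd = population_log_sd,
                 missing_rows = as.integer(missing_rows),
                 outcome = outcome, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic mortality table with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with components `table` (a `mortality_table` in long format)
#'   and `truth` (a `ground_truth` list recording the informative set, effect
#'   sizes, per-country latent severity z, and the seed).
#' @export
generate_mortality_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  countries <- sprintf("C%03d", seq_len(config$n_countries))
  vars <- c(config$variables, config$outcome)
  nv <- length(vars); ny <- length(config$years); nc <- config$n_countries

  z <- stats::rnorm(nc)
  names(z) <- countries
  baselines <- stats::rnorm(nv, config$baseline_log_mean, config$baseline_log_sd)
  names(baselines) <- vars
  effects <- stats::setNames(numeric(nv), vars)
  effects[names(config$effect_sizes)] <- config$effect_sizes
  effects[config$outcome] <- 1

  grid <- expand.grid(country = countries, year = config$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  population <- stats::rlnorm(nrow(grid), config$population_log_mean,
                              config$population_log_sd)

  long <- expand.grid(country = countries, year = config$years,
                      variable = vars, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  zi <- z[long$country]
  lograte <- baselines[long$variable] + effects[long$variable] * zi +
    stats::rnorm(nrow(long), 0, config$noise_sd)
  pop <- rep(population, times = nv)
  long$deaths <- round(exp(lograte) * pop)
  long$population <- pop

  if (config$missing_rows > 0L) {
    drop_units <- sample(nrow(grid), config$missing_rows)
    drop_key <- paste(grid$country[drop_units], grid$year[drop_units])
    long <- long[!paste(long$country, long$year) %in% drop_key, , drop = FALSE]
  } else {
    drop_key <- character(0)
  }
  rownames(long) <- NULL

  table <- as_mortality_table(long, variables = config$variables,
                              outcome = config$outcome)
  truth <- structure(list(informative = config$informative,
                          effect_sizes = config$effect_sizes,
                          variables = config$variables,
                          z = z, dropped_units = drop_key,
                          seed = config$seed),
                     class = "ground_truth")
  list(table = table, truth = truth)
}

#' Fraction of planted informative factors recovered in the top k
#'
#' @param ranking Character vector: all risk-factor names ordered from most to
#'   least important.
#' @param truth A `ground_truth` from [generate_mortality_data()].
#' @param k Size of the head of the ranking to inspect.
#' @return Fraction (in `[0, 1]`) of the informative set found among the top
#'   `k` entries of `ranking`.
#' @export
recovery_report <- function(ranking, truth, k) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!setequal(ranking, truth$variables) ||
      length(ranking) != length(truth$variables))
    stop("ranking must be a permutation of the ground-truth variable set")
  if (k > length(ranking) || k < 1L) stop("k must be in 1..", length(ranking))
  if (!length(truth$informative))
    stop("ground truth has an empty informative set")
  length(intersect(utils::head(ranking, k), truth$informative)) /
    length(truth$informative)
}
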