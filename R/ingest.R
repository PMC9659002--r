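#' Canonical risk-factor vocabulary
#'
#' The 30 risk-factor acronyms used as independent variables (disease burden,
#' tuberculosis, unsafe water source, ..., diet low in nuts and seeds).
#' Mortality tables additionally carry the outcome variable, `"LCM"` (lung
#' cancer mortality) by default.
#'
#' @return Character vector of 30 acronyms.
#' @export
fim_variables <- function() {
  c("DB", "TB", "UWS", "USN", "NHF", "HAP", "NEB", "DBF", "CW", "CS",
    "LBW", "SHS", "AU", "DU", "DLF", "DLV", "USX", "LPA", "HFP", "HBM",
    "HBP", "IDY", "Smoking", "VAD", "LBD", "AP", "OAP", "DHS", "DLG", "DLN")
}

#' Read and validate a long-format mortality table
#'
#' Reads a GBD-style long CSV with one row per (country, year, variable) and
#' validates it: required columns present, no duplicate triples, deaths
#' non-negative, population positive, and the variable vocabulary restricted
#' to a configured set.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping the standard column
#'   names (`country`, `year`, `variable`, `deaths`, `population`) to the
#'   column names used in the file, e.g. `c(country = "location_name")`.
#' @param variables Permitted risk-factor names; defaults to [fim_variables()].
#' @param outcome Name of the outcome variable; default `"LCM"`.
#' @param strict If `TRUE` (default) any invalid row is an error naming the
#'   offending rows; if `FALSE` invalid rows are dropped and recorded in the
#'   `"rejected"` attribute with a per-row reason.
#' @return A `mortality_table` (a validated data frame with columns country,
#'   year, variable, deaths, population).
#' @export
read_mortality_table <- function(path, schema = NULL,
                                 variables = fim_variables(),
                                 outcome = "LCM", strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  std <- c("country", "year", "variable", "deaths", "population")
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), std)
    if (length(bad)) stop("unknown schema keys: ", paste(bad, collapse = ", "))
    for (nm in names(schema)) {
      if (!schema[[nm]] %in% names(raw))
        stop("schema error: column '", schema[[nm]], "' (mapped to '", nm,
             "') not present in ", path)
      names(raw)[names(raw) == schema[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(std, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[std]
  as_mortality_table(raw, variables = variables, outcome = outcome,
                     strict = strict)
}

#' Validate a data frame as a mortality table
#'
#' @param df Data frame with columns country, year, variable, deaths, population.
#' @inheritParams read_mortality_table
#' @return A `mortality_table`.
#' @export
as_mortality_table <- function(df, variables = fim_variables(),
                               outcome = "LCM", strict = TRUE) {
  vocab <- c(variables, outcome)
  reason <- character(nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[cond & reason == ""] <<- why
  }
  flag(is.na(df$deaths) | df$deaths < 0, "negative or missing deaths")
  flag(is.na(df$population) | df$population <= 0, "non-positive population")
  flag(!df$variable %in% vocab, "variable outside configured vocabulary")
  key <- paste(df$country, df$year, df$variable, sep = "\r")
  flag(duplicated(key) | duplicated(key, fromLast = TRUE),
       "duplicate (country, year, variable) triple")
  bad <- which(reason != "")
  if (length(bad)) {
    log <- data.frame(row = bad, reason = reason[bad])
    if (strict) {
      show <- utils::head(log, 5L)
      stop("validation error in ", length(bad), " row(s), e.g. ",
           paste(sprintf("row %d (%s)", show$row, show$reason),
                 collapse = "; "))
    }
    message("dropping ", length(bad), " invalid row(s)")
    df <- df[-bad, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "rejected") <- log
  }
  df$year <- as.integer(df$year)
  attr(df, "variables") <- variables
  attr(df, "outcome") <- outcome
  class(df) <- c("mortality_table", "data.frame")
  df
}

#' Write a mortality table to CSV
#'
#' @param table A `mortality_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mortality_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("country", "year", "variable",
                                            "deaths", "population")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Crude mortality rates per observation unit
#'
#' Computes crude rates (deaths per person) and pivots them to an
#' observations x variables matrix. With `unit = "country-year"` each
#' (country, year) pair is an observation and the rate is deaths/population
#' for that row. With `unit = "country"` the rate is the mean of deaths over
#' the available years divided by the mean population over those years.
#' Observation units missing any variable are dropped listwise with a message.
#'
#' @param table A `mortality_table`.
#' @param unit Observation unit, `"country-year"` (default) or `"country"`.
#' @return Numeric matrix of crude rates; rows are observation units, columns
#'   variables (risk factors plus the outcome). Attribute `"unit"` records the
#'   unit used.
#' @export
crude_rates <- function(table, unit = c("country-year", "country")) {
  unit <- match.arg(unit)
  stopifnot(inherits(table, "mortality_table"))
  df <- as.data.frame(table)
  if (unit == "country-year") {
    df$obs <- paste(df$country, df$year, sep = ":")
    df$rate <- df$deaths / df$population
  } else {
    # average deaths and average population per country across years
    md <- stats::aggregate(deaths ~ country + variable, df, mean)
    pop <- unique(df[, c("country", "year", "population")])
    mp <- stats::aggregate(population ~ country, pop, mean)
    df <- merge(md, mp, by = "country")
    df$obs <- df$country
    df$rate <- df$deaths / df$population
  }
  vars <- intersect(c(attr(table, "variables"), attr(table, "outcome")),
                    unique(df$variable))
  m <- tapply(df$rate, list(df$obs, factor(df$variable, levels = vars)),
              identity)
  incomplete <- apply(m, 1L, anyNA)
  if (any(incomplete)) {
    message("dropping ", sum(incomplete),
            " observation(s) with missing variables: ",
            paste(utils::head(rownames(m)[incomplete], 5L), collapse = ", "),
            if (sum(incomplete) > 5L) ", ..." else "")
    m <- m[!incomplete, , drop = FALSE]
  }
  storage.mode(m) <- "double"
  attr(m, "unit") <- unit
  attr(m, "outcome") <- attr(table, "outcome")
  m
}

#' Quintile risk-level classification
#'
#' Classifies every variable of a rate matrix into five ordered risk levels
#' (1 = very low ... 5 = very high) by quintiles: observations are ranked by
#' rate (ties broken by original row order) and cut at ranks
#' `ceiling(n * k / 5)`, k = 1..4. A constant column carries no ordering
#' information and is assigned level 1 throughout, with a warning.
#'
#' @param rates Numeric matrix from [crude_rates()] (observations x variables).
#' @return Integer matrix of the same shape with values in 1..5; attributes
#'   carried over from `rates`.
#' @export
quintile_classify <- function(rates) {
  stopifnot(is.matrix(rates), is.numeric(rates))
  n <- nrow(rates)
  if (n < 5L) stop("need at least 5 observations per variable, got ", n)
  cuts <- ceiling(n * (1:4) / 5)
  out <- apply(rates, 2L, function(x) {
    if (length(unique(x)) == 1L) {
      warning("constant column: all observations assigned level 1",
              call. = FALSE)
      return(rep(1L, n))
    }
    r <- rank(x, ties.method = "first")
    1L + rowSums(outer(r, cuts, `>`))
  })
  out <- matrix(as.integer(out), nrow = n, dimnames = dimnames(rates))
  attr(out, "unit") <- attr(rates, "unit")
  attr(out, "outcome") <- attr(rates, "outcome")
  out
}

#' Risk-level frequencies for one variable
#'
#' @param levels Integer level matrix from [quintile_classify()].
#' @param variable Column name.
#' @return Integer vector of length 5 (counts at levels 1..5), summing to the
#'   number of observations.
#' @export
level_frequencies <- function(levels, variable) {
  if (!variable %in% colnames(levels))
    stop("unknown variable: ", variable)
  tabulate(levels[, variable], nbins = 5L)
}
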