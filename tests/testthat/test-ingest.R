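test_that("a valid long CSV round-trips through read/write", {
  df <- make_long_table(nc = 2, ny = 1, variables = fim_variables())
  expect_equal(nrow(df), 62)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  tbl <- read_mortality_table(path)
  expect_s3_class(tbl, "mortality_table")
  expect_equal(nrow(tbl), 62)

  out <- withr::local_tempfile(fileext = ".csv")
  write_mortality_table(tbl, out)
  again <- read_mortality_table(out)
  expect_equal(as.data.frame(again), as.data.frame(tbl))
})

test_that("schema mapping renames columns and missing columns are an error", {
  df <- make_long_table()
  names(df)[names(df) == "country"] <- "location_name"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_mortality_table(path), "schema error")
  tbl <- read_mortality_table(path, schema = c(country = "location_name"),
                              variables = c("DB", "TB"))
  expect_equal(sort(unique(tbl$variable)), c("DB", "LCM", "TB"))
})

test_that("invalid rows are rejected with a reason, or dropped when not strict", {
  df <- make_long_table(variables = c("DB", "TB"))
  df$population[3] <- 0
  df$deaths[5] <- -1
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_mortality_table(path, variables = c("DB", "TB")),
               "row 3")
  tbl <- suppressMessages(
    read_mortality_table(path, variables = c("DB", "TB"), strict = FALSE))
  rej <- attr(tbl, "rejected")
  expect_equal(rej$row, c(3L, 5L))
  expect_match(rej$reason[1], "population")
  expect_equal(nrow(tbl), nrow(df) - 2)

  dup <- rbind(df[1, ], df)
  expect_error(as_mortality_table(dup, variables = c("DB", "TB")),
               "duplicate")
})

test_that("crude rates divide deaths by population per unit", {
  df <- data.frame(country = "A", year = 2006, variable = c("DB", "LCM"),
                   deaths = c(50, 10), population = 1e6)
  tbl <- as_mortality_table(df, variables = "DB")
  r <- crude_rates(tbl, unit = "country-year")
  expect_equal(unname(r["A:2006", "DB"]), 5e-5)

  # country unit: mean deaths over years / mean population over years
  df2 <- data.frame(country = "A", year = c(2006, 2007, 2006, 2007),
                    variable = c("DB", "DB", "LCM", "LCM"),
                    deaths = c(40, 60, 5, 5), population = 1e6)
  r2 <- crude_rates(as_mortality_table(df2, variables = "DB"),
                    unit = "country")
  expect_equal(unname(r2["A", "DB"]), 5e-5)
})

test_that("units missing a variable are dropped listwise", {
  df <- make_long_table(nc = 4, ny = 2, variables = c("DB", "TB"))
  df <- df[!(df$country == "C02" & df$year == 2006 & df$variable == "TB"), ]
  tbl <- as_mortality_table(df, variables = c("DB", "TB"))
  expect_message(r <- crude_rates(tbl), "dropping 1 observation")
  expect_equal(nrow(r), 7)
  expect_false("C02:2006" %in% rownames(r))
})

test_that("quintile classification matches the brute-force rank-split oracle", {
  expect_equal(unname(quintile_classify(cbind(v = c(1, 2, 3, 4, 5)))[, 1]),
               1:5)
  expect_equal(unname(quintile_classify(cbind(v = 1:10))[, 1]),
               rep(1:5, each = 2))
  set.seed(99)
  for (n in c(5, 7, 23, 101, 200)) {
    x <- sample(round(runif(n), 2), n, replace = TRUE)  # induces ties
    got <- quintile_classify(cbind(v = x))[, 1]
    expect_equal(unname(got), oracle_quintile(x), info = paste("n =", n))
  }
})

test_that("quintile levels are balanced, monotone in rate, and equivariant", {
  set.seed(7)
  x <- runif(1097)
  lv <- quintile_classify(cbind(v = x))[, 1]
  expect_equal(sort(as.integer(table(lv)), decreasing = TRUE),
               c(220L, 220L, 219L, 219L, 219L))
  # monotone: lower rate never gets a higher level
  ord <- order(x)
  expect_true(all(diff(lv[ord]) >= 0))
  # scaling deaths by c > 0 leaves levels unchanged
  expect_equal(quintile_classify(cbind(v = 3.7 * x))[, 1], lv)
  # permuting rows permutes levels identically
  p <- sample(length(x))
  expect_equal(unname(quintile_classify(cbind(v = x[p]))[, 1]),
               unname(lv[p]))
})

test_that("degenerate inputs to quintile classification are handled", {
  expect_error(quintile_classify(cbind(v = 1:4)), "at least 5")
  expect_warning(lv <- quintile_classify(cbind(v = rep(2, 9))), "constant")
  expect_equal(unname(lv[, 1]), rep(1L, 9))
})

test_that("level frequencies count observations per level", {
  lv <- cbind(v = 1:5)
  expect_equal(level_frequencies(quintile_classify(cbind(v = 1:5)), "v"),
               rep(1L, 5))
  expect_error(level_frequencies(quintile_classify(cbind(v = 1:5)), "nope"),
               "unknown variable")
  # the published pooled frequencies sum to the published n
  t4 <- fim_fixture("table4_frequencies")
  expect_equal(sum(t4$frequency), 1097)
})
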