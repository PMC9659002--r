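# Shared fixtures and independent oracles.

# Tiny long-format table: nc countries x ny years x the given variables (+ LCM),
# rates drawn freely; returns a valid data frame (not yet a mortality_table).
make_long_table <- function(nc = 2, ny = 1, variables = c("DB", "TB"),
                            outcome = "LCM", seed = 42) {
  set.seed(seed)
  grid <- expand.grid(country = sprintf("C%02d", seq_len(nc)),
                      year = 2006 + seq_len(ny) - 1,
                      variable = c(variables, outcome),
                      stringsAsFactors = FALSE)
  grid$population <- 1e6
  grid$deaths <- rpois(nrow(grid), 50)
  grid
}

# Brute-force quintile oracle: sort values (stable), cut sorted positions at
# index ceiling(n * k / 5).
oracle_quintile <- function(x) {
  n <- length(x)
  cuts <- ceiling(n * (1:4) / 5)
  ord <- order(x)                      # stable in R
  lv <- integer(n)
  pos_level <- 1L + rowSums(outer(seq_len(n), cuts, `>`))
  lv[ord] <- pos_level
  lv
}

# Mid-rank ridit oracle: expand frequencies to observations, mid-rank each,
# average within level, divide by n.
oracle_ridit <- function(freq) {
  obs <- rep(seq_along(freq), freq)
  mr <- rank(obs, ties.method = "average")
  n <- length(obs)
  r <- as.vector(tapply(mr, factor(obs, levels = seq_along(freq)), mean)) /
    n - 0.5 / n
  # an empty level has no observations; its mid-rank position is the
  # cumulative count below it
  empty <- freq == 0
  r[empty] <- (cumsum(freq) - freq)[empty] / n
  r
}

# Consistent AHP matrix from a weight vector.
consistent_matrix <- function(w) {
  m <- outer(w, w, "/")
  dimnames(m) <- list(names(w), names(w))
  m
}

# Random membership vector of length 5 (non-negative, sums to 1).
random_membership <- function() {
  v <- runif(5)
  v / sum(v)
}

# Level matrix with a planted relationship: `match_var` equals the LCM level
# column exactly, all other variables are independent uniform levels.
make_levels <- function(n = 250, vars = paste0("V", 1:6), match_var = NULL,
                        seed = 1) {
  set.seed(seed)
  lcm <- oracle_quintile(runif(n))
  m <- sapply(vars, function(v) sample(1:5, n, replace = TRUE))
  if (!is.null(match_var)) m[, match_var] <- lcm
  out <- cbind(m, LCM = lcm)
  storage.mode(out) <- "integer"
  attr(out, "outcome") <- "LCM"
  out
}
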