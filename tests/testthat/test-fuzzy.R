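test_that("membership rows are point masses or uniform in degenerate cases", {
  # single observation agreeing with the outcome at level 3
  lv <- cbind(A = 3L, LCM = 3L)
  attr(lv, "outcome") <- "LCM"
  R <- membership_matrix(lv)
  expect_equal(unname(R["A", ]), c(0, 0, 1, 0, 0))

  # factor identical to the outcome with balanced quintiles: uniform row
  lv2 <- make_levels(n = 250, vars = "X", match_var = "X", seed = 3)
  R2 <- membership_matrix(lv2)
  expect_equal(unname(R2["X", ]), rep(0.2, 5))

  # no agreement anywhere: uniform row with a warning
  lv3 <- cbind(A = rep(1:5, 4), LCM = rep(c(2:5, 1L), 4))
  attr(lv3, "outcome") <- "LCM"
  expect_warning(R3 <- membership_matrix(lv3), "uniform")
  expect_equal(unname(R3["A", ]), rep(0.2, 5))
})

test_that("membership rows of independent factors are near uniform", {
  set.seed(14)
  devs <- replicate(20, {
    lv <- make_levels(n = 500, vars = "X", seed = sample.int(1e6, 1))
    max(abs(membership_matrix(lv)["X", ] - 0.2))
  })
  expect_lt(mean(devs), 0.1)
  # every row sums to 1 on arbitrary data
  lv <- make_levels(n = 80, vars = paste0("V", 1:4), seed = 6)
  expect_equal(unname(rowSums(membership_matrix(lv))), rep(1, 4))
})

test_that("fuzzy composition is the normalized weight-membership product", {
  R <- rbind(a = c(0.5, 0.5, 0, 0, 0), b = c(0, 0, 0, 0.5, 0.5),
             c = rep(0.2, 5), d = c(1, 0, 0, 0, 0))
  colnames(R) <- paste0("l", 1:5)
  # point mass on one variable returns that row
  expect_equal(unname(fuzzy_compose(c(a = 1, b = 0, c = 0, d = 0), R)),
               unname(R["a", ]))
  # uniform weights over identical rows return the row
  R2 <- rbind(a = c(0.1, 0.2, 0.3, 0.2, 0.2), b = c(0.1, 0.2, 0.3, 0.2, 0.2))
  expect_equal(unname(fuzzy_compose(c(a = 0.5, b = 0.5), R2)),
               c(0.1, 0.2, 0.3, 0.2, 0.2))
  # brute-force dot-product oracle on random inputs
  set.seed(44)
  for (i in 1:20) {
    A <- runif(4); A <- A / sum(A); names(A) <- rownames(R)[1:4]
    B <- fuzzy_compose(A, R)
    oracle <- sapply(1:5, function(l) sum(A * R[names(A), l]))
    expect_equal(unname(B), oracle / sum(oracle))
    expect_equal(sum(B), 1)
    expect_true(all(B >= 0))
  }
  expect_error(fuzzy_compose(c(x = 1), R), "match")
})

test_that("inner/outer compositions and nearness have their closed forms", {
  C <- c(0.0292, 0.0718, 0.1541, 0.3066, 0.4383)
  expect_equal(inner_composition(C, C), max(C))
  expect_equal(outer_composition(C, C), min(C))
  expect_equal(lattice_nearness(C, C), 0.5 * (max(C) + 1 - min(C)))
  expect_equal(lattice_nearness(C, C), 0.70455)

  expect_equal(inner_composition(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1)), 0)
  expect_equal(outer_composition(rep(0.2, 5), rep(0.2, 5)), 0.2)
  expect_equal(lattice_nearness(rep(0.2, 5), rep(0.2, 5)), 0.5)
})

test_that("nearness is symmetric and respects its lattice bounds", {
  set.seed(55)
  for (i in 1:50) {
    B <- random_membership(); C <- random_membership()
    s <- lattice_nearness(B, C)
    expect_equal(s, lattice_nearness(C, B))
    expect_gte(s, 0.5 * (1 - min(pmax(B, C))))
    expect_lte(s, 0.5 * (1 + max(pmin(B, C))))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("select_optimal picks the maximal method with deterministic ties", {
  expect_equal(select_optimal(c(chisq = 0.6936, ridit = 0.6918, ahp = 0.6671)),
               "chisq")
  expect_equal(select_optimal(c(only = 0.4)), "only")
  expect_message(sel <- select_optimal(c(ahp = 0.5, ridit = 0.5)), "tie")
  expect_equal(sel, "ridit")
  expect_error(select_optimal(numeric(0)), "no nearness")
})

test_that("the reference vector tracks the outcome's rate mass by level", {
  rates <- cbind(A = runif(10), LCM = rep(0.3, 10))
  levels <- cbind(A = rep(3L, 10), LCM = rep(4L, 10))
  attr(levels, "outcome") <- "LCM"
  expect_equal(unname(reference_membership(rates, levels)),
               c(0, 0, 0, 1, 0))

  lv <- make_levels(n = 250, vars = "X", seed = 10)
  rates2 <- cbind(X = runif(250), LCM = rep(0.1, 250))
  lv2 <- lv
  expect_equal(unname(reference_membership(rates2, lv2)), rep(0.2, 5),
               tolerance = 1e-12)

  # increasing across levels for monotone rate-to-level assignment
  set.seed(66)
  for (i in 1:10) {
    r <- sort(runif(100))
    lvm <- cbind(LCM = rep(1:5, each = 20))
    attr(lvm, "outcome") <- "LCM"
    C <- reference_membership(cbind(LCM = r), lvm)
    expect_true(all(diff(C) > 0))
  }
  expect_error(reference_membership(cbind(LCM = rep(0, 10)),
                                    {l <- cbind(LCM = rep(1L, 10))
                                     attr(l, "outcome") <- "LCM"; l}),
               "zero")
})

test_that("the published nearness table reproduces end to end", {
  fix <- fim_fixture("table8_nearness")
  sigmas <- sapply(c("chisq", "ridit", "ahp"), function(m) {
    v <- reconstruct_membership(m, fix)
    lattice_nearness(v$B, v$C)
  })
  expect_equal(round(100 * sigmas["chisq"], 2), c(chisq = 69.36))
  expect_equal(round(100 * sigmas["ahp"], 2), c(ahp = 66.71))
  expect_equal(select_optimal(sigmas), "chisq")

  # reconstructed composed vectors reproduce the printed inner/outer rows
  v <- reconstruct_membership("chisq", fix)
  expect_equal(unname(round(100 * pmin(v$B, v$C), 2)),
               c(2.92, 7.18, 14.48, 23.44, 43.83))
  expect_equal(unname(round(100 * pmax(v$B, v$C), 2)),
               c(5.11, 9.52, 15.41, 30.66, 47.44))
  expect_equal(round(100 * inner_composition(v$B, v$C), 2), 43.83)
  expect_equal(round(100 * outer_composition(v$B, v$C), 2), 5.11)
})
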