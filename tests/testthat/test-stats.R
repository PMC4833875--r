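test_that("ROR matches the published worked examples and conventions", {
  expect_equal(round(ror(c(3287, 62998, 64291, 3683647)), 2), 2.99)
  expect_equal(round(ror(c(1098, 7903, 66480, 3738742)), 2), 7.81)
  expect_equal(ror(c(1, 1, 1, 1)), 1.0)
  expect_identical(ror(c(5, 0, 10, 100)), Inf)
  expect_true(is.nan(ror(c(0, 0, 0, 5))))
  expect_equal(ror(c(1, 1, 1, 1), haldane = TRUE), 1.0)
  expect_gt(ror(c(5, 0, 10, 100), haldane = TRUE), 0)
})

test_that("ROR reciprocity under column swap", {
  set.seed(11)
  for (i in 1:50) {
    x <- sample(1:40, 4, replace = TRUE)
    expect_equal(ror(c(x[2], x[1], x[4], x[3])), 1 / ror(x))
  }
})

test_that("log-space Fisher matches enumeration and base R on small tables", {
  expect_equal(fisher_exact_log(c(5, 5, 5, 5)), 0)
  expect_equal(exp(fisher_exact_log(c(2, 3, 4, 5))), fisher_enum(2, 3, 4, 5),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:60) {
    x <- sample(0:25, 4, replace = TRUE)
    if (any(c(x[1] + x[2], x[3] + x[4], x[1] + x[3], x[2] + x[4]) == 0)) next
    m <- matrix(x, 2, byrow = TRUE)
    expect_equal(exp(fisher_exact_log(x)),
                 fisher.test(m)$p.value, tolerance = 1e-8)
    expect_equal(exp(fisher_exact_log(x, "greater")),
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-8)
    expect_equal(exp(fisher_exact_log(x, "less")),
                 fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-8)
  }
  expect_error(fisher_exact_log(c(0, 0, 3, 4)), "degenerate margin")
})

test_that("Fisher P survives far below double-precision underflow", {
  lp <- fisher_exact_log(c(3287, 62998, 64291, 3683647)) / log(10)
  expect_lt(lp, -308)  # displays as 0
  expect_true(is.finite(lp))
})

test_that("Fisher test is invariant under transpose and double swap", {
  set.seed(7)
  for (i in 1:40) {
    x <- sample(1:30, 4, replace = TRUE)
    transposed <- c(x[1], x[3], x[2], x[4])
    double_swapped <- c(x[4], x[3], x[2], x[1])
    expect_equal(fisher_exact_log(transposed), fisher_exact_log(x),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_log(double_swapped), fisher_exact_log(x),
                 tolerance = 1e-12)
  }
})

test_that("one-sided P is monotone in n11 along fixed margins", {
  set.seed(13)
  for (i in 1:20) {
    x <- sample(2:25, 4, replace = TRUE)
    p1 <- fisher_exact_log(x, "greater")
    shifted <- c(x[1] + 1, x[2] - 1, x[3] - 1, x[4] + 1)
    if (any(shifted < 0)) next
    expect_lte(fisher_exact_log(shifted, "greater"), p1 + 1e-12)
  }
})

test_that("conditional MLE odds ratio solves the expected-count equation", {
  expect_equal(conditional_mle_or(c(1, 1, 1, 1)), 1.0)
  # published enrichment table: prints as 9.21 at fisher.test's precision
  or <- conditional_mle_or(c(48, 8, 247, 380))
  expect_equal(or, 9.2035, tolerance = 1e-4)
  expect_equal(or, unname(fisher.test(matrix(c(48, 8, 247, 380), 2,
                                             byrow = TRUE))$estimate),
               tolerance = 1e-3)
  # boundary conventions
  expect_identical(conditional_mle_or(c(5, 0, 3, 7)), Inf)
  expect_identical(conditional_mle_or(c(0, 5, 7, 3)), 0)
})

test_that("conditional MLE matches a grid-search likelihood maximizer", {
  grid_mle <- function(x) {
    r1 <- x[1] + x[2]; c1 <- x[1] + x[3]; N <- sum(x)
    lo <- max(0, c1 - (N - r1)); hi <- min(r1, c1)
    k <- lo:hi
    base <- choose(r1, k) * choose(N - r1, c1 - k)
    ll <- function(psi) x[1] * log(psi) - log(sum(base * psi^(k - lo) *
                                                    psi^lo))
    grid <- exp(seq(log(1e-3), log(1e3), length.out = 20001))
    grid[which.max(vapply(grid, ll, 0))]
  }
  set.seed(23)
  for (i in 1:15) {
    x <- sample(1:15, 4, replace = TRUE)
    expect_equal(conditional_mle_or(x), grid_mle(x), tolerance = 1e-3)
  }
})

test_that("ranking orders by log10 P, then descending ROR, then name", {
  res <- tibble::tibble(
    drug = c("drug1", "drug2", "drug3"),
    ror = c(2, 5, 3),
    log10_p = log10(c(.01, .001, .01))
  )
  ranked <- rank_signals(res)
  expect_equal(ranked$drug, c("drug2", "drug3", "drug1"))
  expect_equal(ranked$rank, 1:3)

  tied <- tibble::tibble(drug = c("zeta", "alpha"), ror = c(2, 2),
                         log10_p = c(-3, -3))
  expect_equal(rank_signals(tied)$drug, c("alpha", "zeta"))

  deep <- tibble::tibble(drug = c("a", "b"), ror = c(2, 2),
                         log10_p = c(-315, -320))
  expect_equal(rank_signals(deep)$drug, c("b", "a"))
})

test_that("screening the published top-20 counts reproduces every printed ROR", {
  t20 <- table1_counts()
  s <- signal_screen(t20)
  expect_equal(round(s$ror, 2), s$printed_ror)
  expect_true(all(s$log10_p < -270))
  # display-scale P of the deepest rows underflows to exactly 0
  expect_true(any(s$p_display == 0))
  # adjusted columns exist but never drive the ordering
  expect_true(all(c("p_bonferroni", "p_bh") %in% names(s)))
  expect_equal(s$rank, order(order(s$log10_p, -s$ror, s$drug)))
})

test_that("drugs tied at display-zero are still ordered by log-space P", {
  t20 <- table1_counts()
  s <- signal_screen(t20)
  iso <- s[s$drug == "isosorbide", ]
  aml <- s[s$drug == "amlodipine", ]
  # both print near/below double underflow yet remain distinguishable
  expect_lt(iso$log10_p, aml$log10_p)
  expect_lt(iso$rank, aml$rank)
  # two-sided log10 P agrees with the printed magnitudes
  expect_equal(aml$log10_p, log10(3.95e-315), tolerance = 2e-3)
  expect_equal(iso$log10_p, log10(5.12e-319), tolerance = 2e-3)
  # display-zero rows stay mutually distinguishable: ranks strictly
  # follow log-space P even where the display value collapses to 0
  zero_rows <- s[s$p_display == 0, ]
  expect_gt(nrow(zero_rows), 5)
  expect_true(all(diff(zero_rows$log10_p) > 0))  # already rank-sorted
  expect_true(all(zero_rows$log10_p < -308))
})
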