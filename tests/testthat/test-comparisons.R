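test_that("Mann-Whitney: exact path matches brute-force enumeration", {
  res <- compareTwoGroups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p, 0.1)                       # frozen: 2 * 1/20
  expect_equal(res$p, bruteMannWhitneyP(c(1, 2, 3), c(4, 5, 6)))

  set.seed(31)
  for (rep in 1:10) {
    a <- round(rnorm(sample(3:6, 1)), 6)
    b <- round(rnorm(sample(3:6, 1), 0.5), 6)
    res <- compareTwoGroups(a, b)
    expect_equal(res$p, bruteMannWhitneyP(a, b), tolerance = 1e-12)
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(res$p, wt$p.value, tolerance = 1e-12)
    expect_equal(res$U, unname(wt$statistic))
  }
})

test_that("Mann-Whitney: normal path matches wilcox.test with corrections", {
  set.seed(32)
  for (rep in 1:10) {
    a <- rnorm(30); b <- rnorm(25, 0.3)
    if (rep %% 2 == 0) { a <- round(a, 1); b <- round(b, 1) }  # force ties
    res <- compareTwoGroups(a, b)
    expect_equal(res$method, "normal")
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(res$p, wt$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney degenerate and extreme cases", {
  res <- compareTwoGroups(c(2, 2, 3), c(2, 2, 3))
  expect_equal(res$p, 1)
  expect_equal(res$fold_change, 1)

  big <- compareTwoGroups(rnorm(50), rnorm(50) + 100)
  expect_lt(big$p, 1e-10)

  a <- rexp(8); b <- rexp(9)
  expect_equal(compareTwoGroups(a, b)$fold_change,
               1 / compareTwoGroups(b, a)$fold_change, tolerance = 1e-12)

  expect_error(compareTwoGroups(numeric(0), 1), "nonempty")
})

test_that("Kruskal-Wallis H matches hand computation and handles degeneracy", {
  ## groups [1,2],[3,4],[5,6]: rank sums 3, 7, 11 ->
  ## H = 12/42 * (9/2 + 49/2 + 121/2) - 21 = 32/7
  res <- compareKGroups(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(res$H, 32 / 7, tolerance = 1e-12)
  expect_equal(res$p, stats::pchisq(32 / 7, 2, lower.tail = FALSE))

  same <- compareKGroups(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  ## two-group KW is consistent with the Mann-Whitney decision
  set.seed(5)
  a <- rnorm(12); b <- rnorm(12, 2)
  kw <- compareKGroups(list(a = a, b = b))
  mw <- compareTwoGroups(a, b)
  expect_lt(abs(log10(kw$p) - log10(mw$p)), 1)   # same order of magnitude
  expect_equal(kw$H, unname(stats::kruskal.test(list(a, b))$statistic))
})

test_that("Dunn post hoc runs only on a significant omnibus and flags the pair", {
  set.seed(6)
  g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15) + 3)
  res <- compareKGroups(g)
  expect_false(is.null(res$dunn))
  worst <- res$dunn[order(res$dunn$q), ][1:2, ]
  expect_setequal(c(worst$group_a, worst$group_b)[c(worst$group_a, worst$group_b) == "c"], "c")

  null_res <- compareKGroups(list(a = rnorm(5), b = rnorm(5)),
                             dunnAlpha = 1e-6)
  expect_null(null_res$dunn)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  ## order-preserving with input
  p <- c(0.04, 0.001, 0.5)
  expect_equal(bhAdjust(p), stats::p.adjust(p, "BH"))
})

test_that("family comparison enforces the 10-mutation-per-family filter", {
  rates <- list(H1 = rexp(6), H2A = rexp(6), H2B = rexp(6),
                H3 = rexp(6), H4 = rexp(6))
  totals <- c(H1 = 30, H2A = 25, H2B = 40, H3 = 12, H4 = 9)
  res <- familyComparison(rates, totals)
  expect_true(res$skipped)
  expect_match(res$reason, "H4")

  totals["H4"] <- 10
  res2 <- familyComparison(rates, totals)
  expect_false(res2$skipped)
  expect_true(is.finite(res2$H))
})

test_that("family comparison detects a 10x-scaled family", {
  set.seed(88)
  hits <- 0L
  for (rep in 1:200) {
    rates <- list(H1 = rexp(30), H2A = rexp(30), H2B = rexp(30),
                  H3 = rexp(30), H4 = rexp(30) * 10)
    totals <- setNames(rep(50, 5), names(rates))
    res <- familyComparison(rates, totals)
    if (bhAdjust(res$p) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 190)          # >= 95% power at n = 30/family
})
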