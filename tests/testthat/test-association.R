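test_that("contingency test: OR and exact one-sided p match oracles", {
  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  res <- contingencyTest(tab)
  expect_equal(res$odds_ratio, 9)
  expect_false(res$haldane)
  expect_equal(res$p_one_sided, enumHyperGreaterP(30, 10, 10, 30),
               tolerance = 1e-12)
  ## identity: p equals 1 - hypergeometric CDF at a - 1
  expect_equal(res$p_one_sided,
               1 - stats::phyper(29, 40, 40, 40), tolerance = 1e-9)
  ## cross-check against fisher.test
  expect_equal(res$p_one_sided,
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("contingency test: symmetry, Haldane, degeneracy", {
  set.seed(12)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    res <- contingencyTest(tab)
    ## simultaneous row and column swap leaves OR and greater-p unchanged
    swapped <- tab[2:1, 2:1]
    res_sw <- contingencyTest(swapped)
    expect_equal(res_sw$odds_ratio, res$odds_ratio, tolerance = 1e-12)
    expect_equal(res_sw$p_one_sided, res$p_one_sided, tolerance = 1e-12)
    ## direction flip: less-p complements greater-p up to the point mass
    res_less <- contingencyTest(tab, direction = "less")
    a <- tab[1, 1]
    pm <- stats::dhyper(a, sum(tab[, 1]), sum(tab[, 2]), sum(tab[1, ]))
    expect_equal(res$p_one_sided + res_less$p_one_sided, 1 + pm,
                 tolerance = 1e-9)
  }

  zc <- contingencyTest(matrix(c(0, 10, 10, 30), 2, byrow = TRUE))
  expect_true(zc$haldane)
  expect_equal(zc$odds_ratio, (0.5 * 30.5) / (10.5 * 10.5))

  degen <- contingencyTest(matrix(c(0, 0, 10, 30), 2, byrow = TRUE))
  expect_true(degen$degenerate)
  expect_equal(degen$p_one_sided, 1)
})

test_that("cooccurrenceTest classifies patients and restricts to drivers", {
  reg <- toyRegistry()
  v <- rbind(mkVar("p1", "HH.g1", pos = 5L),            # histone
             mkVar("p1", "POLE", pos = 10L),            # query
             mkVar("p2", "POLE", pos = 20L),
             mkVar("p2", "NG1", pos = 4L),
             mkVar("p3", "NG1", pos = 6L),
             mkVar("p4", "HX", pos = 2L))
  res <- cooccurrenceTest(v, reg, "POLE")
  expect_equal(unname(res$table[1, ]), c(1L, 1L))       # both / query-only
  expect_equal(unname(res$table[2, ]), c(1L, 1L))

  ## driver restriction: only the pos-10 call counts as query-mutated
  drv <- data.frame(gene_symbol = "POLE", pos = 10L, alt_allele = "T")
  res_d <- cooccurrenceTest(v, reg, "POLE", driverPositions = drv)
  expect_equal(sum(res_d$table[1, ]), 1L)

  ## explicit patient universe adds never-mutated patients to cell [2,2]
  res_u <- cooccurrenceTest(v, reg, "POLE",
                            patients = c("p1", "p2", "p3", "p4", "p5"))
  expect_equal(res_u$table[2, 2], 2L)
})

test_that("covariate correlations recover exact and designed relationships", {
  rates <- data.frame(gene_symbol = paste0("G", 1:30),
                      rate = seq(0.001, 0.03, length.out = 30))
  cov <- data.frame(gene_symbol = rates$gene_symbol,
                    expression = 2 * rates$rate,
                    replication_time = rev(seq(100, 1500, length.out = 30)),
                    chromatin_state = rep(0, 30))
  res <- covariateCorrelation(rates, cov)
  expect_equal(res$pcc[res$covariate == "expression"], 1, tolerance = 1e-9)
  expect_equal(res$pcc[res$covariate == "replication_time"], -1,
               tolerance = 1e-9)
  expect_true(res$undefined[res$covariate == "chromatin_state"])

  ## genes missing a covariate are dropped pairwise
  cov$expression[1:5] <- NA
  res2 <- covariateCorrelation(rates, cov)
  expect_equal(res2$n_genes[res2$covariate == "expression"], 25L)
})

test_that("null covariates stay near zero correlation (sampling bound)", {
  set.seed(19)
  ok <- 0L
  for (rep in 1:100) {
    rates <- data.frame(gene_symbol = paste0("G", 1:1000),
                        rate = rexp(1000))
    cov <- data.frame(gene_symbol = rates$gene_symbol,
                      expression = rnorm(1000),
                      replication_time = runif(1000, 100, 1500),
                      chromatin_state = runif(1000, -50, 50))
    res <- covariateCorrelation(rates, cov)
    if (all(abs(res$pcc) < 0.08)) ok <- ok + 1L
  }
  expect_gte(ok, 95)
})
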