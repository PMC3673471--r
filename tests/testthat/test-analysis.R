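test_that("%dfi categories are left-closed, right-open, last closed at 100", {
  expect_equal(binByPctDfi(c(19.999, 20, 39.999, 40, 100)),
               c(1L, 2L, 2L, 3L, 5L))
  expect_equal(binByPctDfi(100), 5L)
  expect_equal(binByPctDfi(50, edges = 50), 2L)
  expect_error(binByPctDfi(0), "\\(0, 100\\]")
  expect_error(binByPctDfi(100.5), "\\(0, 100\\]")
  expect_error(binByPctDfi(50, edges = c(40, 20)), "strictly increasing")
})

test_that("expected counts follow E_i = (n_i / N) * M and are conserved", {
  pct <- seq(5, 95, by = 10)                  # two positions per 20%-bin
  e <- enrichment(pct, variantPositions = c(1, 3, 5, 7, 9), edges = c(20, 40, 60, 80))
  ## n_i = (2, 2, 2, 2, 2): E_i = (2/10) * 5 = 1 in every bin
  expect_equal(e@nPerBin, rep(2, 5))
  expect_equal(e@expected, rep(1, 5))
  expect_equal(sum(e@expected), 5, tolerance = 1e-9)
  expect_equal(sum(e@observed), 5)

  ## observed == expected: chi2 = 0, ratios 1, p = 1
  expect_equal(e@observed, rep(1, 5))
  expect_equal(e@chi2, 0)
  expect_equal(e@ratio, rep(1, 5))
  expect_equal(e@p, 1)
})

test_that("enrichment reproduces the hand-computed toy chi-squared", {
  ## bins n = (5, 5), N = 10, M = 4, O = (4, 0):
  ## E = (2, 2), ratios (2, 0), chi2 = (4-2)^2/2 + (0-2)^2/2 = 4, dof 1
  pct <- seq(5, 95, by = 10)
  e <- enrichment(pct, variantPositions = c(1, 2, 3, 4), edges = 50)
  expect_equal(e@expected, c(2, 2))
  expect_equal(e@ratio, c(2, 0))
  expect_equal(e@chi2, 4)
  expect_identical(e@dof, 1L)
  expect_equal(e@p, pchisq(4, 1, lower.tail = FALSE))
})

test_that("the chi-squared statistic matches an independently coded oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 200
    pct <- percentileRank(runif(n))
    pos <- sample.int(n, 80, replace = TRUE)
    e <- enrichment(pct, pos)
    o <- tabulate(binByPctDfi(pct[pos]), 5)
    exp_i <- tabulate(binByPctDfi(pct), 5) / n * 80
    expect_equal(e@chi2, sum((o - exp_i)^2 / exp_i), tolerance = 1e-12)
    expect_equal(sum(e@expected), 80, tolerance = 1e-9)
  }
  expect_error(enrichment(percentileRank(1:10), c(2, 11)), "outside")
  expect_error(enrichment(percentileRank(1:10), integer(0)), "M >= 1")
})

test_that("flexibility distributions normalize and report threshold fractions", {
  pct <- percentileRank(seq_len(100))          # 1, 2, ..., 100
  d <- flexibilityDistribution(pct, seq_len(100), binWidth = 20)
  expect_equal(sum(d$frequency), 1)
  ## flat for uniform percentiles, up to the boundary convention
  ## (interior boundaries are left-closed): counts 19/20/20/20/21
  expect_equal(d$frequency, c(19, 20, 20, 20, 21) / 100)
  expect_equal(flexibilityDistribution(pct, 1:100,
                                       threshold = 100)$fractionAtOrBelow, 1)

  ## a set planted in the lowest quartile is fully below the 25% threshold
  low <- which(pct <= 25)
  expect_equal(flexibilityDistribution(pct, low)$fractionAtOrBelow, 1)
  expect_error(flexibilityDistribution(pct, integer(0)), "empty")
})

test_that("sliding-window rate correlation behaves on known dependences", {
  pct <- percentileRank(seq_len(120))
  ## rates identical to %dfi: perfect correlation
  r <- rateDfiSliding(pct, pct, window = 20, step = 10)
  expect_equal(r$correlation, 1)

  ## invariance to strictly monotone transforms of the sort key
  r2 <- rateDfiSliding(pct^3, pct, window = 20, step = 10)
  expect_equal(r2$windowRate, r$windowRate)

  ## two-window hand case
  r3 <- rateDfiSliding(c(10, 90), c(0.1, 0.9), window = 1, step = 1)
  expect_equal(r3$correlation, 1)
  expect_equal(r3$windowPct, c(10, 90))

  expect_error(rateDfiSliding(pct, pct, window = 200), "exceeds")
  expect_error(rateDfiSliding(pct, pct[1:10]), "1:1")
})

test_that("conservation groups partition by rate and summarize %dfi", {
  pct <- percentileRank(seq_len(9))
  g <- conservationGroups(pct, rates = rep(0, 9))
  expect_equal(nrow(g), 1L)
  expect_equal(g$group, "ultra_conserved")
  expect_equal(g$n, 9L)

  g3 <- conservationGroups(pct[1:3], rates = c(0, 0.5, 2))
  expect_equal(g3$group, c("ultra_conserved", "well_conserved",
                           "less_conserved"))
  expect_equal(g3$n, rep(1L, 3))
  ## boundary: r = 1 belongs to well-conserved
  gb <- conservationGroups(c(10, 20), rates = c(1, 1.0001))
  expect_equal(gb$group, c("well_conserved", "less_conserved"))

  ## planting the ultra-conserved in the lowest-%dfi third orders the medians
  pct2 <- percentileRank(seq_len(30))
  rates <- rep(2, 30)
  rates[pct2 <= 100 / 3] <- 0
  gp <- conservationGroups(pct2, rates)
  expect_lt(gp$median[gp$group == "ultra_conserved"],
            gp$median[gp$group == "less_conserved"])
})

test_that("Welch test matches the closed form and handles degenerate input", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(2.0, 2.5, 7.7)
  got <- groupDifferenceTest(a, b)
  want <- welchOracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  far <- groupDifferenceTest(c(1, 2, 3), c(101, 102, 103))
  expect_lt(far$p, 1e-4)
  expect_gt(abs(far$t), 50)

  same <- groupDifferenceTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_equal(groupDifferenceTest(c(2, 2), c(2, 2)),
               list(t = 0, df = NA_real_, p = 1))
  expect_equal(groupDifferenceTest(c(2, 2), c(3, 3))$p, 0)
  expect_error(groupDifferenceTest(1, c(1, 2)), "at least 2")
})
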