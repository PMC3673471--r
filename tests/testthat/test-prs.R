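test_that("force sets are unit, antipodal, zero-sum and reproducible", {
  f2 <- sampleForces(2, seed = 5)
  expect_equal(f2@directions[1, ], -f2@directions[2, ])
  expect_equal(colSums(f2@directions), c(0, 0, 0))

  f10 <- sampleForces(10, seed = 17)
  expect_equal(nrow(f10@directions), 10L)
  expect_equal(sqrt(rowSums(f10@directions^2)), rep(1, 10), tolerance = 1e-14)
  expect_lt(max(abs(colSums(f10@directions))), 1e-12)
  expect_identical(f10@directions, sampleForces(10, seed = 17)@directions)

  expect_error(sampleForces(11), "antipodal")
  expect_error(sampleForces(0), "antipodal")
})

test_that("two-residue responses match the hand-worked pseudo-inverse", {
  ## Two residues on x at r = 2, inverse-square springs: only the x-x subspace
  ## is constrained, K_x = (1/r^2) [[1,-1],[-1,1]], pseudo-inverse
  ## (r^2/4) [[1,-1],[-1,1]]. Every 3x3 coupling block is diag(r^2/4, 0, 0),
  ## so each analytic entry is sqrt((r^2/4)^2 / 3) = r^2 / (4 sqrt(3)).
  s <- new("CalphaStructure",
           residues = data.frame(chain = "A", resnum = 1:2, icode = "",
                                 resname = "GLY"),
           coords = cbind(c(0, 2), 0, 0), sourceLabel = "pair")
  m <- suppressWarnings(invertHessian(buildHessian(s)))
  A <- responseMatrix(responseMatrixAnalytic(m))
  expect_equal(A, matrix(1 / sqrt(3), 2, 2), tolerance = 1e-12)

  ## MC with an x-aligned antipodal pair: |dR| = r^2/4 for both residues
  fx <- new("ForceSet", directions = rbind(c(1, 0, 0), c(-1, 0, 0)))
  Amc <- responseMatrix(responseMatrixMC(m, fx))
  expect_equal(Amc, matrix(1, 2, 2), tolerance = 1e-12)

  expect_error(responseMatrixMC(buildHessian(s), fx), "pseudo-inverse")
  expect_error(responseMatrixAnalytic(buildHessian(s)), "pseudo-inverse")
})

test_that("analytic responses agree with an svd-route brute-force oracle", {
  g <- makeStructure("globule", n = 12, seed = 14)
  m <- invertHessian(buildHessian(g))
  A <- responseMatrixAnalytic(m)@A
  Hi <- svdPinv(hessian(buildHessian(g)))
  n <- 12
  for (i in c(1, 5, 12)) {
    for (j in c(2, 8)) {
      G <- Hi[(3 * j - 2):(3 * j), (3 * i - 2):(3 * i)]
      expect_equal(A[i, j], sqrt(sum(G^2) / 3), tolerance = 1e-9)
    }
  }
})

test_that("responses scale linearly with the inverse spring constant", {
  g <- makeStructure("globule", n = 10, seed = 1)
  A1 <- responseMatrix(responseMatrixAnalytic(invertHessian(
    buildHessian(g, gamma = 1))))
  A2 <- responseMatrix(responseMatrixAnalytic(invertHessian(
    buildHessian(g, gamma = 2))))
  expect_equal(A1, 2 * A2, tolerance = 1e-12)
})

test_that("ring responses depend only on sequence separation around the ring", {
  n <- 12
  ring <- makeStructure("ring", n = n)
  A <- suppressWarnings(responseMatrixAnalytic(
    invertHessian(buildHessian(ring))))@A
  sep <- outer(seq_len(n), seq_len(n),
               function(i, j) pmin((i - j) %% n, (j - i) %% n))
  spread <- vapply(split(A, sep), function(v) diff(range(v)), numeric(1))
  expect_lt(max(spread), 1e-10)
})

test_that("dfi normalization, symmetry and end effects", {
  ## symmetric ring: every residue identical
  p <- quietProfile(makeStructure("ring", n = 12))
  expect_equal(sum(dfi(p)), 1, tolerance = 1e-12)
  expect_lt(max(dfi(p)) - min(dfi(p)), 1e-10)
  expect_equal(pctDfi(p), rep(100 * 13 / 24, 12))   # all ranks tied

  ## 9-residue chain: termini take the two highest dfi, minimum is interior
  p9 <- quietProfile(makeStructure("linear_chain", n = 9))
  r <- rank(-dfi(p9))
  expect_true(all(r[c(1, 9)] <= 2))
  expect_true(which.min(dfi(p9)) %in% 2:8)

  ## normalization holds for every fixture and for excludeSelf
  for (s in list(makeStructure("globule", n = 30, seed = 2),
                 makeStructure("dumbbell", seed = 3))) {
    for (ex in c(FALSE, TRUE)) {
      pp <- quietProfile(s, excludeSelf = ex)
      expect_equal(sum(dfi(pp)), 1, tolerance = 1e-12)
      expect_true(all(dfi(pp) > 0))
    }
  }

  ## self-perturbation toggle moves dfi only at O(1/N)
  g <- makeStructure("globule", n = 40, seed = 5)
  pIn <- quietProfile(g)
  pEx <- quietProfile(g, excludeSelf = TRUE)
  expect_lt(max(abs(dfi(pIn) - dfi(pEx))), 5 / 40 * max(dfi(pIn)))

  zero <- new("ResponseMatrix", A = matrix(0, 3, 3), mode = "analytic")
  expect_error(dfiFromResponse(zero), "degenerate profile")
})

test_that("dfi is invariant to rigid motion and exactly invariant to spring scale", {
  g <- makeStructure("globule", n = 40, seed = 5)
  p <- dfiProfile(g)
  set.seed(31)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  g2 <- g
  g2@coords <- coords(g) %*% Q + matrix(c(5, -3, 11), 40, 3, byrow = TRUE)
  expect_lt(max(abs(dfi(p) - dfi(dfiProfile(g2)))), 1e-9)

  p10 <- dfiProfile(g, gamma = 10)
  expect_identical(dfi(p), dfi(p10))
  expect_equal(totalResponse(p), 10 * totalResponse(p10), tolerance = 1e-12)
})

test_that("percentile ranks follow the 100 * rank / N convention with tie averaging", {
  expect_equal(percentileRank(c(1, 2, 3, 4)), c(25, 50, 75, 100))
  expect_equal(percentileRank(c(4, 1, 3, 2)), c(100, 25, 75, 50))
  expect_equal(percentileRank(rep(7, 5)), rep(100 * 6 / 10, 5))
  expect_equal(percentileRank(c(1, 1, 3)), c(50, 50, 100))
  expect_equal(percentileRank(42), 100)
  expect_error(percentileRank(numeric(0)), "empty")
  expect_error(percentileRank(c(1, NA)), "finite")
})

test_that("Monte-Carlo dfi converges to the analytic profile", {
  g <- makeStructure("globule", n = 25, seed = 16)
  m <- invertHessian(buildHessian(g))
  Aan <- responseMatrixAnalytic(m)@A
  Amc <- responseMatrixMC(m, sampleForces(4000, seed = 8))@A
  expect_lt(max(abs(Amc - Aan) / Aan), 0.05)

  pan <- dfiFromResponse(responseMatrixAnalytic(m))
  pmc <- dfiFromResponse(responseMatrixMC(m, sampleForces(10, seed = 7)))
  expect_gte(cor(dfi(pan), dfi(pmc), method = "spearman"), 0.9)
})

test_that("dfiProfile and computeDfi are deterministic and compose end-to-end", {
  path <- writeToyPdb()
  p1 <- suppressWarnings(computeDfi(path))
  p2 <- suppressWarnings(computeDfi(path))
  expect_identical(dfi(p1), dfi(p2))
  expect_equal(length(p1), 3L)

  pm1 <- suppressWarnings(computeDfi(path, mode = "monte_carlo", seed = 5))
  pm2 <- suppressWarnings(computeDfi(path, mode = "monte_carlo", seed = 5))
  expect_identical(dfi(pm1), dfi(pm2))

  out <- tempfile(fileext = ".tsv")
  pdbOut <- tempfile(fileext = ".pdb")
  suppressWarnings(computeDfi(path, out = out, pdbOut = pdbOut))
  expect_equal(nrow(readDfiTable(out)), 3L)
  expect_true(file.exists(pdbOut))
})

test_that("dumbbell linker residues are among the most rigid sites", {
  db <- makeStructure("dumbbell", seed = 7)
  p <- dfiProfile(db)
  li <- dumbbellLinkerIdx()
  ## the hinge linker sits at the rigid end of the profile (lowest quartile)
  expect_true(all(pctDfi(p)[li] <= 25))
})
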