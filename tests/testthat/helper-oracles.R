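## Independent oracles, kept deliberately separate from the package's code
## paths: brute-force potential energy + finite differences for the Hessian,
## an svd-based pseudo-inverse, and closed-form Welch statistics.

## Pairwise harmonic network potential V = sum_{i<j} g_ij (|r_ij| - |r0_ij|)^2 / 2
## with spring constants taken from the REFERENCE geometry xyz0.
enmPotential <- function(flat, xyz0, weighting = "inverse_square",
                         cutoff = 10) {
  n <- nrow(xyz0)
  xyz <- matrix(flat, n, 3, byrow = TRUE)
  v <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r0 <- sqrt(sum((xyz0[i, ] - xyz0[j, ])^2))
      g <- if (weighting == "inverse_square") 1 / r0^2 else {
        if (r0 <= cutoff) 1 else 0
      }
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      v <- v + g * (r - r0)^2 / 2
    }
  }
  v
}

## Central-difference Hessian of enmPotential at the reference coordinates.
## Coordinate order matches the package: (x1, y1, z1, x2, ...).
numericalHessian <- function(xyz0, h = 1e-5, weighting = "inverse_square") {
  flat0 <- as.vector(t(xyz0))
  m <- length(flat0)
  H <- matrix(0, m, m)
  f <- function(x) enmPotential(x, xyz0, weighting)
  for (a in seq_len(m)) {
    for (b in a:m) {
      xpp <- flat0; xpp[a] <- xpp[a] + h; xpp[b] <- xpp[b] + h
      xpm <- flat0; xpm[a] <- xpm[a] + h; xpm[b] <- xpm[b] - h
      xmp <- flat0; xmp[a] <- xmp[a] - h; xmp[b] <- xmp[b] + h
      xmm <- flat0; xmm[a] <- xmm[a] - h; xmm[b] <- xmm[b] - h
      H[a, b] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}

## svd-based Moore-Penrose pseudo-inverse (independent of the package's
## eigendecomposition route).
svdPinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Closed-form Welch unequal-variance t statistic and two-sided p.
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Hand-written toy PDB content used across structure-io tests.
toyPdbLines <- function() {
  c(
    sprintf("ATOM  %5d  N   ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
            1, 1, 0.5, 0.5, 0.5, 1, 0),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            2, 1, 0, 0, 0, 1, 0),
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            3, 2, 3.8, 0, 0, 1, 0),
    sprintf("ATOM  %5d  CA  SER A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            4, 3, 7.6, 0, 0, 1, 0),
    "END"
  )
}

writeToyPdb <- function(lines = toyPdbLines()) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

## Quietly build + invert a Hessian (several fixtures are deliberately
## degenerate and warn about their zero-mode count).
quietModel <- function(structure, ...) {
  suppressWarnings(invertHessian(buildHessian(structure, ...)))
}

quietProfile <- function(structure, ...) {
  suppressWarnings(dfiProfile(structure, ...))
}
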