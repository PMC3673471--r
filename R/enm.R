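#' Build the elastic-network Hessian of a C-alpha structure
#'
#' Every residue pair (i, j) at separation vector d (length r) contributes an
#' off-diagonal 3 x 3 block -gamma_ij (d d')/r^2 to the 3N x 3N Hessian; the
#' diagonal blocks are the negated sums of the off-diagonal blocks in their
#' row, so rigid translations are exact zero modes by construction. Two
#' spring-weight rules are supported:
#'
#' * `inverse_square` (default): gamma_ij = 1/r^2 for **all** pairs, so the
#'   block is -(d d')/r^4. Distance weighting replaces a hard interaction
#'   cutoff; every pair interacts, with strength decaying smoothly.
#' * `cutoff`: gamma_ij = 1 for r <= `cutoff`, else 0 (classic ANM), provided
#'   for cross-checks.
#'
#' The global spring constant `gamma` only sets the energy scale; it is stored
#' as a scalar and cancels exactly out of dfi.
#'
#' @param structure a [CalphaStructure-class] object.
#' @param weighting `"inverse_square"` or `"cutoff"`.
#' @param cutoff interaction radius in Angstrom for `cutoff` weighting.
#' @param gamma global spring-constant scale (default 1).
#' @return a [HessianModel-class] (not yet inverted).
#' @examples
#' s <- makeStructure("ring", n = 12)
#' h <- buildHessian(s)
#' @export
buildHessian <- function(structure, weighting = c("inverse_square", "cutoff"),
                         cutoff = 10, gamma = 1) {
  stopifnot(is(structure, "CalphaStructure"))
  weighting <- match.arg(weighting)
  xyz <- coords(structure)
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  if (any(d2[upper.tri(d2)] < 1e-12)) {
    stop("degenerate geometry: coincident residues (zero separation)")
  }

  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r2 <- d2[i, j]
      w <- switch(weighting,
        inverse_square = 1 / r2,
        cutoff = if (r2 <= cutoff^2) 1 else 0
      )
      if (w == 0) next
      d <- xyz[i, ] - xyz[j, ]
      blk <- -(w / r2) * tcrossprod(d)
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  new("HessianModel", hessian = H, gamma = gamma, weighting = weighting)
}

#' Pseudo-invert an elastic-network Hessian
#'
#' Eigendecomposes the Hessian and inverts on the subspace of eigenvalues
#' above `zeroTol * lambda_max`; everything below is treated as a rigid-body
#' null mode and discarded. A non-degenerate 3-D structure has exactly 6 zero
#' modes (3 translations + 3 rotations); any other count triggers a
#' degenerate-geometry warning (e.g. 7 for collinear structures, where one
#' rotation axis costs no energy and, with inverse-square weighting, the
#' transverse displacements decouple entirely).
#'
#' @param model a [HessianModel-class] from [buildHessian()].
#' @param zeroTol relative eigenvalue threshold for zero modes (default 1e-10).
#' @return the model with `inverse`, `nullDim` and `eigenvalues` filled in.
#' @export
invertHessian <- function(model, zeroTol = 1e-10) {
  stopifnot(is(model, "HessianModel"))
  eig <- eigen(model@hessian, symmetric = TRUE)
  lmax <- max(eig$values)
  if (lmax <= 0) stop("singular model: Hessian has no positive eigenvalues")
  keep <- eig$values > zeroTol * lmax
  if (!any(keep)) stop("singular model: all eigenvalues below zero threshold")
  nd <- as.integer(sum(!keep))
  if (nd != 6L) {
    warning("degenerate geometry: ", nd,
            " zero modes removed (expected 6 rigid-body modes)")
  }
  V <- eig$vectors[, keep, drop = FALSE]
  model@inverse <- V %*% (t(V) / eig$values[keep])
  model@nullDim <- nd
  model@eigenvalues <- eig$values
  model
}

#' GNM-style effective mobility from the slowest modes
#'
#' Builds the N x N Kirchhoff-style connectivity matrix under the same spring
#' weighting as the 3-D model (inverse-square by default), pseudo-inverts it
#' (one zero mode), and sums the mode contributions u_k u_k' / lambda_k over
#' the `nSlowModes` smallest non-zero modes. The diagonal of that partial
#' pseudo-inverse is the per-residue effective mobility; its percentile rank
#' (%EM) makes it comparable to %dfi. Effective mobility captures equilibrium
#' fluctuations in the slowest modes only, whereas dfi probes the response to
#' out-of-equilibrium perturbations across all modes.
#'
#' @param structure a [CalphaStructure-class] object.
#' @param nSlowModes number of slowest non-zero modes to sum (default 10;
#'   values >= N-1 are reduced to N-1 with a warning).
#' @param weighting,cutoff spring-weight rule, as in [buildHessian()].
#' @return data.frame with columns `mobility` and `pct_em`.
#' @export
gnmMobility <- function(structure, nSlowModes = 10,
                        weighting = c("inverse_square", "cutoff"),
                        cutoff = 10) {
  stopifnot(is(structure, "CalphaStructure"))
  weighting <- match.arg(weighting)
  xyz <- coords(structure)
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  if (any(d2[upper.tri(d2)] < 1e-12)) {
    stop("degenerate geometry: coincident residues (zero separation)")
  }
  W <- switch(weighting,
    inverse_square = 1 / d2,
    cutoff = (d2 <= cutoff^2) * 1
  )
  diag(W) <- 0
  K <- diag(rowSums(W)) - W

  eig <- eigen(K, symmetric = TRUE)
  lmax <- max(eig$values)
  keep <- which(eig$values > 1e-10 * lmax)  # ascending order after rev below
  ord <- keep[order(eig$values[keep])]
  nAvail <- length(ord)
  if (nSlowModes > n - 1) {
    warning("nSlowModes reduced to N-1 = ", n - 1)
    nSlowModes <- n - 1
  }
  nSlowModes <- min(nSlowModes, nAvail)
  ## complete degenerate multiplets: a partial sum over a degenerate
  ## eigenspace is basis-dependent (and would break e.g. ring symmetry)
  while (nSlowModes < nAvail &&
         abs(eig$values[ord[nSlowModes + 1]] - eig$values[ord[nSlowModes]]) <
           1e-8 * lmax) {
    nSlowModes <- nSlowModes + 1L
  }
  use <- ord[seq_len(nSlowModes)]
  mob <- rowSums(eig$vectors[, use, drop = FALSE]^2 /
                   rep(eig$values[use], each = n))
  ## rank on 10 significant digits so symmetry-equal values tie exactly
  data.frame(mobility = mob, pct_em = percentileRank(signif(mob, 10)))
}
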