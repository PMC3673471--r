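.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample an isotropic set of unit force directions
#'
#' Draws k/2 directions uniformly on the sphere and appends their antipodes,
#' so the vector sum of the set is exactly zero ("zero angular average") and
#' the applied forcing is isotropic by construction. The default k = 10 is the
#' number of random directions used per perturbed residue.
#'
#' @param k number of directions; must be even (antipodal pairing).
#' @param seed integer RNG seed for reproducibility, or NULL.
#' @return a [ForceSet-class] object.
#' @examples
#' f <- sampleForces(10, seed = 17)
#' colSums(f@directions)   # exactly zero
#' @export
sampleForces <- function(k = 10, seed = NULL) {
  if (k < 2 || k %% 2 != 0) {
    stop("k must be even and >= 2: directions are built as antipodal pairs ",
         "so that their vector sum is exactly zero")
  }
  half <- .withSeed(seed, {
    m <- matrix(stats::rnorm(3 * k / 2), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  new("ForceSet", directions = rbind(half, -half),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

.requireInverse <- function(model) {
  if (!is(model, "HessianModel") || !length(model@inverse)) {
    stop("model has no pseudo-inverse; call invertHessian() first")
  }
}

#' Monte-Carlo perturbation-response matrix
#'
#' For each perturbed residue i, a unit force f is placed on residue i's three
#' components of the force vector and the linear response of the whole chain
#' is read off as dR = H^-1 dF. Entry `A[i, j]` is the root-mean-square over
#' the k force directions of the displacement magnitude |dR_j| of residue j
#' (the per-residue mean-square fluctuation under the random kicks, on the
#' magnitude scale). With the antipodal force sets of [sampleForces()] the
#' directional average of the response *vector* is exactly zero, which is why
#' the magnitude, not the vector, is averaged; as k grows this converges to
#' the exact isotropic RMS of [responseMatrixAnalytic()].
#'
#' @param model an inverted [HessianModel-class].
#' @param forces a [ForceSet-class].
#' @return a [ResponseMatrix-class], mode `"monte_carlo"`.
#' @export
responseMatrixMC <- function(model, forces) {
  .requireInverse(model)
  stopifnot(is(forces, "ForceSet"))
  Hi <- model@inverse
  n <- nrow(Hi) / 3L
  Ft <- t(forces@directions)            # 3 x k
  k <- ncol(Ft)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    G <- Hi[, (3 * i - 2):(3 * i), drop = FALSE]   # 3N x 3
    D <- G %*% Ft                                  # 3N x k displacements
    sq <- D^2
    ## per-residue squared magnitude: fold triples of rows
    mag2 <- sq[seq(1, 3 * n, 3), ] + sq[seq(2, 3 * n, 3), ] +
      sq[seq(3, 3 * n, 3), ]
    A[i, ] <- sqrt(rowMeans(mag2))
  }
  new("ResponseMatrix", A = A, mode = "monte_carlo", gamma = model@gamma,
      k = as.integer(k))
}

#' Exact isotropic perturbation-response matrix
#'
#' Deterministic closed form of the Monte-Carlo average: for a unit force
#' uniformly distributed on the sphere at residue i, the mean squared
#' displacement of residue j is trace(G G') / 3 where G is the 3 x 3 block of
#' H^-1 coupling response j to perturbation i, so
#' `A[i, j] = sqrt(trace(G G') / 3)`.
#'
#' @param model an inverted [HessianModel-class].
#' @return a [ResponseMatrix-class], mode `"analytic"`.
#' @export
responseMatrixAnalytic <- function(model) {
  .requireInverse(model)
  Hi <- model@inverse
  n <- nrow(Hi) / 3L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    G <- Hi[, (3 * i - 2):(3 * i), drop = FALSE]
    rs <- rowSums(G^2)                  # squared Frobenius rows
    A[i, ] <- sqrt((rs[seq(1, 3 * n, 3)] + rs[seq(2, 3 * n, 3)] +
                      rs[seq(3, 3 * n, 3)]) / 3)
  }
  new("ResponseMatrix", A = A, mode = "analytic", gamma = model@gamma)
}

#' Percentile ranks of per-residue scores
#'
#' `100 * rank / N` with average ranks for ties: the maximum maps to 100, the
#' minimum of N distinct values to 100/N, and N equal values all map to
#' `100 * (N + 1) / (2N)`. This is the normalization that makes flexibility
#' comparable across proteins of different sizes.
#'
#' @param values numeric vector of finite scores.
#' @return numeric vector of percentiles in (0, 100].
#' @examples
#' percentileRank(c(1, 2, 3, 4))   # 25 50 75 100
#' @export
percentileRank <- function(values) {
  if (!length(values)) stop("empty value vector")
  if (!all(is.finite(values))) stop("values must be finite")
  100 * rank(values, ties.method = "average") / length(values)
}

#' Dynamic flexibility profile from a response matrix
#'
#' The total response of residue j is the mean of column j of the response
#' matrix over perturbation sites i, i.e. the average displacement of j when
#' every residue of the chain is kicked in turn. Normalizing over the chain
#' gives the dynamic flexibility index, `dfi_j = S_j / sum(S)`, and percentile
#' ranking gives %dfi. High dfi marks residues easily displaced by
#' perturbations elsewhere (flexible sites); low dfi marks residues that
#' absorb and transmit perturbations without moving (hinge-like sites).
#'
#' Whether the self-perturbation row i = j is counted changes dfi only at
#' O(1/N); the matrix-mean convention (include it) is the default, and
#' `excludeSelf = TRUE` restricts the mean to i != j.
#'
#' @param response a [ResponseMatrix-class].
#' @param excludeSelf drop the i = j (self-perturbation) term from the mean.
#' @param residues optional residue table to attach (from the structure).
#' @return a [DfiProfile-class].
#' @export
dfiFromResponse <- function(response, excludeSelf = FALSE, residues = NULL) {
  stopifnot(is(response, "ResponseMatrix"))
  A <- response@A
  n <- nrow(A)
  if (all(A == 0)) stop("degenerate profile: response matrix is all zero")
  if (excludeSelf) {
    s <- (colSums(A) - diag(A)) / (n - 1)
  } else {
    s <- colMeans(A)
  }
  tot <- sum(s)
  if (tot <= 0) stop("degenerate profile: total response is not positive")
  ## dfi is computed at unit spring scale: the global gamma cancels exactly
  d <- s / tot
  ## ranks are taken on 10 significant digits so values equal up to
  ## floating-point noise (e.g. symmetric structures) tie as they should
  new("DfiProfile",
      S = s / response@gamma,
      dfi = d,
      pctDfi = percentileRank(signif(d, 10)),
      residues = if (is.null(residues)) data.frame() else residues,
      mode = response@mode)
}

#' Compute a dfi profile for a structure
#'
#' In-memory pipeline: build the inverse-square Hessian, pseudo-invert it,
#' form the response matrix (analytic by default, Monte-Carlo on request) and
#' derive S, dfi and %dfi.
#'
#' @param structure a [CalphaStructure-class].
#' @param mode `"analytic"` (deterministic, default) or `"monte_carlo"`.
#' @param k number of force directions in Monte-Carlo mode (default 10).
#' @param seed RNG seed for Monte-Carlo force sampling.
#' @param excludeSelf see [dfiFromResponse()].
#' @param weighting,cutoff,gamma passed to [buildHessian()].
#' @return a [DfiProfile-class] carrying the structure's residue table.
#' @examples
#' s <- makeStructure("globule", n = 30, seed = 1)
#' p <- dfiProfile(s)
#' head(as.data.frame(p))
#' @export
dfiProfile <- function(structure, mode = c("analytic", "monte_carlo"),
                       k = 10, seed = NULL, excludeSelf = FALSE,
                       weighting = "inverse_square", cutoff = 10, gamma = 1) {
  mode <- match.arg(mode)
  model <- invertHessian(buildHessian(structure, weighting = weighting,
                                      cutoff = cutoff, gamma = gamma))
  resp <- if (mode == "analytic") {
    responseMatrixAnalytic(model)
  } else {
    responseMatrixMC(model, sampleForces(k, seed = seed))
  }
  dfiFromResponse(resp, excludeSelf = excludeSelf,
                  residues = structure@residues)
}

#' End-to-end dfi computation from a PDB file
#'
#' Reads the structure, runs [dfiProfile()] and, if `out` is given, writes the
#' per-residue table (and optionally a B-factor-annotated copy of the PDB for
#' ribbon coloring by %dfi).
#'
#' @param path PDB file.
#' @param mode,k,seed,excludeSelf see [dfiProfile()].
#' @param chains,model see [readCalphaStructure()].
#' @param out optional path for the residue table ([writeDfiTable()]).
#' @param pdbOut optional path for the %dfi-in-B-factor PDB copy.
#' @param headerLines extra comment lines for the table.
#' @return a [DfiProfile-class], invisibly when `out` is given.
#' @export
computeDfi <- function(path, mode = c("analytic", "monte_carlo"), k = 10,
                       seed = NULL, excludeSelf = FALSE, chains = NULL,
                       model = 1L, out = NULL, pdbOut = NULL,
                       headerLines = character()) {
  mode <- match.arg(mode)
  structure <- readCalphaStructure(path, chains = chains, model = model)
  prof <- dfiProfile(structure, mode = mode, k = k, seed = seed,
                     excludeSelf = excludeSelf)
  if (!is.null(out)) {
    writeDfiTable(prof, structure, out, headerLines = headerLines)
  }
  if (!is.null(pdbOut)) writeBfactorPDB(path, prof, pdbOut)
  if (is.null(out)) prof else invisible(prof)
}
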