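#' @import methods
NULL

#' Coarse-grained C-alpha structure
#'
#' One chain (or a chain selection) of a protein reduced to its C-alpha trace:
#' an ordered residue table and an N x 3 coordinate matrix in Angstrom. This is
#' the only structural information the elastic network model uses.
#'
#' @slot residues data.frame with columns `chain`, `resnum`, `icode`, `resname`,
#'   one row per residue, in file order within the selected chains.
#' @slot coords numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @slot sourceLabel free-text provenance (file path, fixture description, ...).
#'
#' @aliases CalphaStructure-class
#' @exportClass CalphaStructure
setClass("CalphaStructure",
  representation(
    residues = "data.frame",
    coords = "matrix",
    sourceLabel = "character"
  )
)

setValidity("CalphaStructure", function(object) {
  res <- object@residues
  xyz <- object@coords
  msgs <- character(0)
  need <- c("chain", "resnum", "icode", "resname")
  if (!all(need %in% names(res))) {
    return(paste("residues must have columns", paste(need, collapse = ", ")))
  }
  n <- nrow(res)
  if (n < 2L) msgs <- c(msgs, "a structure needs at least 2 residues")
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != n) {
    msgs <- c(msgs, "coords must be a numeric N x 3 matrix matching residues")
  } else if (!all(is.finite(xyz))) {
    msgs <- c(msgs, "coordinates must be finite")
  }
  key <- paste(res$chain, res$resnum, res$icode, sep = "|")
  if (anyDuplicated(key)) {
    msgs <- c(msgs, "duplicate (chain, resnum, icode) residue keys")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Elastic-network Hessian model
#'
#' The 3N x 3N stiffness matrix of the C-alpha network and, after
#' [invertHessian()], its eigendecomposition-based pseudo-inverse. Both are
#' stored at unit spring scale; the physical scale `gamma` is kept as a scalar
#' so that downstream ratios (dfi) are exactly scale-free.
#'
#' @slot hessian 3N x 3N symmetric matrix at unit gamma.
#' @slot inverse pseudo-inverse of `hessian` (0 x 0 until [invertHessian()]).
#' @slot gamma global spring-constant scale (energy/Angstrom^2).
#' @slot nullDim number of eigenvalues treated as zero modes (NA until inverted).
#' @slot weighting `"inverse_square"` or `"cutoff"` spring-weight rule.
#' @slot eigenvalues eigenvalues of `hessian` (empty until inverted).
#'
#' @aliases HessianModel-class
#' @exportClass HessianModel
setClass("HessianModel",
  representation(
    hessian = "matrix",
    inverse = "matrix",
    gamma = "numeric",
    nullDim = "integer",
    weighting = "character",
    eigenvalues = "numeric"
  ),
  prototype(
    inverse = matrix(numeric(0), 0, 0),
    gamma = 1,
    nullDim = NA_integer_,
    eigenvalues = numeric(0)
  )
)

setValidity("HessianModel", function(object) {
  H <- object@hessian
  if (nrow(H) != ncol(H) || nrow(H) %% 3L != 0L) {
    return("hessian must be square with dimension a multiple of 3")
  }
  sc <- max(abs(H))
  if (sc > 0 && max(abs(H - t(H))) > 1e-10 * sc) {
    return("hessian is not symmetric within 1e-10 relative tolerance")
  }
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma <= 0) {
    return("gamma must be a single positive number")
  }
  TRUE
})

#' Set of perturbation force directions
#'
#' k unit vectors with exactly zero vector sum, built as antipodal pairs so the
#' applied forcing is isotropic ("zero angular average").
#'
#' @slot directions k x 3 matrix of unit vectors.
#' @slot seed integer RNG seed used to draw them, or NA.
#'
#' @aliases ForceSet-class
#' @exportClass ForceSet
setClass("ForceSet",
  representation(directions = "matrix", seed = "integer"),
  prototype(seed = NA_integer_)
)

setValidity("ForceSet", function(object) {
  F <- object@directions
  if (ncol(F) != 3L || nrow(F) < 2L) return("directions must be k x 3, k >= 2")
  nrm <- sqrt(rowSums(F^2))
  if (any(abs(nrm - 1) > 1e-12)) return("directions must be unit vectors (1e-12)")
  if (any(abs(colSums(F)) > 1e-12)) {
    return("directions must sum to the zero vector (1e-12)")
  }
  TRUE
})

#' Perturbation-response matrix
#'
#' N x N matrix A whose entry `A[i, j]` is the displacement-magnitude response
#' of residue j to an isotropically averaged unit force at residue i, stored at
#' unit spring scale (divide by `gamma` for physical Angstrom-per-unit-force).
#' A is generally not symmetric: perturbation and response roles differ.
#'
#' @slot A N x N non-negative response matrix (unit gamma).
#' @slot mode `"analytic"` (exact isotropic RMS) or `"monte_carlo"`.
#' @slot gamma spring scale inherited from the Hessian model.
#' @slot k number of Monte-Carlo force directions (NA in analytic mode).
#'
#' @aliases ResponseMatrix-class
#' @exportClass ResponseMatrix
setClass("ResponseMatrix",
  representation(A = "matrix", mode = "character", gamma = "numeric",
                 k = "integer"),
  prototype(gamma = 1, k = NA_integer_)
)

setValidity("ResponseMatrix", function(object) {
  A <- object@A
  if (nrow(A) != ncol(A)) return("A must be square")
  if (!all(is.finite(A))) return("A entries must be finite")
  if (any(A < 0)) return("A entries must be non-negative")
  if (!object@mode %in% c("analytic", "monte_carlo")) {
    return("mode must be 'analytic' or 'monte_carlo'")
  }
  TRUE
})

#' Per-residue dynamic flexibility profile
#'
#' Holds, for every residue, the total response S_j (mean displacement response
#' over perturbation sites, physical scale), the normalized dynamic flexibility
#' index dfi_j = S_j / sum(S), and the per-protein percentile rank %dfi in
#' (0, 100].
#'
#' @slot S numeric per-residue total response.
#' @slot dfi numeric per-residue flexibility index; sums to 1.
#' @slot pctDfi numeric percentile ranks, ties averaged; max value maps to 100.
#' @slot residues residue table carried over from the structure (may have 0
#'   rows when the profile was built from a bare matrix).
#' @slot mode response mode that produced the profile.
#'
#' @aliases DfiProfile-class
#' @exportClass DfiProfile
setClass("DfiProfile",
  representation(
    S = "numeric",
    dfi = "numeric",
    pctDfi = "numeric",
    residues = "data.frame",
    mode = "character"
  ),
  prototype(residues = data.frame(), mode = "analytic")
)

setValidity("DfiProfile", function(object) {
  n <- length(object@dfi)
  if (length(object@S) != n || length(object@pctDfi) != n) {
    return("S, dfi and pctDfi must have equal length")
  }
  if (n && !all(is.finite(object@dfi))) return("dfi values must be finite")
  if (n && (any(object@pctDfi <= 0) || any(object@pctDfi > 100))) {
    return("pctDfi must lie in (0, 100]")
  }
  if (nrow(object@residues) && nrow(object@residues) != n) {
    return("residue table must match profile length")
  }
  TRUE
})

#' Variant enrichment by %dfi bin
#'
#' Observed and expected variant counts per %dfi category, their ratio, and the
#' chi-squared goodness-of-fit test against the uniform-placement null. The
#' expected count in bin i is E_i = (n_i / N) * M where n_i is the number of
#' residue positions in the bin, N the total positions and M the total variants.
#'
#' @slot binEdges interior %dfi boundaries (e.g. 20, 40, 60, 80).
#' @slot nPerBin residue positions per bin.
#' @slot observed variants per bin.
#' @slot expected E_i per bin.
#' @slot ratio observed / expected (NA where expected is 0).
#' @slot chi2,dof,p chi-squared statistic over bins with E_i > 0, its degrees
#'   of freedom (bins - 1), and the upper-tail probability.
#'
#' @aliases EnrichmentResult-class
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(
    binEdges = "numeric",
    nPerBin = "numeric",
    observed = "numeric",
    expected = "numeric",
    ratio = "numeric",
    chi2 = "numeric",
    dof = "integer",
    p = "numeric"
  )
)

setValidity("EnrichmentResult", function(object) {
  nb <- length(object@nPerBin)
  if (length(object@observed) != nb || length(object@expected) != nb ||
      length(object@ratio) != nb) {
    return("per-bin vectors must have equal length")
  }
  if (abs(sum(object@observed) - sum(object@expected)) > 1e-9) {
    return("sum(expected) must equal sum(observed) = M within 1e-9")
  }
  TRUE
})
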