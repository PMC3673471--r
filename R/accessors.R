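#' Accessors for CalphaStructure objects
#'
#' @param x a [CalphaStructure-class] object.
#' @return `nResidues` the residue count; `coords` the N x 3 coordinate matrix;
#'   `residueKeys` a data.frame of (chain, resnum, icode, resname).
#' @name CalphaStructure-accessors
#' @examples
#' s <- makeStructure("ring", n = 12)
#' nResidues(s)
#' head(coords(s))
NULL

#' @rdname CalphaStructure-accessors
#' @export
setMethod("nResidues", "CalphaStructure", function(x) nrow(x@residues))

#' @rdname CalphaStructure-accessors
#' @export
setMethod("coords", "CalphaStructure", function(x) x@coords)

#' @rdname CalphaStructure-accessors
#' @export
setMethod("residueKeys", "CalphaStructure", function(x) x@residues)

setMethod("show", "CalphaStructure", function(object) {
  cat("CalphaStructure with", nResidues(object), "residues\n")
  ch <- unique(object@residues$chain)
  cat("  chains:", paste(ch, collapse = ", "), "\n")
  cat("  source:", object@sourceLabel, "\n")
})

#' Accessors for HessianModel objects
#'
#' `hessian` and `hessianInverse` return the matrices on the physical scale,
#' i.e. multiplied (respectively divided) by the global spring constant gamma.
#' `nullDim` returns the number of zero modes removed during pseudo-inversion
#' (NA before [invertHessian()] has been called).
#'
#' @param x a [HessianModel-class] object.
#' @name HessianModel-accessors
NULL

#' @rdname HessianModel-accessors
#' @export
setMethod("hessian", "HessianModel", function(x) x@gamma * x@hessian)

#' @rdname HessianModel-accessors
#' @export
setMethod("hessianInverse", "HessianModel", function(x) {
  if (!length(x@inverse)) {
    stop("Hessian has not been pseudo-inverted; call invertHessian() first")
  }
  x@inverse / x@gamma
})

#' @rdname HessianModel-accessors
#' @export
setMethod("nullDim", "HessianModel", function(x) x@nullDim)

setMethod("show", "HessianModel", function(object) {
  n <- nrow(object@hessian) / 3L
  cat("HessianModel:", n, "residues (", nrow(object@hessian), "x",
      ncol(object@hessian), "),", object@weighting, "weighting\n")
  cat("  gamma:", object@gamma,
      " inverted:", length(object@inverse) > 0,
      " null modes:", object@nullDim, "\n")
})

#' @rdname ResponseMatrix-class
#' @param x a `ResponseMatrix` object.
#' @export
setMethod("responseMatrix", "ResponseMatrix", function(x) x@A / x@gamma)

setMethod("show", "ResponseMatrix", function(object) {
  cat("ResponseMatrix:", nrow(object@A), "x", ncol(object@A),
      "(", object@mode, ")\n")
  if (!is.na(object@k)) cat("  force directions:", object@k, "\n")
})

#' Accessors for DfiProfile objects
#'
#' @param x a [DfiProfile-class] object.
#' @return `dfi` the normalized flexibility indices (sum to 1); `pctDfi` the
#'   percentile ranks; `totalResponse` the per-residue S values;
#'   `as.data.frame` the residue table with S, dfi and pct_dfi columns.
#' @name DfiProfile-accessors
NULL

#' @rdname DfiProfile-accessors
#' @export
setMethod("dfi", "DfiProfile", function(x) x@dfi)

#' @rdname DfiProfile-accessors
#' @export
setMethod("pctDfi", "DfiProfile", function(x) x@pctDfi)

#' @rdname DfiProfile-accessors
#' @export
setMethod("totalResponse", "DfiProfile", function(x) x@S)

#' @rdname DfiProfile-accessors
#' @export
setMethod("length", "DfiProfile", function(x) length(x@dfi))

#' @rdname DfiProfile-accessors
#' @param row.names,optional ignored (data.frame coercion protocol).
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "DfiProfile",
  function(x, row.names = NULL, optional = FALSE, ...) {
    res <- x@residues
    if (!nrow(res)) {
      res <- data.frame(chain = NA_character_, resnum = seq_along(x@dfi),
                        icode = "", resname = NA_character_)
    }
    data.frame(res[, c("chain", "resnum", "icode", "resname")],
               S = x@S, dfi = x@dfi, pct_dfi = x@pctDfi,
               row.names = NULL)
  })

setMethod("show", "DfiProfile", function(object) {
  n <- length(object@dfi)
  cat("DfiProfile over", n, "residues (", object@mode, "mode )\n")
  if (n) {
    qs <- stats::quantile(object@dfi, c(0, .5, 1))
    cat(sprintf("  dfi: min %.4g  median %.4g  max %.4g\n",
                qs[1], qs[2], qs[3]))
  }
})

setMethod("show", "EnrichmentResult", function(object) {
  edges <- object@binEdges
  lab <- character(length(object@nPerBin))
  lo <- c(0, edges)
  hi <- c(edges, 100)
  for (i in seq_along(lab)) lab[i] <- sprintf("[%g,%g%s", lo[i], hi[i],
                                              if (i == length(lab)) "]" else ")")
  df <- data.frame(bin = lab, n = object@nPerBin, observed = object@observed,
                   expected = round(object@expected, 3),
                   ratio = round(object@ratio, 3))
  cat("EnrichmentResult (chi2 =", format(object@chi2, digits = 5),
      ", dof =", object@dof, ", p =", format.pval(object@p), ")\n")
  print(df, row.names = FALSE)
})
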