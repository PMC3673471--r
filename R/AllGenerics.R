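#' @rdname CalphaStructure-accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname CalphaStructure-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname CalphaStructure-accessors
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname HessianModel-accessors
#' @export
setGeneric("hessian", function(x) standardGeneric("hessian"))

#' @rdname HessianModel-accessors
#' @export
setGeneric("hessianInverse", function(x) standardGeneric("hessianInverse"))

#' @rdname HessianModel-accessors
#' @export
setGeneric("nullDim", function(x) standardGeneric("nullDim"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' @rdname DfiProfile-accessors
#' @export
setGeneric("dfi", function(x) standardGeneric("dfi"))

#' @rdname DfiProfile-accessors
#' @export
setGeneric("pctDfi", function(x) standardGeneric("pctDfi"))

#' @rdname DfiProfile-accessors
#' @export
setGeneric("totalResponse", function(x) standardGeneric("totalResponse"))
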