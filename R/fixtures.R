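.globulePoints <- function(n, radius, minDist = 3.5, maxAttempts = 1e4,
                           center = c(0, 0, 0)) {
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    if (attempts >= maxAttempts) {
      stop("packing failed after ", maxAttempts, " rejection attempts; ",
           "use a larger radius (current ", round(radius, 2), " A)")
    }
    p <- stats::runif(3, -radius, radius)
    attempts <- attempts + 1L
    if (sum(p^2) > radius^2) next
    if (placed > 0L) {
      d2 <- rowSums((pts[seq_len(placed), , drop = FALSE] -
                       matrix(p, placed, 3, byrow = TRUE))^2)
      if (any(d2 < minDist^2)) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
  }
  sweep(pts, 2, center, `+`)
}

.radiusForDensity <- function(n, density) (3 * n / (4 * pi * density))^(1 / 3)

#' Generate a synthetic C-alpha structure
#'
#' Toy structures with known geometry, covering the qualitative regimes of
#' the elastic-network model:
#'
#' * `linear_chain`: collinear points at fixed spacing (degenerate geometry;
#'   7+ zero modes, strong end effects).
#' * `ring`: n points on a circle with adjacent (chord) distances exactly
#'   equal to `spacing`; fully symmetric, so every residue has the same dfi.
#' * `globule`: self-avoiding random points (minimum pair distance 3.5 A)
#'   inside a sphere sized for ~0.6 residues/nm^3; the simplest structure
#'   with 6 rigid modes and a heterogeneous dfi profile.
#' * `dumbbell`: two dense lobes (folded-domain-like packing, 6 residues/nm^3)
#'   joined by a collinear linker along x; the linker is the hinge and sits at
#'   the bottom of the %dfi range.
#'
#' @param kind one of `"linear_chain"`, `"ring"`, `"globule"`, `"dumbbell"`.
#' @param n residue count (for `dumbbell`, ignored in favour of
#'   `lobeSizes` + `linkerLength`).
#' @param spacing backbone spacing in Angstrom (default 3.8, the C-alpha
#'   virtual bond length).
#' @param seed RNG seed for the random kinds.
#' @param density globule packing density in residues per A^3 (default
#'   6e-4, i.e. 0.6 residues/nm^3).
#' @param lobeSizes residue counts of the two dumbbell lobes.
#' @param linkerLength number of linker residues between the lobes.
#' @param lobeDensity dumbbell lobe packing density (default 6e-3 / A^3,
#'   i.e. 6 residues/nm^3, folded-domain-like).
#' @param chain chain identifier for the residue table.
#' @return a [CalphaStructure-class]; residues are numbered 1..N, resname GLY.
#' @examples
#' ring <- makeStructure("ring", n = 12)
#' db <- makeStructure("dumbbell", lobeSizes = c(20, 20), linkerLength = 3,
#'                     seed = 7)
#' nResidues(db)   # 43
#' @export
makeStructure <- function(kind = c("linear_chain", "ring", "globule",
                                   "dumbbell"),
                          n = 20, spacing = 3.8, seed = NULL,
                          density = 6e-4, lobeSizes = c(20, 20),
                          linkerLength = 3, lobeDensity = 6e-3,
                          chain = "A") {
  kind <- match.arg(kind)
  stopifnot(n >= 2, spacing > 0)
  xyz <- .withSeed(seed, switch(kind,
    linear_chain = cbind((seq_len(n) - 1) * spacing, 0, 0),
    ring = {
      ## radius chosen so adjacent chord distances equal the spacing exactly
      r <- spacing / (2 * sin(pi / n))
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(r * cos(th), r * sin(th), 0)
    },
    globule = .globulePoints(n, .radiusForDensity(n, density)),
    dumbbell = {
      stopifnot(length(lobeSizes) == 2, all(lobeSizes >= 2), linkerLength >= 1)
      r1 <- .radiusForDensity(lobeSizes[1], lobeDensity)
      r2 <- .radiusForDensity(lobeSizes[2], lobeDensity)
      gap <- (linkerLength + 1) * spacing
      c1 <- c(0, 0, 0)
      c2 <- c(r1 + gap + r2, 0, 0)
      lob1 <- .globulePoints(lobeSizes[1], r1, center = c1)
      lob2 <- .globulePoints(lobeSizes[2], r2, center = c2)
      link <- cbind(r1 + seq_len(linkerLength) * spacing, 0, 0)
      rbind(lob1, link, lob2)
    }
  ))
  nTot <- nrow(xyz)
  res <- data.frame(chain = chain, resnum = seq_len(nTot), icode = "",
                    resname = "GLY", stringsAsFactors = FALSE)
  lab <- sprintf("synthetic %s (n=%d, spacing=%g%s)", kind, nTot, spacing,
                 if (is.null(seed)) "" else sprintf(", seed=%d", seed))
  new("CalphaStructure", residues = res, coords = xyz, sourceLabel = lab)
}

#' Indices of the linker residues of a dumbbell fixture
#'
#' @param lobeSizes,linkerLength the dumbbell parameters used in
#'   [makeStructure()].
#' @return integer indices of the linker residues in the residue order.
#' @export
dumbbellLinkerIdx <- function(lobeSizes = c(20, 20), linkerLength = 3) {
  lobeSizes[1] + seq_len(linkerLength)
}

#' Generate a planted annotation table for a dfi profile
#'
#' Emulates the statistical structure of real variant/rate data with known
#' ground truth: variant positions are sampled with probability proportional
#' to a per-bin weight of each residue's %dfi category (weights above 1 in
#' the low-flexibility bins plant the disease-variant enrichment pattern),
#' and per-site evolutionary rates follow a truncated linear model
#' `r = slope * (%dfi / 100) + Normal(0, sigma)`, clipped at 0, so rates
#' increase with flexibility.
#'
#' @param profile a [DfiProfile-class] (or a bare numeric %dfi vector).
#' @param weights per-bin sampling weights, one per %dfi category (default
#'   `c(1.45, 1, 1, 1, 0.65)`, mirroring an enrichment of variants at rigid
#'   sites and a deficit at flexible ones).
#' @param m number of variants to sample.
#' @param edges %dfi bin boundaries (default 20/40/60/80).
#' @param label variant label to assign (default `"disease"`).
#' @param rateSlope,rateSigma slope (substitutions/site/Byr at %dfi = 100) and
#'   noise sd of the rate model; defaults 1 and 0.25.
#' @param replace sample variant positions with replacement (default TRUE:
#'   several variants may hit one site). With `replace = FALSE`, `m` may not
#'   exceed the number of positions.
#' @param seed RNG seed.
#' @param proteinId identifier written into the table.
#' @return list with `variants` (integer positions, length m), `rates`
#'   (numeric, per residue) and `table` (a data.frame in the annotation
#'   format: protein_id, chain, resnum, icode, label, rate; one row per
#'   variant plus one `"."`-labeled row per residue carrying its rate).
#' @export
makeAnnotations <- function(profile, weights = c(1.45, 1, 1, 1, 0.65),
                            m = 1000, edges = c(20, 40, 60, 80),
                            label = "disease", rateSlope = 1,
                            rateSigma = 0.25, replace = TRUE, seed = NULL,
                            proteinId = "synthetic") {
  pct <- if (is(profile, "DfiProfile")) pctDfi(profile) else profile
  n <- length(pct)
  if (length(weights) != length(edges) + 1L) {
    stop("need one weight per %dfi bin (", length(edges) + 1L, ")")
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop("bin weights must be >= 0 and not all zero")
  }
  if (m < 1) stop("m must be >= 1")
  if (!replace && m > n) {
    stop("cannot draw ", m, " variants without replacement from ", n,
         " positions")
  }
  bins <- binByPctDfi(pct, edges)
  w <- weights[bins]
  .withSeed(seed, {
    variants <- sample.int(n, m, replace = replace, prob = w)
    rates <- pmax(0, rateSlope * pct / 100 + stats::rnorm(n, 0, rateSigma))
    resTab <- if (is(profile, "DfiProfile") && nrow(profile@residues)) {
      profile@residues
    } else {
      data.frame(chain = "A", resnum = seq_len(n), icode = "",
                 resname = "GLY", stringsAsFactors = FALSE)
    }
    tab <- rbind(
      data.frame(protein_id = proteinId, chain = resTab$chain[variants],
                 resnum = resTab$resnum[variants],
                 icode = resTab$icode[variants], label = label,
                 rate = rates[variants], stringsAsFactors = FALSE),
      data.frame(protein_id = proteinId, chain = resTab$chain,
                 resnum = resTab$resnum, icode = resTab$icode, label = ".",
                 rate = rates, stringsAsFactors = FALSE)
    )
    list(variants = variants, rates = rates, table = tab)
  })
}

#' Write / read annotation tables
#'
#' Tab-separated with header `protein_id chain resnum icode label rate`;
#' multiple labels on one row are comma-separated, `"."` marks a rate-only
#' row.
#'
#' @param table annotation data.frame (as from [makeAnnotations()]`$table`).
#' @param path file path.
#' @return `writeAnnotations` invisibly returns `path`; `readAnnotations`
#'   returns the data.frame.
#' @export
writeAnnotations <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  df <- utils::read.delim(path, colClasses = c(protein_id = "character",
                                               chain = "character",
                                               icode = "character",
                                               label = "character"),
                          stringsAsFactors = FALSE)
  df$icode[is.na(df$icode)] <- ""
  df
}
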