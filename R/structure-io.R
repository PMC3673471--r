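## PDB fixed-width layout (1-based columns):
## 1-6 record, 7-11 serial, 13-16 atom name, 17 altloc, 18-20 resname,
## 22 chain, 23-26 resseq, 27 icode, 31-38/39-46/47-54 x/y/z,
## 55-60 occupancy, 61-66 B-factor, 77-78 element.

.pdbField <- function(lines, from, to) substr(lines, from, to)

.residueKey <- function(chain, resnum, icode) {
  paste(chain, resnum, icode, sep = "|")
}

#' Read a C-alpha structure from a PDB file
#'
#' Parses ATOM records (plus HETATM records for modified residues, MSE by
#' default) and keeps one C-alpha coordinate per residue. For alternate
#' locations the highest-occupancy conformer wins, ties broken by file order.
#' Multi-model (NMR) files are resolved to a single model, the first by
#' default. Waters, ligands and side-chain atoms are ignored: the elastic
#' network is built on the C-alpha trace only.
#'
#' @param path path to a PDB file.
#' @param chains optional character vector of chain identifiers to keep
#'   (default: all chains of the selected model).
#' @param model model number for multi-model files (1-based, default 1).
#' @param hetatmInclude residue names whose HETATM records are treated as part
#'   of the polymer (default `"MSE"`, selenomethionine).
#' @return a [CalphaStructure-class] object; residue order follows file order.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeStructurePDB(makeStructure("linear_chain", n = 5), pdb)
#' readCalphaStructure(pdb)
#' @export
readCalphaStructure <- function(path, chains = NULL, model = 1L,
                                hetatmInclude = "MSE") {
  if (!file.exists(path)) {
    stop("cannot read PDB file: ", path)
  }
  lines <- readLines(path, warn = FALSE)

  ## multi-model handling: restrict to the requested MODEL block if present
  modelStarts <- grep("^MODEL", lines)
  if (length(modelStarts)) {
    if (model > length(modelStarts)) {
      stop("requested model ", model, " but file has only ",
           length(modelStarts), " model(s)")
    }
    ends <- grep("^ENDMDL", lines)
    from <- modelStarts[model]
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    lines <- lines[from:to]
  }

  rec <- .pdbField(lines, 1, 6)
  isAtom <- rec == "ATOM  "
  isHet <- rec == "HETATM" &
    trimws(.pdbField(lines, 18, 20)) %in% hetatmInclude
  keep <- isAtom | isHet
  lines <- lines[keep]

  chainId <- .pdbField(lines, 22, 22)
  if (!is.null(chains)) {
    lines <- lines[chainId %in% chains]
    chainId <- .pdbField(lines, 22, 22)
  }
  selLabel <- if (is.null(chains)) "all chains" else {
    paste("chain(s)", paste(chains, collapse = ","))
  }

  atomName <- trimws(.pdbField(lines, 13, 16))
  resnum <- as.integer(.pdbField(lines, 23, 26))
  icode <- trimws(.pdbField(lines, 27, 27))
  resname <- trimws(.pdbField(lines, 18, 20))
  key <- .residueKey(chainId, resnum, icode)

  isCA <- atomName == "CA"
  ## residues with atoms but no C-alpha are skipped, with a warning
  missing <- setdiff(unique(key), unique(key[isCA]))
  if (length(missing)) {
    warning("skipping ", length(missing),
            " residue(s) without a C-alpha atom: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  }

  caIdx <- which(isCA)
  if (!length(caIdx)) {
    stop("no C-alpha atoms found for selection (", selLabel,
         ", model ", model, ") in ", path)
  }

  occ <- suppressWarnings(as.numeric(.pdbField(lines[caIdx], 55, 60)))
  occ[is.na(occ)] <- 1
  caKey <- key[caIdx]
  ## altloc: highest occupancy, ties broken by file order (stable which.max)
  pick <- vapply(split(seq_along(caIdx), factor(caKey, unique(caKey))),
                 function(ii) ii[which.max(occ[ii])], integer(1))
  pick <- sort(pick)               # restore file order of residues
  sel <- caIdx[pick]

  xyz <- cbind(
    as.numeric(.pdbField(lines[sel], 31, 38)),
    as.numeric(.pdbField(lines[sel], 39, 46)),
    as.numeric(.pdbField(lines[sel], 47, 54))
  )
  res <- data.frame(
    chain = chainId[sel],
    resnum = resnum[sel],
    icode = icode[sel],
    resname = resname[sel],
    stringsAsFactors = FALSE
  )
  new("CalphaStructure", residues = res, coords = xyz, sourceLabel = path)
}

#' Write a C-alpha structure as a minimal PDB file
#'
#' Emits one ATOM record per residue (the C-alpha), occupancy 1.00 and
#' B-factor 0.00, at the standard 3-decimal coordinate precision.
#'
#' @param structure a [CalphaStructure-class] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeStructurePDB <- function(structure, path) {
  stopifnot(is(structure, "CalphaStructure"))
  res <- structure@residues
  xyz <- structure@coords
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(res)), res$resname, res$chain, res$resnum, res$icode,
    xyz[, 1], xyz[, 2], xyz[, 3], 1, 0
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a per-residue dfi table
#'
#' Tab-separated table with columns chain, resnum, icode, resname, S, dfi,
#' pct_dfi, one row per residue. Optional `headerLines` (run parameters,
#' provenance) are written first, prefixed with `#`.
#'
#' @param profile a [DfiProfile-class] object.
#' @param structure the [CalphaStructure-class] the profile was computed on;
#'   may be NULL when the profile already carries its residue table.
#' @param path output file path.
#' @param headerLines character vector of comment lines (without the `#`).
#' @return invisibly, `path`.
#' @seealso [readDfiTable()]
#' @export
writeDfiTable <- function(profile, structure = NULL, path,
                          headerLines = character()) {
  stopifnot(is(profile, "DfiProfile"))
  if (!is.null(structure)) {
    if (nResidues(structure) != length(profile)) {
      stop("profile length (", length(profile),
           ") does not match structure residue count (",
           nResidues(structure), ")")
    }
    profile@residues <- structure@residues
  }
  df <- as.data.frame(profile)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(headerLines)) writeLines(paste0("# ", headerLines), con)
  writeLines(paste(c("chain", "resnum", "icode", "resname",
                     "S", "dfi", "pct_dfi"), collapse = "\t"), con)
  body <- sprintf("%s\t%d\t%s\t%s\t%.12g\t%.12g\t%.12g",
                  df$chain, df$resnum, df$icode, df$resname,
                  df$S, df$dfi, df$pct_dfi)
  writeLines(body, con)
  invisible(path)
}

#' Read a dfi table written by [writeDfiTable()]
#'
#' @param path path to the tab-separated table; `#` comment lines are skipped.
#' @return a data.frame with columns chain, resnum, icode, resname, S, dfi,
#'   pct_dfi.
#' @export
readDfiTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(chain = "character",
                                         icode = "character",
                                         resname = "character"),
                          stringsAsFactors = FALSE)
  df$icode[is.na(df$icode)] <- ""
  df
}

#' Copy a PDB file with %dfi written into the B-factor column
#'
#' Every atom of every profiled residue carries that residue's percentile
#' flexibility (%dfi) in the B-factor field (columns 61-66, two decimals), so
#' molecular viewers can color ribbons by flexibility. Atoms of residues not
#' in the profile get 0.00.
#'
#' @param sourcePath the original PDB file.
#' @param profile a [DfiProfile-class] whose residue table maps into the file.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeBfactorPDB <- function(sourcePath, profile, path) {
  stopifnot(is(profile, "DfiProfile"))
  if (!nrow(profile@residues)) {
    stop("profile carries no residue table; cannot map onto the PDB file")
  }
  lines <- readLines(sourcePath, warn = FALSE)
  rec <- .pdbField(lines, 1, 6)
  isAtomLine <- rec %in% c("ATOM  ", "HETATM")

  key <- .residueKey(.pdbField(lines, 22, 22),
                     as.integer(.pdbField(lines, 23, 26)),
                     trimws(.pdbField(lines, 27, 27)))
  res <- profile@residues
  profKey <- .residueKey(res$chain, res$resnum, res$icode)
  absent <- setdiff(profKey, unique(key[isAtomLine]))
  if (length(absent)) {
    stop("profile residues not present in ", sourcePath, ": ",
         paste(absent, collapse = ", "))
  }
  idx <- which(isAtomLine)
  b <- rep(0, length(idx))
  hit <- match(key[idx], profKey)
  b[!is.na(hit)] <- profile@pctDfi[hit[!is.na(hit)]]
  padded <- formatC(lines[idx], width = 66, flag = "-")
  lines[idx] <- paste0(substr(padded, 1, 60), sprintf("%6.2f", b),
                       substr(padded, 67, nchar(padded)))
  writeLines(lines, path)
  invisible(path)
}
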