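#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records, preserving author residue numbering,
#' insertion codes (e.g. the inserted glycine G80b of ttRNH) and multiple
#' chains. Alternate locations other than blank or 'A' are dropped.
#' Secondary-structure ranges (HELIX/SHEET header records), when present,
#' are returned so that analyses can be restricted to secondary-structure
#' elements.
#'
#' @param path path to a PDB file.
#' @param keepHetatm logical, keep HETATM records (default FALSE).
#' @return list with elements `topology` ([Topology-class]), `frame`
#'   (nAtoms x 3 coordinate matrix, Angstrom) and `sse` (data.frame of
#'   helix/sheet ranges with columns `chain`, `start`, `end`, `type`;
#'   zero rows when the file has no header annotation).
#' @examples
#' pdb <- system.file("extdata", "synthetic_ecRNH_like.pdb",
#'                    package = "HandleDynamics")
#' s <- readStructure(pdb)
#' s$topology
#' @export
readStructure <- function(path, keepHetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  .checkPdbCoordinates(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  if (!keepHetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  alt <- a$alt; alt[is.na(alt)] <- ""
  a <- a[alt %in% c("", "A"), , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure: no ATOM records in ", path)
  ins <- a$insert; ins[is.na(ins)] <- ""
  chain <- a$chain; chain[is.na(chain)] <- ""
  ele <- a$elesy; ele[is.na(ele)] <- ""
  topo <- new("Topology", atoms = data.frame(
    atomName = a$elety, resName = a$resid, chain = chain,
    resNo = as.integer(a$resno), insCode = ins, element = ele,
    stringsAsFactors = FALSE))
  frame <- unname(cbind(a$x, a$y, a$z))
  sse <- .sseTable(pdb)
  list(topology = topo, frame = frame, sse = sse)
}

.checkPdbCoordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0) stop("empty structure: no ATOM records in ", path)
  for (i in rec) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46),
      substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinate fields at line ", i, " of ", path)
  }
  invisible(TRUE)
}

.sseTable <- function(pdb) {
  out <- data.frame(chain = character(), start = integer(),
                    end = integer(), type = character())
  for (kind in c("helix", "sheet")) {
    h <- pdb[[kind]]
    if (!is.null(h) && length(h$start) > 0) {
      out <- rbind(out, data.frame(
        chain = if (is.null(h$chain)) "A" else h$chain,
        start = as.integer(h$start), end = as.integer(h$end), type = kind))
    }
  }
  out
}

#' Write a structure or trajectory to (multi-model) PDB
#'
#' One MODEL per frame for a multi-frame [Trajectory-class]; a plain
#' single-model file for one frame. Coordinates are written at PDB
#' precision (1e-3 Angstrom).
#'
#' @param x a [Trajectory-class], or a [Topology-class] together with
#'   `coords`.
#' @param path output file.
#' @param coords nAtoms x 3 matrix when `x` is a `Topology`.
#' @return invisibly, `path`.
#' @export
writeStructure <- function(x, path, coords = NULL) {
  if (is(x, "Trajectory")) {
    topo <- x@topology
    xyz <- t(apply(x@coords, 3, function(m) as.numeric(t(m))))
    if (dim(x@coords)[3] == 1)
      xyz <- matrix(as.numeric(t(x@coords[, , 1])), nrow = 1)
  } else if (is(x, "Topology")) {
    if (is.null(coords)) stop("coords required when writing a Topology")
    topo <- x
    xyz <- matrix(as.numeric(t(coords)), nrow = 1)
  } else stop("x must be a Trajectory or Topology")
  a <- topo@atoms
  pdb <- list(atom = data.frame(
    type = "ATOM", eleno = seq_len(nrow(a)), elety = a$atomName, alt = "",
    resid = a$resName, chain = a$chain, resno = a$resNo, insert = a$insCode,
    x = 0, y = 0, z = 0, o = 1, b = 0, segid = "", elesy = a$element,
    charge = "", stringsAsFactors = FALSE),
    xyz = bio3d::as.xyz(xyz))
  class(pdb) <- "pdb"
  bio3d::write.pdb(pdb, file = path)
  invisible(path)
}

#' Read trajectory frames against a known topology
#'
#' Accepts binary DCD files (via bio3d) or multi-model PDB files. The atom
#' count of every frame must match the topology; coordinates are Angstrom
#' internally.
#'
#' @param topology a [Topology-class] from [readStructure()].
#' @param path trajectory file (`.dcd` or multi-model `.pdb`).
#' @param format "auto" (by extension), "dcd" or "pdb".
#' @param frameInterval time between frames, ps.
#' @param temperature simulation temperature label, K.
#' @param label free-text label.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(topology, path, format = c("auto", "dcd", "pdb"),
                           frameInterval = 1, temperature = 300,
                           label = basename(path)) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  nAtoms <- nrow(topology@atoms)
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
  }
  xyz <- unclass(xyz)
  if (ncol(xyz) != 3 * nAtoms)
    stop("topology error: file has ", ncol(xyz) / 3,
         " atoms per frame, topology has ", nAtoms)
  coords <- array(0, c(nAtoms, 3, nrow(xyz)))
  for (f in seq_len(nrow(xyz)))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  new("Trajectory", topology = topology, coords = coords,
      frameInterval = frameInterval, temperature = temperature,
      label = label)
}

#' Select atoms by chain, residue, residue name or atom name
#'
#' The selection mini-language is a conjunction of optional filters, each a
#' vector of allowed values; `resNo` may be any integer vector (e.g.
#' `89:100`). Residues may instead be addressed exactly by `resKeys`
#' (strings from [resKey()]), which is the only way to address inserted
#' residues like G80b.
#'
#' @param topology a [Topology-class] (or [Trajectory-class]).
#' @param chain,resNo,insCode,resName,atomName optional filter vectors; a
#'   `NULL` filter matches everything.
#' @param resKeys optional character vector of residue keys
#'   ("chain|resNo|insCode"); overrides chain/resNo/insCode.
#' @return integer vector of atom indices in topology order; an empty
#'   selection is returned with a warning.
#' @examples
#' pdb <- system.file("extdata", "synthetic_ecRNH_like.pdb",
#'                    package = "HandleDynamics")
#' topo <- readStructure(pdb)$topology
#' selectAtoms(topo, resNo = 85, atomName = "CA")
#' @export
selectAtoms <- function(topology, chain = NULL, resNo = NULL, insCode = NULL,
                        resName = NULL, atomName = NULL, resKeys = NULL) {
  if (is(topology, "Trajectory")) topology <- topology@topology
  a <- topology@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resKeys)) {
    keys <- paste(a$chain, a$resNo, a$insCode, sep = "|")
    keep <- keep & keys %in% resKeys
  } else {
    if (!is.null(chain)) {
      if (!any(a$chain %in% chain))
        stop("selection error: no such chain: ", paste(chain, collapse = ","))
      keep <- keep & a$chain %in% chain
    }
    if (!is.null(resNo)) keep <- keep & a$resNo %in% as.integer(resNo)
    if (!is.null(insCode)) keep <- keep & a$insCode %in% insCode
  }
  if (!is.null(resName)) keep <- keep & a$resName %in% resName
  if (!is.null(atomName)) keep <- keep & a$atomName %in% atomName
  idx <- which(keep)
  if (length(idx) == 0) warning("selection matched no atoms")
  idx
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Closed-form optimal rotation and translation of `mobile` onto
#' `reference` by SVD of the cross-covariance; reflections are rejected by
#' forcing det(R) = +1. The RMSD after the transform is the least-squares
#' minimum.
#'
#' @param mobile,reference n x 3 coordinate matrices, equal n >= 3,
#'   not all collinear.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3;
#'   the transform is `x %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom, after transform) and `transformed` (the transformed mobile
#'   coordinates).
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' fit <- superpose(ref + 5, ref)   # pure translation: rmsd ~ 0
#' fit$rmsd
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("dimension error: coordinate sets must both be n x 3 with equal n")
  n <- nrow(mobile)
  if (n < 3) stop("underdetermined: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be non-negative, one per point")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sv <- svd(crossprod(Q * w, Q))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate reference: points are (nearly) collinear")
  H <- crossprod(P * w, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- sweep(P %*% t(R), 2, cr, "+")
  rmsd <- sqrt(sum(w * rowSums((P %*% t(R) - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       rmsd = rmsd, transformed = transformed)
}

#' Mean all-to-all RMSD between two conformational ensembles
#'
#' Every frame pair (a from `trajA`, b from `trajB`) is least-squares
#' superposed on the selected atoms and the mean pairwise RMSD returned;
#' this is the metric used to compare handle-region ensembles across
#' homologs.
#'
#' @param trajA,trajB [Trajectory-class] objects.
#' @param selectionA,selectionB atom index vectors (from [selectAtoms()]),
#'   or character residue-key vectors whose C-alpha atoms are used.
#' @param map optional residue map (from [mapEquivalentResidues()]) applied
#'   to translate residue keys of A into B when `selectionA` is a key
#'   vector and `selectionB` is missing.
#' @param stride keep every `stride`-th frame of both trajectories.
#' @return list with `meanRmsd` (Angstrom), `nPairs`, and the `rmsd`
#'   matrix (framesA x framesB).
#' @export
ensembleRmsd <- function(trajA, trajB, selectionA, selectionB = NULL,
                         map = NULL, stride = 1) {
  if (is.character(selectionA)) {
    keysA <- selectionA
    if (is.null(selectionB)) {
      if (is.null(map)) stop("selection error: selectionB or map required")
      keysB <- applyResidueMap(map, keysA)
      if (anyNA(keysB))
        stop("selection error: unmapped residues: ",
             paste(keysA[is.na(keysB)], collapse = ", "))
    } else keysB <- selectionB
    selectionA <- selectAtoms(trajA, resKeys = keysA, atomName = "CA")
    selectionB <- selectAtoms(trajB, resKeys = keysB, atomName = "CA")
  }
  if (length(selectionA) == 0 || length(selectionB) == 0)
    stop("selection error: empty mapped selection")
  if (length(selectionA) != length(selectionB))
    stop("selection error: mapped selections differ in atom count")
  fA <- seq(1, dim(trajA@coords)[3], by = stride)
  fB <- seq(1, dim(trajB@coords)[3], by = stride)
  m <- matrix(0, length(fA), length(fB))
  for (i in seq_along(fA)) {
    ca <- trajA@coords[selectionA, , fA[i], drop = FALSE][, , 1]
    for (j in seq_along(fB)) {
      cb <- trajB@coords[selectionB, , fB[j], drop = FALSE][, , 1]
      m[i, j] <- superpose(ca, cb)$rmsd
    }
  }
  list(meanRmsd = mean(m), nPairs = length(m), rmsd = m)
}

#' Map equivalent residues between two homologs from a pairwise alignment
#'
#' Aligned non-gap columns define the correspondence (e.g. which ttRNH
#' residue is equivalent to W85 of ecRNH); gap columns are unmapped. The
#' alignment rows must reproduce the topologies' one-letter sequences
#' exactly, which is verified before mapping.
#'
#' @param alignment character vector of two equal-length aligned sequences
#'   (gap "-"), or a `Biostrings::AAStringSet` of length 2.
#' @param source,target [Topology-class] objects in alignment row order.
#' @return a `ResidueMap`: data.frame with columns `sourceKey`,
#'   `targetKey`, class `c("ResidueMap", "data.frame")`. Injective on
#'   mapped keys.
#' @seealso [applyResidueMap()], [invertResidueMap()]
#' @export
mapEquivalentResidues <- function(alignment, source, target) {
  if (is(alignment, "AAStringSet")) alignment <- as.character(alignment)
  if (length(alignment) != 2 || nchar(alignment[1]) != nchar(alignment[2]))
    stop("alignment must be two equal-length aligned sequences")
  rows <- strsplit(toupper(alignment), "")
  keys <- lapply(list(source, target), residueKeys)
  seqs <- lapply(list(source, target), .topologySequence)
  for (k in 1:2) {
    ungapped <- rows[[k]][rows[[k]] != "-"]
    if (length(ungapped) != length(seqs[[k]]) ||
        !all(ungapped == seqs[[k]])) {
      bad <- which(ungapped != seqs[[k]])[1]
      stop("consistency error: alignment row ", k,
           " does not match topology sequence (first discrepancy at ",
           "residue ", if (is.na(bad)) "length" else bad, ")")
    }
  }
  posS <- cumsum(rows[[1]] != "-")
  posT <- cumsum(rows[[2]] != "-")
  both <- rows[[1]] != "-" & rows[[2]] != "-"
  map <- data.frame(sourceKey = keys[[1]][posS[both]],
                    targetKey = keys[[2]][posT[both]],
                    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(map$sourceKey), !anyDuplicated(map$targetKey))
  class(map) <- c("ResidueMap", "data.frame")
  map
}

.topologySequence <- function(topology) {
  a <- topology@atoms
  first <- !duplicated(paste(a$chain, a$resNo, a$insCode, sep = "|"))
  bio3d::aa321(a$resName[first])
}

#' Translate residue keys through a ResidueMap
#'
#' @param map a `ResidueMap` from [mapEquivalentResidues()].
#' @param keys source residue keys.
#' @return target keys (NA where unmapped).
#' @export
applyResidueMap <- function(map, keys) {
  map$targetKey[match(keys, map$sourceKey)]
}

#' Invert a ResidueMap
#'
#' @param map a `ResidueMap`.
#' @return the inverse map (target becomes source).
#' @export
invertResidueMap <- function(map) {
  inv <- data.frame(sourceKey = map$targetKey, targetKey = map$sourceKey,
                    stringsAsFactors = FALSE)
  class(inv) <- c("ResidueMap", "data.frame")
  inv
}

#' Read an alignment from a FASTA file
#'
#' @param path FASTA file of aligned sequences (gap "-").
#' @return named character vector of aligned sequences.
#' @export
readAlignmentFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
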