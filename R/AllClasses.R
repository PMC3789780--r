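#' @import methods
NULL

#' Topology: atom metadata for a structure or trajectory
#'
#' A `Topology` holds the ordered atom records of a molecular structure:
#' atom names, residue names, author residue numbers with PDB insertion
#' codes (so that inserted residues such as G80b keep their identity), and
#' chain identifiers. Atom order is the file order and is stable across
#' trajectory frames.
#'
#' @slot atoms data.frame with columns `atomName`, `resName`, `chain`,
#'   `resNo` (integer, author numbering), `insCode` (single character,
#'   `""` when absent) and `element`.
#'
#' @seealso [readStructure()], [selectAtoms()], [residueKeys()]
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("atomName", "resName", "chain", "resNo", "insCode", "element")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("topology has zero atoms")
  key <- paste(a$chain, a$resNo, a$insCode, a$atomName, sep = "|")
  if (anyDuplicated(key))
    return("duplicate (chain, resNo, insCode, atomName) atom keys")
  TRUE
})

#' Trajectory: topology plus an ordered stack of coordinate frames
#'
#' Coordinates are stored in Angstrom as an `nAtoms x 3 x nFrames` array.
#' The temperature label and frame interval carry the simulation conditions
#' through all downstream analyses.
#'
#' @slot topology a [Topology-class] object.
#' @slot coords numeric array, `nAtoms x 3 x nFrames`, Angstrom.
#' @slot frameInterval numeric, time between frames in ps (> 0).
#' @slot temperature numeric, simulation temperature label in K.
#' @slot label character, free-text protein/run label.
#'
#' @seealso [readTrajectory()], [genTwoStateTrajectory()], [handleDistance()]
#' @export
setClass("Trajectory", representation(
  topology = "Topology", coords = "array",
  frameInterval = "numeric", temperature = "numeric", label = "character"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an nAtoms x 3 x nFrames array")
  if (d[1] != nrow(object@topology@atoms))
    return("coords atom count does not match topology")
  if (d[3] < 1) return("trajectory must contain at least one frame")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    return("frameInterval must be a single positive number (ps)")
  if (!all(is.finite(object@coords))) return("non-finite coordinates")
  TRUE
})

#' DistanceSeries: the handle-region reaction coordinate
#'
#' Per-frame Cartesian distance (Angstrom) between two C-alpha atoms, by
#' default the anchor on helix C (W85 in ecRNH numbering) and the tip of the
#' handle loop (A93). This internal coordinate needs no superposition.
#'
#' @slot values numeric, one distance per frame, Angstrom.
#' @slot anchor,tip character residue keys ("chain|resNo|insCode").
#' @slot label character source trajectory label.
#' @slot temperature numeric, K.
#'
#' @seealso [handleDistance()], [classifyStates()]
#' @export
setClass("DistanceSeries", representation(
  values = "numeric", anchor = "character", tip = "character",
  label = "character", temperature = "numeric"))

setValidity("DistanceSeries", function(object) {
  if (!all(is.finite(object@values)) || any(object@values < 0))
    return("distances must be finite and non-negative")
  TRUE
})

#' StateSeries: per-frame open/closed labels
#'
#' A frame is open iff its reaction-coordinate value strictly exceeds the
#' threshold (default 10 Angstrom); a value exactly at the threshold is
#' closed.
#'
#' @slot states character vector, each "open" or "closed".
#' @slot threshold numeric, Angstrom.
#' @export
setClass("StateSeries", representation(
  states = "character", threshold = "numeric"))

setValidity("StateSeries", function(object) {
  if (!all(object@states %in% c("open", "closed")))
    return("states must be 'open' or 'closed'")
  if (object@threshold <= 0) return("threshold must be positive")
  TRUE
})

#' PopulationSummary: open-state population with a Wilson confidence interval
#'
#' @slot nOpen,nClosed integer frame counts after equilibration discard.
#' @slot pOpen numeric open-state fraction.
#' @slot ciLevel,ciLo,ciHi numeric Wilson score interval.
#' @slot nDiscarded integer equilibration frames discarded.
#' @export
setClass("PopulationSummary", representation(
  nOpen = "integer", nClosed = "integer", pOpen = "numeric",
  ciLevel = "numeric", ciLo = "numeric", ciHi = "numeric",
  nDiscarded = "integer"))

setValidity("PopulationSummary", function(object) {
  n <- object@nOpen + object@nClosed
  if (n < 1) return("no frames after discard")
  if (abs(object@pOpen - object@nOpen / n) > 1e-12)
    return("pOpen must equal nOpen/(nOpen+nClosed)")
  if (!(object@ciLo >= 0 && object@ciLo <= object@pOpen + 1e-12 &&
        object@pOpen <= object@ciHi + 1e-12 && object@ciHi <= 1))
    return("confidence interval must satisfy 0 <= lo <= pOpen <= hi <= 1")
  TRUE
})

#' FreeEnergyGap: free-energy difference between closed and open states
#'
#' DeltaG = -R T log(pOpen/pClosed) with R = 1.987e-3 kcal/(mol K), i.e. a
#' negative gap means the open state is the more populated one. The sign
#' convention string is carried in the object.
#'
#' @slot deltaG numeric, kcal/mol.
#' @slot temperature numeric, K.
#' @slot convention character description of the sign convention.
#' @export
setClass("FreeEnergyGap", representation(
  deltaG = "numeric", temperature = "numeric", convention = "character"))

#' ModeDecomposition: Cartesian PCA of loop C-alpha coordinates
#'
#' @slot mean numeric matrix, `L x 3`, the iteratively refined mean loop
#'   conformation the frames were superposed onto.
#' @slot center numeric, length 3L, the coordinate mean of the superposed
#'   fitting frames (subtracted before projection).
#' @slot eigenvalues numeric, Angstrom^2, descending.
#' @slot eigenvectors numeric matrix, `3L x k`, orthonormal columns with a
#'   deterministic sign convention (largest-magnitude entry positive).
#' @slot varianceFractions numeric, eigenvalues over total variance.
#' @slot fittedOn character labels of the trajectories entering the fit.
#' @slot superposed logical; FALSE when the decomposition was fitted on
#'   pre-aligned frames without internal superposition.
#' @seealso [loopPCA()], [projectOntoModes()]
#' @export
setClass("ModeDecomposition", representation(
  mean = "matrix", center = "numeric", eigenvalues = "numeric",
  eigenvectors = "matrix", varianceFractions = "numeric",
  fittedOn = "character", superposed = "logical"))

setValidity("ModeDecomposition", function(object) {
  ev <- object@eigenvalues
  if (any(ev < -1e-9)) return("negative eigenvalue")
  if (is.unsorted(rev(ev), strictly = FALSE))
    return("eigenvalues must be descending")
  if (abs(sum(object@varianceFractions) - 1) > 1e-9)
    return("variance fractions must sum to 1")
  TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat("Topology:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resNo, a$insCode))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory '%s': %d atoms x %d frames @ %g ps, %g K\n",
              object@label, d[1], d[3], object@frameInterval,
              object@temperature))
})

setMethod("show", "DistanceSeries", function(object) {
  cat(sprintf(
    "DistanceSeries '%s' (%g K): %d frames, %s -> %s, range %.2f-%.2f A\n",
    object@label, object@temperature, length(object@values),
    object@anchor, object@tip, min(object@values), max(object@values)))
})

setMethod("show", "StateSeries", function(object) {
  cat(sprintf("StateSeries: %d frames, %d open / %d closed (threshold %g A)\n",
              length(object@states), sum(object@states == "open"),
              sum(object@states == "closed"), object@threshold))
})

setMethod("show", "PopulationSummary", function(object) {
  cat(sprintf(
    "PopulationSummary: p(open) = %.4f [%.4f, %.4f] (%g%% Wilson), n = %d (+%d discarded)\n",
    object@pOpen, object@ciLo, object@ciHi, 100 * object@ciLevel,
    object@nOpen + object@nClosed, object@nDiscarded))
})

setMethod("show", "FreeEnergyGap", function(object) {
  cat(sprintf("FreeEnergyGap: %+.3f kcal/mol at %g K (%s)\n",
              object@deltaG, object@temperature, object@convention))
})

setMethod("show", "ModeDecomposition", function(object) {
  vf <- object@varianceFractions
  cat(sprintf(
    "ModeDecomposition: %d modes over %d coordinates; PC1 %.1f%%, PC1+PC2 %.1f%%\n",
    length(object@eigenvalues), nrow(object@eigenvectors),
    100 * vf[1], 100 * sum(vf[seq_len(min(2, length(vf)))])))
})

# ---- accessors ------------------------------------------------------------

#' Accessors for HandleDynamics containers
#'
#' Small accessor generics: `nFrames()` and `topology()` for trajectories,
#' `distanceValues()` for a [DistanceSeries-class], `stateLabels()` for a
#' [StateSeries-class], `pOpen()` for a [PopulationSummary-class] and
#' `deltaG()` for a [FreeEnergyGap-class].
#'
#' @param x the object.
#' @return the slot contents described above.
#' @name accessors
#' @aliases nFrames topology distanceValues stateLabels pOpen deltaG
#' @export nFrames topology distanceValues stateLabels pOpen deltaG
NULL

setGeneric("nFrames", function(x) standardGeneric("nFrames"))
setGeneric("topology", function(x) standardGeneric("topology"))
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
setGeneric("pOpen", function(x) standardGeneric("pOpen"))
setGeneric("deltaG", function(x) standardGeneric("deltaG"))

#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("topology", "Trajectory", function(x) x@topology)
#' @rdname accessors
setMethod("distanceValues", "DistanceSeries", function(x) x@values)
#' @rdname accessors
setMethod("stateLabels", "StateSeries", function(x) x@states)
#' @rdname accessors
setMethod("pOpen", "PopulationSummary", function(x) x@pOpen)
#' @rdname accessors
setMethod("deltaG", "FreeEnergyGap", function(x) x@deltaG)

#' Residue keys of a topology
#'
#' Residue keys are strings `"chain|resNo|insCode"` in file order; they are
#' how every HandleDynamics function addresses residues, so that inserted
#' residues (insertion code "b" of G80b) are distinct from their neighbours.
#'
#' @param x a [Topology-class] or [Trajectory-class].
#' @return character vector of unique residue keys in topology order.
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname residueKeys
setMethod("residueKeys", "Topology", function(x) {
  a <- x@atoms
  unique(paste(a$chain, a$resNo, a$insCode, sep = "|"))
})

#' @rdname residueKeys
setMethod("residueKeys", "Trajectory", function(x) residueKeys(x@topology))

#' Build a residue key string
#'
#' @param chain chain identifier (default "A").
#' @param resNo author residue number.
#' @param insCode insertion code, `""` when absent.
#' @return character key `"chain|resNo|insCode"`.
#' @examples
#' resKey(resNo = 85)            # "A|85|"
#' resKey("A", 80, "b")          # the inserted glycine G80b
#' @export
resKey <- function(chain = "A", resNo, insCode = "") {
  paste(chain, resNo, insCode, sep = "|")
}
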