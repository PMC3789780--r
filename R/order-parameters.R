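#' Extract per-frame bond unit vectors after removing global motion
#'
#' Each frame is least-squares superposed onto a reference frame (the
#' first frame by default) on a fit selection -- by default the backbone
#' heavy atoms (N, CA, C, O) of the whole topology -- before the bond
#' vector is taken and normalized. Restricting the fit selection to
#' secondary-structure residues avoids letting loop motion leak into the
#' overall-rotation removal.
#'
#' @param traj a [Trajectory-class].
#' @param residue residue key of the bond (see [resKey()]).
#' @param atoms length-2 atom-name pair, default `c("N", "H")` for the
#'   backbone amide.
#' @param fitSelection atom indices used for the superposition; `NULL` for
#'   backbone heavy atoms of all residues; `NA` to skip superposition
#'   (frames already aligned).
#' @param reference frame index to superpose onto (default 1).
#' @return matrix nFrames x 3 of unit vectors (class attribute
#'   `"BondVectorSeries"`, with attributes `residue` and `atoms`).
#' @export
extractBondVectors <- function(traj, residue, atoms = c("N", "H"),
                               fitSelection = NULL, reference = 1L) {
  i1 <- selectAtoms(traj, resKeys = residue, atomName = atoms[1])
  i2 <- suppressWarnings(
    selectAtoms(traj, resKeys = residue, atomName = atoms[2]))
  if (length(i1) != 1 || length(i2) != 1)
    stop("capability error: residue ", residue, " lacks atom pair ",
         atoms[1], "-", atoms[2],
         if (atoms[2] %in% c("H", "HN", "HE"))
           " (hydrogen-containing input required)" else "")
  nFr <- dim(traj@coords)[3]
  doFit <- !(length(fitSelection) == 1 && is.na(fitSelection))
  if (doFit && is.null(fitSelection))
    fitSelection <- selectAtoms(traj, atomName = c("N", "CA", "C", "O"))
  v <- matrix(0, nFr, 3)
  refXyz <- traj@coords[fitSelection, , reference, drop = FALSE][, , 1]
  for (f in seq_len(nFr)) {
    if (doFit) {
      fit <- superpose(traj@coords[fitSelection, , f, drop = FALSE][, , 1],
                       refXyz)
      x1 <- traj@coords[i1, , f] %*% t(fit$rotation)
      x2 <- traj@coords[i2, , f] %*% t(fit$rotation)
    } else {
      x1 <- traj@coords[i1, , f]; x2 <- traj@coords[i2, , f]
    }
    v[f, ] <- x2 - x1
  }
  v <- v / sqrt(rowSums(v^2))
  structure(v, class = c("BondVectorSeries", class(v)),
            residue = residue, atoms = atoms)
}

#' Generalized order parameter S2 of a bond-vector series
#'
#' The tensor-average expression over unit-vector components
#' \deqn{S^2 = \frac{3}{2}\left[\langle x^2\rangle^2 + \langle y^2\rangle^2 +
#'   \langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
#'   2\langle yz\rangle^2\right] - \frac{1}{2}}
#' computed over the (post-equilibration) frames. 1 for a rigid vector,
#' 0 in the isotropic limit. This is the infinite-time plateau of the
#' internal correlation function and needs no time-window fitting.
#'
#' @param v nFrames x 3 matrix of unit vectors (rows unit norm to 1e-6),
#'   e.g. from [extractBondVectors()] or [genConeVectors()].
#' @param equilFraction fraction of initial frames discarded (default 0,
#'   the series is treated as already production data).
#' @return S2, a single number; values outside \[0, 1\] by numerical
#'   error are clamped with a message.
#' @examples
#' orderParameter(matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)) # 1
#' @export
orderParameter <- function(v, equilFraction = 0) {
  v <- as.matrix(unclass(v))
  if (nrow(v) < 2) stop("need at least 2 frames")
  norms <- sqrt(rowSums(v^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("normalization error: vectors must be unit norm")
  nDiscard <- ceiling(equilFraction * nrow(v))
  if (nDiscard > 0) v <- v[-seq_len(nDiscard), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  s2 <- 1.5 * (mean(x * x)^2 + mean(y * y)^2 + mean(z * z)^2 +
               2 * mean(x * y)^2 + 2 * mean(x * z)^2 + 2 * mean(y * z)^2) -
        0.5
  if (s2 < 0 || s2 > 1) {
    message("S2 = ", format(s2), " clamped to [0, 1]")
    s2 <- min(1, max(0, s2))
  }
  s2
}

#' Per-residue S2 profile from a trajectory
#'
#' One order parameter per residue over a residue range for a fixed atom
#' pair (backbone N-H by default). Residues lacking the pair -- prolines
#' and termini for N-H, or any residue in a hydrogen-free crystal
#' structure -- are skipped with a message.
#'
#' @param traj a [Trajectory-class].
#' @param resNo integer vector of residue numbers (chain A assumed unless
#'   `keys` given).
#' @param keys optional character residue keys overriding `resNo`.
#' @param atoms atom-name pair, default `c("N", "H")`.
#' @param fitSelection,equilFraction passed to [extractBondVectors()] /
#'   [orderParameter()]; equilibration discard defaults to 0.1 as in
#'   [estimatePopulations()].
#' @return data.frame (class `"OrderParameterSet"`) with columns
#'   `residueKey`, `resNo`, `s2`.
#' @export
s2Profile <- function(traj, resNo = NULL, keys = NULL,
                      atoms = c("N", "H"), fitSelection = NULL,
                      equilFraction = 0.1) {
  if (is.null(keys)) {
    if (is.null(resNo)) stop("argument error: resNo or keys required")
    if (length(resNo) == 0) stop("argument error: empty residue range")
    all <- residueKeys(traj)
    keys <- all[as.integer(vapply(strsplit(all, "|", fixed = TRUE),
                                  `[`, "", 2)) %in% resNo]
  }
  if (length(keys) == 0) stop("argument error: empty residue range")
  rows <- lapply(keys, function(k) {
    v <- tryCatch(extractBondVectors(traj, k, atoms, fitSelection),
                  error = function(e) NULL)
    if (is.null(v)) {
      message("residue ", k, " skipped: missing ", atoms[1], "-", atoms[2])
      return(NULL)
    }
    data.frame(residueKey = k,
               resNo = as.integer(strsplit(k, "|", fixed = TRUE)[[1]][2]),
               s2 = orderParameter(v, equilFraction = equilFraction),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(residueKey = character(), resNo = integer(),
                      s2 = numeric())
  class(out) <- c("OrderParameterSet", "data.frame")
  out
}

#' Compare simulated and experimental order parameters
#'
#' Pairs residues present in both sets, reports the Pearson correlation
#' and the slope of the (unconstrained) least-squares regression of the
#' experimental on the simulated values; the experimental series rescaled
#' by that slope is returned for plotting.
#'
#' @param sim,exp data.frames with columns `resNo` and `s2` (an
#'   `OrderParameterSet` from [s2Profile()] works directly; experimental
#'   tables read from delimited text need just those two columns).
#' @return list with `pairs` (data.frame resNo, sim, exp, expRescaled),
#'   `pearsonR`, `slope`, `intercept`, `n`.
#' @export
compareS2ToExperiment <- function(sim, exp) {
  m <- merge(sim[, c("resNo", "s2")], exp[, c("resNo", "s2")],
             by = "resNo", suffixes = c(".sim", ".exp"))
  if (nrow(m) < 3) stop("need at least 3 common residues")
  if (stats::sd(m$s2.sim) == 0 || stats::sd(m$s2.exp) == 0)
    stop("undefined-correlation error: constant series")
  fit <- stats::lm(s2.exp ~ s2.sim, data = m)
  slope <- unname(stats::coef(fit)[2])
  list(pairs = data.frame(resNo = m$resNo, sim = m$s2.sim, exp = m$s2.exp,
                          expRescaled = m$s2.exp / slope),
       pearsonR = stats::cor(m$s2.sim, m$s2.exp), slope = slope,
       intercept = unname(stats::coef(fit)[1]), n = nrow(m))
}
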