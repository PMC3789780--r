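# Cartesian PCA of handle-loop C-alpha coordinates.

# Superpose each frame (rows of X, 3L coords) onto the iteratively refined
# mean loop conformation. Returns the superposed frames, the superposition
# target actually used for the final pass (so projections of the fitting
# set reproduce it exactly), and the coordinate mean of the fitted frames.
.iterativeMeanFit <- function(X, L, tol = 1e-9, maxIter = 100L) {
  toMat <- function(row) matrix(row, ncol = 3, byrow = FALSE)
  # coordinates are stored (x1..xL, y1..yL, z1..zL) per row
  target <- toMat(X[1, ])
  for (iter in seq_len(maxIter)) {
    fitted <- t(apply(X, 1, function(row) {
      as.numeric(superpose(toMat(row), target)$transformed)
    }))
    center <- colMeans(fitted)
    shift <- sqrt(mean((toMat(center) - target)^2))
    if (shift < tol) break
    target <- toMat(center)
  }
  list(X = fitted, target = target, center = center)
}

# Extract the pooled L x 3 C-alpha coordinates of a trajectory as an
# nFrames x 3L matrix in (x1..xL, y1..yL, z1..zL) layout.
.loopCoordMatrix <- function(traj, keys) {
  sel <- selectAtoms(traj, resKeys = keys, atomName = "CA")
  if (length(sel) != length(keys))
    stop("mapping error: trajectory '", traj@label, "' yields ",
         length(sel), " loop CA atoms, expected ", length(keys))
  nFr <- dim(traj@coords)[3]
  X <- matrix(0, nFr, 3 * length(sel))
  for (f in seq_len(nFr))
    X[f, ] <- as.numeric(traj@coords[sel, , f])
  X
}

#' Cartesian principal component analysis of the handle loop
#'
#' Pools the loop C-alpha coordinates of one or several trajectories
#' (residues 89-100 in ecRNH numbering by default), superposes every frame
#' onto the iteratively refined pooled mean of the loop itself, and
#' diagonalizes the covariance of the 3L Cartesian coordinates. Fitting on
#' the loop (not the protein core) makes the principal components pure
#' internal loop-shape modes. Eigenvector signs are fixed
#' deterministically (largest-magnitude entry positive).
#'
#' @param trajs a [Trajectory-class] or list of them.
#' @param keys residue keys of the loop selection, common to all
#'   trajectories; or use `resNo` on chain A.
#' @param resNo residue numbers of the loop (default 89:100). For
#'   cross-homolog decompositions, map each trajectory's keys through
#'   [mapEquivalentResidues()] first and pass per-trajectory key lists.
#' @param maps optional list of `ResidueMap`s (one per trajectory)
#'   translating the reference keys into each trajectory's numbering.
#' @param nComponents number of components to keep (default all).
#' @param superpose superpose frames onto the iterated loop mean before
#'   the decomposition (default TRUE). Set FALSE for frames that are
#'   already expressed in a common reference frame, in which case the
#'   decomposition operates on the raw Cartesian coordinates; a purely
#'   linear (rank-1) motion then yields exactly one nonzero eigenvalue.
#' @return a [ModeDecomposition-class].
#' @examples
#' g <- genTwoStateTrajectory(twoStateSpec(300, pOpen = 0.5, seed = 3))
#' dec <- loopPCA(g$trajectory, resNo = 89:96)
#' dec@varianceFractions[1]          # dominant open/closed mode
#' @export
loopPCA <- function(trajs, keys = NULL, resNo = 89:100, maps = NULL,
                    nComponents = NULL, superpose = TRUE) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  if (is.null(keys)) keys <- vapply(resNo, function(r) resKey(resNo = r), "")
  Xs <- lapply(seq_along(trajs), function(i) {
    k <- if (is.null(maps)) keys else {
      mk <- applyResidueMap(maps[[i]], keys)
      if (anyNA(mk))
        stop("mapping error: trajectory '", trajs[[i]]@label,
             "' has unmapped loop residues: ",
             paste(keys[is.na(mk)], collapse = ", "))
      mk
    }
    .loopCoordMatrix(trajs[[i]], k)
  })
  X <- do.call(rbind, Xs)
  L <- length(keys)
  fit <- if (superpose) .iterativeMeanFit(X, L) else
    list(X = X, target = matrix(colMeans(X), ncol = 3),
         center = colMeans(X))
  Xc <- sweep(fit$X, 2, fit$center)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    i0 <- which.max(abs(vec[, j]))
    if (vec[i0, j] < 0) vec[, j] <- -vec[, j]
  }
  k <- if (is.null(nComponents)) ncol(vec) else min(nComponents, ncol(vec))
  new("ModeDecomposition", mean = fit$target, center = fit$center,
      eigenvalues = ev[seq_len(k)],
      eigenvectors = vec[, seq_len(k), drop = FALSE],
      varianceFractions = ev[seq_len(k)] / sum(ev),
      fittedOn = vapply(trajs, function(t) t@label, ""),
      superposed = superpose)
}

#' Project frames or a static structure into a fitted mode space
#'
#' Superposes the input loop coordinates onto the decomposition mean,
#' subtracts the mean and takes inner products with the eigenvectors.
#' Projections of the fitting set have zero mean per component and
#' per-component variance equal to the eigenvalue.
#'
#' @param dec a [ModeDecomposition-class] from [loopPCA()].
#' @param x a [Trajectory-class], or an nAtoms x 3 coordinate matrix of a
#'   single structure whose selected loop matches the fitted selection.
#' @param keys,resNo loop selection as in [loopPCA()] (only needed when
#'   `x` is a Trajectory; a bare matrix must already be the L x 3 loop).
#' @param map optional `ResidueMap` translating reference keys into `x`'s
#'   numbering.
#' @return matrix nFrames x nComponents of projections (Angstrom).
#' @export
projectOntoModes <- function(dec, x, keys = NULL, resNo = 89:100,
                             map = NULL) {
  L <- nrow(dec@mean)
  if (is(x, "Trajectory")) {
    if (is.null(keys))
      keys <- vapply(resNo, function(r) resKey(resNo = r), "")
    if (!is.null(map)) {
      mk <- applyResidueMap(map, keys)
      if (anyNA(mk))
        stop("mapping error: unmapped residues: ",
             paste(keys[is.na(mk)], collapse = ", "))
      keys <- mk
    }
    X <- .loopCoordMatrix(x, keys)
  } else {
    x <- as.matrix(x)
    if (!all(dim(x) == c(L, 3)))
      stop("structure coordinates must be L x 3 matching the fit")
    X <- matrix(as.numeric(x), 1)
  }
  proj <- t(apply(X, 1, function(row) {
    fitted <- if (dec@superposed)
      as.numeric(superpose(matrix(row, ncol = 3), dec@mean)$transformed)
    else row
    (fitted - dec@center) %*% dec@eigenvectors
  }))
  if (ncol(dec@eigenvectors) == 1) proj <- matrix(proj, ncol = 1)
  colnames(proj) <- paste0("PC", seq_len(ncol(proj)))
  proj
}
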