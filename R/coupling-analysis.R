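# chi1 rotamers, state-rotamer association, shift-coordinate correlation,
# and hydrogen-bond occupancy.

# gamma heavy atom defining chi1 (N-CA-CB-G) per residue type
.chi1GammaAtom <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1")

# signed dihedral (degrees, IUPAC) for four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' chi1 sidechain dihedral series from a trajectory
#'
#' The signed N-CA-CB-gamma dihedral per IUPAC convention, in degrees in
#' (-180, 180\]. The gamma heavy atom per residue type follows the
#' standard naming (CG for most residues, CG1 for Val/Ile, OG for Ser,
#' OG1 for Thr, SG for Cys).
#'
#' @param traj a [Trajectory-class].
#' @param residue residue key (see [resKey()]).
#' @return numeric vector, one angle per frame, with attribute `residue`.
#' @export
chi1Series <- function(traj, residue) {
  a <- traj@topology@atoms
  keys <- paste(a$chain, a$resNo, a$insCode, sep = "|")
  rIdx <- which(keys == residue)
  if (length(rIdx) == 0) stop("capability error: no residue ", residue)
  rn <- a$resName[rIdx[1]]
  gamma <- .chi1GammaAtom[rn]
  if (is.na(gamma))
    stop("capability error: residue type ", rn, " has no chi1 dihedral")
  need <- c("N", "CA", "CB", unname(gamma))
  idx <- vapply(need, function(at) {
    i <- rIdx[a$atomName[rIdx] == at]
    if (length(i) != 1) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx))
    stop("capability error: residue ", residue, " missing atom(s): ",
         paste(need[is.na(idx)], collapse = ", "))
  nFr <- dim(traj@coords)[3]
  ang <- vapply(seq_len(nFr), function(f) {
    .dihedral(traj@coords[idx[1], , f], traj@coords[idx[2], , f],
              traj@coords[idx[3], , f], traj@coords[idx[4], , f])
  }, numeric(1))
  structure(.wrapAngle(ang), residue = residue)
}

#' Classify chi1 angles into rotamer classes
#'
#' Nearest canonical center by circular distance: -60 degrees gauche-,
#' +60 gauche+, 180 trans. Angles exactly on a class boundary (0, +120,
#' -120) are assigned deterministically to the side containing the angle
#' after adding 1e-9 degrees.
#'
#' @param angles numeric chi1 angles in degrees (any wrap).
#' @return character vector in `c("gauche-", "gauche+", "trans")`.
#' @examples
#' classifyRotamers(c(-60, 60, 179, -179))
#' @export
classifyRotamers <- function(angles) {
  a <- .wrapAngle(as.numeric(angles) + 1e-9)
  centers <- .rotamerCenters
  dmat <- vapply(centers, function(cc) {
    d <- abs(.wrapAngle(a - cc)); d
  }, numeric(length(a)))
  if (length(a) == 1) dmat <- matrix(dmat, nrow = 1)
  names(centers)[apply(dmat, 1, which.min)]
}

#' Association between handle state and rotamer class
#'
#' Builds the state x rotamer contingency table and reports the chi-square
#' statistic (no continuity correction), degrees of freedom, p-value and
#' Cramer's V. Cells with expected counts below 5 are flagged.
#'
#' @param rotamers character rotamer classes per frame (from
#'   [classifyRotamers()]).
#' @param states a [StateSeries-class] or character "open"/"closed" per
#'   frame.
#' @return list with `table`, `chisq`, `df`, `p`, `cramersV`,
#'   `lowExpected` (logical).
#' @export
stateRotamerAssociation <- function(rotamers, states) {
  if (is(states, "StateSeries")) states <- states@states
  if (length(rotamers) != length(states))
    stop("alignment error: series lengths differ")
  tab <- table(state = states, rotamer = rotamers)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2))
    stop("association undefined: a series is constant")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(unname(ct$statistic) / (n * (min(dim(tab)) - 1)))
  list(table = tab, chisq = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, cramersV = v,
       lowExpected = any(ct$expected < 5))
}

#' Correlation of per-frame chemical shift with the reaction coordinate
#'
#' Overall Pearson correlation between a per-frame shift series and the
#' handle distance, with optional per-rotamer-class conditioning (class
#' mean shift and distance, and within-class correlation) -- the summary
#' behind shift-distance-rotamer coupling scatter plots.
#'
#' @param shifts numeric per-frame shifts (ppm).
#' @param d a [DistanceSeries-class] or numeric per-frame distances.
#' @param rotamers optional character rotamer classes per frame.
#' @return list with `pearsonR`, `n`, and when `rotamers` is given
#'   `byClass` (data.frame class, n, meanShift, meanDistance, r).
#' @export
shiftCoordinateCorrelation <- function(shifts, d, rotamers = NULL) {
  v <- if (is(d, "DistanceSeries")) d@values else as.numeric(d)
  if (length(shifts) != length(v))
    stop("alignment error: series lengths differ")
  if (stats::sd(shifts) == 0)
    stop("undefined-correlation error: constant shift series")
  out <- list(pearsonR = stats::cor(shifts, v), n = length(v))
  if (!is.null(rotamers)) {
    if (length(rotamers) != length(v))
      stop("alignment error: rotamer series length differs")
    out$byClass <- do.call(rbind, lapply(
      sort(unique(rotamers)), function(cl) {
        i <- rotamers == cl
        r <- if (sum(i) >= 3 && stats::sd(shifts[i]) > 0 &&
                 stats::sd(v[i]) > 0) stats::cor(shifts[i], v[i]) else NA
        data.frame(class = cl, n = sum(i), meanShift = mean(shifts[i]),
                   meanDistance = mean(v[i]), r = r)
      }))
  }
  out
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A donor/acceptor pair is bonded in a frame when the donor-acceptor
#' heavy-atom distance is at most `distanceCutoff` and the D-H...A angle
#' (at the hydrogen) is at least `angleCutoff`. Supports multiple pairs --
#' e.g. the Asn88 sidechain-to-backbone pair set (Nd2-H...O of residue 91
#' and Od1...H-N of residue 91) whose simultaneous presence buttresses the
#' single-state handle conformation.
#'
#' @param traj a [Trajectory-class]; the topology must contain the donor
#'   hydrogens.
#' @param pairs data.frame with columns `donorKey`, `donorAtom`,
#'   `hydrogenAtom`, `acceptorKey`, `acceptorAtom` (keys from [resKey()]).
#' @param distanceCutoff donor-acceptor heavy-atom cutoff, Angstrom
#'   (default 3.5).
#' @param angleCutoff minimum D-H...A angle, degrees (default 120).
#' @param equilFraction fraction of initial frames excluded from the
#'   occupancy denominator (default 0).
#' @return list with `perPair` (data.frame pair, occupancy), `flags`
#'   (frames x pairs logical matrix over analyzed frames), and
#'   `jointOccupancy` (fraction of frames with all pairs bonded).
#' @export
hbondOccupancy <- function(traj, pairs, distanceCutoff = 3.5,
                           angleCutoff = 120, equilFraction = 0) {
  if (distanceCutoff <= 0 || angleCutoff <= 0)
    stop("cutoffs must be positive")
  a <- traj@topology@atoms
  keys <- paste(a$chain, a$resNo, a$insCode, sep = "|")
  one <- function(key, at) {
    i <- which(keys == key & a$atomName == at)
    if (length(i) != 1)
      stop("capability error: atom ", at, " of residue ", key,
           if (grepl("^H", at)) " (hydrogen-containing topology required)"
           else "", " not found")
    i
  }
  nFr <- dim(traj@coords)[3]
  first <- ceiling(equilFraction * nFr) + 1
  frames <- first:nFr
  flags <- matrix(FALSE, length(frames), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    iD <- one(pairs$donorKey[p], pairs$donorAtom[p])
    iH <- one(pairs$donorKey[p], pairs$hydrogenAtom[p])
    iA <- one(pairs$acceptorKey[p], pairs$acceptorAtom[p])
    for (j in seq_along(frames)) {
      f <- frames[j]
      D <- traj@coords[iD, , f]; H <- traj@coords[iH, , f]
      A <- traj@coords[iA, , f]
      if (sqrt(sum((D - A)^2)) > distanceCutoff) next
      u <- D - H; w <- A - H
      ang <- acos(pmin(1, pmax(-1, sum(u * w) /
                                 sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
      flags[j, p] <- ang >= angleCutoff
    }
  }
  list(perPair = data.frame(pair = seq_len(nrow(pairs)),
                            occupancy = colMeans(flags)),
       flags = flags, jointOccupancy = mean(apply(flags, 1, all)))
}
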