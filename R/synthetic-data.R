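# Synthetic-data generators. Each generator draws from its own seeded RNG
# stream and restores the caller's RNG state, so calls are bit-reproducible
# and do not disturb the session.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.wrapAngle <- function(x) {
  # wrap degrees into (-180, 180]
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' Specification for a synthetic two-state handle trajectory
#'
#' The generator emulates the statistical structure of the handle-region
#' reaction coordinate: Markov switching between an open and a closed
#' basin, each Gaussian in the anchor-tip C-alpha distance. Open and
#' closed basin means straddle the 10 Angstrom classification threshold.
#'
#' Either `pOpen` (states drawn independently with the stationary open
#' fraction) or `rates` (per-frame transition probabilities
#' `c(kOpenToClosed, kClosedToOpen)`, giving an autocorrelated chain with
#' stationary open fraction `kCO/(kOC+kCO)`) must be supplied, not both.
#'
#' @param nFrames number of frames.
#' @param pOpen stationary open fraction in \[0, 1\], or NULL.
#' @param rates length-2 per-frame transition probabilities, or NULL.
#' @param dOpenMean,dClosedMean basin mean distances, Angstrom. Defaults
#'   13.0 / 7.5 place the basins well on either side of the 10 Angstrom
#'   threshold.
#' @param basinSd within-basin standard deviation, Angstrom.
#' @param loopLength number of toy loop residues (>= 9 so the tip residue
#'   93 exists; default 12).
#' @param noiseSd isotropic Gaussian jitter (Angstrom) added to loop atoms
#'   other than anchor and tip, which carry the controlled distance.
#' @param seed integer RNG seed.
#' @return a validated list of class `"TwoStateSpec"`.
#' @export
twoStateSpec <- function(nFrames, pOpen = NULL, rates = NULL,
                         dOpenMean = 13.0, dClosedMean = 7.5, basinSd = 0.8,
                         loopLength = 12, noiseSd = 0.05, seed = 1) {
  if (!is.null(pOpen) && !is.null(rates))
    stop("ambiguity error: give pOpen or rates, not both")
  if (is.null(pOpen) && is.null(rates))
    stop("one of pOpen or rates is required")
  if (!is.null(pOpen) && (pOpen < 0 || pOpen > 1))
    stop("pOpen must be in [0, 1]")
  if (!is.null(rates) && (length(rates) != 2 || any(rates <= 0) ||
                          any(rates > 1)))
    stop("rates must be two per-frame transition probabilities in (0, 1]")
  if (!(dOpenMean > 10 && 10 > dClosedMean))
    stop("basin means must straddle the 10 Angstrom threshold: ",
         "dOpenMean > 10 > dClosedMean")
  if (basinSd <= 0) stop("basinSd must be positive")
  if (loopLength < 9) stop("loopLength must be >= 9 (tip residue is 93)")
  structure(list(nFrames = as.integer(nFrames), pOpen = pOpen,
                 rates = rates, dOpenMean = dOpenMean,
                 dClosedMean = dClosedMean, basinSd = basinSd,
                 loopLength = as.integer(loopLength), noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "TwoStateSpec")
}

# Fixed open/closed template conformations for the toy handle loop.
# Anchor (TRP 85) sits at the origin and the tip (ALA 93) on the +x axis at
# the basin mean distance, so the anchor-tip distance is exactly affine in
# the interpolation coordinate and PCA on the loop has a known rank-1
# dominant mode.
.loopTemplates <- function(spec) {
  n <- spec$loopLength
  tipIdx <- 9L                      # residue 93, 1-based from residue 85
  g <- (seq_len(n) - 1) / (tipIdx - 1)   # g=0 at anchor, g=1 at tip
  mk <- function(d, bulge) cbind(x = d * g, y = bulge * sin(pi * g), z = 0)
  list(closed = mk(spec$dClosedMean, 3.0), open = mk(spec$dOpenMean, 1.2),
       tipIdx = tipIdx)
}

#' Generate a synthetic two-state handle trajectory with known ground truth
#'
#' Frames switch between open and closed states; each frame is an
#' interpolation between fixed open/closed loop templates chosen so that
#' the anchor-tip C-alpha distance is Normal(basin mean, basinSd) for the
#' frame's state. The topology names the anchor residue TRP 85 and the tip
#' ALA 93, so downstream selections used on real trajectories work
#' verbatim.
#'
#' @param spec a [twoStateSpec()].
#' @param temperature temperature label, K.
#' @param label trajectory label.
#' @return list with `trajectory` ([Trajectory-class]), `states` (true
#'   per-frame labels), and `pOpen` (the true stationary open fraction).
#' @examples
#' g <- genTwoStateTrajectory(twoStateSpec(500, pOpen = 0.4, seed = 7))
#' mean(g$states == "open")
#' @export
genTwoStateTrajectory <- function(spec, temperature = 300,
                                  label = "synthetic") {
  stopifnot(inherits(spec, "TwoStateSpec"))
  .withSeed(spec$seed, {
    n <- spec$nFrames
    if (!is.null(spec$pOpen)) {
      states <- ifelse(stats::runif(n) < spec$pOpen, "open", "closed")
      pTrue <- spec$pOpen
    } else {
      kOC <- spec$rates[1]; kCO <- spec$rates[2]
      pTrue <- kCO / (kCO + kOC)
      states <- character(n)
      states[1] <- if (stats::runif(1) < pTrue) "open" else "closed"
      u <- stats::runif(n)
      for (f in seq_len(n - 1)) {
        states[f + 1] <- if (states[f] == "open") {
          if (u[f] < kOC) "closed" else "open"
        } else {
          if (u[f] < kCO) "open" else "closed"
        }
      }
    }
    tpl <- .loopTemplates(spec)
    mu <- ifelse(states == "open", spec$dOpenMean, spec$dClosedMean)
    d <- stats::rnorm(n, mu, spec$basinSd)
    lambda <- (d - spec$dClosedMean) / (spec$dOpenMean - spec$dClosedMean)
    nRes <- spec$loopLength
    coords <- array(0, c(nRes, 3, n))
    for (k in 1:3) {
      coords[, k, ] <- outer(tpl$closed[, k], 1 - lambda) +
        outer(tpl$open[, k], lambda)
    }
    if (spec$noiseSd > 0) {
      jitterIdx <- setdiff(seq_len(nRes), c(1L, tpl$tipIdx))
      coords[jitterIdx, , ] <- coords[jitterIdx, , ] +
        stats::rnorm(length(jitterIdx) * 3 * n, 0, spec$noiseSd)
    }
    resNo <- 84L + seq_len(nRes)
    resName <- rep("GLY", nRes)
    resName[1] <- "TRP"; resName[tpl$tipIdx] <- "ALA"
    topo <- new("Topology", atoms = data.frame(
      atomName = "CA", resName = resName, chain = "A", resNo = resNo,
      insCode = "", element = "C", stringsAsFactors = FALSE))
    traj <- new("Trajectory", topology = topo, coords = coords,
                frameInterval = 1, temperature = temperature, label = label)
    list(trajectory = traj, states = states, pOpen = pTrue)
  })
}

#' Specification for uniform-in-cone bond vectors
#'
#' @param semiangle cone semiangle, degrees in (0, 90\].
#' @param nFrames number of vectors.
#' @param seed integer RNG seed.
#' @return list of class `"ConeSpec"`.
#' @export
coneSpec <- function(semiangle, nFrames, seed = 1) {
  if (semiangle <= 0 || semiangle > 90)
    stop("semiangle must be in (0, 90] degrees")
  structure(list(semiangle = semiangle, nFrames = as.integer(nFrames),
                 seed = as.integer(seed)), class = "ConeSpec")
}

#' Generate unit vectors uniform within a cone, with the analytic S2
#'
#' Vectors are i.i.d. uniform (by area) on the spherical cap of the given
#' semiangle about +z. For this model the generalized order parameter has
#' the closed form S2 = \[cos(t) (1 + cos(t)) / 2\]^2 with t the semiangle,
#' which is returned as ground truth for validating [orderParameter()].
#'
#' @param spec a [coneSpec()].
#' @return list with `vectors` (nFrames x 3 unit vectors) and `s2Analytic`.
#' @examples
#' g <- genConeVectors(coneSpec(60, 1000, seed = 2))
#' g$s2Analytic                       # (cos60 * 1.5 / 2)^2 = 0.140625
#' @export
genConeVectors <- function(spec) {
  stopifnot(inherits(spec, "ConeSpec"))
  .withSeed(spec$seed, {
    c0 <- cos(spec$semiangle * pi / 180)
    u <- stats::runif(spec$nFrames, c0, 1)      # cos(theta), area-uniform
    phi <- stats::runif(spec$nFrames, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - u^2))
    v <- cbind(s * cos(phi), s * sin(phi), u)
    list(vectors = v, s2Analytic = (c0 * (1 + c0) / 2)^2)
  })
}

#' Specification for a synthetic chi1 rotamer series
#'
#' @param populations length-3 probabilities over classes
#'   (gauche-, gauche+, trans); must sum to 1.
#' @param jitterSd wrapped-Gaussian angular jitter sd, degrees.
#' @param coupling optional list with elements `open` and `closed`, each a
#'   length-3 class-probability vector used instead of `populations` for
#'   frames in that state.
#' @param nFrames number of frames.
#' @param seed integer RNG seed.
#' @return list of class `"RotamerSpec"`.
#' @export
rotamerSpec <- function(populations = c(1 / 3, 1 / 3, 1 / 3), jitterSd = 10,
                        coupling = NULL, nFrames, seed = 1) {
  if (length(populations) != 3 || abs(sum(populations) - 1) > 1e-9 ||
      any(populations < 0))
    stop("populations must be 3 non-negative numbers summing to 1")
  if (!is.null(coupling)) {
    if (!all(c("open", "closed") %in% names(coupling)))
      stop("coupling must have elements 'open' and 'closed'")
    for (p in coupling)
      if (length(p) != 3 || abs(sum(p) - 1) > 1e-9 || any(p < 0))
        stop("each coupling distribution must be 3 probabilities summing to 1")
  }
  structure(list(populations = populations, jitterSd = jitterSd,
                 coupling = coupling, nFrames = as.integer(nFrames),
                 seed = as.integer(seed)), class = "RotamerSpec")
}

# canonical chi1 class centers, degrees
.rotamerCenters <- c("gauche-" = -60, "gauche+" = 60, "trans" = 180)

#' Generate a synthetic chi1 angle series with known rotamer classes
#'
#' Each frame's class is drawn from the class populations (optionally
#' biased by the frame's open/closed state when a coupling is given) and
#' the angle is the class center (-60/+60/180 degrees) plus wrapped
#' Gaussian jitter.
#'
#' @param spec a [rotamerSpec()].
#' @param states optional character vector of per-frame "open"/"closed"
#'   labels; required when `spec$coupling` is set.
#' @return list with `angles` (degrees in (-180, 180\]) and `classes`
#'   (true class labels).
#' @export
genRotamerSeries <- function(spec, states = NULL) {
  stopifnot(inherits(spec, "RotamerSpec"))
  if (!is.null(spec$coupling) && is.null(states))
    stop("argument error: coupling requires per-frame states")
  if (!is.null(states) && length(states) != spec$nFrames)
    stop("states length must equal nFrames")
  .withSeed(spec$seed, {
    n <- spec$nFrames
    classNames <- names(.rotamerCenters)
    if (is.null(spec$coupling)) {
      cls <- sample(classNames, n, replace = TRUE, prob = spec$populations)
    } else {
      cls <- character(n)
      for (s in c("open", "closed")) {
        idx <- which(states == s)
        if (length(idx))
          cls[idx] <- sample(classNames, length(idx), replace = TRUE,
                             prob = spec$coupling[[s]])
      }
    }
    ang <- .wrapAngle(.rotamerCenters[cls] + stats::rnorm(n, 0, spec$jitterSd))
    list(angles = unname(ang), classes = cls)
  })
}

#' Specification for a synthetic annotated sequence set
#'
#' Emulates a bacterial RNase H alignment annotated by source-organism
#' growth-temperature class: every sequence is the background with the
#' diagnostic positions redrawn from class-specific residue frequency
#' tables, and the G80b insertion realized as presence/absence of an
#' inserted G in the column between reference positions 80 and 81.
#'
#' @param counts named counts per class, e.g.
#'   `c(psychrophile = 50, mesophile = 100, thermophile = 50)`.
#' @param positionTables named list; names are reference positions ("88",
#'   "95", "101"), each a per-class list of residue-frequency vectors
#'   (named by one-letter residue, summing to 1).
#' @param insertionProb named per-class probability that the G80b
#'   insertion is present.
#' @param background reference one-letter sequence (the ecRNH-numbering
#'   reference); must reach the largest requested position.
#' @param seed integer RNG seed.
#' @return list of class `"SequenceSetSpec"`.
#' @export
sequenceSetSpec <- function(counts, positionTables, insertionProb,
                            background, seed = 1) {
  classes <- c("psychrophile", "mesophile", "thermophile")
  if (!all(names(counts) %in% classes))
    stop("counts must be named by growth class")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (pos in names(positionTables)) {
    for (cl in names(positionTables[[pos]])) {
      tab <- positionTables[[pos]][[cl]]
      if (abs(sum(tab) - 1) > 1e-9 || any(tab < 0))
        stop("frequency table for position ", pos, " class ", cl,
             " must sum to 1")
      if (!all(names(tab) %in% aa))
        stop("spec error: non-standard residue letter in table for position ",
             pos)
    }
  }
  maxPos <- max(as.integer(names(positionTables)))
  if (nchar(background) < maxPos)
    stop("background sequence shorter than requested position ", maxPos)
  structure(list(counts = counts, positionTables = positionTables,
                 insertionProb = insertionProb, background = background,
                 seed = as.integer(seed)), class = "SequenceSetSpec")
}

#' Generate an annotated alignment with class-dependent residue frequencies
#'
#' @param spec a [sequenceSetSpec()].
#' @param fastaPath,annotationPath optional output paths; when given, the
#'   aligned FASTA and the annotation TSV (columns `id`, `class`) are
#'   written there.
#' @return list with `alignment` (named character vector of aligned
#'   sequences, including the ungapped-by-construction reference row
#'   `"reference"`), `annotation` (data.frame `id`, `class`), and
#'   `truth` (the per-sequence residues drawn at each position and the
#'   insertion indicator).
#' @export
genSequenceSet <- function(spec, fastaPath = NULL, annotationPath = NULL) {
  stopifnot(inherits(spec, "SequenceSetSpec"))
  .withSeed(spec$seed, {
    bg <- strsplit(spec$background, "")[[1]]
    L <- length(bg)
    insCol <- 81L                      # column between ref positions 80, 81
    refRow <- append(bg, "-", after = 80)
    colOf <- function(pos) if (pos <= 80) pos else pos + 1L
    ids <- character(0); classes <- character(0)
    rows <- list()
    truth <- list()
    for (cl in names(spec$counts)) {
      nc <- spec$counts[[cl]]
      if (nc == 0) next
      for (i in seq_len(nc)) {
        id <- sprintf("%s_%03d", cl, i)
        row <- refRow
        rec <- list()
        ins <- stats::runif(1) < spec$insertionProb[[cl]]
        row[insCol] <- if (ins) "G" else "-"
        rec$insertion <- ins
        for (pos in names(spec$positionTables)) {
          tab <- spec$positionTables[[pos]][[cl]]
          if (is.null(tab)) next
          letter <- sample(names(tab), 1, prob = tab)
          row[colOf(as.integer(pos))] <- letter
          rec[[pos]] <- letter
        }
        ids <- c(ids, id); classes <- c(classes, cl)
        rows[[id]] <- paste(row, collapse = "")
        truth[[id]] <- rec
      }
    }
    alignment <- c(reference = paste(refRow, collapse = ""),
                   unlist(rows))
    annotation <- data.frame(id = ids, class = classes,
                             stringsAsFactors = FALSE)
    if (!is.null(fastaPath)) {
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(alignment), fastaPath)
    }
    if (!is.null(annotationPath)) {
      utils::write.table(annotation, annotationPath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(alignment = alignment, annotation = annotation, truth = truth)
  })
}

#' Specification for synthetic per-frame chemical-shift tables
#'
#' @param means data.frame with columns `resNo`, `resName`, `nucleus`,
#'   `openMean`, `closedMean` (ppm).
#' @param noiseSd Gaussian per-frame noise sd, ppm (>= 0).
#' @param seed integer RNG seed.
#' @return list of class `"ShiftEmulationSpec"`.
#' @export
shiftEmulationSpec <- function(means, noiseSd = 0.1, seed = 1) {
  need <- c("resNo", "resName", "nucleus", "openMean", "closedMean")
  if (!all(need %in% names(means)))
    stop("means must have columns: ", paste(need, collapse = ", "))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(means = means, noiseSd = noiseSd, seed = as.integer(seed)),
            class = "ShiftEmulationSpec")
}

#' Generate a per-frame chemical-shift table with state-dependent means
#'
#' Emulates the output of an external per-frame shift predictor run on a
#' two-state trajectory: for every frame and every (residue, nucleus) in
#' the spec, ppm = state mean + Gaussian noise.
#'
#' @param spec a [shiftEmulationSpec()].
#' @param states character vector of per-frame "open"/"closed" labels.
#' @return a FrameShiftTable: data.frame with columns `frame`, `chain`,
#'   `resNo`, `insCode`, `resName`, `nucleus`, `ppm`.
#' @export
genFrameShiftTable <- function(spec, states) {
  stopifnot(inherits(spec, "ShiftEmulationSpec"))
  if (!all(states %in% c("open", "closed")))
    stop("states must be 'open'/'closed'")
  .withSeed(spec$seed, {
    n <- length(states)
    m <- spec$means
    out <- do.call(rbind, lapply(seq_len(nrow(m)), function(r) {
      mu <- ifelse(states == "open", m$openMean[r], m$closedMean[r])
      data.frame(frame = seq_len(n), chain = "A", resNo = m$resNo[r],
                 insCode = "", resName = m$resName[r],
                 nucleus = m$nucleus[r],
                 ppm = mu + stats::rnorm(n, 0, spec$noiseSd),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
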