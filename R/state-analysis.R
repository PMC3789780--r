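#' Handle-region reaction coordinate: anchor-tip C-alpha distance
#'
#' The per-frame Cartesian distance between the C-alpha atoms of the
#' anchor residue on helix C (W85 in ecRNH numbering) and the tip of the
#' handle loop (A93). An internal coordinate: no superposition is applied,
#' so it is invariant to rigid motion of each frame.
#'
#' @param traj a [Trajectory-class].
#' @param anchor,tip residue keys (see [resKey()]); defaults address W85
#'   and A93 on chain A.
#' @return a [DistanceSeries-class].
#' @examples
#' g <- genTwoStateTrajectory(twoStateSpec(100, pOpen = 0.3, seed = 1))
#' d <- handleDistance(g$trajectory)
#' head(distanceValues(d))
#' @export
handleDistance <- function(traj, anchor = resKey(resNo = 85),
                           tip = resKey(resNo = 93)) {
  ia <- selectAtoms(traj, resKeys = anchor, atomName = "CA")
  it <- selectAtoms(traj, resKeys = tip, atomName = "CA")
  if (length(ia) != 1)
    stop("capability error: residue ", anchor, " has no unique CA atom")
  if (length(it) != 1)
    stop("capability error: residue ", tip, " has no unique CA atom")
  dv <- sqrt(colSums((traj@coords[ia, , ] - traj@coords[it, , ])^2))
  new("DistanceSeries", values = as.numeric(dv), anchor = anchor, tip = tip,
      label = traj@label, temperature = traj@temperature)
}

#' Classify frames as open or closed by the 10 Angstrom threshold
#'
#' A frame is open iff its reaction-coordinate value strictly exceeds the
#' threshold; a value exactly equal to the threshold is closed. The
#' default threshold of 10 Angstrom is the standard setting for the
#' handle-region coordinate.
#'
#' @param d a [DistanceSeries-class] (or a bare numeric vector, Angstrom).
#' @param threshold Angstrom, > 0.
#' @return a [StateSeries-class].
#' @examples
#' classifyStates(c(7, 9, 11, 13, 10))   # closed closed open open closed
#' @export
classifyStates <- function(d, threshold = 10.0) {
  if (threshold <= 0) stop("threshold must be positive")
  v <- if (is(d, "DistanceSeries")) d@values else as.numeric(d)
  new("StateSeries", states = ifelse(v > threshold, "open", "closed"),
      threshold = threshold)
}

# Wilson score interval for a binomial proportion
.wilson <- function(k, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Estimate open-state population with a Wilson confidence interval
#'
#' The first `ceiling(equilFraction * n)` frames are discarded as
#' equilibration; the open fraction over the remaining frames is reported
#' with a Wilson score interval. Because MD frames are autocorrelated, a
#' moving-block bootstrap interval is offered as an alternative
#' (`method = "block"`); for independently drawn synthetic frames the two
#' agree.
#'
#' @param s a [StateSeries-class].
#' @param equilFraction fraction of initial frames to discard (default 0.1).
#' @param ciLevel confidence level (default 0.95).
#' @param method "wilson" (default) or "block" (moving-block bootstrap).
#' @param blockLength block length in frames for `method = "block"`.
#' @param nBoot bootstrap replicates for `method = "block"`.
#' @return a [PopulationSummary-class].
#' @export
estimatePopulations <- function(s, equilFraction = 0.1, ciLevel = 0.95,
                                method = c("wilson", "block"),
                                blockLength = 100, nBoot = 500) {
  method <- match.arg(method)
  st <- s@states
  nAll <- length(st)
  nDiscard <- ceiling(equilFraction * nAll)
  if (nDiscard >= nAll) stop("empty-data error: no frames survive discard")
  st <- st[(nDiscard + 1):nAll]
  n <- length(st)
  k <- sum(st == "open")
  if (method == "wilson") {
    ci <- .wilson(k, n, ciLevel)
  } else {
    x <- as.numeric(st == "open")
    bl <- min(blockLength, n)
    nb <- ceiling(n / bl)
    starts <- seq_len(n - bl + 1)
    means <- vapply(seq_len(nBoot), function(b) {
      idx <- unlist(lapply(sample(starts, nb, replace = TRUE),
                           function(s0) s0:(s0 + bl - 1)))[1:n]
      mean(x[idx])
    }, numeric(1))
    a <- (1 - ciLevel) / 2
    q <- stats::quantile(means, c(a, 1 - a), names = FALSE)
    ci <- c(lo = max(0, min(q[1], k / n)), hi = min(1, max(q[2], k / n)))
  }
  new("PopulationSummary", nOpen = as.integer(k),
      nClosed = as.integer(n - k), pOpen = k / n, ciLevel = ciLevel,
      ciLo = unname(ci["lo"]), ciHi = unname(ci["hi"]),
      nDiscarded = as.integer(nDiscard))
}

# gas constant, kcal/(mol K)
.Rgas <- 1.987e-3

#' Free-energy gap between closed and open states
#'
#' DeltaG = -R T log(pOpen / pClosed), R = 1.987e-3 kcal/(mol K): negative
#' when the open state is the more populated. Undefined at pOpen of 0
#' or 1, which raises an error rather than returning an infinity.
#'
#' @param p a [PopulationSummary-class] or a bare open fraction in (0, 1).
#' @param temperature K.
#' @return a [FreeEnergyGap-class].
#' @examples
#' deltaG(freeEnergyGap(0.5, 300))   # 0: equally populated states
#' @export
freeEnergyGap <- function(p, temperature) {
  pv <- if (is(p, "PopulationSummary")) p@pOpen else as.numeric(p)
  if (pv <= 0 || pv >= 1)
    stop("undefined-gap error: pOpen must be strictly inside (0, 1)")
  new("FreeEnergyGap", deltaG = -.Rgas * temperature * log(pv / (1 - pv)),
      temperature = temperature,
      convention = "deltaG = -RT log(pOpen/pClosed); negative favors open")
}

#' Normalized distribution of the reaction coordinate
#'
#' Histogram (density normalized so that sum(density * width) = 1) or
#' Gaussian kernel density of the handle distance, the representation
#' behind the temperature- and mutant-comparison distribution panels.
#' Crystal-structure reference distances can be attached as markers.
#'
#' @param d a [DistanceSeries-class] or numeric vector, Angstrom.
#' @param mode "histogram" or "kde".
#' @param binWidth histogram bin width, Angstrom (> 0).
#' @param bandwidth KDE bandwidth (default `stats::bw.nrd0`).
#' @param markers optional named numeric vector of reference distances
#'   (e.g. crystal-structure values), stored in the result.
#' @return list of class `"DistanceDistribution"`: for histograms,
#'   `breaks`, `mids`, `density`; for KDE, `x`, `density`; plus `mode` and
#'   `markers`.
#' @export
distanceDistribution <- function(d, mode = c("histogram", "kde"),
                                 binWidth = 0.25, bandwidth = NULL,
                                 markers = NULL) {
  mode <- match.arg(mode)
  v <- if (is(d, "DistanceSeries")) d@values else as.numeric(d)
  if (mode == "histogram") {
    if (binWidth <= 0) stop("argument error: binWidth must be positive")
    lo <- floor(min(v) / binWidth) * binWidth
    hi <- ceiling(max(v) / binWidth) * binWidth
    if (hi <= lo) hi <- lo + binWidth
    breaks <- seq(lo, hi, by = binWidth)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    out <- list(mode = "histogram", breaks = h$breaks, mids = h$mids,
                density = h$density, markers = markers)
  } else {
    if (length(v) < 2) stop("kde needs at least 2 values")
    k <- if (is.null(bandwidth)) stats::density(v) else
      stats::density(v, bw = bandwidth)
    out <- list(mode = "kde", x = k$x, density = k$y, bandwidth = k$bw,
                markers = markers)
  }
  class(out) <- "DistanceDistribution"
  out
}

#' Tabulate population summaries across proteins and temperatures
#'
#' @param summaries named list of [PopulationSummary-class] objects; names
#'   are "protein|temperature" (e.g. `"ecRNH|300"`), or supply `keys`.
#' @param keys optional data.frame with columns `protein`, `temperature`
#'   (K), one row per summary, overriding the names.
#' @return long-format data.frame (protein, temperature, pOpen, ciLo,
#'   ciHi, nFrames), sorted by protein then temperature, with an attribute
#'   `"monotone"` naming proteins whose open population is monotone in
#'   temperature.
#' @export
temperatureComparison <- function(summaries, keys = NULL) {
  if (length(summaries) == 0) stop("aggregation error: empty input")
  if (is.null(keys)) {
    parts <- strsplit(names(summaries), "|", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("summaries must be named 'protein|temperature'")
    keys <- data.frame(protein = vapply(parts, `[`, "", 1),
                       temperature = as.numeric(vapply(parts, `[`, "", 2)))
  }
  if (anyDuplicated(paste(keys$protein, keys$temperature)))
    stop("aggregation error: duplicate (protein, temperature) key")
  tab <- data.frame(
    protein = keys$protein, temperature = keys$temperature,
    pOpen = vapply(summaries, function(s) s@pOpen, numeric(1)),
    ciLo = vapply(summaries, function(s) s@ciLo, numeric(1)),
    ciHi = vapply(summaries, function(s) s@ciHi, numeric(1)),
    nFrames = vapply(summaries, function(s) s@nOpen + s@nClosed,
                     numeric(1)))
  tab <- tab[order(tab$protein, tab$temperature), ]
  rownames(tab) <- NULL
  mono <- vapply(split(tab, tab$protein), function(g) {
    nrow(g) >= 2 && (!is.unsorted(g$pOpen) || !is.unsorted(rev(g$pOpen)))
  }, logical(1))
  attr(tab, "monotone") <- names(mono)[mono]
  tab
}
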