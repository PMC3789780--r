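# Dynamic averaging of externally predicted per-frame chemical shifts and
# per-region RMSD reports against experiment. The per-frame predictor is
# external; this module only defines the exchange format and the averaging
# and validation arithmetic.

.shiftCols <- c(frame = "frame", chain = "chain", resnum = "resNo",
                inscode = "insCode", resname = "resName",
                nucleus = "nucleus", ppm = "ppm")

#' Read / write per-frame chemical-shift tables (exchange CSV)
#'
#' The interchange format is a CSV with columns
#' `frame,chain,resnum,inscode,resname,nucleus,ppm` -- one row per
#' (frame, residue, nucleus) prediction from an external per-frame shift
#' predictor. Experimental shift tables use the same columns minus
#' `frame`.
#'
#' @param path CSV file.
#' @return data.frame with internal column names (`frame`, `chain`,
#'   `resNo`, `insCode`, `resName`, `nucleus`, `ppm`).
#' @export
readFrameShiftTable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(x) <- ifelse(names(x) %in% names(.shiftCols),
                     .shiftCols[names(x)], names(x))
  if (!all(c("resNo", "nucleus", "ppm") %in% names(x)))
    stop("shift table must have columns resnum, nucleus, ppm")
  if (is.null(x$chain)) x$chain <- "A"
  if (is.null(x$insCode)) x$insCode <- ""
  x$insCode[is.na(x$insCode)] <- ""
  if (!all(is.finite(x$ppm))) stop("non-finite ppm values")
  x
}

#' @rdname readFrameShiftTable
#' @param x a frame-shift table (data.frame as above).
#' @export
writeFrameShiftTable <- function(x, path) {
  out <- x
  inv <- stats::setNames(names(.shiftCols), .shiftCols)
  names(out) <- ifelse(names(out) %in% names(inv), inv[names(out)],
                       names(out))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trajectory-average externally predicted chemical shifts
#'
#' Arithmetic mean per (residue, nucleus) over frames surviving the
#' equilibration discard -- the dynamic conformational averaging that
#' makes trajectory-based shift predictions comparable to experiment.
#' Entries missing from some frames are averaged over the frames where
#' they are present, with the coverage recorded.
#'
#' @param t a frame-shift table (see [readFrameShiftTable()] or
#'   [genFrameShiftTable()]).
#' @param equilFraction fraction of initial frames discarded (default
#'   0.1, as in [estimatePopulations()]).
#' @return a ShiftPrediction: data.frame `chain`, `resNo`, `insCode`,
#'   `resName`, `nucleus`, `ppm` (the mean), `sd`, `nFrames`.
#' @export
averageShifts <- function(t, equilFraction = 0.1) {
  if (nrow(t) == 0) stop("empty-data error: no shift records")
  nAll <- max(t$frame)
  keep <- t$frame > ceiling(equilFraction * nAll)
  t <- t[keep, , drop = FALSE]
  if (nrow(t) == 0) stop("empty-data error: no frames survive discard")
  key <- interaction(t$chain, t$resNo, t$insCode, t$resName, t$nucleus,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(t, key), function(g) {
    data.frame(chain = g$chain[1], resNo = g$resNo[1],
               insCode = g$insCode[1], resName = g$resName[1],
               nucleus = g$nucleus[1], ppm = mean(g$ppm),
               sd = if (nrow(g) > 1) stats::sd(g$ppm) else 0,
               nFrames = nrow(g), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$chain, agg$resNo, agg$insCode, agg$nucleus), ]
  rownames(agg) <- NULL
  agg
}

#' Random-coil reference shifts shipped with the package
#'
#' Loads the bundled random-coil table: synthetic demonstration values
#' (file `random_coil_synthetic.csv`; plausible magnitudes per residue
#' type and nucleus, *not* a published experimental compilation). For real
#' analyses supply your preferred published random-coil table as a
#' data.frame with columns `resName`, `nucleus`, `ppm`.
#'
#' @return data.frame `resName` (3-letter), `nucleus`, `ppm` covering the
#'   20 standard residues for nuclei CA, CB, C, N, HN, HA.
#' @export
randomCoilShifts <- function() {
  utils::read.csv(system.file("extdata", "random_coil_synthetic.csv",
                              package = "HandleDynamics"),
                  stringsAsFactors = FALSE)
}

#' Secondary chemical shifts (deviation from random coil)
#'
#' @param p a shift table with columns `resName`, `nucleus` and a value
#'   column `ppm` (a ShiftPrediction from [averageShifts()] or an
#'   experimental table).
#' @param rc random-coil table (`resName`, `nucleus`, `ppm`); default the
#'   bundled synthetic demonstration table ([randomCoilShifts()]).
#' @return `p` with an added column `secondary` = ppm - random-coil ppm.
#' @export
secondaryShifts <- function(p, rc = randomCoilShifts()) {
  m <- match(paste(p$resName, p$nucleus),
             paste(rc$resName, rc$nucleus))
  if (anyNA(m)) {
    bad <- unique(paste(p$resName, p$nucleus)[is.na(m)])
    stop("lookup error: no random-coil value for: ",
         paste(bad, collapse = ", "))
  }
  p$secondary <- p$ppm - rc$ppm[m]
  p
}

#' Per-region RMSD between predicted and experimental shifts
#'
#' RMSD over the common (residue, nucleus) entries of each named region,
#' plus an "Average" region covering every assigned residue -- the layout
#' behind handle-vs-average comparisons of dynamically averaged (MD) and
#' static-structure (Xray) predictions. RMSDs use absolute shift values.
#'
#' @param p predicted shifts (`resNo`, `nucleus`, `ppm`; e.g. from
#'   [averageShifts()]).
#' @param e experimental shifts (same columns).
#' @param regions named list of residue-number vectors, e.g.
#'   `list(Handle = 71:100)`.
#' @param nuclei nuclei to report (default: all present in `e`).
#' @return data.frame `region`, `nucleus`, `rmsd`, `n`; cells with no
#'   common entries have `rmsd = NA` and `n = 0`.
#' @export
regionRmsd <- function(p, e, regions = list(Handle = 71:100),
                       nuclei = NULL) {
  if (is.null(nuclei)) nuclei <- sort(unique(e$nucleus))
  regions <- c(regions, list(Average = sort(unique(e$resNo))))
  m <- merge(p[, c("resNo", "nucleus", "ppm")],
             e[, c("resNo", "nucleus", "ppm")],
             by = c("resNo", "nucleus"), suffixes = c(".pred", ".exp"))
  out <- do.call(rbind, lapply(names(regions), function(rg) {
    do.call(rbind, lapply(nuclei, function(nu) {
      g <- m[m$resNo %in% regions[[rg]] & m$nucleus == nu, ]
      data.frame(region = rg, nucleus = nu,
                 rmsd = if (nrow(g)) sqrt(mean((g$ppm.pred - g$ppm.exp)^2))
                        else NA_real_,
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
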