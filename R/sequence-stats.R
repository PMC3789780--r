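# Growth-temperature comparative sequence statistics: alignment ingest,
# reference-position mapping (including the G80b insertion), residue and
# category frequency tables by class, chi-square enrichment tests with
# Bonferroni correction, percent identity.

.growthClasses <- c("psychrophile", "mesophile", "thermophile")

#' Assemble an annotated alignment
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (gap "-").
#' @param annotation data.frame with columns `id`, `class` (one of
#'   psychrophile/mesophile/thermophile) and/or `temperature` (degrees C,
#'   used to assign a class when `class` is absent: < 20 psychrophile,
#'   20-45 mesophile, > 45 thermophile).
#' @param reference id of the reference row (ecRNH-numbering reference).
#' @param collapseDuplicates drop exact duplicate sequences (keeping the
#'   first), mirroring redundancy filtering of sequence sets.
#' @return list of class `"AnnotatedAlignment"` with elements `alignment`,
#'   `annotation` (id, class, annotated), `reference`.
#' @export
annotatedAlignment <- function(alignment, annotation, reference,
                               collapseDuplicates = FALSE) {
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment error: rows differ in length")
  if (!reference %in% names(alignment))
    stop("reference sequence '", reference, "' not in alignment")
  if (collapseDuplicates) {
    dup <- duplicated(alignment) & names(alignment) != reference
    if (any(dup)) {
      message("collapsed ", sum(dup), " duplicate sequence(s): ",
              paste(names(alignment)[dup], collapse = ", "))
      alignment <- alignment[!dup]
    }
  }
  ids <- setdiff(names(alignment), reference)
  cls <- rep(NA_character_, length(ids))
  m <- match(ids, annotation$id)
  if (!is.null(annotation$class)) cls <- annotation$class[m]
  if (!is.null(annotation$temperature)) {
    tt <- annotation$temperature[m]
    fill <- is.na(cls) & !is.na(tt)
    cls[fill] <- ifelse(tt[fill] < 20, "psychrophile",
                        ifelse(tt[fill] <= 45, "mesophile", "thermophile"))
  }
  bad <- !is.na(cls) & !cls %in% .growthClasses
  if (any(bad))
    stop("unknown growth class: ", paste(unique(cls[bad]), collapse = ", "))
  structure(list(alignment = alignment,
                 annotation = data.frame(id = ids, class = cls,
                                         annotated = !is.na(cls),
                                         stringsAsFactors = FALSE),
                 reference = reference),
            class = "AnnotatedAlignment")
}

#' Load an annotated alignment from FASTA + annotation TSV
#'
#' @param fastaPath aligned FASTA (gap "-").
#' @param annotationPath TSV with columns `id`, `class` and/or
#'   `temperature`.
#' @param reference reference row id (default `"reference"`).
#' @param collapseDuplicates see [annotatedAlignment()].
#' @return an `AnnotatedAlignment`.
#' @export
loadAnnotatedAlignment <- function(fastaPath, annotationPath,
                                   reference = "reference",
                                   collapseDuplicates = FALSE) {
  aln <- readAlignmentFasta(fastaPath)
  ann <- utils::read.delim(annotationPath, stringsAsFactors = FALSE)
  missing <- setdiff(ann$id, names(aln))
  if (length(missing))
    stop("annotation ids absent from alignment: ",
         paste(missing, collapse = ", "))
  annotatedAlignment(aln, ann, reference, collapseDuplicates)
}

#' Map reference positions to alignment columns
#'
#' Reference (ecRNH) numbering counts the non-gap columns of the reference
#' row. The special position `"80b"` denotes the insertion column(s)
#' between reference positions 80 and 81 (gap in the reference); a
#' sequence "has the insertion" when it is non-gap there.
#'
#' @param a an `AnnotatedAlignment`.
#' @param positions vector of reference positions (integers, or `"80b"`).
#' @return list with `columns` (named integer; NA for "80b" when the
#'   alignment has no insertion column), `letters` (matrix: sequences x
#'   positions; for "80b", "+" when inserted, "-" when not), and
#'   `insertionColumns`.
#' @export
mapReferencePositions <- function(a, positions) {
  rows <- strsplit(a$alignment, "")
  ref <- rows[[a$reference]]
  nonGap <- ref != "-"
  refPos <- cumsum(nonGap)
  maxPos <- max(refPos)
  colFor <- function(p) {
    if (p > maxPos) stop("range error: position ", p,
                         " beyond reference length ", maxPos)
    which(nonGap & refPos == p)
  }
  insCols <- integer(0)
  if (maxPos >= 81) {
    c80 <- colFor(80); c81 <- colFor(81)
    if (c81 > c80 + 1) insCols <- (c80 + 1):(c81 - 1)
  }
  ids <- setdiff(names(a$alignment), a$reference)
  letters <- matrix("", length(ids), length(positions),
                    dimnames = list(ids, as.character(positions)))
  columns <- stats::setNames(rep(NA_integer_, length(positions)),
                             as.character(positions))
  for (j in seq_along(positions)) {
    p <- positions[j]
    if (identical(as.character(p), "80b")) {
      if (length(insCols) == 0) {
        warning("alignment has no insertion column between 80 and 81")
        letters[, j] <- "-"
      } else {
        for (id in ids) {
          letters[id, j] <-
            if (any(rows[[id]][insCols] != "-")) "+" else "-"
        }
        columns[j] <- insCols[1]
      }
    } else {
      cc <- colFor(as.integer(p))
      columns[j] <- cc
      for (id in ids) letters[id, j] <- rows[[id]][cc]
    }
  }
  list(columns = columns, letters = letters, insertionColumns = insCols)
}

#' Residue-category clustering used at position 101
#'
#' Alanine; branched (Ile, Leu, Val); linear/polar (Arg, Lys, Glu, Gln);
#' all other residues.
#'
#' @return named list of one-letter residue vectors.
#' @export
position101Categories <- function() {
  list(Ala = "A", branched = c("I", "L", "V"),
       "linear/polar" = c("R", "K", "E", "Q"),
       other = setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       c("A", "I", "L", "V", "R", "K", "E", "Q")))
}

#' Residue (or category) frequencies at a reference position, by class
#'
#' Counts per residue letter -- or per category when a categorization such
#' as [position101Categories()] is supplied -- for each growth class and
#' overall. Gap rows are excluded from the counts and tracked separately.
#'
#' @param a an `AnnotatedAlignment`.
#' @param position reference position (integer or `"80b"`).
#' @param categorization optional named list of letter vectors.
#' @return list of class `"FrequencyTable"`: `position`, `counts` (matrix
#'   category x class, with an `overall` column over annotated
#'   sequences), `gaps` (per class), `classTotals`.
#' @export
residueFrequencies <- function(a, position, categorization = NULL) {
  mp <- mapReferencePositions(a, list(position))
  ann <- a$annotation[a$annotation$annotated, ]
  lets <- mp$letters[ann$id, 1]
  if (!is.null(categorization)) {
    lut <- stats::setNames(
      rep(names(categorization), lengths(categorization)),
      unlist(categorization))
    cats <- ifelse(lets == "-", "-", lut[lets])
    if (anyNA(cats))
      stop("letter(s) not covered by categorization: ",
           paste(unique(lets[is.na(cats)]), collapse = ", "))
    levelsUsed <- names(categorization)
  } else {
    cats <- lets
    levelsUsed <- sort(unique(lets[lets != "-"]))
  }
  classes <- .growthClasses[.growthClasses %in% ann$class]
  counts <- matrix(0L, length(levelsUsed), length(classes) + 1,
                   dimnames = list(levelsUsed, c(classes, "overall")))
  gaps <- stats::setNames(integer(length(classes)), classes)
  for (cl in classes) {
    x <- cats[ann$class == cl]
    gaps[cl] <- sum(x == "-")
    t0 <- table(factor(x[x != "-"], levels = levelsUsed))
    counts[, cl] <- as.integer(t0)
  }
  counts[, "overall"] <- rowSums(counts[, classes, drop = FALSE])
  structure(list(position = position, counts = counts, gaps = gaps,
                 classTotals = table(factor(ann$class, levels = classes))),
            class = "FrequencyTable")
}

#' Chi-square enrichment tests per growth class with Bonferroni control
#'
#' For every class, the observed category counts are tested against (a)
#' the uniform distribution over categories (flag `*` when significant)
#' and (b) the overall-dataset category proportions (flag `#`), each at
#' the Bonferroni-corrected level `alpha / nTests`.
#'
#' @param f a `FrequencyTable` from [residueFrequencies()].
#' @param alpha family-wise significance level (default 0.05).
#' @param nTests number of tests entering the Bonferroni correction
#'   (supplied by the caller; e.g. 15 tests give a corrected level of
#'   0.0033).
#' @return data.frame per class: `class`, `chisqUniform`, `dfUniform`,
#'   `pUniform`, `star`, `chisqOverall`, `dfOverall`, `pOverall`, `hash`,
#'   `lowExpected`; attribute `"correctedLevel"`.
#' @export
enrichmentTests <- function(f, alpha = 0.05, nTests) {
  counts <- f$counts
  classes <- setdiff(colnames(counts), "overall")
  keep <- counts[, "overall"] > 0
  if (sum(keep) < 2)
    stop("test undefined: fewer than 2 categories with nonzero counts")
  counts <- counts[keep, , drop = FALSE]
  k <- nrow(counts)
  pOverall <- counts[, "overall"] / sum(counts[, "overall"])
  level <- alpha / nTests
  rows <- lapply(classes, function(cl) {
    obs <- counts[, cl]
    n <- sum(obs)
    if (n == 0) {
      warning("class ", cl, " empty after gap exclusion; tests skipped")
      return(data.frame(class = cl, chisqUniform = NA, dfUniform = NA,
                        pUniform = NA, star = NA, chisqOverall = NA,
                        dfOverall = NA, pOverall = NA, hash = NA,
                        lowExpected = NA))
    }
    tu <- suppressWarnings(stats::chisq.test(obs, p = rep(1 / k, k)))
    to <- suppressWarnings(stats::chisq.test(obs, p = pOverall))
    data.frame(class = cl,
               chisqUniform = unname(tu$statistic),
               dfUniform = unname(tu$parameter), pUniform = tu$p.value,
               star = tu$p.value < level,
               chisqOverall = unname(to$statistic),
               dfOverall = unname(to$parameter), pOverall = to$p.value,
               hash = to$p.value < level,
               lowExpected = any(tu$expected < 5) || any(to$expected < 5))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "correctedLevel") <- level
  out
}

#' Fraction of sequences carrying the G80b insertion, per class
#'
#' @param a an `AnnotatedAlignment`.
#' @return data.frame `class`, `n`, `nInserted`, `fraction` (NA for
#'   classes with no sequences).
#' @export
insertionFrequency <- function(a) {
  mp <- mapReferencePositions(a, list("80b"))
  ann <- a$annotation[a$annotation$annotated, ]
  ins <- mp$letters[ann$id, 1] == "+"
  do.call(rbind, lapply(.growthClasses, function(cl) {
    i <- ann$class == cl
    data.frame(class = cl, n = sum(i), nInserted = sum(ins[i]),
               fraction = if (sum(i)) mean(ins[i]) else NA_real_)
  }))
}

#' Percent identity of an aligned sequence pair
#'
#' 100 x identical columns / columns where at least one sequence is
#' non-gap. The denominator convention is recorded in the result because
#' published identities for the same pair differ with the convention.
#'
#' @param seqA,seqB equal-length aligned sequences (character strings).
#' @return numeric percentage with attribute `"convention"`.
#' @export
percentIdentity <- function(seqA, seqB) {
  x <- strsplit(seqA, "")[[1]]; y <- strsplit(seqB, "")[[1]]
  if (length(x) != length(y))
    stop("aligned sequences must have equal length")
  den <- sum(x != "-" | y != "-")
  if (den == 0) stop("undefined: all columns are gap-gap")
  idn <- sum(x != "-" & x == y)
  structure(100 * idn / den,
            convention = "identities / columns with >=1 non-gap")
}
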