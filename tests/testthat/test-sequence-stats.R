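demoAlignment <- function() {
  # reference ungapped; thermophiles carry the 80b insertion
  bg <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 6), collapse = "")
  spec <- sequenceSetSpec(
    counts = c(psychrophile = 30, mesophile = 200, thermophile = 200),
    positionTables = list(
      "88" = list(psychrophile = c(K = 0.7, R = 0.2, N = 0.1),
                  mesophile = c(R = 0.55, K = 0.3, N = 0.15),
                  thermophile = c(N = 0.55, R = 0.3, K = 0.15)),
      "101" = list(psychrophile = c(V = 0.5, I = 0.3, A = 0.2),
                   mesophile = c(V = 0.4, R = 0.3, A = 0.2, W = 0.1),
                   thermophile = c(R = 0.5, A = 0.3, E = 0.2))),
    insertionProb = c(psychrophile = 0.1, mesophile = 0.15,
                      thermophile = 0.7),
    background = substr(bg, 1, 110), seed = 51)
  gs <- genSequenceSet(spec)
  annotatedAlignment(gs$alignment, gs$annotation, "reference")
}

test_that("annotated alignments join, flag and collapse correctly", {
  aln <- c(reference = "ACDE", s1 = "ACDE", s2 = "AC-E", s3 = "ACDE")
  ann <- data.frame(id = c("s1", "s2"),
                    class = c("mesophile", "thermophile"))
  a <- annotatedAlignment(aln, ann, "reference")
  expect_equal(sum(a$annotation$annotated), 2)
  expect_false(a$annotation$annotated[a$annotation$id == "s3"])
  # duplicate collapse drops the repeated sequence
  expect_message(
    a2 <- annotatedAlignment(aln, ann, "reference",
                             collapseDuplicates = TRUE), "collapsed")
  expect_false("s3" %in% names(a2$alignment))
  # class from growth temperature when class column is absent
  annT <- data.frame(id = c("s1", "s2"), temperature = c(10, 60))
  a3 <- annotatedAlignment(aln, annT, "reference")
  expect_equal(a3$annotation$class[match(c("s1", "s2"),
                                         a3$annotation$id)],
               c("psychrophile", "thermophile"))
  expect_error(annotatedAlignment(c(reference = "ACDE", s1 = "ACD"),
                                  ann, "reference"), "alignment error")
})

test_that("reference-position mapping respects gaps and the 80b insertion", {
  # gapless reference: column = position
  aln <- c(reference = "ACDEFGHIKL", s1 = "ACDEFGHIKL")
  a <- annotatedAlignment(aln, data.frame(id = "s1", class = "mesophile"),
                          "reference")
  expect_equal(unname(mapReferencePositions(a, list(3))$columns), 3)
  # a reference gap shifts all later columns by one
  aln2 <- c(reference = "AC-DEFGHIKL", s1 = "ACXDEFGHIKL")
  a2 <- annotatedAlignment(aln2,
                           data.frame(id = "s1", class = "mesophile"),
                           "reference")
  expect_equal(unname(mapReferencePositions(a2, list(3))$columns), 4)
  expect_error(mapReferencePositions(a2, list(99)), "range error")

  a3 <- demoAlignment()
  mp <- mapReferencePositions(a3, list("80b", 88))
  expect_equal(length(mp$insertionColumns), 1)
  expect_equal(unname(mp$columns[["88"]]), 89)  # insertion shifts by one
})

test_that("residue frequencies and categories count correctly", {
  a <- demoAlignment()
  f <- residueFrequencies(a, 88)
  # counts + gaps = class totals
  for (cl in c("psychrophile", "mesophile", "thermophile")) {
    expect_equal(sum(f$counts[, cl]) + f$gaps[[cl]],
                 as.integer(f$classTotals[[cl]]))
  }
  # class-specific enrichment visible in raw frequencies
  expect_gt(f$counts["N", "thermophile"] / sum(f$counts[, "thermophile"]),
            f$counts["N", "mesophile"] / sum(f$counts[, "mesophile"]))

  # hand-counted category clustering at position 101
  lets <- c("A", "I", "L", "V", "R", "K", "E", "Q", "W")
  aln <- c(reference = paste(rep("A", 110), collapse = ""),
           stats::setNames(vapply(lets, function(l) {
             s <- rep("A", 110); s[101] <- l
             paste(s, collapse = "")
           }, ""), paste0("s", seq_along(lets))))
  ann <- data.frame(id = paste0("s", seq_along(lets)),
                    class = "mesophile")
  aC <- annotatedAlignment(aln, ann, "reference")
  fc <- residueFrequencies(aC, 101,
                           categorization = position101Categories())
  expect_equal(unname(fc$counts[, "overall"]), c(1, 3, 4, 1))
  expect_equal(rownames(fc$counts),
               c("Ala", "branched", "linear/polar", "other"))

  # degenerate: all sequences identical at the position
  expect_equal(unname(residueFrequencies(aC, 5)$counts[, "overall"]), 9)
})

test_that("enrichment tests match the chi-square formula and flag per
           the star/hash convention", {
  a <- demoAlignment()
  f <- residueFrequencies(a, 88)
  res <- enrichmentTests(f, alpha = 0.05, nTests = 15)
  expect_equal(attr(res, "correctedLevel"), 0.05 / 15, tolerance = 1e-12)
  # brute-force chi-square + CDF oracle for the thermophile class
  obs <- f$counts[f$counts[, "overall"] > 0, "thermophile"]
  k <- length(obs)
  Eu <- rep(sum(obs) / k, k)
  x2u <- sum((obs - Eu)^2 / Eu)
  row <- res[res$class == "thermophile", ]
  expect_equal(row$chisqUniform, x2u, tolerance = 1e-9)
  expect_equal(row$pUniform, pchisq(x2u, k - 1, lower.tail = FALSE),
               tolerance = 1e-9)
  pO <- f$counts[f$counts[, "overall"] > 0, "overall"]
  pO <- pO / sum(pO)
  Eo <- sum(obs) * pO
  x2o <- sum((obs - Eo)^2 / Eo)
  expect_equal(row$chisqOverall, x2o, tolerance = 1e-9)
  expect_equal(row$pOverall, pchisq(x2o, k - 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # planted effects: thermophile Asn enrichment departs from the overall
  # dataset; the small psychrophile class does not
  expect_true(row$hash)
  expect_equal(res$star, c(TRUE, TRUE, TRUE))

  # null case: observed equal to uniform expectation
  fNull <- f
  fNull$counts[, "mesophile"] <- 50L
  fNull$counts[, "overall"] <- rowSums(
    fNull$counts[, c("psychrophile", "mesophile", "thermophile")])
  resNull <- enrichmentTests(fNull, alpha = 0.05, nTests = 15)
  mrow <- resNull[resNull$class == "mesophile", ]
  expect_equal(mrow$chisqUniform, 0)
  expect_equal(mrow$pUniform, 1)
  expect_false(mrow$star)

  # invariance to category order
  fRev <- f
  fRev$counts <- f$counts[rev(rownames(f$counts)), ]
  resRev <- enrichmentTests(fRev, alpha = 0.05, nTests = 15)
  expect_equal(resRev$chisqUniform, res$chisqUniform, tolerance = 1e-12)

  # single-category tables are undefined
  f1 <- f
  f1$counts <- f$counts[1, , drop = FALSE]
  expect_error(enrichmentTests(f1, nTests = 15), "test undefined")
})

test_that("hash-test power on planted class differences is high", {
  hits <- vapply(1:20, function(i) {
    bg <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 6), collapse = "")
    spec <- sequenceSetSpec(
      counts = c(mesophile = 200, thermophile = 200),
      positionTables = list(
        "88" = list(mesophile = c(R = 0.55, K = 0.3, N = 0.15),
                    thermophile = c(N = 0.55, R = 0.3, K = 0.15))),
      insertionProb = c(mesophile = 0.15, thermophile = 0.7),
      background = substr(bg, 1, 110), seed = 700 + i)
    gs <- genSequenceSet(spec)
    a <- annotatedAlignment(gs$alignment, gs$annotation, "reference")
    res <- enrichmentTests(residueFrequencies(a, 88), alpha = 0.05,
                           nTests = 15)
    res$hash[res$class == "thermophile"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("insertion frequency is reported per class with missing data", {
  a <- demoAlignment()
  insf <- insertionFrequency(a)
  expect_equal(insf$fraction[insf$class == "thermophile"], 0.7,
               tolerance = 0.12)
  expect_equal(insf$fraction[insf$class == "mesophile"], 0.15,
               tolerance = 0.1)
  # degenerate: all thermophiles inserted, no mesophiles
  aln <- c(reference = "ACDEFGHIKL", t1 = "ACDEFGHIKL",
           t2 = "ACDEFGHIKL")
  ann <- data.frame(id = c("t1", "t2"), class = "thermophile")
  a2 <- annotatedAlignment(aln, ann, "reference")
  expect_warning(insf2 <- insertionFrequency(a2), "no insertion column")
  expect_true(is.na(insf2$fraction[insf2$class == "mesophile"]))
})

test_that("percent identity follows the declared convention", {
  expect_equal(as.numeric(percentIdentity("ACDE", "ACDE")), 100)
  expect_equal(as.numeric(percentIdentity("AAAA", "CCCC")), 0)
  expect_equal(as.numeric(percentIdentity("ACDEFGHIKL", "ACDEFGHIYW")),
               80)   # 8 identities / 10 columns
  expect_equal(as.numeric(percentIdentity("ACDEFGXXXX", "ACDEFGYYYZ")),
               60)
  # symmetry
  expect_equal(as.numeric(percentIdentity("AC-E", "ACDE")),
               as.numeric(percentIdentity("ACDE", "AC-E")))
  expect_error(percentIdentity("AC", "ACD"), "equal length")
  expect_error(percentIdentity("--", "--"), "undefined")
})
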