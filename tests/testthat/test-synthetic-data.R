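test_that("two-state generator honors spec validation", {
  expect_error(twoStateSpec(10, pOpen = 0.5, rates = c(0.1, 0.1)),
               "ambiguity")
  expect_error(twoStateSpec(10), "pOpen or rates")
  expect_error(twoStateSpec(10, pOpen = 0.5, dOpenMean = 9), "straddle")
  expect_error(twoStateSpec(10, pOpen = 0.5, dClosedMean = 11), "straddle")
  expect_error(twoStateSpec(10, pOpen = 0.5, basinSd = 0), "basinSd")
})

test_that("two-state generator controls the anchor-tip distance", {
  # single-state limit: every frame open, far above threshold
  g1 <- genTwoStateTrajectory(twoStateSpec(500, pOpen = 1, seed = 5))
  d1 <- distanceValues(handleDistance(g1$trajectory))
  expect_true(all(d1 > 13 - 4 * 0.8))
  expect_true(all(g1$states == "open"))

  # empirical open fraction within the 99% binomial interval
  n <- 50000; p <- 0.15
  g <- genTwoStateTrajectory(twoStateSpec(n, pOpen = p, seed = 6))
  half <- qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(g$states == "open") - p), half)

  # basin structure: per-state distances match the spec means
  d <- distanceValues(handleDistance(g$trajectory))
  expect_equal(mean(d[g$states == "open"]), 13.0, tolerance = 0.05)
  expect_equal(mean(d[g$states == "closed"]), 7.5, tolerance = 0.05)
  expect_equal(sd(d[g$states == "closed"]), 0.8, tolerance = 0.05)

  # bimodality: histogram modes near the basin means
  h <- distanceDistribution(d, binWidth = 0.25)
  locmax <- which(diff(sign(diff(h$density))) == -2) + 1
  modes <- h$mids[locmax][order(h$density[locmax], decreasing = TRUE)][1:2]
  expect_true(any(abs(modes - 7.5) < 0.8) && any(abs(modes - 13.0) < 0.8))
})

test_that("two-state generator is bit-reproducible and restores RNG state", {
  set.seed(99); before <- runif(1)
  set.seed(99)
  a <- genTwoStateTrajectory(twoStateSpec(200, pOpen = 0.3, seed = 8))
  after <- runif(1)
  expect_identical(before, after)   # generator did not disturb the stream
  b <- genTwoStateTrajectory(twoStateSpec(200, pOpen = 0.3, seed = 8))
  expect_identical(a$trajectory@coords, b$trajectory@coords)
  expect_identical(a$states, b$states)
})

test_that("rate mode converges to the Markov stationary open fraction", {
  kOC <- 0.02; kCO <- 0.01   # stationary p = 1/3
  g <- genTwoStateTrajectory(twoStateSpec(60000, rates = c(kOC, kCO),
                                          seed = 9))
  expect_equal(g$pOpen, kCO / (kCO + kOC))
  # wide band: the chain is autocorrelated (tau ~ 1/(kOC+kCO) frames)
  expect_lt(abs(mean(g$states == "open") - g$pOpen), 0.06)
})

test_that("cone vectors are unit norm, axial, and carry the closed form", {
  g <- genConeVectors(coneSpec(60, 50000, seed = 10))
  expect_equal(max(abs(sqrt(rowSums(g$vectors^2)) - 1)), 0,
               tolerance = 1e-12)
  m <- colMeans(g$vectors)
  expect_lt(max(abs(m[1:2])), 0.01)
  expect_gt(m[3], 0.7)
  expect_equal(g$s2Analytic, (cos(pi / 3) * (1 + cos(pi / 3)) / 2)^2)
  # rigid and isotropic limits of the closed form
  expect_equal(genConeVectors(coneSpec(0.01, 10))$s2Analytic, 1,
               tolerance = 1e-6)
  expect_equal(genConeVectors(coneSpec(90, 10))$s2Analytic, 0)
})

test_that("rotamer series recover class populations and coupling", {
  r1 <- genRotamerSeries(rotamerSpec(populations = c(1, 0, 0),
                                     jitterSd = 5, nFrames = 1000,
                                     seed = 11))
  expect_true(all(abs(r1$angles - (-60)) < 4 * 5 + 1))
  expect_true(all(r1$classes == "gauche-"))

  pops <- c(0.2, 0.3, 0.5)
  r2 <- genRotamerSeries(rotamerSpec(populations = pops, nFrames = 30000,
                                     seed = 12))
  obs <- table(factor(r2$classes,
                      c("gauche-", "gauche+", "trans"))) / 30000
  half <- qnorm(0.995) * sqrt(pops * (1 - pops) / 30000)
  expect_true(all(abs(as.numeric(obs) - pops) < half))

  states <- rep(c("open", "closed"), each = 5000)
  r3 <- genRotamerSeries(rotamerSpec(
    coupling = list(open = c(0.1, 0.1, 0.8), closed = c(0.8, 0.1, 0.1)),
    nFrames = 10000, seed = 13), states)
  tab <- table(states, r3$classes)
  expect_lt(chisq.test(tab)$p.value, 0.001)
  expect_error(genRotamerSeries(rotamerSpec(
    coupling = list(open = c(1, 0, 0), closed = c(1, 0, 0)),
    nFrames = 10, seed = 1)), "argument error")
})

test_that("sequence sets realize class-dependent frequencies and schema", {
  bg <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 6), collapse = "")
  spec <- sequenceSetSpec(
    counts = c(mesophile = 300, thermophile = 50),
    positionTables = list(
      "88" = list(mesophile = c(R = 0.5, K = 0.3, N = 0.2),
                  thermophile = c(N = 1.0))),
    insertionProb = c(mesophile = 0.0, thermophile = 1.0),
    background = substr(bg, 1, 110), seed = 14)
  gs <- genSequenceSet(spec)
  a <- annotatedAlignment(gs$alignment, gs$annotation, "reference")
  mp <- mapReferencePositions(a, list(88, "80b"))
  th <- gs$annotation$id[gs$annotation$class == "thermophile"]
  me <- gs$annotation$id[gs$annotation$class == "mesophile"]
  # degenerate thermophile table: all N at 88; all inserted
  expect_true(all(mp$letters[th, "88"] == "N"))
  expect_true(all(mp$letters[th, "80b"] == "+"))
  expect_true(all(mp$letters[me, "80b"] == "-"))
  # mesophile letter frequencies within a 99% multinomial band
  obs <- table(factor(mp$letters[me, "88"], c("R", "K", "N"))) / 300
  p <- c(0.5, 0.3, 0.2)
  expect_true(all(abs(as.numeric(obs) - p) <
                  qnorm(0.995) * sqrt(p * (1 - p) / 300)))
  # annotation schema: one row per non-reference record, known classes
  expect_equal(nrow(gs$annotation), length(gs$alignment) - 1)
  expect_true(all(gs$annotation$class %in%
                  c("psychrophile", "mesophile", "thermophile")))
  # generator truth round-trips through the mapping
  expect_equal(unname(mp$letters[me, "88"]),
               unname(vapply(gs$truth[me], `[[`, "", "88")))
  # file round trip
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  genSequenceSet(spec, fa, tsv)
  a2 <- loadAnnotatedAlignment(fa, tsv)
  expect_equal(a2$alignment[["reference"]], gs$alignment[["reference"]])
  # non-standard letters rejected
  expect_error(sequenceSetSpec(
    counts = c(mesophile = 1),
    positionTables = list("88" = list(mesophile = c(X = 1))),
    insertionProb = c(mesophile = 0), background = substr(bg, 1, 110)),
    "spec error")
})

test_that("frame shift tables mix state means as specified", {
  means <- data.frame(resNo = 98, resName = "VAL", nucleus = "CA",
                      openMean = 55, closedMean = 58)
  states <- rep(c("open", "closed"), 500)
  # noiseless: per-frame shifts exactly equal the state means
  t0 <- genFrameShiftTable(shiftEmulationSpec(means, noiseSd = 0,
                                              seed = 15), states)
  expect_equal(t0$ppm, ifelse(states == "open", 55, 58))
  # noisy mixture: trajectory average near the population-weighted mean
  t1 <- genFrameShiftTable(shiftEmulationSpec(means, noiseSd = 0.5,
                                              seed = 16), states)
  expect_equal(mean(t1$ppm), 56.5, tolerance = 3 * 0.5 / sqrt(1000) + 0.1)
  # determinism
  t2 <- genFrameShiftTable(shiftEmulationSpec(means, noiseSd = 0.5,
                                              seed = 16), states)
  expect_identical(t1, t2)
})
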