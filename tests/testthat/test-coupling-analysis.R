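# chi1 geometry helper: N, CA, CB, CG1 coordinates with a prescribed
# dihedral (degrees), built by rotating the gamma atom about the CA-CB
# axis starting from the N reference orientation.
chi1Coords <- function(angle) {
  N <- c(1.2, 0, -0.5); CA <- c(0, 0, 0); CB <- c(0, 0, 1.5)
  a <- angle * pi / 180
  G <- c(1.3 * cos(a), 1.3 * sin(a), 2.1)
  rbind(N, CA, CB, G)
}

chi1Topology <- function(resName = "VAL") {
  gamma <- c(VAL = "CG1", ASN = "CG", ARG = "CG", SER = "OG",
             THR = "OG1", CYS = "SG", ILE = "CG1")[resName]
  new("Topology", atoms = data.frame(
    atomName = c("N", "CA", "CB", unname(gamma)), resName = resName,
    chain = "A", resNo = 98L, insCode = "", element = "C",
    stringsAsFactors = FALSE))
}

test_that("chi1 dihedrals follow the IUPAC sign convention", {
  topo <- chi1Topology()
  tr <- toyTrajectory(topo, list(chi1Coords(180)))
  expect_equal(chi1Series(tr, "A|98|")[1], 180, tolerance = 1e-6)

  # mirror image negates the dihedral
  c60 <- chi1Coords(60)
  mirror <- c60; mirror[, 1] <- -mirror[, 1]
  tr2 <- toyTrajectory(topo, list(c60, mirror))
  a <- chi1Series(tr2, "A|98|")
  expect_equal(a[2], -a[1], tolerance = 1e-6)

  # random conformers vs the independent bio3d torsion implementation
  set.seed(42)
  angles <- runif(20, -179, 179)
  frames <- lapply(angles, chi1Coords)
  tr3 <- toyTrajectory(topo, frames)
  mine <- chi1Series(tr3, "A|98|")
  ref <- vapply(frames, function(f)
    bio3d::torsion.xyz(as.numeric(t(f)), atm.inc = 4), numeric(1))
  expect_equal(mine, ref, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mine, angles, tolerance = 1e-6, ignore_attr = TRUE)

  expect_error(chi1Series(tr3, "A|99|"), "capability error")
  glyTopo <- toyTopology(1, resNo = 98, resName = "GLY")
  glyTr <- toyTrajectory(glyTopo, list(matrix(0, 1, 3)))
  expect_error(chi1Series(glyTr, "A|98|"), "no chi1")
})

test_that("rotamer classification is canonical, circular and recoverable", {
  expect_equal(classifyRotamers(c(-60, 60, 180)),
               c("gauche-", "gauche+", "trans"))
  expect_equal(classifyRotamers(c(179, -179)), c("trans", "trans"))
  # deterministic boundary handling at 0 and +/-120
  expect_equal(classifyRotamers(0), "gauche+")
  expect_equal(classifyRotamers(120), "trans")
  expect_equal(classifyRotamers(-120), "gauche-")
  # planted classes with 10-degree jitter: >= 99.9% recovery
  r <- genRotamerSeries(rotamerSpec(populations = c(0.3, 0.3, 0.4),
                                    jitterSd = 10, nFrames = 20000,
                                    seed = 43))
  expect_gte(mean(classifyRotamers(r$angles) == r$classes), 0.999)
})

test_that("state-rotamer association matches the textbook chi-square", {
  # hand-checkable 2x3 table: chisq = sum (O-E)^2 / E
  states <- rep(c("closed", "open"), times = c(60, 60))
  rot <- c(rep(c("gauche-", "gauche+", "trans"), times = c(10, 20, 30)),
           rep(c("gauche-", "gauche+", "trans"), times = c(30, 20, 10)))
  res <- stateRotamerAssociation(rot, states)
  O <- rbind(c(10, 20, 30), c(30, 20, 10))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chisq, sum((O - E)^2 / E), tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$p, pchisq(sum((O - E)^2 / E), 2, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$cramersV,
               sqrt(sum((O - E)^2 / E) / (120 * 1)), tolerance = 1e-9)

  # perfect coupling: V = 1
  s2 <- rep(c("open", "closed"), each = 50)
  r2 <- ifelse(s2 == "open", "trans", "gauche-")
  expect_equal(stateRotamerAssociation(r2, s2)$cramersV, 1)

  # independence: V near 0 at n = 20000
  set.seed(44)
  s3 <- sample(c("open", "closed"), 20000, replace = TRUE)
  r3 <- sample(c("gauche-", "gauche+", "trans"), 20000, replace = TRUE)
  expect_lt(stateRotamerAssociation(r3, s3)$cramersV, 0.05)

  expect_error(stateRotamerAssociation(r2[1:10], s2), "alignment error")
})

test_that("planted coupling is detected with high power", {
  # calibration: the generator's coupled mode must be detected at
  # n = 10000 in (at least) 19 of 20 seeded replicates
  hits <- vapply(1:20, function(i) {
    states <- rep(c("open", "closed"), each = 5000)
    r <- genRotamerSeries(rotamerSpec(
      coupling = list(open = c(0.2, 0.2, 0.6), closed = c(0.5, 0.3, 0.2)),
      nFrames = 10000, seed = 600 + i), states)
    stateRotamerAssociation(classifyRotamers(r$angles), states)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("shift-coordinate correlation recovers linear and class structure", {
  set.seed(45)
  d <- c(rnorm(300, 7.5, 0.8), rnorm(300, 13, 0.8))
  exact <- 0.3 * d + 50
  expect_equal(shiftCoordinateCorrelation(exact, d)$pearsonR, 1,
               tolerance = 1e-12)
  expect_error(shiftCoordinateCorrelation(rep(1, 600), d),
               "undefined-correlation")
  expect_error(shiftCoordinateCorrelation(exact[1:10], d), "alignment")

  # generator: per-class conditional means recover the spec state means
  states <- rep(c("closed", "open"), each = 300)
  means <- data.frame(resNo = 98, resName = "VAL", nucleus = "CA",
                      openMean = 55, closedMean = 58)
  fst <- genFrameShiftTable(shiftEmulationSpec(means, noiseSd = 0.3,
                                               seed = 46), states)
  rot <- ifelse(states == "open", "trans", "gauche-")
  rep1 <- shiftCoordinateCorrelation(fst$ppm, d, rot)
  bc <- rep1$byClass
  expect_equal(bc$meanShift[bc$class == "trans"], 55,
               tolerance = 3 * 0.3 / sqrt(300))
  expect_equal(bc$meanShift[bc$class == "gauche-"], 58,
               tolerance = 3 * 0.3 / sqrt(300))

  # permutation null: shuffled shifts decorrelate
  set.seed(47)
  big <- rnorm(20000)
  dd <- rnorm(20000, 10, 2)
  expect_lt(abs(shiftCoordinateCorrelation(sample(big), dd)$pearsonR),
            0.05)
})

hbondTopology <- function() {
  new("Topology", atoms = data.frame(
    atomName = c("ND2", "HD21", "O"),
    resName = c("ASN", "ASN", "GLY"), chain = "A",
    resNo = c(88L, 88L, 91L), insCode = "", element = c("N", "H", "O"),
    stringsAsFactors = FALSE))
}

hbondFrame <- function(dDA = 2.9, angle = 165) {
  D <- c(0, 0, 0)
  H <- c(0, 0, 1)
  a <- (180 - angle) * pi / 180    # D-H...A angle at the hydrogen
  A <- H + (dDA - 1) * c(sin(a), 0, cos(a))
  rbind(D, H, A)
}

test_that("hydrogen-bond occupancy applies distance and angle gates", {
  topo <- hbondTopology()
  pairs <- data.frame(donorKey = "A|88|", donorAtom = "ND2",
                      hydrogenAtom = "HD21", acceptorKey = "A|91|",
                      acceptorAtom = "O", stringsAsFactors = FALSE)
  bonded <- hbondFrame(2.9, 165)
  tr <- toyTrajectory(topo, list(bonded))
  expect_equal(hbondOccupancy(tr, pairs)$perPair$occupancy, 1)

  far <- hbondFrame(6.0, 180)
  expect_equal(hbondOccupancy(toyTrajectory(topo, list(far)),
                              pairs)$perPair$occupancy, 0)
  bent <- hbondFrame(2.9, 100)
  expect_equal(hbondOccupancy(toyTrajectory(topo, list(bent)),
                              pairs)$perPair$occupancy, 0)

  # 100-frame fixture with 40 hand-constructed bonded frames
  frames <- c(rep(list(bonded), 40), rep(list(far), 60))
  tr100 <- toyTrajectory(topo, frames)
  occ <- hbondOccupancy(tr100, pairs)
  expect_equal(occ$perPair$occupancy, 0.40)
  expect_equal(occ$jointOccupancy, 0.40)

  # monotone: relaxing the distance gate can only add frames; tightening
  # the angle gate can only remove them
  mixed <- toyTrajectory(topo, lapply(seq(2.5, 6, length.out = 50),
                                      function(d) hbondFrame(d, 150)))
  occs <- vapply(c(3.0, 3.5, 4.5, 6.0), function(cut)
    hbondOccupancy(mixed, pairs, distanceCutoff = cut)$perPair$occupancy,
    numeric(1))
  expect_true(all(diff(occs) >= 0))
  occsA <- vapply(c(180, 150, 120, 90), function(cut)
    hbondOccupancy(mixed, pairs, angleCutoff = cut)$perPair$occupancy,
    numeric(1))
  expect_true(all(diff(occsA) >= 0))

  expect_error(hbondOccupancy(tr, transform(pairs, hydrogenAtom = "HZ")),
               "capability error")
})
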