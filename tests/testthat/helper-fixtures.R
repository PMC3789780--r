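# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Topology with one named atom per residue (CA by default).
toyTopology <- function(n, resNo = 84 + seq_len(n), atomName = "CA",
                        resName = "GLY", chain = "A", insCode = "") {
  new("Topology", atoms = data.frame(
    atomName = atomName, resName = resName, chain = chain,
    resNo = as.integer(resNo), insCode = insCode, element = "C",
    stringsAsFactors = FALSE))
}

# Trajectory from a list of nAtoms x 3 coordinate matrices.
toyTrajectory <- function(topology, frames, temperature = 300,
                          label = "toy") {
  coords <- array(0, c(nrow(topology@atoms), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  new("Trajectory", topology = topology, coords = coords,
      frameInterval = 1, temperature = temperature, label = label)
}

# Uniformly random proper rotation matrix (QR of a Gaussian matrix).
randomRotation <- function() {
  qr0 <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr0) %*% diag(sign(diag(qr.R(qr0))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Independent superposition oracle: minimize RMSD over rotations by a
# coarse Euler-angle grid followed by Nelder-Mead refinement. Never calls
# superpose().
bruteForceRmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rotOf <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((P %*% t(rotOf(ang)) - Q)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); bestV <- obj(best)
  for (a in grid) for (b in grid[grid <= pi]) for (cc in grid) {
    v <- obj(c(a, b, cc))
    if (v < bestV) { bestV <- v; best <- c(a, b, cc) }
  }
  o <- stats::optim(best, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  o$value
}

# Trajectory of nRes residues with N and H atoms; the N-H unit vector of
# residue r in frame f is vectors[[r]][f, ]. No global motion.
bondVectorTrajectory <- function(vectors) {
  nRes <- length(vectors)
  nFr <- nrow(vectors[[1]])
  atoms <- do.call(rbind, lapply(seq_len(nRes), function(r) {
    data.frame(atomName = c("N", "H"), resName = "ALA", chain = "A",
               resNo = 84L + r, insCode = "", element = c("N", "H"),
               stringsAsFactors = FALSE)
  }))
  topo <- new("Topology", atoms = atoms)
  coords <- array(0, c(2 * nRes, 3, nFr))
  for (r in seq_len(nRes)) {
    base <- c(10 * r, 0, 0)
    for (f in seq_len(nFr)) {
      coords[2 * r - 1, , f] <- base
      coords[2 * r, , f] <- base + vectors[[r]][f, ]
    }
  }
  new("Trajectory", topology = topo, coords = coords, frameInterval = 1,
      temperature = 300, label = "bondvec")
}

# Synthetic homolog pair for equivalence-mapping / SSE superposition
# tests: a base C-alpha fold with two helical segments and a flexible
# loop, and a homolog with an extra inserted residue in the loop, a
# perturbed loop, slightly perturbed SSEs, and an arbitrary rigid motion.
syntheticHomologPair <- function(seed = 1, loopShift = 2.5, sseJitter = 0.1) {
  set.seed(seed)
  nh <- 12                       # residues per helix
  nl <- 8                        # loop residues
  t1 <- seq_len(nh); t2 <- seq_len(nh); tl <- seq_len(nl)
  helix <- function(t0, origin) cbind(
    origin[1] + 2.3 * cos(t0 * 100 * pi / 180),
    origin[2] + 2.3 * sin(t0 * 100 * pi / 180),
    origin[3] + 1.5 * t0)
  A <- rbind(helix(t1, c(0, 0, 0)),
             cbind(5 + 3 * sin(tl / 2), 8 + tl, 18 + cos(tl)),
             helix(t2, c(12, 0, 0)))
  nRes <- nrow(A)
  resNoA <- seq_len(nRes)
  # homolog: insert one loop residue after position nh+4
  insAt <- nh + 4
  B <- A
  B[(nh + 1):(nh + nl), ] <- B[(nh + 1):(nh + nl), ] +
    matrix(rnorm(3 * nl, 0, loopShift), nl)
  B[c(seq_len(nh), (nh + nl + 1):nRes), ] <-
    B[c(seq_len(nh), (nh + nl + 1):nRes), ] +
    matrix(rnorm(3 * (2 * nh), 0, sseJitter), 2 * nh)
  Bins <- rbind(B[seq_len(insAt), ], c(6, 14, 20), B[(insAt + 1):nRes, ])
  R <- randomRotation()
  Bins <- sweep(Bins %*% t(R), 2, c(5, -3, 7), "+")
  seqLetters <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       nRes, replace = TRUE)
  aa123 <- function(x) bio3d::aa123(x)
  topoA <- new("Topology", atoms = data.frame(
    atomName = "CA", resName = aa123(seqLetters), chain = "A",
    resNo = resNoA, insCode = "", element = "C", stringsAsFactors = FALSE))
  seqB <- append(seqLetters, "G", after = insAt)
  topoB <- new("Topology", atoms = data.frame(
    atomName = "CA", resName = aa123(seqB), chain = "A",
    resNo = seq_len(nRes + 1), insCode = "", element = "C",
    stringsAsFactors = FALSE))
  alnA <- paste(append(seqLetters, "-", after = insAt), collapse = "")
  alnB <- paste(seqB, collapse = "")
  list(topoA = topoA, coordsA = A, topoB = topoB, coordsB = Bins,
       alignment = c(alnA, alnB),
       sseResNoA = c(seq_len(nh), (nh + nl + 1):nRes))
}
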