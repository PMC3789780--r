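---
title: "Methods: two-state handle-region dynamics and their observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state handle-region dynamics and their observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HandleDynamics)
```

# The scientific problem

The handle region of ribonuclease HI — helices B and C plus the
following loop — is part of the substrate-binding interface, and its
conformational dynamics differ systematically across homologs from
organisms with different preferred growth temperatures. The analyses in
this package center on a one-dimensional reaction coordinate for that
motion, the Cartesian distance between the Cα atoms of the helix-C
anchor (W85 in ecRNH numbering) and the loop tip (A93), and on the
observables used to validate and interpret it: NMR order parameters,
dynamically averaged chemical shifts, loop principal components, rotamer
and hydrogen-bond coupling, and residue-usage statistics across
growth-temperature classes.

# The two-state model

Frames are classified **open** when the anchor–tip distance strictly
exceeds the threshold and **closed** otherwise. The threshold defaults
to 10 Å; a value exactly at the threshold is closed, because the open
state is defined by distances *greater than* the threshold. Both the
threshold and the strictness are visible in the returned objects.

Population estimation discards the first `ceiling(0.1 n)` frames as
equilibration (the fraction is configurable; the analysis literature
rarely states a discard, and 10% is a conservative default for
trajectories initiated from energy-minimized crystal structures). The
open fraction over the remaining frames is reported with a **Wilson
score interval**, chosen over the Wald interval for its behavior at
small counts and extreme fractions. Because MD frames are autocorrelated
and the Wilson interval assumes independence, a moving-block bootstrap
(default block length 100 frames, configurable) is provided as an
alternative; for independently drawn synthetic frames the two agree,
while for strongly autocorrelated data the block interval is the honest
one.

The free-energy gap between the states is

$$\Delta G = -RT \ln\frac{p_\mathrm{open}}{p_\mathrm{closed}},
\qquad R = 1.987\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}},$$

so a negative gap favors the open state. The gap is undefined at
$p_\mathrm{open} \in \{0, 1\}$ and the function refuses those inputs
rather than returning an infinity: a 100-ns-scale trajectory that never
visits a state supports no free-energy statement about it.

# Order parameters

The generalized order parameter of a bond vector is computed as the
tensor average over unit-vector components,

$$S^2 = \tfrac{3}{2}\left[\langle x^2\rangle^2 + \langle y^2\rangle^2 +
\langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
2\langle yz\rangle^2\right] - \tfrac{1}{2},$$

the infinite-time plateau of the internal correlation function. This
form needs no time-correlation windowing, which makes it the right
default for trajectories whose length is comparable to the slowest
internal motions; the cost is that slow motions are fully averaged
rather than separated by timescale. Whether to compute over whole
trajectories or windows is left to the caller (the default is the whole
post-equilibration trajectory).

Global motion is removed before vector extraction by least-squares
superposition of each frame onto a reference (first frame by default) on
a fit selection that defaults to backbone heavy atoms; restricting the
fit to secondary-structure residues prevents loop motion from leaking
into the overall-rotation estimate, and the selection is an explicit
argument. No vibrational or zero-point correction is applied to S².

Two closed forms anchor the implementation: vectors uniform in a cone of
semiangle $\theta$ have $S^2 = [\cos\theta(1+\cos\theta)/2]^2$, and an
equal-population two-site jump with inter-site angle $\beta$ has
$S^2 = (1+3\cos^2\beta)/4$. Both are used as oracles in the test suite
(at $10^5$ vectors, agreement within 0.01), together with the exact
rigid limit ($S^2 = 1$) and the isotropic limit ($S^2 \to 0$).

Comparison to experimental order parameters reports the Pearson
correlation over common residues and the slope of the unconstrained
least-squares regression of experiment on simulation; the rescaled
experimental series is returned for plotting. No temperature correction
is attempted when the experimental data were acquired at a different
temperature — that caveat travels with the data, not the arithmetic.

# Loop principal components

The loop PCA pools the Cα coordinates of the handle loop (default
ecRNH residues 89–100) across one or several trajectories, superposes
every frame onto the **iteratively refined mean of the loop itself**,
and diagonalizes the covariance of the 3L Cartesian coordinates.
Fitting on the loop rather than the protein core is a deliberate
choice: the principal components are then pure internal loop-shape
modes (open/closed, one-state/two-state), not mixtures of loop shape
with hinge motion relative to the core. The superposition can be
switched off entirely for frames already expressed in a common frame —
in that mode a purely linear motion yields exactly one nonzero
eigenvalue, which the tests exploit.

Numerical choices: the mean-superposition iteration runs until the mean
shift falls below 1e-9 Å (at most 100 iterations), tight enough that
projections of the fitting set have zero mean per component to 1e-9 and
per-component variance equal to the eigenvalue; eigenvector signs are
fixed deterministically (largest-magnitude entry positive) so repeated
runs are identical; eigenvalues are clamped at zero against roundoff.
Cross-homolog decompositions require a common mapped Cα set, obtained
from pairwise alignments via residue-equivalence maps; insertion
positions (80b) drop out of pooled selections because gap columns are
unmapped.

Whether static crystal structures should enter the fit or only be
projected is genuinely open; the implementation fits on trajectories
and projects anything (frames or single structures) afterwards, which
keeps the mode space independent of how many structures one projects.

# Rotamers, coupling, hydrogen bonds

χ1 is the N–CA–CB–γ dihedral with the standard γ-atom naming (CG for
most residues, CG1 for Val/Ile, OG for Ser, OG1 for Thr, SG for Cys),
signed per IUPAC; the implementation agrees with an independent
four-point torsion implementation to numerical precision. Rotamer
classes use the convention gauche− = −60°, gauche+ = +60°,
trans = 180°, assignment is by nearest canonical center in circular
distance, and the boundary angles (0°, ±120°) are assigned
deterministically by a 1e-9-degree nudge — stated explicitly because
"gauche−" is convention-dependent in the literature.

State–rotamer association uses the contingency-table χ² (no continuity
correction) with Cramér's V as the effect size; expected counts below 5
are flagged. Hydrogen bonds require donor–acceptor heavy-atom distance
≤ 3.5 Å **and** D–H···A angle ≥ 120°, standard practice defaults; both
cutoffs are arguments, and occupancy is monotone in each (relaxing the
distance gate can only add frames, tightening the angle gate can only
remove them). Hydrogen-free topologies (crystal structures) raise a
capability error rather than silently computing heavy-atom geometry.

# Chemical-shift observables

Per-frame chemical shifts come from an external predictor; the exchange
format is a CSV with columns `frame,chain,resnum,inscode,resname,nucleus,ppm`.
The package's contribution is the averaging and validation arithmetic:
arithmetic means per (residue, nucleus) over post-equilibration frames
(coverage recorded when entries are missing from some frames),
secondary shifts as deviations from a random-coil table, and per-region
RMSDs against experimental shifts, with an "Average" region over all
assigned residues. RMSDs use absolute shift values even where plots
show secondary shifts.

The shipped random-coil table is a clearly labelled synthetic
demonstration set (`random_coil_synthetic.csv`): plausible magnitudes
per residue type and nucleus, not a published compilation — no
machine-readable published table could be bundled, and the choice of
table is configurable everywhere it is used. Region definitions are
likewise configuration: the default "Handle" region is ecRNH 71–100
(helices B, C and the loop), but the exact residue set is an analysis
choice, not a fact of the method.

# The synthetic-data generators

Every analysis in the package is validated against generated data with
known ground truth, because the original 100-ns explicit-solvent
trajectories behind this class of analysis are not generally available
and are in any case too expensive to regenerate for testing. The
generators emulate the *statistical structure* the analyses assume, and
nothing more:

- **Two-state trajectories.** States switch between open and closed —
  independently per frame when a stationary `pOpen` is given, or as a
  two-state Markov chain when per-frame transition probabilities are
  given (stationary fraction $k_{co}/(k_{oc}+k_{co})$). Each frame is an
  interpolation between fixed open/closed loop templates chosen so that
  the anchor–tip Cα distance is exactly Normal(basin mean, basin sd)
  for the frame's state; the anchor is named TRP 85 and the tip ALA 93
  so selections written for real structures work verbatim. Default
  basin means are 13.0 Å (open) and 7.5 Å (closed) with sd 0.8 Å —
  values chosen once to place both basins well clear of the 10 Å
  threshold at realistic loop-fluctuation width; the distribution
  panels of published handle-region analyses are graphical, so these
  are package choices, not literature values. Isotropic jitter
  (default 0.05 Å) is added to the non-anchor/tip atoms only, keeping
  the reaction coordinate exactly controlled.
- **Cone vectors** are uniform by area on a spherical cap, giving the
  analytic S² above.
- **Rotamer series** draw a class per frame (optionally biased by the
  frame's state) and add wrapped Gaussian jitter about the class center.
- **Shift tables** put state-dependent means plus Gaussian noise on each
  (residue, nucleus).
- **Sequence sets** realize class-specific residue frequencies at the
  diagnostic positions (88, 95, 101) on a fixed background, with the
  G80b insertion as presence/absence of an inserted G in the column
  between reference positions 80 and 81.

All generators draw from their own seeded stream and restore the
caller's RNG state, so results are bit-reproducible and composable.

What the generators deliberately do **not** emulate: solvent and
force-field energetics, realistic transition kinetics beyond two-state
Markov switching, correlated noise across residues, predictor error
structure in shifts, or phylogenetic correlation among sequences.
Passing tests therefore demonstrate that the analysis chain recovers
known statistical structure without bias — not that any particular
force field or trajectory length reproduces experiment.

# Calibration and problem sizes

The test suite checks the classify→estimate chain two ways. A property
test verifies nominal 95% Wilson coverage over 100 independent
replicates with a binomially sane acceptance band. A calibration test
runs 200 replicates of 50,000 frames at true open fractions 0.15 and
0.40 — the wild-type-like and triple-mutant-like regimes — and demands
≥ 99% empirical coverage; the interval is taken at the 99.9% level for
that check, because demanding ≥ 99% of a 95% interval would fail by
construction and demanding ≥ 99% of a 99% interval would flake on
sampling noise (about a 1-in-3 chance of more than two misses in 200).
The 99.9% level makes the requirement statistically stable while still
detecting any bias in the chain (a distance-classification bias of even
half a basin standard deviation would fail it decisively).

Other standing sizes: order-parameter oracles run at 10⁵ vectors
(closed-form agreement within 0.01), PCA state-separation at 5,000
frames, association power checks at 10⁴–2×10⁴ frames, and sequence
enrichment at 200 sequences per class. These sizes were chosen so that
sampling error sits comfortably below the assertion tolerances.

# Degenerate inputs and error policy

Errors are raised, never silently absorbed, for: structures with zero
atoms or malformed coordinate fields (with the line number); trajectory
atom counts that do not match the topology; superposition of fewer than
three or collinear points; reflections (rejected by forcing
det(R) = +1); residues lacking the atoms an analysis needs (missing
hydrogens name the residue and say that hydrogen-containing input is
required); free-energy gaps at boundary populations; correlations of
constant series; enrichment tests with a single category; and config
files with unknown keys (typo guard). Empty atom selections are legal
but warn. Alternate locations other than blank/'A' are dropped on
reading, the standard crystallographic convention.

# Percent identity and other conventions

Published identities for the same homolog pair differ with the
denominator convention, so `percentIdentity()` states its convention
(identities over columns with at least one non-gap) in the returned
object. The number of tests entering the Bonferroni correction is
supplied by the caller rather than guessed (a corrected level near
0.003 corresponds to about 15 tests at α = 0.05). Growth classes, when
derived from temperatures rather than given, use <20 °C / 20–45 °C /
>45 °C — documented, configurable cutoffs.

# Limitations

- No kinetic analysis: transition counting, rate estimation and Markov
  state models are out of scope; only populations and their free-energy
  gaps are computed, and 100-ns-scale trajectories may not reach
  equilibrium between states.
- Trajectory input is DCD or multi-model PDB; no XTC reader is
  available to pure-R tooling, so XTC users should convert first.
- The shipped random-coil table is a demonstration stand-in; real
  secondary-shift analyses should supply a published table.
- Chemical-shift prediction itself (ring currents, predictor error) is
  external; the package averages and validates predictions, it does not
  make them.
- The structural comparison utilities (equivalence mapping,
  SSE-restricted superposition) are validated on synthetic homolog
  pairs; applying them to real crystal structures requires the user to
  supply the PDB files.
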