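---
title: "Inferring chromatin fiber properties from whole-nucleus simulations"
author: "chromInfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromatin fiber properties from whole-nucleus simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Budding-yeast chromosomes are modelled as generic semiflexible polymers
with a handful of sequence-specific constraints.  Each of the 16
chromosomes is a chain of beads of diameter `W` (nm); the number of beads
follows from the chromosome's genomic length and the compaction `C`
(bp/nm), with `C * W` bp per bead (ceiling division, so no sequence is
dropped and the terminal partial bead keeps full diameter).  Four
structural parameters index a model:

* `P` — persistence length of the fiber (nm), setting the bending rigidity;
* `C` — linear compaction (bp/nm);
* `W` — fiber width, used as bead diameter and excluded-volume scale (nm);
* `L` — rest length of the microtubule tether from each centromere to the
  spindle pole body, SPB (nm).

The flat prior box used for inference is `P` 27–252 nm, `C` 25–110 bp/nm,
`W` 30–60 nm, `L` 200–400 nm.

Nucleus-specific constraints: chains are confined to a sphere of radius
`R_N` = 1000 nm; every centromeric bead is tied to a fixed SPB point on
the envelope by a harmonic spring of rest length `L`; the 32 telomeric
beads feel a constant radially outward force active only within a
100 nm shell below the envelope; and the rDNA region of chromosome 12 is
replaced by 150 enlarged beads whose diameter is set so their net volume
is a fraction `V` (default 14%) of the nuclear volume — this crowding
creates the nucleolar compartment.  The bead diameter for a given `V` is
`2 R_N (V / 150)^(1/3)`, i.e. about 195 nm at the defaults.

## Potentials and their parameterization

The paper-level description leaves the potential forms open; the package
fixes them as follows (all energies in kT, lengths in nm):

* **Bonds**: finitely extensible springs symmetric about the rest length
  `r0` (the mean of the two bead diameters), with a logarithmic divergence
  at `|r - r0| = 0.5 r0` (maximum extension 1.5 `r0`) and central
  stiffness 0.5 kT/nm².  Together with the repulsive cores this prevents
  chain crossing: a bead passing between two bonded beads at maximal
  extension would have to climb tens of kT of overlap energy, and the
  crossing monitor in the test-suite confirms non-adjacent bonds never
  approach closely.
* **Bending**: `U = k (1 - cos theta)` on consecutive bond pairs.  The
  continuum mapping `k = P / b` underestimates the realized persistence
  length by up to ~20% at the bead sizes in play (`b = W = 30` nm is not
  much smaller than the smallest `P` of interest): for the discrete chain
  `<cos theta> = coth(k) - 1/k`, so the continuum choice yields an
  effective `P` of roughly `P - b/2`.  The package therefore calibrates
  `k` by inverting the Langevin function so that
  `<cos theta> = exp(-b / P)` holds exactly, making the tangent
  correlation decay as `exp(-s/P)` at any bead size; the continuum
  mapping remains available (`bendingConstantFromP(..., mapping =
  "continuum")`).  Along the rDNA stretch the same `P` is applied over
  the larger bond length.
* **Excluded volume**: harmonic overlap repulsion (1 kT/nm²) between all
  bead pairs, with per-pair contact distance equal to the mean of the two
  diameters.  A purely repulsive soft core keeps the integrator stable at
  practical time steps while still blocking chain passage.
* **Confinement**: harmonic wall (1 kT/nm²) on the excess of the
  bead-center radius beyond `R_N - W/2`.
* **SPB tether**: harmonic spring, 0.1 kT/nm², rest length `L`, anchored
  at `(0, 0, -R_N)` (any fixed envelope point is equivalent by symmetry).
* **Telomere attraction**: constant outward force of 0.2 kT/nm (2 kT per
  10 nm), active within 100 nm of the envelope — the simplest reading of
  a short-range, purely radial outward force.

## Dynamics and numerical choices

Integration is overdamped (first-order) Langevin dynamics with friction
coefficient 1 and kT = 1, so the free-bead diffusion coefficient is
1 nm² per time unit: each step a bead moves by `dt` times the total force
plus a Gaussian kick of per-axis variance `2 dt`.  Equilibrium statistics
do not depend on the inertial/overdamped choice.  The default `dt` (0.5
for crowded whole-nucleus runs, 0.25 for free-chain studies) keeps
`dt * k < 2` for every harmonic stiffness; a per-step displacement cap of
`W/10` tames the stiff FENE core, and a startup check rejects unstable
settings.  Pair interactions use a Verlet neighbour list (cell-binned for
ordinary beads, direct sweep for the few enlarged rDNA beads) with a
0.8 `W` skin, rebuilt when any bead has drifted half a skin.

Initial configurations: free chains are drawn from the exact equilibrium
ensemble of the discrete worm-like chain (bond lengths at rest, joint
angles from the Boltzmann density of the bending potential), so static
chain statistics need no equilibration.  Confined systems are grown as
soft self-avoiding walks, each chain from its centromere placed within
`2 L` of the SPB — close to its tethered steady state.  A Spearman trend
test on the sampled radius of gyration (and potential energy) flags runs
whose sampling window started before equilibrium.

## Observables

The observable schema mirrors nine dataset classes: median 3D distances
between subtelomeric locus pairs (O1), median angles between a locus and
the axis joining the nuclear and nucleolar centers (O2), distances of
chromosome-12 loci to the nucleolar centroid (O3), median 2D distances on
the longest chromosome (O4), mean 3D intrachromosomal distances (O5),
modes of 3D distances (O6) and of SPB–telomere distances (O7), and two
Hi-C-style summary sets (O8, O9): per-chromosome intra- and
inter-chromosomal mean contact frequencies plus intrachromosomal contact
frequency at genomic separations 25–85 Kb in 5 Kb bins, genome-wide and
centromere-anchored.  For the 16-chromosome yeast genome the default
counts are 62/37/15/12/13/8/7/56/56 = 266 observables.

Numerical conventions: loci map to the bead whose `C*W`-bp tile contains
them (sub-bead interpolation would be false precision); contacts are
distance cutoffs at twice the fiber width (surface proximity),
configurable; 2D projections apply a fresh uniform random rotation per
frame before dropping an axis, so projected statistics are rotation
invariant despite the SPB anisotropy (a fixed laboratory axis is a
config option); distance modes use a Gaussian kernel density with
Silverman bandwidth; contact-frequency-versus-separation curves are
computed at bead resolution and interpolated onto the 5 Kb bin centers,
since the bead size `C*W` need not divide 5 Kb; the distance to the
nucleolus is taken to the rDNA bead centroid (a surface-distance
convention would subtract an effective nucleolar radius and is left to
the caller).  Mean-square displacements are time-and-ensemble averages
over frames; a single multiplicative time-axis scale per experimental
dataset maps simulation time to seconds, fitted by least squares on log
MSD.

## Surrogate grid and inference

Predictions at arbitrary parameter values interpolate a library of
simulations at discrete parameter points (at least two replicas per
point, differing only by seed).  Interpolation is piecewise multilinear
on the tensor lattice: exact at nodes, continuous across cells, and
monotonicity-preserving per cell — the properties that matter for a
surrogate; smoother schemes (RBF, Gaussian processes) were deliberately
not used because they can overshoot between noisy nodes.  Queries outside
the grid are errors: the inference prior box must lie within the grid.

The likelihood is Gaussian and independent across the measurements:
residuals between data `Y_k^E` and interpolated predictions `Y_k^M(Pi)`
have variance `sigma_k^2` parameterized per data group — live imaging,
fixed imaging, and each Hi-C study separately — as `sigma_k = xi_g s_k`,
with `s_k` the measured magnitude (floored at 10% of the dataset's median
magnitude so near-zero measurements cannot acquire zero variance).  Each
`xi_g` is a nuisance parameter with a broad half-normal prior (scale
0.5), estimated jointly and marginalized.  Structural priors are flat on
the box.  Sampling uses an affine-invariant ensemble (stretch-move)
sampler, default 24–32 walkers over a few hundred to a few thousand
steps with 25–40% burn-in; acceptance below 5% triggers a stuck-sampler
warning.  Posterior summaries are kernel-smoothed marginals; the MAP is
the argmax of the smoothed (P, C) marginal (matching the density-based
presentation of the posteriors; the joint best draw is available as an
alternative), and credible regions are highest-density iso-contours
enclosing 68%/95% of the mass.

## Synthetic validation and the reduced-scale study conditions

The validation harness generates noisy synthetic data from a chosen
ground-truth model: `Y_k^S = Y_k^M0 + eps_k`, `eps_k` Gaussian with
standard deviation proportional to the observable magnitude.  Noise
levels are fixed at low = 5%, medium = 10% and high = 20% relative sd —
the high level chosen to sit at or above realistic experimental noise —
and values are clamped to physical ranges.  Recovery experiments repeat
dataset generation and full inference, reporting per-truth RMS errors of
the MAP and credible-region coverage.  The rDNA-volume mismatch
experiment regenerates data from fresh simulations with `W_rDNA` changed
to volume fractions V between 5% and 30% and infers against the unmodified
grid; its control arm (V = 14%) doubles as a held-out-replica check, since
the data then come from simulations not used in the interpolation.

Desk-scale defaults: a three-chromosome genome (chromosomes 1, 4, 12 at
one fifth length, rDNA on the third), nucleus radius 360 nm — preserving
the genome-bp per nuclear volume of the full system — 30 rDNA beads at
V = 14%, fixed `W` = 30 nm and `L` = 130 nm, and a 4 x 3 (P, C) lattice
spanning 40–160 nm by 30–90 bp/nm with 2 replicas per node.  Default runs
use 2.4e5 steps per replica (6e4 equilibration, 200 samples); the test
suite trims this to 1.7e5 steps.  The two recovery truth points sit at
the interior-row nodes (80, 60) and (120, 60): on a coarse reduced
lattice, corner nodes would put the truth on the prior boundary, where
the KDE-mode MAP is biased by density truncation, so corner truths would
measure estimator boundary bias rather than recovery error.

What the reduced harness does and does not show.  Because the truth
points of a recovery experiment are grid nodes, the synthetic data are
noise around exactly the values the surrogate returns there, so node
recovery isolates the inference machinery (likelihood, nuisance
estimation, sampling, MAP) from simulation sampling noise — this mirrors
the core-simulation protocol and is why recovery errors stay far below
the lattice spacing.  Conversely, statistics that depend on the surrogate
*between* nodes are desk-scale limited: with two short replicas per node
the per-observable replica scatter is of order 10–20%, which imprints
jitter on the interpolated surfaces.  Two visible consequences, both
documented by the tests: held-out-replica (control-arm) inference
recovers `C` well but constrains `P` only to about one lattice cell; and
the classic (P, C) ridge under intrachromosomal-only data — level sets of
`(P^(1-nu)/C^nu)^2 s^(2 nu)`, i.e. `C` proportional to roughly `P^0.7` —
is masked by surface jitter on the simulated grid, so the
ridge-versus-localization property is asserted on an analytic grid that
embodies the scaling law exactly.  At full scale (dense grids, long runs,
many replicas) both effects shrink with replica noise.  Likewise the
stretching of pericentromeric chromatin relative to arm-internal regions
— a polymer-brush effect of the 32 arms crowding around the SPB — shows
up only as a noisy positive trend with the reduced genome's six arms and
is therefore a full-scale prediction, not a desk-scale assertion.

## Known limitations

* The chromatin fiber is homogeneous (single `P`, `C`, `W` genome-wide
  except the rDNA); heterogeneous fibers are out of scope.
* Hydrodynamic interactions, replication and explicit microtubule
  dynamics are not modelled; the tether is a spring.
* Contact definitions are cutoff-based; capture-probability weighting
  would change absolute frequencies but not the schema or relative
  comparisons used here.
* Trajectories persist via native R serialization (plus XYZ text export);
  the container format is an implementation detail behind
  `writeTrajectory()`/`readTrajectory()`.
* The full-genome, full-grid workflow (hundreds of simulations of 1e9+
  steps) is supported by the same functions via configuration but is a
  cluster-scale computation and is not exercised by the tests.
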