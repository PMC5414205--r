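# chromInfer

Bayesian inference of average chromatin fiber properties — compaction
*C* (bp/nm), persistence length *P* (nm), fiber width *W* (nm) and
microtubule tether length *L* (nm) — from nuclear-architecture data, built
around whole-nucleus polymer simulations of the budding-yeast genome.

The package is aimed at quantitative chromosome biologists and polymer
modellers who want to (a) simulate all 16 yeast chromosomes as tethered
bead–spring chains inside the nuclear envelope, (b) predict imaging- and
Hi-C-style summary statistics from those simulations, and (c) invert the
map from structural parameters to observables with full uncertainty
quantification.

## The method in brief

Each chromosome is a chain of beads of diameter *W* with *C·W* bp per
bead, bending rigidity set by *P*, excluded volume, spherical confinement
(R_N = 1 µm), a harmonic centromere–SPB tether of rest length *L*, an
outward envelope force on the 32 telomeric beads, and 150 enlarged beads
for the rDNA whose net volume is 14% of the nucleus. Trajectories evolve
by overdamped Langevin dynamics. A library of simulations over a lattice
of parameter points Π = (P, C, W, L), with replicas per point, yields
predicted observables Y_k^M(Π) at any Π by multilinear interpolation.
Given measurements Y_k^E, the posterior follows Bayes' rule

    p(Π, Ξ | D) ∝ p(D | Π, Ξ) p(Π) p(Ξ),

with a Gaussian likelihood whose unknown variances are parameterized per
data group by nuisance scales Ξ (marginalized), flat priors on Π over the
lattice box, affine-invariant ensemble MCMC for sampling, and
kernel-smoothed marginals for MAP estimates and 68%/95% highest-density
credible regions. A synthetic-data harness validates parameter recovery
at 5/10/20% relative noise and under rDNA-volume model mismatch.

## Worked example

A desk-scale run: simulate the reduced three-chromosome validation
system, build the (P, C) model grid, and recover known parameters from
noisy synthetic data.

```r
library(chromInfer)

# 1. discretize and simulate one model
genome <- reducedGenome()
chains <- discretizeGenome(genome, parameterPoint(P = 80, C = 60, W = 30, L = 130),
                           reducedGeometry())
chains
#> BeadChainSet: 3 chains, 345 beads (1800 bp/bead), 30 rDNA beads

# 2. simulation grid + synthetic data + inference
grid <- buildReducedGrid(seed = 42, simConfig = reducedSimConfig(
  nSteps = 2.4e5, sampleEvery = 900, equilibrationSteps = 6e4))
grid
#> ModelGrid: 12 points (P:4 C:3), 214 observables, 2 replicas/point

rec <- recoveryExperiment(grid, reducedTruthPoints(), noiseSpec("high"),
                          nRepeats = 3, seed = 7)
rec
#> RecoveryResult: 6 runs at noise 'high'
#>  truth_id      rms_P     rms_C
#>         1 0.52411793 0.1511514
#>         2 0.04854286 0.1386427
#> coverage: 68% = 0.83, 95% = 1.00
```

Reading the output: at 20% relative measurement noise the maximum RMS
error of the MAP estimates across truth points is about 0.5 nm for the
persistence length and 0.15 bp/nm for the compaction — comfortably
inside the tolerances the validation protocol demands (< 4 nm and
< 2.5 bp/nm at high noise) — and the 95% credible region covers the true
parameters in every run.

The fiber-structure arithmetic connecting an inferred compaction to
nucleosome packing:

```r
nucleosomeDensity(61)            # 4.02 nucleosomes per 11 nm of fiber
fiberMixtureGenomeFractions(c(6, 1))  # 0.857 0.143
```

A full-genome simulation uses the same functions with `yeastGenome()` and
`nucleusGeometry()`; `cliSimulate()`, `cliObserve()`, `cliInfer()` and
`cliValidate()` (or `inst/scripts/chrominfer-cli.R`) run the pipeline
from YAML configurations.

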