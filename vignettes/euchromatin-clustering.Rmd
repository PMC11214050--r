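---
title: "Modeling nucleosome clustering in euchromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nucleosome clustering in euchromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoclust)
```

## The physical picture

Euchromatin in vivo is not a regular 30-nm fiber: electron tomography shows
disordered chains of nucleosomes interrupted by sporadic clusters a few to a
few tens of nanometers across. `nucleoclust` implements a minimal physical
model of how such clusters can arise from three experimentally grounded
ingredients:

1. repressive H3K9me3 marks occur in exponentially correlated patterns along
   the fiber;
2. HP1 reader proteins bind marked histone tails preferentially; and
3. HP1 proteins bound to adjacent nucleosomes oligomerize when the
   intervening linker DNA is short enough for them to bridge.

Because HP1--HP1 contacts are only possible across short linkers, the free
energy gained by oligomerization biases linker lengths downward wherever HP1
is bound, and bound HP1 concentrates where marks are dense. Marked domains
therefore collapse into runs of short linkers -- nucleosome clusters -- while
unmarked stretches stay open.

The model deliberately isolates this mechanism. HP1 interactions are
restricted to adjacent nucleosomes, which is appropriate for euchromatin
where long-range contacts are rare; the package makes no claims about
heterochromatin, where abundant readers and looping change the physics.
Histone H1, chromatin remodelers, DNA unwrapping, electrostatics, and mark
dynamics are all outside the model's scope.

## Stage 1: mark patterns

A nucleosome carries `s_i` in {0, 1, 2} marked tails. Patterns are generated
by `generate_marks()` as two independent stationary two-state Markov chains
(one per tail) whose transition probabilities are solved from the target
marked fraction `rho_target` and the correlation length `corr_length_nuc`:
with per-step eigenvalue `e = exp(-1/corr_length_nuc)`, the flip
probabilities are `a = rho (1 - e)` and `b = (1 - rho)(1 - e)`. This is the
minimal process whose autocovariance is exactly exponential, which is the
only property of real H3K9me3 patterns the model uses. It does not reproduce
other features of ChIP-seq data (broad domains, mappability artifacts,
mark-density heterogeneity beyond the first two moments), so passing tests
here say nothing about those.

The correlation length of H3K9me3 in euchromatin is not pinned down by the
constants above; the package exposes it as a required parameter with a
placeholder default of 10 nucleosomes. `mark_autocorrelation()` normalizes
each lag's autocovariance by its pair count, so exact toy sequences give
exact values; `fit_mark_correlation()` estimates the decay length by a
log-linear fit weighted by the squared autocorrelation, which keeps the
noisiest long lags from dominating.

## Stage 2: HP1 binding thermodynamics

Binding is treated grand-canonically: free HP1 forms a reservoir at chemical
potential `mu_HP1` (kBT units; `mu = log [HP1]_free`, but the concentration
itself is never used). Each nucleosome holds `sigma_i` in {0, 1, 2} HP1s.
The single-nucleosome free energy `binding_free_energy()` has five branches
that count the ways HP1 can occupy marked and unmarked tails, with marked
tails favored by `eps_m = -1.5` kBT; a doubly occupied nucleosome gains one
oligomerization energy `J_int = -3.92` kBT. HP1s on adjacent nucleosomes
interact with energy `J_int * gamma_i * sigma_i * sigma_{i+1}`, where
`gamma_i` indicates a linker of at most `l_c = 15` bp.

`evaluate_ensemble()` computes the partition function by the transfer-matrix
method: each bond carries a 3x3 matrix of Boltzmann weights with the site
energies split half-and-half across the two adjacent bonds, and the trace of
the ordered product gives the partition function under periodic closure.
Numerically, every running product is rescaled to unit max-norm with the log
scale factors accumulated, so the method cannot overflow at any array
length; occupancies come from cached prefix/suffix products in O(M) matrix
multiplications total. Arrays of at least 200 nucleosomes avoid noticeable
finite-size effects from the periodic closure.

The test suite checks the transfer matrix against exhaustive 3^M enumeration
to a relative tolerance of 1e-10 for all M up to 6, including randomized
parameters.

## Stage 3: linker-length sampling

Absent interactions, linker lengths follow a geometric law
`P(l) ~ z^l` on l = 1, 2, ... with `z = 1 - 1/l0` and `l0 = 45` bp, the
typical genome-wide mean. Enabling an interaction across linker `i` changes
the total free energy by `delta_phi <= 0` (computed exactly from two
transfer-matrix evaluations), which reweights the short branch:

P(l) is proportional to `exp(-delta_phi) z^l` for `l <= l_c` and to `z^l`
beyond, with the closed-form normalization
`N = z/(1-z) [(1 - z^l_c) exp(-delta_phi) + z^l_c]`.

`run_sampler()` performs heat-bath Monte Carlo: each update recomputes
`delta_phi` for one linker with all others frozen and redraws that linker
exactly from its conditional law by inverse CDF (branch first, then a
truncated or shifted geometric; no rejection, no tail truncation). Exact
conditional draws leave the joint law invariant under any update schedule.
Two schedules are provided:

* `scan = "random"` picks a uniformly random linker per update, at O(M)
  matrix products per update;
* `scan = "systematic"` (default) visits linkers in order, which allows a
  per-sweep suffix cache plus an incrementally updated prefix product --
  amortized O(1) matrix products per update, roughly 200x faster at
  M = 1000.

Both schedules pass a chi-squared test against the exactly enumerated
Boltzmann marginal of the indicator states on a 4-nucleosome array, and they
agree on long-run observables on larger arrays.

Convergence is not instantaneous: at strong coupling, clusters nucleate and
coarsen collectively, and the short-linker fraction at M = 1000 wanders on a
scale of hundreds of sweeps. The pipeline therefore runs 500 sweeps by
default, discards 250 as burn-in, and reports the time-averaged short-linker
fraction; `sampler_converged()` implements a sliding-window diagnostic
(two consecutive 10-sweep windows within 0.005). These sweep counts are the
package's own choices and are configurable.

## Stage 4: growing the 3D fiber

`grow_chain()` builds an open 3D fiber one base pair at a time under the
kinked twistable wormlike chain. Each linker bp contributes a rotation drawn
from the Boltzmann weight of the discrete elastic energy: the bend angle has
density proportional to `exp(kappa cos theta)` on the sphere with
`kappa = lp/L1` (`lp = 50` nm, `L1 = 0.332` nm/bp), whose mean cosine is the
Langevin-type `coth(kappa) - 1/kappa`; the bend azimuth is uniform; the
twist is Gaussian with mean `tau = 2 pi / 10.5` rad per bp and variance
`L1/lt` (`lt = 100` nm). Positions advance by exactly `L1` along the new
tangent, so contour length is conserved to machine precision, and frames are
re-orthonormalized every 500 steps (drift stays below 1e-9 over 1e5 bp).

A subtlety worth recording: `tau` is stored in radians per base pair, and
the per-bp twist mean is `tau` itself -- not `tau * L1`, which would
correspond to treating `tau` as a per-nm rate and gives a helical repeat of
~33 bp per turn instead of 10.5.

Each nucleosome inserts a fixed rigid kink: 147 bp wrapped as a left-handed
superhelix of radius 4.19 nm, 1.7 turns, and 2.39 nm pitch by default. The
exact crystallographic entry/exit transform is not reproduced here; the wrap
is a parametric approximation, every parameter is configurable, and no
quantitative acceptance test depends on the kink -- only trend-level cluster
statistics do. The recorded nucleosome pose is the DNA entry pose (the first
nucleosome sits at the origin with the identity frame); `turns = 0` gives a
degenerate straight pass-through used as a control. The 1D model's periodic
closure has no 3D counterpart, so a `linker_state`'s last linker is ignored
when growing the open fiber.

Recovered observables define the validation: bare-DNA tangent correlations
decay with length `-L1 / log(coth(kappa) - 1/kappa)` = 49.83 nm (within the
5% band around the nominal 50 nm), the helical repeat is 10.5 bp per turn,
the twist variance recovers `lt = 100` nm, and the mean squared end-to-end
distance matches the closed-form wormlike-chain expression.

## Stage 5: steric relaxation

Chain growth ignores excluded volume, so grown fibers are relaxed by
nucleosome-resolution Metropolis Monte Carlo (`relax()`). Two energy terms
enter:

* **Sterics.** The shifted, truncated Lennard-Jones repulsion
  `V0 [(2R/D)^12 - 2 (2R/D)^6 + 1]` for `D < 2R` and 0 otherwise, with
  `V0 = 1` kBT and `R = 4.19` nm. The bracket is zero-valued at contact and
  non-negative inside it; it is implemented exactly in this form, including
  its slope discontinuity at `D = 2R`. Coincident nucleosomes get a large
  finite energy (certain rejection) rather than an error.
* **Elasticity.** Each inter-nucleosome virtual bond (exit pose of one
  nucleosome to entry pose of the next, `L = l * L1`) carries a quadratic
  form: `lp/(2L)` times each of the two bend angles squared (bond vector
  against exit and entry tangents), `lt/(2L)` times the squared twist
  deviation from `tau * l`, and a stretch term `k_s/2 (|r| - L)^2` with
  `k_s = 90 lp^2 / L^4`, the stiff-limit wormlike-chain estimate of the
  longitudinal stiffness. Transverse shear is penalized implicitly through
  the two bend half-joints. The published constants behind the fully
  parameterized shearable chain are not printed in the source material, so
  this parameterization is the package's own; it is zero at the ground
  state, quadratic in small deformations, and exposed via
  `elastic_model()`.

The move set mixes crankshaft rotations of internal segments about the axis
joining their anchors (endpoints fixed), rigid pivots of terminal segments,
and single-nucleosome perturbations, at probabilities 0.4/0.3/0.3 with
amplitudes tuned to roughly 30--50% acceptance and a default segment cap of
20 nucleosomes. Rigid segment moves change only the two boundary bonds'
elastic energies and the moved-against-unmoved steric pairs, so energy
differences are evaluated on exactly those terms; with the segment cap this
direct pair loop is O(N) per move at the fiber sizes used (a spatial cell
list was considered and found unnecessary at N = 200--1000). Energy totals
are maintained incrementally in extended precision and agree with full
recomputation to better than 1e-8 kBT.

Correctness is tested against a closed-form reference: with orientations
frozen and translation-only moves, a two-nucleosome system's bond vector has
separable Boltzmann marginals in `cos(theta)` and `|r|` that are sampled
directly by rejection and compared to the Metropolis trajectory.

## Stage 6: cluster statistics

A cluster is a maximal run of at least four consecutive nucleosomes whose
internal linkers are all at most `l_c`. Cluster size is the minor principal
axis of the member positions projected on a coordinate plane: the square
root of the smaller eigenvalue of the summed (not count-normalized) outer
product matrix about the 2D centroid, the analogue of chromatin widths
measured on tomography slices. The summed convention makes sizes grow with
membership; the gyration-tensor normalization is available via
`normalized = TRUE` but off by default, and no doubling to a "diameter" is
applied. Ensemble distributions pool sizes over configurations and the XY,
XZ, and YZ planes; pooling three fixed planes is only weakly sensitive to a
global rotation of the ensemble, and exact rotation invariance is not
claimed. Histograms use fixed-width bins (default 5 nm), with the mass of
the first two bins reported by the sweep runner as a compactness summary.

## Orchestration, defaults, and reproducibility

`run_pipeline()` chains all six stages for an ensemble of replicates;
`sweep_grid()` runs grids over mark abundance and chemical potential, and
`preset_sweep()` exposes three standard experiments: abundance bands 0--2%,
8--10%, and 14--16% at `mu = -9.7`; potentials -9.8/-9.7/-9.6 at 10--12%
marks; and four abundance bands at `mu = -9.66` for histogram comparisons.
Abundance bands are realized by drawing each replicate's fraction uniformly
within the band, since the conditions are reported as ranges rather than
points. The four bands of the histogram preset are the package's choice
(0--2, 4--6, 8--10, 14--16%), spanning low to high euchromatic abundance.

Configuration is a nested YAML-serializable list (`default_config()`,
`validate_config()`; unknown keys are rejected before any computation). One
master seed spawns independent per-replicate and per-stage streams, so runs
are bit-reproducible and single stages can be re-derived; replicate streams
are shared across sweep cells, which pairs conditions and sharpens trend
comparisons. Defaults follow the printed model constants throughout
(`eps_m = -1.5`, `J_int = -3.92`, `l_c = 15`, `l0 = 45`, `lp = 50`,
`lt = 100`, `L1 = 0.332`, 10.5 bp/turn, 147 bp wrap, `R = 4.19`, `V0 = 1`,
minimum cluster size 4), with 1D observables from 20 replicates of
1,000-nucleosome arrays, 3D fibers of 200 nucleosomes, and 1e5 relaxation
steps.

The test suite uses scaled problem sizes chosen to keep the full run under a
minute of simulation per property: trend checks use 10 replicates per
condition, 500 sweeps, and 20,000 relaxation steps; polymer-statistics
checks use 60--120 chains of 10,000 bp. At these sizes all monotone
orderings (cluster size and short-linker fraction versus abundance and
chemical potential, and the rightward histogram shift at `mu = -9.66`) are
reproduced.

## A small worked example

```{r example, eval = FALSE}
library(nucleoclust)

cfg <- list(
  marks = list(M_1d = 1000L, M_3d = 200L, rho_band = c(0.14, 0.16)),
  binding = list(mu_hp1 = -9.7),
  sterics = list(n_steps = 20000L),
  ensemble = list(n_replicates = 10L),
  seed = 101L
)
res <- run_pipeline(cfg, quiet = TRUE)
res$short_linker_fraction # ~0.36 at these conditions
res$mean_cluster_size     # ~12 nm pooled minor-axis mean
```

## Known limitations

* The synthetic mark generator captures only the stationary fraction and the
  exponential two-point correlation of real H3K9me3 patterns.
* The entry/exit kink and the coarse elastic constants are documented
  approximations; absolute cluster geometries inherit their uncertainty,
  which is why quantitative validation rests on the 1D thermodynamics and
  bare-DNA polymer statistics while 3D claims are trend-level.
* The 1D binding model is exact, but the 3D relaxation makes no
  thermodynamic-observable claims beyond cluster geometry.
* Only nearest-neighbor HP1 interactions are modeled; results do not
  transfer to heterochromatin.
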