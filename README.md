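# nucleoclust

Physical simulation of nucleosome clustering in euchromatin driven by
cooperative HP1 binding to H3K9me3-marked chromatin.

Electron tomography of interphase nuclei shows euchromatin as a disordered
chain of nucleosomes punctuated by small clusters (roughly 5–25 nm), not as
a regular 30-nm fiber. `nucleoclust` is for chromatin biophysicists and
epigenomics researchers who want a mechanistic, parameter-explicit model of
how such clusters emerge from three ingredients: exponentially correlated
H3K9me3 mark patterns, preferential HP1 binding to marked histone tails, and
short-range HP1–HP1 oligomerization across linkers of at most l<sub>c</sub> = 15 bp.

## The model

A 1D array of M nucleosomes carries marks s<sub>i</sub> ∈ {0,1,2} (marked
tails) and HP1 occupancies σ<sub>i</sub> ∈ {0,1,2}, treated
grand-canonically at chemical potential μ<sub>HP1</sub> (all energies in
k<sub>B</sub>T):

- single-nucleosome binding free energy φ<sub>bind</sub>(σ<sub>i</sub>; s<sub>i</sub>)
  with a marked-tail preference ε<sub>m</sub> = −1.5 and an intra-nucleosome
  pair term J<sub>int</sub> = −3.92 for σ = 2;
- nearest-neighbor coupling φ<sub>int</sub> = J<sub>int</sub> γ<sub>i</sub> σ<sub>i</sub> σ<sub>i+1</sub>,
  where γ<sub>i</sub> = 1 iff linker i is ≤ 15 bp;
- the partition function Ξ = Tr ∏<sub>i</sub> T<sub>i</sub> evaluated exactly by the
  transfer-matrix method (3×3 bond matrices, periodic closure, max-norm
  rescaling so arbitrary M cannot overflow), giving Φ = −log Ξ and all
  occupancies ⟨σ<sub>i</sub>⟩.

Linker lengths follow a geometric law with mean l<sub>0</sub> = 45 bp,
reweighted by exp(−ΔΦ) on the short branch, where ΔΦ ≤ 0 is the exact
free-energy change of enabling one linker's interaction. A heat-bath Monte
Carlo sampler redraws linkers from their exact conditional law. Sampled
linkers seed a base-pair-resolved 3D fiber under the kinked twistable
wormlike chain (l<sub>p</sub> = 50 nm, l<sub>t</sub> = 100 nm, 0.332 nm/bp,
10.5 bp/turn, 147-bp superhelical wrap per nucleosome), which is then
relaxed by Metropolis Monte Carlo under linker elasticity plus a shifted
Lennard-Jones nucleosome repulsion (R = 4.19 nm, V<sub>0</sub> = 1
k<sub>B</sub>T). Clusters are maximal runs of ≥ 4 nucleosomes joined by
short linkers, sized by the minor principal axis of their 2D-projected
inertia matrix.

See the vignette (`vignettes/euchromatin-clustering.Rmd`) for assumptions,
parameter meanings, and numerical choices.

## Worked example

High-abundance euchromatin (14–16% of tails marked, μ = −9.7) versus a
nearly unmarked control, 10 replicates each:

```r
library(nucleoclust)

cfg <- list(
  marks = list(M_1d = 1000L, M_3d = 200L, rho_band = c(0.14, 0.16)),
  binding = list(mu_hp1 = -9.7),
  sterics = list(n_steps = 20000L),
  ensemble = list(n_replicates = 10L),
  seed = 101L
)
res <- run_pipeline(cfg, quiet = TRUE)
round(res$short_linker_fraction, 4)
#> [1] 0.3585
round(res$mean_cluster_size, 2)
#> [1] 12.02

cfg$marks$rho_band <- c(0, 0.02)
lo <- run_pipeline(cfg, quiet = TRUE)
round(c(lo$short_linker_fraction, lo$mean_cluster_size), c(4, 2))
#> [1] 0.2862 4.33
```

At 0–2% marks the short-linker fraction sits at the interaction-free
baseline, 1 − (44/45)<sup>15</sup> ≈ 0.286, and the few clusters that occur
by chance are small (pooled minor-axis mean 4.3 nm). Raising the marked
fraction to 14–16% pulls a quarter more linkers under the 15-bp cutoff and
triples the mean cluster size to ~12 nm — marked domains have collapsed into
clusters. `sweep_grid()` with `preset_sweep("mark_abundance")`,
`"hp1_potential"`, or `"cluster_histogram"` runs the standard condition
grids; a thin CLI wrapper is installed at `inst/scripts/nucleoclust`.

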