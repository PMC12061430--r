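# booldyn

Synchronous Boolean network simulation of cell-fate decisions under
hypoxia, biomechanical signals and TGF-β.

Solid tumors are hypoxic, stiff and crowded, and those microenvironmental
signals — not only mutations — drive the epithelial–mesenchymal transition
(EMT), proliferation arrest and apoptosis resistance that underlie
metastasis. Boolean regulatory network models are the standard
coarse-grained formalism for reasoning about these switches: each gene or
signal is ON/OFF, all nodes update simultaneously by logic rules, and the
stable phenotypes of the cell are exactly the attractors of the dynamics.
`booldyn` is for systems biologists who build and interrogate such models:
it provides the full simulation and analysis stack —

* **Model I/O** — a BooleanNet-style rule dialect (`Name *= A and not B`,
  `inputs:` declarations, `module` groupings), round-trip safe, with
  syntactic link counting.
* **Dynamics** — deterministic synchronous update plus stochastic layers:
  per-node flip noise `p`, per-step Bernoulli clamping (partial knockdown /
  hyper-activation with probability `q`), and non-saturating environmental
  inputs (level in [0, 1], resampled each step).
* **Attractors** — exhaustive enumeration with exact basin weights
  (≤ 22 free nodes), and the stochastic sampling protocol for large
  networks: `N` noisy time courses of length `T` per environment
  (defaults `N = 100`, `T = 25`, `p = 0.02`, all binary input
  combinations), every visited state descended deterministically, cycles
  canonicalised and deduplicated.
* **Phenotyping** — module-level signatures (epithelial / hybrid E/M /
  mesenchymal, cycling / quiescent, apoptotic) mapping states, attractors
  and trajectory windows to named cell fates.
* **Protocols** — windowed experiments over cell ensembles: pulse
  sequences, dose series on the 0–80% log2 ladder, two-axis environment ×
  perturbation grids over mutation backgrounds, continuous runs with
  apoptosis-aware live-step accounting, and a seven-pulse
  metastatic-cascade preset.
* **Validation** — Welch t-test scoring of perturbed vs. control ensembles
  against curated in vitro assay directions: a match requires a
  significant change in the expected direction of at least 5% of the
  average of the two compared values (or, for "no change", the absence of
  such a change).

Everything is runnable offline: the package ships the 6-node EMT core
switch, a 21-node hypoxia–EMT demonstration network, a seeded
random-network generator and a synthetic assay panel. Published models in
the same rule dialect load through `load_published_model()`.

## Worked example

```r
library(booldyn)

m <- hypoxia_demo_model()
m
#> <boolean_model> hypoxia_demo: 21 nodes (6 inputs), 48 links
#>   module core: Hypoxia, GF, TGFb_ext, Stiff_ECM, ECM_attached, Density_High
#>   module EMT: SNAI1, miR200, ZEB1, Ecadherin
#>   module Hypoxia: PHD, VHL, Hif1a_basal, Hif1a_High, Src
#>   module Proliferation: Myc, CyclinD, CellCycle
#>   module Survival: Apoptosis
#>   module TGFb: TGFb_secr, TGFbR

# What does a mitogen-stimulated cell on a stiff ECM do under hypoxia?
land <- enumerate_attractors(m, c(Hypoxia = 1, GF = 1,
                                  Stiff_ECM = 1, ECM_attached = 1))
land
#> <bn_attractor_set> enumerate: 1 attractor(s) over 32,768 states
#>   environment: Hypoxia=1, GF=1, TGFb_ext=0, Stiff_ECM=1, ECM_attached=1, Density_High=0
#>   fixed point, basin 1.0000
classify_attractor(land$attractors[[1]], demo_signatures())
#>           EMT Proliferation      Survival
#> "Mesenchymal"   "Quiescent"       "Alive"
```

Every initial state descends to a single fixed point: hypoxia drives full
EMT (ZEB1 on, E-cadherin lost) with cell-cycle arrest — the mesenchymal,
quiescent, surviving phenotype.

```r
# The metastatic cascade: 7 microenvironment pulses, 100 cells
res <- run_cascade_preset(m, steps_per_pulse = 100, ensemble = 100, seed = 1)
dominant_phenotypes(res, "EMT")
#> [1] "Epithelial"  "Epithelial"  "Mesenchymal" "Mesenchymal" "Mesenchymal"
#> [6] "Mesenchymal" "Epithelial"
```

High density protects the epithelial cell from hypoxia-driven EMT
(pulse 2); a density drop triggers EMT (pulse 3); the mesenchymal state —
sustained by autocrine TGF-β — survives detachment in circulation
(pulse 5, where an epithelial cell would die of anoikis); high density at
the secondary site reverses it (pulse 7, MET).

```r
# Score the model against a curated assay panel
v <- run_validation(m, system.file("extdata", "demo_assays_synthetic.csv",
                                   package = "booldyn"), seed = 11)
v
#> <bn_validation> 12 assays (13 tests): 100.0% assays matched (12/12),
#>   100.0% tests matched (13/13)
```

`tidy(v)` returns the per-test table (means, t statistic, p value,
relative change, verdict); `glance(v)` the one-row summary;
`autoplot()` methods draw trajectory rasters and per-window phenotype
fractions.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "booldyn.R", package = "booldyn"))') \
  attractors --model emt_switch --mode enumerate --out attractors.csv
```

Subcommands: `attractors`, `simulate` (protocol YAML in, long-format CSVs
out), `validate` (assay CSV in, report + summary out), `fixtures export`.
Every run honors `--seed` and writes a JSON manifest sufficient to
reproduce its outputs bit-exactly.

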