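---
title: "Methods: synchronous Boolean simulation of hypoxia-driven EMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchronous Boolean simulation of hypoxia-driven EMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(booldyn)
```

## The modeling framework

`booldyn` simulates Boolean regulatory networks under synchronous update:
each node holds 0/1 and all nodes apply their logic rules simultaneously at
every discrete time step. The framework targets single-cell fate decisions
in the hypoxia / mechanosensing / TGF-β signaling context — epithelial–
mesenchymal transition (EMT), proliferation and apoptosis — where
synchronous Boolean logic is the established coarse-grained formalism: it
makes the attractor structure (stable phenotypes and oscillations) exact
and enumerable, at the cost of abstracting kinetic detail.

A deterministic synchronous step is wrapped in three stochastic layers,
applied in a fixed order each step:

1. every non-input node's rule is evaluated on the previous state
   simultaneously;
2. every environmental input is resampled as Bernoulli(level), so a level
   in (0, 1) models a *non-saturating* environment (for example 40%
   hypoxia exposure);
3. every clamped node is overridden to its forced value with probability
   `q` — `q = 1` is a hard knockout or constitutive activation, fractional
   `q` a partial knockdown/hyper-activation re-drawn independently every
   step;
4. every non-input, non-clamped node is flipped with probability `p`
   (biological noise).

With `p = 0` and all levels binary the step is deterministic, and
probability-0/1 events consume no random draws, so deterministic runs are
bit-identical across seeds. Noise deliberately excludes inputs (they define
the environment being studied) and clamped nodes (a clamp is an
experimental intervention, not a fluctuating species). Partial knockdowns
are re-drawn every step with no dwell time; this is the simplest semantics
consistent with a per-step Bernoulli environment, and it produces the
intermittent signaling loss that makes fractional perturbations of
autocrine loops informative. Dwell-time alternatives (bursty inputs) are a
known omission.

## Attractors and basins

Two routes to the attractor landscape:

* `enumerate_attractors()` descends from *every* state of the free-node
  hypercube (non-input, non-hard-clamped nodes) and reports exact basin
  weights. It is exact and serves as the internal oracle, but is capped
  (default 22 free nodes) by the 2^f state space.
* `sample_attractors()` implements the stochastic protocol used for large
  networks: for each combination of binary environmental inputs, `N`
  noisy time courses of length `T` (defaults `N = 100`, `T = 25`,
  `p = 0.02`) are run from uniform-random initial states, and every
  visited state is descended noise-free to its attractor.

Cycles are canonicalised by rotating them to start at the lexicographically
smallest state (states compared as 0/1 strings in node order), so the same
cycle entered at any phase deduplicates to one attractor; attractors are
ordered by descending basin weight with the canonical key as tie-break.

**Two basin estimates.** Sampling reports two weights per attractor.
`basin` is the fraction of all visited states descending to the attractor —
the direct reading of the sampling protocol. Because states along a noisy
time course concentrate near attractors, this estimates a *noise-tilted
occupancy measure*: it converges, as `N` grows, to a quantity that can
differ by several percentage points from the deterministic basin weight
(we measured persistent ~8-point differences on 12-node random networks).
`initial_basin` is the fraction of the `N` uniform-random initial
conditions descending to the attractor — an unbiased estimator of the
deterministic basin weight that `enumerate_attractors()` reports, with
plain binomial error sqrt(w(1−w)/N). Use `basin` to describe where a noisy
cell population actually spends its time, and `initial_basin` when
comparing against exhaustive enumeration; the package's own
oracle-equivalence tests do exactly that.

## Phenotype signatures

A phenotype signature is a partial node-state pattern attached to a module
(for example Mesenchymal: `ZEB1 = 1, miR200 = 0, Ecadherin = 0` in module
EMT). `classify_state()` returns, per module, the highest-priority
satisfied signature (priority 1 highest), else `"unclassified"`; two
satisfied signatures of equal priority are an error, so shipped signature
sets are designed mutually exclusive and priorities act only as a safety
net. Window statistics report, per time window, the fraction of live steps
matching each phenotype (fractions per module sum to 1, `"unclassified"`
included) and the mean ON-fraction of every node.

## Experiment protocols

`experiment_spec()` fixes the reproducible unit of simulation: a model, an
initial condition (an explicit state, or a named phenotype resolved to the
unique matching attractor of the initial environment), an ordered window
schedule (each window with its own environment, clamps and noise), an
ensemble size and a master seed. Two run modes:

* **fixed mode** — every cell runs the schedule once; all steps count.
* **continuous mode** — the schedule repeats until a total *live-step
  budget* is consumed; a cell whose state matches the death signature (by
  default the apoptosis-execution phenotype) is terminated — the step on
  which death is detected is its last live step — and replaced by a fresh
  cell restarted from the spec's initial condition. Total recorded live
  steps equal the budget exactly; when the budget is not divisible by the
  ensemble size the final step counts only the first remaining cells.

Restart-from-initial-condition (rather than re-drawing from the attractor
distribution) was chosen because it models a replacement cell entering the
assay in the prepared condition, and keeps the continuous run's statistics
interpretable as "live cell time under the protocol". Dose series default
to the log2-style ladder 0, 0.625, 1.25, 2.5, 5, 10, 20, 40, 80% used for
titration experiments; grids sweep two axes (input levels or clamp
probabilities) over any set of clamp backgrounds and return long-format
tables.

Ensembles advance as one state matrix under a single seeded RNG stream.
This vectorisation is what makes pure-R simulation fast enough for 10^5
live-step budgets; the contract is bit-exact reproducibility for a fixed
seed. We deliberately did not implement per-trajectory counter-derived
substreams (which would make individual cells order-independent): no
analysis in the package depends on per-cell stream identity, only on
ensemble-level reproducibility.

## The validation statistic

`compare_assay()` scores a perturbed simulation arm against its control
with a two-sided unpaired Welch t-test at α = 0.05 (Welch because ensemble
arms routinely have unequal variances; the pooled-variance test is
config-exposed). A comparison **matches** an expected in vitro direction
when the change is significant, in that direction, and at least 5% of the
average of the two compared values; it matches an expected "no change"
when the change is non-significant, exactly zero, or below that same 5%
threshold. The 5% floor prevents large-`n` ensembles from flagging
biologically meaningless differences. When both arms are degenerate (zero
variance — Boolean ensembles saturate easily), significance falls back to
exact equality of means. Per-cell readouts are mean node activities (or
phenotype-match fractions) over the assay's window. An assay with several
statistical tests matches only if all of them match; failing assays whose
sources contradict each other are flagged `contradictory-source` rather
than plain mismatches. No multiple-testing correction is applied, matching
standard practice for this kind of directional concordance screen.

## Fixture models: what they emulate, and what they do not

The bundled networks are compact, fully documented stand-ins constructed
to satisfy the circuit logic established in the hypoxia-EMT literature;
they are not transcriptions of any published full-scale rule set (a
published model in the same rule dialect can be loaded with
`load_published_model()`, which reports node/link counts for checking
against its publication).

* `emt_switch_fixture()` — the 6-node EMT core: the SNAI1/miR-34 and
  ZEB1/miR-200 double-negative feedback loops with E-cadherin as epithelial
  readout. Under no EMT signal its stable states are epithelial and
  mesenchymal; under signal, hybrid E/M and mesenchymal — three stable
  phenotypes in total, with the hybrid state only reachable while signal
  persists.
* `hypoxia_demo_model()` — 21 nodes coupling oxygen sensing (PHD
  hydroxylation, constitutive VHL, basal vs. strongly stabilised HIF-1α),
  mechanosensing (ECM stiffness/attachment, cell density),
  autocrine TGF-β (ZEB1 → secretion → receptor), the EMT switch, a minimal
  Myc/Cyclin D proliferation axis and an anoikis-capable apoptosis node.
  It reproduces, deterministically: hypoxia-driven EMT with cell-cycle
  arrest, independence of that EMT from TGF-β receptor knockout and from
  VHL hyper-activation, density-mediated protection from EMT, anoikis on
  detachment under normoxia but not hypoxia, TGF-β-induced apoptosis of
  epithelial cells on soft ECM only under normoxia, VHL-loss-driven EMT
  with arrest rescued only by joint Myc + Cyclin D hyper-activation, and
  the seven-pulse metastatic cascade (EMT in the hypoxic primary tumor,
  anoikis resistance in circulation, density-driven MET at the secondary
  site).
* `random_boolean_network()` — seeded random networks (uniform k-regulator
  choice, uniform truth tables rendered as sum-of-products rules; constant
  tables redrawn by default) for property testing.

What the fixtures deliberately omit: migration machinery, ROS, NF-κB/IKK,
FIH, β-catenin/LEF1, origin licensing and the phase-switch cell-cycle
detail of full-scale models. Consequently, passing the bundled test suite
demonstrates that the *machinery* (update semantics, attractor statistics,
protocols, validation scoring) is correct on circuits with the right
qualitative logic; it does not by itself validate any full-scale published
network, whose behaviors must be checked by loading its own rule file and
assay table through the same pipeline.

The bundled `demo_assays_synthetic.csv` is likewise a synthetic assay
panel (12 assays, 13 tests) whose expected directions encode the
demonstration model's literature-anchored behaviors; it exercises the
validation pipeline end to end and is labelled synthetic in its file name.

## Numerical and design choices

* **Link counting** is syntactic: every distinct (regulator, target) pair
  where the regulator appears in the target's rule, with no
  essential-variable reduction; self-loops count, and each environmental
  input carries the conventional self-loop of its `A *= A` serialisation.
  This makes the count reproducible from the rule text alone.
* **Descent cap**: deterministic descent errors beyond 10^6 steps — the
  state space of any model this package can hold is far smaller, so
  hitting the cap signals a bug rather than a long transient.
* **Enumeration cap**: 22 free nodes by default (4M states); beyond it the
  caller is directed to sampling.
* **Visited-state descent** uses a full successor table when the free-node
  count is ≤ 16 and memoised hash walks above that.
* **Basin sums**: both estimators sum to 1 per environment to within 1e-9
  by construction.
* **Seeds**: every stochastic entry point takes an explicit seed;
  deterministic computations consume no randomness at all.
* **Problem sizes** in the shipped tests and acceptance script — 50 random
  12-node networks with `N = 500` sampled trajectories, ensembles of
  100–120 cells over 60–100-step windows, a 10^3-step continuous-mode
  budget — were chosen as the smallest sizes at which the binomial error
  bands of the assertions are decisively narrower than the effects being
  tested.

## Known limitations

Synchronous update only (no asynchronous or generalized-asynchronous
schemes); two-valued logic only; single-cell, non-interacting ensembles
(no tissue or cell–cell coupling); acute-response logic in the
demonstration model (no chronic-hypoxia HIF-2α/HIF-3α program); Boolean
approximation of graded inputs via per-step Bernoulli resampling without
dwell times. The `basin` weight from sampling should not be compared
against exhaustive enumeration (use `initial_basin`; see above).
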