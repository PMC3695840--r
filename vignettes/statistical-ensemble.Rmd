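---
title: "The statistical-ensemble model of heterogeneous NF-κB signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The statistical-ensemble model of heterogeneous NF-κB signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nfkbse)
```

## The model and its assumptions

The package simulates the IKK–IκB–NF-κB–A20 signaling module as a
mass-action reaction network of 28 species: the three IKK forms (neutral
`IKKn`, active `IKKa`, inactive `IKKi`), free cytoplasmic and nuclear
NF-κB, A20 protein and mRNA, and — for each IκB isoform α, β, ε — the free
cytoplasmic and nuclear protein, its mRNA, the cytoplasmic and nuclear
IκB:NF-κB complexes, and the IKK-bound complexes. The reaction list and
both rate-constant columns ship as a plain TSV
(`inst/extdata/reaction_table.tsv`); `nfkb_model()` compiles it into a
stoichiometry matrix plus per-flux substrate indices, so the right-hand
side is literally `S %*% v(x)` with `v_r = k_r [A][B]`. One rate-constant
symbol can feed several fluxes (e.g. `Da` governs dissociation of both the
free and the NF-κB-bound kinase complex), and the shared degradation rows
(`Kdeg`, `W*`) expand to one first-order flux per listed substrate. A
reaction-coverage test enumerates table rows against implemented fluxes.

Assumptions inherited with the formulation: deterministic mass-action
kinetics (no intrinsic molecular noise), well-mixed cytoplasmic and nuclear
compartments, transcription linear in nuclear NF-κB, and no
receptor-level dynamics — stimulation is the single reaction
`IKKn -> IKKa` proceeding at `TR * K1 * [IKKn]` for a dimensionless dosage
`TR`.

### Units

The table does not carry units. The package fixes concentrations in µM and
time in seconds; under this calibration the bimolecular constants
(0.05–1 µM⁻¹s⁻¹), the total NF-κB concentration (0.06 µM), and the
transport rates (10⁻³–10⁻² s⁻¹) produce the hour-scale translocation and
oscillation dynamics the model is known for, which is the only calibration
consistent with all the magnitudes at once. User-facing time is always in
hours.

### Compartment volumes

`Kv` (= 5) is the cytoplasm:nucleus volume ratio. Transport fluxes are
written in cytoplasmic concentration units in both directions: for a
transport reaction with rate constant `k`, the cytoplasmic species changes
by `k·C` and the nuclear species by `Kv·k·C`. This is the convention of
the model lineage this network extends, and it conserves molecule amounts
exactly — the volume-weighted total NF-κB,
`sum(cytoplasmic NF-κB species) + sum(nuclear NF-κB species)/Kv`, is an
algebraic invariant of the stoichiometry. The conservation test asserts it
to 10⁻⁹ relative along stimulated trajectories, and it is the anchor that
pins the convention down: the alternative (dividing the return flux by
`Kv` instead) also conserves amounts but slows nuclear export five-fold
and visibly delays the first translocation beyond the behavior this model
family is documented to produce. Induced transcription (`C1`, `U*`) is
written directly in cytoplasmic mRNA units, `d[mRNA]/dt = k·[NFkBn]`;
nuclear NF-κB acts there as a catalyst, so the invariant is untouched.

## Simulation protocol

Every run starts from the resting condition — all NF-κB free in the
cytoplasm at `NFkB_total`, everything else zero — and equilibrates for a
fixed 33 h with `TR = 0` before stimulation. Equilibration is *warned*,
not enforced: with the fitted column the slow IκBε turnover
(`We ≈ 4·10⁻⁵ s⁻¹`) still drifts by a few percent over a second 33 h, so
`equilibrate()` warns only above a relative drift of 10⁻⁵ s⁻¹ (configurable).

The integrator is classical fixed-step RK4, compiled, with `dt = 1 s` and
output sampling every 60 s by default. `dt = 1 s` sits two orders of
magnitude below the fastest first-order loss timescale in the stimulated
network (~10 s), and the step-halving test verifies the expected
fourth-order error scaling plus < 10⁻⁶ relative agreement against halved
steps and against an adaptive stiff solver. States are clamped at zero
before each flux evaluation; a post-step value below −10⁻⁶ µM (far beyond
truncation undershoot) is treated as divergence and reported with time and
species.

Dose-response sweeps hold each dosage of an ascending logarithmic grid
(default 20 points/decade over 10⁻⁵–10⁻¹, plus `TR = 0`) for 30 h,
carrying the state from step to step, then retrace the grid downward from
the forward sweep's end state; the response per step is mean nuclear NF-κB
over hours 20–30. Hysteresis is declared when the forward/backward gap
exceeds 5% (configurable) anywhere on the grid.

## Ensemble generation

Extrinsic noise is modeled by drawing each kinetic rate constant uniformly
from `(x₀(1−χ), x₀(1+χ))`; `χ = 0.3` is the working heterogeneity. The
draw is Latin hypercube: the interval is cut into `N` equal-probability
strata (equal width, since the density is uniform), one value is drawn per
stratum, and strata are assigned to replicates by an independent random
permutation per symbol. Each symbol derives its own RNG stream from the
master seed and the symbol name, so enlarging `sampled_symbols` never
reshuffles existing columns, and identical configurations are bitwise
reproducible. `Kv` and `NFkB_total` are structural constants and stay
fixed by default; zero-valued rates (including knocked-out synthesis
rates) have zero-width intervals and stay exactly zero, which keeps
knockouts exact under sampling. Which constants the original study
randomized is not recorded; the default randomizes all nonzero rate
constants, and the set is configurable.

Knockouts zero both transcription channels of the targeted gene — induced
(`U*`, or `C1` for A20) and constitutive (`Y*`, or `C2`) — since a gene
deletion removes all mRNA synthesis.

## Feature extraction and pattern classification

The six features of a nuclear NF-κB profile are the first maximum, its
time (first translocation time), the time between the first two peaks
(first period), and the first minimum, second maximum, and steady state,
each normalized by the first maximum. The steady state is the mean over
the final 10% of the stimulated window; features that do not exist (the
period of a single-peaked response) are `NA` and flagged, never zero.

Peak detection is deliberately a declared convention, because the
published pattern fractions depend on it and no exact rule accompanies
them: an interior local maximum counts as a peak when its amplitude is at
least `1e-4 · NFkB_total` and its prominence (height above the higher of
its two flanking valleys) is at least 5% of the global maximum; this keeps
integration-scale wiggles on decaying tails from counting as oscillations.
Troughs are the minima between consecutive kept peaks, so extrema
interleave by construction. The classifier is then: no peak →
monotonic-increasing (this class also absorbs flat non-responders, since
the four-way taxonomy has no "no response" bin; a separate `responder`
flag records them); one peak → single-peaked; two or more peaks →
sustained oscillation when the second/first amplitude ratio is ≥ 0.6 *and*
at least 3 peaks fall in the window, otherwise damped oscillation. All
thresholds are exposed in `feature_settings()`. An exhaustive brute-force
oracle reproduces the detector on synthetic and simulated signals, and
scale/shift equivariance of the features is tested.

## The fitting heuristic

`fit_to_targets()` implements a coordinate search on the SE-average
features: generate an ensemble at the current center and χ, extract the
SE-average features, compute relative deviations from the targets, pick
the worst-deviating feature, and scale the two rate constants assigned to
it by `(1+η)` or `1/(1+η)` (direction = correlation sign × sign of the
needed change). Rejected steps (worst deviation did not improve) roll back
and halve η; when η underflows, χ decreases step-like by 0.05 and η
resets, so the χ values visited are non-increasing. All ensembles inside a
fit share one seed (common random numbers), making deviation changes
attributable to the parameters and the whole fit deterministic.

The feature-to-parameter assignment defaults to the top-2
rank-correlations on a pilot ensemble, and can be overridden with a fixed
table. The defaults η = 0.2, internal tolerance 0.15, `N_fit` = 200 (with
final verification at the analysis size) are design choices: multiplicative
steps keep rates positive, and 0.2 reaches a 1.5-fold error within two
accepted steps. One caveat the tests document: the feature set is sloppy —
different parameter combinations produce nearly identical SE-average
features — so parameter *recovery* (as opposed to feature matching) is only
well-posed when the search is restricted to identifiable parameters via
the override table, and only for parameters the features are actually
sensitive to (`K1`, for instance, both speeds IKK activation and drains
the IKKn pool at `TR = 1`, leaving every feature almost unchanged).

## What the synthetic generator does and does not emulate

`synthetic_signal()` produces constant, saturating-exponential,
damped-cosine, and sustained-sine waveforms with seeded Gaussian noise.
These exercise the analytics (peak rules, feature closed forms, classifier
boundaries such as a 0.3-per-cycle amplitude decay falling below the 0.6
sustain threshold) independently of the ODE model. They do not emulate
measurement noise structure, baseline drift, or the asymmetric spiky
waveforms of real single-cell reporters, so passing analytics tests shows
the conventions are implemented as declared — not that the conventions are
optimal for experimental recordings.

## Numerical and statistical problem sizes

Analysis-grade runs use 1000 replicates. The test suite and the
acceptance script run the same pipelines at 200 replicates, 4-replicate
dose-response sweeps on a 10-points/decade grid, and `N_fit` = 100 for the
recovery experiment; these sizes give pattern fractions a sampling error
of a few percentage points, small against the contrasts being tested.

## Known limitations

- The two rate-constant columns of the shipped table behave differently:
  the nominal column produces faster, less damped nuclear NF-κB
  oscillations (second peak near 2.8 h in the reference replicate) than
  the fitted column (second peak near 4.9 h, first-period mode ≈ 4.4 h,
  essentially no sustained-oscillatory replicates at χ = 0.3). The
  fitted column's smaller `Kprod/Kdeg` ratio (a 3.2× smaller IKK pool) is
  the dominant driver. Statistics that are sensitive to oscillation
  frequency — first-period modes, sustained fractions, SE-average
  second-peak times, small-dosage pattern mixes — therefore depend
  strongly on the column choice; the tests compute them for the fitted
  column, the package default.
- No intrinsic (stochastic) kinetics, no receptor/ligand dynamics, no
  autocrine feedback, and no correlations between sampled parameters; the
  extrinsic-noise law is uniform and time-independent by design.
- The dynamic-pattern taxonomy is one of several reasonable conventions
  (classification by periodicity or steady-state level would partition
  differently); the thresholds are exposed precisely because downstream
  fractions are convention-sensitive.
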