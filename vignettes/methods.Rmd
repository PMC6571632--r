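---
title: "Model and methods behind hippsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind hippsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hippsim simulates a 14-cell CA3–CA1 hippocampal microcircuit built from
shift-register compartmental neurons, applies a progressive
synaptic-deletion protocol that emulates Alzheimer's-type degradation of
CA3 afferents, and analyses the resulting spike trains with classical and
chaos-theoretic statistics. This vignette records the model, its
assumptions, and the choices made where the design was genuinely open.

## The shift-register neuron

Every cell has 16 compartments: an axon segment, the soma, four basal and
ten apical dendritic compartments. A compartment carries at most one
synapse class towards its drive (AMPA, NMDA-paired AMPA, or GABA-A) and
three shift registers E, M, I — one per receptor class — whose boxes each
represent 0.5 ms of future membrane time course. All boxes start at the
resting potential ReP = −80 mV. A presynaptic spike writes a PSP template
into the register starting at the arrival cycle; each cycle, box 0 of each
register is consumed and a fresh resting box enters at the tail.

The template is a discrete alpha shape (difference of exponentials,
normalised so the extremum equals the cell's tabulated EPSPd or IPSPd):
the amplitude is the paper-level parameter; the kinetics are free model
constants. Defaults: AMPA and GABA-A rise 2 ms / decay 6 ms; NMDA rise
5 ms / decay 25 ms, with peak `nmda_frac` × EPSPd (`nmda_frac = 0.5`).
The slow NMDA kinetics justify the separate M register: its head
accumulates across theta-burst arrivals where the AMPA trace has already
decayed. Template support ends when the amplitude falls below 1 % of the
peak; the register length is twice the longest support, which the engine
asserts is enough for any injection with the configured conduction delay
(one box, 0.5 ms, per connection).

The accumulated local potential of compartment k superposes the three
register heads, `S_k = ReP + ΣX (X_k,0 − ReP)`, and the somatic drive is
`ReP + Σ_k w_eff(k) (S_k − ReP)` with `w_eff = w_base × M_mult`. Base
weights fall linearly along each dendritic branch from 1 at the most
proximal compartment to the cell's LSW at the most distal (somatic
synapses weigh 1; the axon carries none). A cell fires when its drive
strictly exceeds its threshold; firing resets every register box of the
cell to ReP and imposes 1.5 ms (three whole cycles) of refractoriness, so
the minimum interspike interval is 2 ms. No floor or ceiling clipping is
applied to register values: inhibition may transiently drive S_k below
ReP, and the quiescence fixed point (no input ⇒ drive = ReP forever) is
exact.

The update is stage-synchronous: spikes fired in cycle t are delivered at
t + delay, so the iteration order over cells within a cycle is
irrelevant and runs are bit-reproducible for a given seed.

## The memory (LTP) rule

Plasticity lives at the NMDA-bearing compartments (mossy-fiber synapses
on CA3, Schaffer synapses on CA1). Each such compartment carries a charge
accumulator C ≥ 0:

* **Gate.** Charge may change only in cycles where `S_k > CaMT` with
  CaMT = −68 mV, the magnesium-unblock threshold. The prose description
  of a "local threshold (ca. 70 mV)" is read as ≈ −70 mV membrane
  potential and unified with the formal −68 mV gate; the formal statement
  wins.
* **Accumulation.** While gated, `C ← C + exp(10·ΔV) − 1` with
  ΔV = (M_k,0 − ReP) expressed in **volts**. Taken literally in
  millivolts the exponential overflows for any physiological
  depolarization; the volts reading keeps single-cycle increments O(0.1),
  commensurate with a forgetting quantum of 1. The rule is evaluated
  every 0.5 ms cycle — the arrival of a presynaptic spike governs when
  the M register is written, not when charge integrates. (An
  arrival-only variant was tried and leaves the memory system inert: the
  gate coincides with an arrival too rarely for C ever to exceed ~0.3.)
* **Forgetting.** On a slow cadence (`decay_every`, default one
  simulated second) `C ← C − FQ` if `C > FQ`, with the forgetting
  coefficient FQ ≥ 1 settable per cell (default 1). Whether the decay is
  tied to gating is not constrained by the rule's source; it runs
  autonomously here, and the cadence is configurable. The asymmetry this
  creates — many small increments per second versus one bounded decrement
  — is the rapid-rise/slow-decay character of the rule, and is verified
  as a property test.
* **Read-out.** The weight multiplier is `M_mult = 1 + ln(C + 1)/6` (1 at
  zero charge, growing logarithmically, never below 1) and the reported
  memory time is `ln(C + 1)/clog` with clog = 2.3026, i.e. log10(C + 1).
  The printed source of this formula is typographically corrupted; this
  disambiguation is a package decision, chosen because it makes the
  multiplier exactly 1 at C = 0 and dimensionally consistent.

## Circuit and inputs

The wiring follows the standard anatomy of the region: entorhinal layer 2
onto CA3 pyramidal and basket distal apical dendrites; dentate mossy
fibers onto CA3 pyramidal mid-dendrites (the dentate relay cell is
transparent); CA3 recurrent collaterals onto basal dendrites; Schaffer
collaterals onto CA1 pyramidal mid-dendrites; entorhinal layer 3 onto
CA1; basket cells inhibiting local pyramidal somas and the adjacent
basket cell; pyramidal cells exciting local basket and O-LM cells; O-LM
cells inhibiting the local pyramidal distal tuft (their targets are not
specified by the source model; standard anatomy is used). Synapse counts
per pathway are fixed so each pyramidal cell carries 13 excitatory
synapses — 4 entorhinal, 5 mid-dendritic, 4 recurrent — giving the
8 × 13 = 104 total that the deletion protocol is defined against.

Inputs are inhomogeneous Poisson processes with rate
`r(t) = rate_peak · max(0, cos(2π·8·t + φ))`, sampled by thinning;
the Poisson family itself is a modelling decision (the source states only
that populations "fire" with theta-modulated strength). EC2 and EC3 are
π out of phase; septal inhibition is strongest when EC2 is weak (φ = π,
configurable). Each of the 100 entorhinal cells is assigned to exactly
one synapse slot of its target field by a balanced seeded draw. The
alternative reading — all 100 cells converging on every target cell — was
implemented and rejected: it produces self-sustaining recurrent activity
that survives complete CA3 deafferentation, contradicting the lesion
phenomenology the model exists to express. Six medial-septum trains map
one-to-one onto the six interneuron somas (their regional division is not
specified; one train per soma is the simplest consistent split).

## Calibrated defaults

The source model prints cell parameters (LSW, EPSPd, IPSPd) but not
input rates, spike thresholds, PSP kinetics or lesion timing. These are
free constants, fixed once as follows and not revisited per run:

| parameter | default | units | note |
|---|---|---|---|
| `ec_rate_peak` | 13 | Hz | peak per entorhinal cell; mean rate is peak/π |
| `dg_rate_peak` | 9.5 | Hz | dentate mossy drive |
| `ms_rate_peak` | 40 | Hz | septal theta trains |
| thresholds | −55 | mV | all cell types |
| `nmda_frac` | 0.5 | — | NMDA peak as fraction of EPSPd |
| lesion window | 500–8200 | ms | uniform spacing of the 44 deletions |
| `FQ` | 1 | — | forgetting quantum, per cell |
| `decay_every` | 2000 | cycles | one forgetting step per second |

They were calibrated so that ten-seed mean pyramidal spike counts of the
10 s control and pathology runs sit inside the published ±1 SD bands
(CA1 control 92.25 ± 29.0; CA1 pathology 24.0 ± 9.4; CA3 pathology
42.75 ± 10.3); the acceptance script recomputes these from scratch. Two
calibration findings are worth recording. First, entorhinal layer-3
input is net-inhibitory for CA1 pyramidal cells at low interneuron
thresholds, because basket cells receive it at full distal weight
(LSW = 1): equalising the interneuron threshold with the pyramidal one
(−55 mV rather than a more excitable −58 mV) restores the expected sign.
Second, CA1 pathology activity is structurally tied to CA3 survival —
with LSW = 0.2 the direct entorhinal pathway sustains little CA1 firing
once CA3 dies — which bounds how close the CA1 pathology count can get
to its printed mean while CA3 stays in band.

## Nonlinear analysis choices

The analysed signal is each cell's ISI sequence (the quantity the source
plots); binned rates can be substituted. Delay selection takes the first
autocorrelation lag at or below 1/e, falling back to the first local
minimum. The false-nearest-neighbor test uses Kennel's two criteria
(Rtol = 15, Atol = 2 SDs, 1 % acceptance, Theiler window = τ) with one
guard: candidate pairs whose augmented distance is numerically zero are
true neighbors (an exactly periodic sampled orbit otherwise flags its
recurrences as false through a 0/0 ratio). The Grassberger–Procaccia
estimator excludes pairs inside the Theiler window and pairs at
numerically zero distance (the r = 0 atom of a periodic orbit is not part
of the continuous scaling law), lays a logarithmic radius grid between
the 1st and 95th percentile of pair distances, and fits the slope of
log C(r) where 0.01 ≤ C(r) ≤ 0.4 — below the saturation shoulder, above
finite-sample noise. On closed-form fixtures this recovers D2 ≈ 1 for an
incommensurately sampled sine and D2 ≈ 2 for planar uniform noise;
entropy anchors (0 for constant series, log2 n_bins for a uniform
histogram) are exact. A commensurately sampled sine is deliberately *not*
used as the curve fixture: its orbit is a finite point lattice whose true
correlation dimension is 0.

Degenerate inputs error early and by name: constant series for delay or
FNN estimation, zero-variance series for correlations, fewer than 100
embedded points for D2, identical constant groups in the two-sample tests
(p = 1 with a warning).

## Problem sizes and what the tests show

The test suite and acceptance script use 10 s runs (20 000 cycles) in
ten seed pairs for the headline comparisons, 1–2 s runs for engine
properties, and series of 400–600 samples for the nonlinear fixtures.
The synthetic inputs emulate theta-modulated firing-rate envelopes and
their antiphase organisation; they do not emulate grid/place structure,
phase precession, spike-history dependence (bursting, adaptation) or
correlated noise across input cells, so passing tests speak to the
lesion/plasticity mechanics of the model, not to quantitative predictions
for biological recordings.

## Known limitations

* Point-amplitude PSPs with fixed kinetics; no dendritic cable physics,
  no conductance-based synapses, no NMDA voltage dependence beyond the
  binary unblock gate.
* Spike generation is a hard threshold on a weighted sum with full
  register reset; no adaptation or relative refractoriness.
* The charge accumulator is a scalar per compartment; no intracellular
  calcium kinetics.
* Synaptic compensation (up-scaling of surviving synapses) is not
  modelled; deletion is pure removal.
* Group statistics at n = 4 cells (or 10 seeds) have little power; the
  package reports the tests, the design limits their sensitivity.
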