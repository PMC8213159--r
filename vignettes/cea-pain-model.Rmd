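---
title: "The CeA pain model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CeA pain model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceapain)
```

## The model in brief

`ceapain` simulates the two dominant inhibitory neuron populations of the
central nucleus of the amygdala — pro-nociceptive PKCδ neurons and
anti-nociceptive SOM neurons — as individual agents in the left and right
hemispheres. A stimulation protocol (one integer current per tick, 0–220
pA) drives damage accumulation, stochastic firing, network inhibition, and
an emergent scalar pain output

$$P_i \;=\; \sum_{\substack{\text{PKC}\delta\\ \text{LF or RS}}}
\frac{d_i}{100}\,Fr_i \;-\; \sum_{\substack{\text{SOM}\\ \text{LF or RS}}}
Fr_i ,$$

summed over both hemispheres. Because PKCδ contributions are weighted by
damage while SOM contributions are not, an uninjured circuit sits at a
negative baseline (tonic analgesia) and sensitization pushes pain upward.

### Agents

1640 agents: 800 typed (PKCδ or SOM) neurons per hemisphere plus 20 passive
"Other" neurons per hemisphere. Other neurons exist solely as sinks for
network links; they carry no physiological state, never transmit, and never
enter the pain sum. Typed neurons carry:

| variable | meaning | value |
|---|---|---|
| `Loc`, `Type` | hemisphere, marker type | fixed at initialization |
| `Freq` | LF / RS / Spont | changes only via SOM conversion |
| `t_L` | damage latency (ticks) | uniform integer in [40, 80] |
| `t_S` | sensitization period (ticks) | uniform integer in [50, 150] |
| `d` | damage, % of full sensitization | 0 at start, non-decreasing |
| `Fr` | firing rate (Hz) | re-sampled every tick |

Firing-class proportions at initialization are 25/48/27 % (LF/RS/Spont) for
PKCδ and 18/27/55 % for SOM. The three population variants are 50:50
(PKCδ:SOM, both hemispheres), 60:40 (56:44 after renormalizing the
published 48 %/38 % marker counts — see below), and 30:70 (left 30:70,
right 37:63, from reporter-line cell counts).

### Per-tick schedule

1. `Cum_S` increments when `S_i ≥ 120` pA (inclusive).
2. Damage: if `Cum_S > t_L` and `S_i ≥ 120`, `d ← min(d + 100/t_S, 100)`.
3. Spontaneous SOM neurons at `d = 100` convert to RS until RS SOM reaches
   48 % of SOM neurons.
4. LF/RS neurons sample `Fr = (1 − d/100)·X + (d/100)·Y`, with `X`
   (unsensitized) and `Y` (sensitized) truncated-normal draws keyed by
   (type, frequency, stimulation level). Spontaneous neurons fire at 2.838
   (PKCδ) / 4.887 (SOM) Hz. Silenced types fire at 0 Hz.
5. Network inhibition: each link carries its transmitter's rate; a typed
   neuron whose summed input is ≥ 15 Hz has its rate zeroed for the tick.
6. Pain and system observations are recorded.

## Tunable parameters that matter

* **`max_in` / `max_out`** (links per neuron, default 3:3). 0:0 disables
  the network; 1:1 gives every neuron exactly one output (1600 links);
  3:3 and 5:5 produce ≈4800 and ≈8000 links. Larger networks inhibit more
  neurons — the majority of them SOM, because SOM→SOM connections are the
  most probable (0.55) — which *raises* pain.
* **Inhibition threshold** (Hz, default 15). Chosen so a single active
  neuron can silence a target, while low-rate neurons must act
  cumulatively. The comparison is inclusive (`≥`): the operational
  submodel's wording wins over the design-concept wording ("exceeds"),
  and a single 15 Hz input inhibits.
* **SOM share per hemisphere** (`pct_som_left/right`). The sensitivity
  analysis identifies this as the dominant parameter: ±0.05 moves mean
  pain by thousands of units during and after injury.
* **Conversion target** (0.48). Evaluated per hemisphere by default;
  global evaluation differs only through rounding and is available via
  `conversion_scope = "global"`.

## The synthetic firing-rate table

The truncated-normal parameters that calibrate firing against slice
recordings are not redistributable, so the package ships a **synthetic**
table (`synthetic_distribution_table()`,
`inst/extdata/synthetic_firing_rate_table.csv`). It preserves, by
construction, the qualitative features the model's behavior rests on:

* rates increase with injected current in every cell;
* PKCδ LF/RS sensitized means lie above unsensitized means (injury makes
  PKCδ fire faster), SOM sensitized means lie below (injury slows SOM);
* sensitized means of the two types are comparable in magnitude, so that
  SOM's higher in-degree under the default connection probabilities keeps
  SOM the majority among inhibited neurons throughout a run, as observed
  in the network experiments.

Means grow linearly over the 120–220 pA grid, σ = 0.25 μ, support
[0.5 μ, 1.5 μ]. Consequences for interpretation: baseline (≈ −2000) and
injured pain levels with this table happen to land near published
magnitudes, but only *signs, orderings, and counts* — conversion totals,
link counts, the exact zero under pre-injury SOM silencing, model
orderings, sensitivity rankings — are meaningful claims; absolute pain
values are not. What passing tests show about real data is correspondingly
qualitative: the test suite asserts structure and direction, never absolute
pain magnitudes.

Truncated normals are sampled by inverse-CDF restricted to `[min, max]`
(renormalized, not clamped). Degenerate cells (σ = 0 or min = max)
collapse to the clamped mean, which the tests exploit to make the mixture
arithmetic deterministic.

## Numerical and algorithmic choices

* **Network termination.** The construction loop draws transmitters
  uniformly among typed neurons with free out-slots; a draw whose sampled
  receiver type has no free in-slot is discarded and redrawn (to-Other
  draws always succeed), and a transmitter is abandoned after 100 failed
  draws. Under the default probabilities this terminates with every
  neuron at full out-degree: 1600 links at 1:1 and the theoretical maxima
  4800/8000 at 3:3/5:5, within 2 % of the published averages. Alternative
  termination readings (requiring transmitters to also have free in-slots,
  or stopping once every neuron is saturated on either side) were
  prototyped and discarded: they undershoot the published 1:1 count by
  20 %.
* **Self-loops** are disallowed (no biological reading); **parallel
  links** between the same ordered pair are allowed.
* **No within-tick inhibition cascade** by default: link strengths are
  frozen at pre-inhibition rates, making the evaluation order irrelevant.
  A cascading mode (`cascade = TRUE`) evaluates neurons in random order
  and removes silenced neurons' outputs for later evaluations.
* **Damage snapping.** Accrual adds `100/t_S` per tick in floating point;
  values within 1e-9 of 100 snap to exactly 100 so that full
  sensitization — which gates the conversion rule — occurs after exactly
  `t_S` accrual ticks.
* **Conversion count.** "Convert until RS SOM reaches 48 %" is
  implemented as converting `⌈0.48 · n_SOM⌉ − n_RS` eligible neurons
  (uniformly at random), equivalent in distribution to one-at-a-time
  conversion. In the 30:70 model this yields 118 (left) + 106 (right)
  = 224 conversions.
* **Current binning.** Off-grid currents in [120, 220] map to the nearest
  tabulated 20 pA level, ties upward; the shipped protocols only use
  on-grid values. Below 120 pA, LF/RS neurons neither fire nor accrue
  damage.
* **Stimulation-level rounding at 130 pA** therefore goes to 140, and
  currents outside [0, 220] are rejected at file-reading time with the
  offending line number.
* **RNG streams.** One root seed derives named substreams (init, network,
  dynamics) so each stage is independently reproducible;
  `run_replicates()` uses consecutive seeds `base_seed + 0..n−1`.
* **Performance.** `run_simulation()` precomputes the truncation CDF
  bounds per table cell (one `qnorm` per draw) and accumulates incoming
  link strengths with a single cumulative sum over receiver-sorted links,
  so a 250-tick, 1640-agent run takes ≈0.35 s.

## Design decisions where the design was open

* **60:40 model from reported proportions.** Published marker counts give
  48 % PKCδ and 38 % SOM with overlap and unlabeled cells excluded;
  renormalizing the pair and rounding to whole percent yields 56:44
  (`renormalize_reported_proportions(0.48, 0.38)`).
* **Category rounding.** Fractional type and frequency counts round to
  the nearest integer per category, with any remainder absorbed by the
  largest category so totals are exact.
* **Sensitivity rebalancing.** Perturbing a connectivity probability by
  ±0.05 is absorbed by the same transmitter row's to-Other probability
  (the non-modeled remainder); perturbing the SOM share complements the
  PKCδ share; perturbing an RS share rescales the type's LF and Spont
  shares proportionally.
* **Effect-size CI.** Hedges' *g* confidence intervals use the standard
  large-sample variance `(n1+n2)/(n1·n2) + g²/(2(n1+n2−2))`; the zero-SD
  group arising from the structurally exact zero of SOM-silenced
  uninjured runs borrows the comparison group's SD.
* **Ramp plateaus.** The ramp protocol splits its duration as evenly as
  possible across the seven plateaus 120→140→…→220→120, remainder to the
  leading plateaus.

## Problem sizes used by the tests

The suite exercises the study conditions at sizes chosen to keep a full
run of the package's checks fast on a laptop: 100 builds per network
variant for link statistics, 5 replicates per cell of the silencing grid
(matching the study's own n = 5 convention), and 15 replicates per
parameter value for the sensitivity analysis (the function's default is
the study's 100; the ranking and sign assertions are clear-cut already at
15, with the SOM-share sensitivities about four times the runner-up's).
Replicate batches elsewhere use 1–5 runs of 12–250 ticks.

## Known limitations

* No spatial geometry: connection probability is independent of distance,
  and secondary/tertiary dendritic branching is not modeled.
* Rates, not spikes: membrane potentials, spike timing, and synaptic
  plasticity are outside the model; link weights are fixed at creation.
* The synthetic table limits quantitative claims (see above); users with
  access to calibrated truncated-normal parameters can supply them via
  `load_distribution_table()` with identical semantics.
* All PKCδ neurons are treated as pro-nociceptive and all SOM neurons as
  anti-nociceptive; subpopulations with reversed roles are not
  represented.
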