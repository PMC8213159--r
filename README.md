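# ceapain

Agent-based simulation of pain-related circuitry in the central nucleus of
the amygdala (CeA).

## The scientific problem

The CeA — the "pain nucleus" of the amygdala — contains two largely
non-overlapping populations of GABAergic neurons with opposing roles in
nociception: protein kinase C-delta (PKCδ) expressing neurons are
pro-nociceptive, somatostatin (SOM) expressing neurons anti-nociceptive.
Their relative abundance in the left and right hemispheres is controversial,
and their interaction through local inhibitory connections is hard to probe
directly. `ceapain` implements an agent-based model that integrates
cell-type-specific slice-physiology and expression data into a single
framework, letting neuroscientists run silencing, connectivity, and
proportion experiments *in silico* before committing to wet-lab work.

## The model

1640 agents represent CeA neurons: 800 PKCδ/SOM neurons per hemisphere plus
20 passive "Other" neurons per hemisphere. Each typed neuron carries a
firing-frequency class (late-firing LF, regular-spiking RS, or spontaneous),
a damage latency period `t_L ~ U{40..80}`, a sensitization period
`t_S ~ U{50..150}`, and a damage level `d ∈ [0, 100]`.

Each tick, driven by a stimulation protocol `S_i` (integers, 0–220 pA):

- A global counter `Cum_S` counts ticks with `S_i ≥ 120` pA.
- **Damage** (injury): once `Cum_S > t_L` and while `S_i ≥ 120`,
  `d ← min(d + 100/t_S, 100)`. A neuron at `d = 100` is sensitized.
- **Adaptation**: spontaneous SOM neurons at full damage convert to RS, one
  at a time, until RS neurons make up 48% of SOM neurons (27% pre-injury).
- **Firing rates**: LF/RS neurons draw an unsensitized rate `X` and a
  sensitized rate `Y` from truncated normal distributions keyed by (type,
  frequency, stimulation level) and mix them by damage:
  `Fr = (1 − d/100)·X + (d/100)·Y`. Spontaneous neurons fire constantly
  (2.838 Hz PKCδ, 4.887 Hz SOM).
- **Inhibition**: a stochastically built, intra-hemisphere directed network
  (connection-type probabilities 0.20/0.10/0.70 from PKCδ and
  0.15/0.55/0.30 from SOM to PKCδ/SOM/Other; per-neuron in/out limits such
  as 3:3) transmits each transmitter's rate; a neuron whose summed input
  reaches 15 Hz is silenced for the tick.
- **Pain** (emergent output, arbitrary units):

  `P = Σ_PKCδ,LF/RS (d/100)·Fr − Σ_SOM,LF/RS Fr`

  summed over both hemispheres — negative at baseline (tonic SOM analgesia),
  rising during injury and staying elevated after.

The experiment layer adds replicate batches, the three population variants
(50:50, 60:40, 30:70 PKCδ:SOM), cell-type silencing (chemogenetic-inhibition
analogue), one-at-a-time local sensitivity analysis (`S± = ΔP/±0.05`), and
Hedges' *g* effect sizes with 95% CIs for comparison against behavioral
data.

The bundled firing-rate table
(`inst/extdata/synthetic_firing_rate_table.csv`) is **synthetic**: it
encodes the published qualitative structure (rates rise with current, PKCδ
fires faster after injury, SOM slower) but not measured values, so absolute
pain magnitudes are indicative while signs, orderings, and counts are
meaningful.

## Worked example

```r
library(ceapain)

cfg <- cea_config("50:50")                    # equal PKCδ:SOM, 3:3 network
protocol <- generate_protocol("constant", 250, 120)
sim <- run_simulation(cfg, protocol, seed = 1)
sim
#> CeA simulation: 250 ticks, 4800 links, seed 1
#>   pain: first -2002.4, last 781.0; final mean damage 100.0%
#>   spontaneous-to-RS SOM conversions: 168

sim$records$pain_total[c(10, 105, 240)]
#> [1] -2053.9435  -550.3128   909.9159
```

Pain starts around −2000 (anti-nociceptive SOM tone dominates an uninjured
circuit), climbs through the injury period as neurons sensitize, and stays
elevated (positive) after damage saturates. 168 spontaneous SOM neurons
converted to regular spiking (taking RS SOM from 27% to 48%).

Silencing experiments and effect sizes:

```r
sil <- silencing_experiment_table(n = 5, base_seed = 11)
subset(sil$summary, injury == "injured" & condition == "intact")
#>   model condition  injury       mean       sd
#> 1 30:70    intact injured -1126.6180 68.16395
#> 2 50:50    intact injured   821.3805 63.59428
#> 3 60:40    intact injured  1615.1983 52.48275

hedges_g(1, 1, 5, 0, 1, 5)
#> Hedges' g = 0.9032 [-0.4130, 2.2195] (95% CI)
```

Injured pain rises with the PKCδ share (60:40 > 50:50 > 30:70); silencing
PKCδ after injury is analgesic, silencing SOM hyperalgesic, and silencing
SOM before injury gives exactly zero pain.

A thin command-line front end over the same functions is installed at
`inst/cli/ceapain.R` (subcommands `simulate`, `replicates`, `sensitivity`,
`table4`, `effectsize`, `make-protocol`, `make-fixture`), writing CSV
results plus a YAML manifest that reproduces each run bit for bit.

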