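# dawave

Desk-scale simulator for a dual-pathway dopaminergic spiking neural network
that learns tactile preferences by classical conditioning — no robot
required. The package targets researchers studying reward-modulated
plasticity and temporal credit assignment in spiking networks: it provides
the neuron/synapse dynamics, the four plasticity rules, the circuit
builders, a synthetic trackball-sweep generator, the experiment protocols
(traveling-wave development, conditioning, extinction) and the metrics
(dopamine burst/dip detection, wave scoring, weight maps) needed to
reproduce the conditioning, preference and extinction experiments on one
CPU.

## The model

Neurons are two-variable quadratic (Izhikevich) units,

    v' = 0.04 v^2 + 5v + 140 - u + I,    u' = a (b v - u),

spiking at 30 mV with reset (v, u) <- (c, u + d), driven through
conductance synapses with AMPA, NMDA (magnesium-block), GABA_A and GABA_B
receptors (decay 5 / 100 / 6 / 150 ms). Learning combines:

* **E-STDP / I-STDP** — exponential and Mexican-hat spike-timing kernels
  that develop and stabilize a *traveling wave* across a 512-column
  prefrontal sheet, so a neuron's x-position encodes time since cue onset;
* **DA-STDP** — pairings accumulate in an eligibility trace c (tau = 1 s)
  and weights move by w' = c·d, where d is the dopamine concentration
  (1–20 uM) of the target pool — the bridge across the cue–reward delay;
* **DA-PSF** — dopamine multiplies the effective excitatory conductance of
  D1-bearing striatal and intermediate populations by (0.9 + 0.1 d).

Touch enters through a fast, somatotopic pathway and a slow (700-ms
delayed) hedonic pathway that converge on posterior insular cortex; their
conjunction gates dopamine bursts, and the slow-pathway weights (0.03 vs
0.04) set the robot's directional preference.

## A worked example

Generate a synthetic hand sweep and ask the tactile pathway whether it
earns a dopamine burst:

```r
library(dawave)

set.seed(42)
sweep <- sample_sweep("down")
sweep
#> <sweep_record> down, 1130 ms, 6.69 in/s, 223 events, noise 10.9%

cfg <- default_config()
net <- build_incremental_network(cfg, th_pic_w = list(
  up = 0.04, down = 0.04, left = 0.04, right = 0.04))
report <- run_tactile_trial(net, sweep, seed = 3)
report$classification
#> [1] "single"
round(report$bursts)
#>   start  end
#> 1  1340 1420
```

The sweep lasted 1130 ms and produced 223 touch events; with all
slow-pathway weights at 0.04 it elicited a single dopaminergic population
burst once the delayed C-fiber drive and the fast somatotopic events
coincided in the insular sheet — the reward signal the conditioning
experiments learn from. Dropping a channel's weight to 0.03 makes bursts rare for that
direction, which is how the simulated robot's preferences are set.

Developing and probing the prefrontal wave:

```r
sheet <- build_pfc_sheet(cfg)            # 512 x 4 + 512 FS, one channel
sheet <- develop_pfc(sheet, seed = 11)   # volleys at the left edge every 4 s
probes <- run_wave_probes(sheet, 20, seed = 99)
mean(!probes$ok); median(probes$latency_ms, na.rm = TRUE)
#> [1] 0.1
#> [1] 2000.5
```

After development the left-edge volley reaches columns 508–511 at a median
of about 2000 ms, inside the 1950–2050 ms window that defines a successful
traversal.

## Command line

A thin CLI over the same functions lives in `inst/scripts/snn.R`:

```sh
Rscript inst/scripts/snn.R describe --seed 1 --out out/
Rscript inst/scripts/snn.R gen-touch --direction down --n 100 --out out/
Rscript inst/scripts/snn.R probe-waves --n 200 --out out/
```

Each subcommand writes a manifest (config hash, seed, package version)
beside its outputs; identical configs and seeds give byte-identical spike
logs.
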