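# pbwmchunk

Rate-coded simulation of a prefrontal cortex–basal ganglia working
memory (PBWM) circuit augmented with a ring-attractor **chunking layer**,
for continuous-report ("color wheel") working-memory tasks.

## The problem and the model

Working-memory capacity debates contrast *slots* (a fixed number of
discrete, high-precision stores) with *resources* (many items at
degraded precision). This package implements a circuit in which both
behaviors emerge from learned **gating**: a small set of PFC "stripes"
act as independently gateable slots, and striatal Go/NoGo populations
learn — from dopaminergic reward prediction errors alone — when to copy a
stimulus into a stripe (input gating) and which stripe to read out at
recall (output gating). A gate opens when Go − NoGo activity (plus
exploration noise) is positive.

Neurons are rate-coded point units: the membrane potential follows

    C_m dV_m/dt = g_e ḡ_e (E_e − V_m) + g_i ḡ_i (E_i − V_m) + g_l ḡ_l (E_l − V_m)

with output rate `y = 1 / (1 + 1/(γ [g_e − g_e^Θ]_+))`, where `g_e^Θ` is
the excitation that would hold the equilibrium potential exactly at the
firing threshold Θ given inhibition and leak. Layer sparsity uses pooled
FFFB inhibition, `g_i = G_i [ff(t) + fb(t)]`.

Chunking: a posterior ring-attractor layer receives the sensory bump
(strong) and all maintained PFC bumps (weaker, top-down). When the input
is similar to a stored item, the settled bump is a **merged**
representation attracted toward its nearest neighbor in memory; when
dissimilar, lateral inhibition suppresses the top-down drive and the
layer mirrors the input. One stripe stores this chunk-layer candidate
instead of the raw input, so the network can *learn* to compress similar
memoranda into one slot — trading precision for effective capacity.

Learning is three-factor: a Rescorla–Wagner critic turns reward
(`r = 1 − |error°|/90`, clipped to [−1, 1]) into prediction errors,
scaled into dopamine bursts/dips, which move eligibility-tagged Go and
NoGo weights in opposite directions. The gating policy per stripe is
summarized by the rectified normalized weight difference
`α = [ΣGo − ΣNoGo]_+ / (ΣGo + ΣNoGo)`.

## Worked example

Train one 2-stripe chunking network on the set-size-2 task (500 epochs
of 100 trials) and evaluate it on 300 fresh episodes:

```r
library(pbwmchunk)
cfg <- experimentConfig(set_size = 2, n_stripes = 2, chunk_enabled = TRUE,
                        seeds = 1)
tr  <- trainNetwork(cfg, seed = 1)
tr
#> <pbwm_trained> seed 1, 500 epochs; final mean |error| 26.3 deg, nonresponse 0.0%
ev  <- evalNetwork(tr, n_episodes = 300)
mean(abs(ev$recall$error_deg))
#> [1] 41.50642
fit <- errorHistogramAndGuessRate(ev$recall$error_deg)
round(c(guess_rate = fit$guess_rate, sd_deg = fit$sd_deg), 3)
#> guess_rate     sd_deg 
#>      0.320     20.384 
stripeUsage(ev$occupancy)$per_stripe
#> [1] 1 1
meanOutputGated(ev$recall)
#> [1] 0.9233333
```

After training, the network stores the two items in its two stripes on
every episode (`per_stripe` usage 1/1), reads out about one stripe per
recall (0.92), and its error distribution is a mixture of recalls
centered on the target (circular SD ≈ 20°, including the precision cost
of occasional chunking) with a uniform guessing component of ≈ 0.32. `chanceRecallProbability(2, 1)` gives the 0.5 baseline an
unlearned 2-stripe policy would achieve on a single item.

Higher-level experiment drivers: `runExperiment()` (multi-seed train +
eval), `daGainSweep()` (dopamine burst/dip grids), `recencyCurve()`,
`ocv()`/`ocvBinnedError()` (out-of-cluster-variance analysis),
`gatingPolicyTrace()` (policy evolution across epochs). A thin CLI over
these functions lives at `inst/scripts/pbwmchunk-run.R`
(`train` / `eval` / `sweep` / `report`, YAML configs via
`loadConfig()`).

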