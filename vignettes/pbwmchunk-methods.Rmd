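---
title: "Model and methods: chunk-augmented gated working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: chunk-augmented gated working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbwmchunk)
```

## What the package simulates

`pbwmchunk` simulates a prefrontal cortex-basal ganglia (PBWM) working
memory circuit performing a continuous-report ("color wheel") task. On
each episode the network is shown a sequence of items, each a continuous
color angle paired with a discrete orientation cue, and is then probed
with one orientation alone; it must reproduce the associated color from
memory. Colors live on a ring of 20 population-coded neurons; memory
lives in a small number of PFC "stripes", anatomically isolated
populations that can each hold one activity bump. Nothing about the use
of those stripes is hard-wired: striatal Go/NoGo pools learn, from
dopaminergic reward prediction errors alone, when to *input gate* (copy a
candidate into a stripe's maintained deep layer) and when to *output
gate* (route a maintained bump to the response pathway).

The scientific question the simulator addresses is how a slot-like
architecture can exhibit resource-like behavior: a posterior
ring-attractor "chunk layer" receives both the sensory bump and top-down
drive from the maintained PFC bumps, so its settled state is either a
copy of the input or a *merged* representation of the input and its
nearest neighbor in memory. One stripe (the "chunk stripe") receives its
storage candidate from this layer instead of directly from the senses.
Whether the network exploits chunking - trading precision for effective
capacity - is decided entirely by reinforcement learning under the task's
reward statistics.

## Rate-coded dynamics

Every layer uses the same point-neuron abstraction. A neuron's membrane
potential integrates excitatory, inhibitory and leak currents, each a
conductance times the driving force toward that channel's reversal
potential; all potentials are expressed on a normalized 0-1 scale with
defaults `E_i = 0.25 < E_l = 0.3 < theta = 0.5 < E_e = 1`, which
guarantees that inhibition and leak pull the membrane below the firing
threshold and excitation above it. The excitatory conductance of a
receiver is the mean over senders of activity times weight, per
projection, combined across projections with relative scales - the
mechanism by which bottom-up input outweighs top-down feedback.

Output rates use a thresholded sigmoid of the excitatory conductance:
`y = 1 / (1 + 1 / (gamma * max(ge - ge_theta, 0)))`, where `ge_theta` is
the exact amount of excitation that would hold the membrane equilibrium
at threshold given the current inhibition and leak,
`ge_theta = (g_i (E_i - theta) + g_l (E_l - theta)) / (theta - E_e)`.
This identity is the package's core numerical invariant, and the test
suite verifies it to 1e-9 over randomized parameters by substituting
`ge_theta` back into the membrane equilibrium.

Lateral inhibition is pooled FFFB: a feedforward term thresholded-linear
in the layer's mean net input plus a feedback term that leaky-integrates
the layer's mean firing rate; the product with the gain `Gi` sets layer
sparsity. The differential equations are integrated by explicit Euler
with an effective rate `dt / Cm = 0.3` per cycle, and layers settle for a
fixed 50 synchronous cycles per trial phase. These are conventional
choices for this class of model; both are exposed in the configuration.
The feedback time constant is `fb_tau = 3` cycles: faster integration
can oscillate when two distant drives compete in the chunk layer,
transiently silencing it, while at 3 cycles settling is smooth across
the whole similarity range.

## Task, coding and reward

Colors are drawn uniformly on the circle and encoded as circular
Gaussian bumps (tuning width 0.875 rad), peak-normalized to 1; with the
0.2 activity floor an average of 10 of the 20 ring neurons are active
per stimulus. Orientations are sampled without replacement from an
inventory of K = 8 discrete values; an episode of set size N presents N
store trials and then one recall probe of a uniformly chosen stored
orientation. Responses are decoded from the output layer by the
population vector (activity-weighted circular mean), and scored by the
signed circular error in degrees on [-180, 180).

Reward is linear in absolute error, `r = 1 - |error| / 90` clipped to
[-1, 1]. The zero crossing at 90 degrees makes uniform random responding
reward-neutral in expectation, so the critic's baseline does not drift
merely because the network guesses. When no occupied stripe is output
gated (or the output layer carries no decodable activity), the trial is
a non-response and its error is sampled uniformly - the same scoring
convention used for guessing.

## Circuit organization

**Maintenance as a latch.** Deep-layer maintenance is implemented as an
idealized latch: a gated stripe copies its candidate bump
(peak-normalized) and holds it unchanged until re-gated. The object of
study is the learned gating policy, and the latch isolates it from
maintenance noise; a `maintain_leak` option provides graded decay for
sensitivity analyses.

**The chunk layer.** The chunk layer receives the sensory bump at
relative scale 1.0 and the occupied stripes' deep bumps at scale 0.8,
each through a Gaussian topographic kernel (width 0.28 rad), with the
top-down contribution normalized as one projection - the mean over
occupied stripes - so duplicated memory content cannot outweigh the
senses. After FFFB settling (gain 3, graded activation gain 15), the
decoded chunk-layer state moves toward the nearest maintained bump by
about 40-50% of their separation for separations up to roughly 90
degrees, and collapses to a copy of the input beyond about 120 degrees,
where lateral inhibition suppresses the non-overlapping top-down bump.
This gives genuine mergers for similar items and faithful transmission
for dissimilar ones.

**Striatal pools and control inputs.** Each stripe has one scalar Go and
one NoGo pool per channel (input gating, output gating). Their
activities are learned weights from the orientation control inputs,
which are *distributed* patterns over the K control units: neighboring
orientations overlap with similarity `0.35^(d^2)` for circular distance
d. The overlap matters for learning, not just realism - reinforcement
credit generalizes across similar control patterns, which keeps rarely
rewarded gates from freezing shut and, at high allocated capacity,
spreads credit across stripes in the way that degrades output-gating
selectivity. A gate opens iff Go - NoGo plus Gaussian exploration noise
(sd 0.1) is positive; decisions are independent per stripe and channel.

**Occupancy input.** The input-gating pools additionally receive the
stripe's own occupancy (a 0/1 summary of its deep layer, standing in for
the PFC-to-striatum projection), with learned weights. Input-linked
stripes start with an occupancy-to-NoGo weight of 0.3 - an occupied
stripe resists being overwritten until reinforcement says otherwise -
while the chunk-linked stripe is exempt, since its candidate already
incorporates its own content through the chunk layer, making re-gating
non-destructive. The output channel is purely orientation-addressed: an
occupancy signal there cannot discriminate which occupied stripe is
correct and only encourages indiscriminate opening.

**Response pathway.** The output drive is the *mean* of the deep bumps
of all opened, occupied stripes, so reading out several stripes
contaminates rather than saturates the response - the source of moderate
errors when output gating is unselective.

## Learning machinery

A single scalar Rescorla-Wagner critic tracks expected reward
(`lr_v = 0.05`); its prediction error, scaled by separate burst
(positive) and dip (negative) gains, is the dopamine signal. The default
gains are the balanced setting 0.6/0.6.

Gating decisions are flagged by synaptic eligibility tags that decay by
0.7 per trial and reset at the episode boundary, so credit spans the
store-to-recall gap at set size 4 without leaking across episodes. Tags
are incremented by pre-synaptic activity on the Go side of every opened
gate and - at reduced weight `nogo_tag_scale = 0.35` - on the NoGo side
of every gate that took part in a competition but stayed closed. At
recall, dopamine drives an opponent three-factor update: for Go-side
tags, bursts move Go weights up and NoGo weights down (and dips the
reverse); NoGo-side tags learn with the opposite sign. Tagging the
withheld decision is what keeps collapsed policies recoverable: a
"never gate" policy that keeps failing accumulates dips that push its Go
weights back up, whereas with open-only tagging a closed gate is an
absorbing state and networks that explore unluckily die early. Weights
clip to [0, 1] and start at small uniform random values (up to 0.05);
the random initialization breaks the symmetry between stripes, without
which opponent learning updates both stripes identically and no
stripe-specific policy can form.

The two plastic report mappings - input to output, and PFC output to
output - learn by the supervised delta rule with `lr_rep = 0.05`. The
rate is bounded by stability: the delta rule on bump inputs requires
`lr * sum(x^2) < 1` for monotone convergence, and the default bump gives
`sum(x^2)` near 8.

## Calibration

The constants above that the rate-equation framework leaves free (FFFB
gains, projection scales, kernel width, learning rates, tag decay,
exploration noise, initial weights) were calibrated, in that order of
priority, so that (i) the chunk layer's similarity profile shows
attraction for nearby memoranda and faithful copying for distant ones;
(ii) training at set size 2 reliably converges to using both stripes
with low error within 500 epochs; and (iii) the high-load conditions
express the management phenomena the circuit is meant to exhibit
(guessing mixtures, non-responses, multi-stripe read-out at high
allocated capacity). Calibration used the behavior of small seed batches
during development; all constants are fixed defaults in
`networkConfig()` and none are adjusted at run time.

## Study conditions and problem sizes

Training follows the standard schedule: 500 epochs of 100 trials,
episodes packed as N store trials plus one recall. Analyses evaluate
trained networks on 250 fresh episodes with plasticity frozen but
exploration noise intact - the learned stochastic policy, not a greedy
readout, is the object of measurement. Seed counts are scaled to desk
use (10-20 per condition versus 80-160 in large studies); every
experiment is bit-reproducible from its seed because all randomness
flows through R's RNG, including inside the compiled engine.

## What the synthetic task does and does not emulate

The generator reproduces the structure of delayed-estimation color
tasks: continuous uniform colors, discrete orientation cues, sequential
presentation, single probe, linear reward in error. It does not model
perceptual encoding noise, stimulus displays, response dynamics or
reaction times, set-size-dependent encoding time, or human prior
knowledge of the task (networks learn from random weights, where humans
arrive instructed). Passing tests therefore speak to the circuit's
learning and management dynamics under these idealized statistics, not
to quantitative fits of human data.

## Numerical and convention choices

Angles are radians in [0, 2*pi) internally; errors are degrees in
[-180, 180) with the boundary mapped to -180. Decoding requires at least
one unit above the 0.1 floor, otherwise the trial is a non-response. A
storage candidate whose settled peak falls below 0.3 leaves the stripe
empty (with the calibrated chunk layer this is rare but possible when
inhibition from competing drives is strong). The guess rate is
quantified by maximum likelihood over a two-component mixture - uniform
plus zero-centered von Mises - fitted on the logit/log scale with
box constraints; histograms are reported alongside because the mixture
is a summary, not a substitute, for the error distribution. Out-of-
cluster variance (OCV) is the circular standard deviation in degrees of
the non-probed items, which keeps the units interpretable and is
wraparound-safe.

## Open choices resolved

Episodes carry a single recall probe (the minimal reading of the task);
the orientation inventory is K = 8, comfortably above the largest set
size; striatal pools receive orientation and occupancy signals but not
the color itself, so gating policies are role-addressed rather than
content-addressed; dopaminergic plasticity fires at recall only, when
reward arrives; and analyses freeze plasticity during evaluation.

## Known limitations

One chunk layer with one fixed merging profile (no reservoir of
chunking thresholds); a single scalar critic rather than a
state-conditioned one; scalar Go/NoGo pools rather than spiking
populations; and an idealized latch for maintenance. At high load the
learned policies store a subset of orientations and accumulate NoGo
weight on the rest, so the rectified normalized gating-policy index is
conservative there - it reports 0 whenever a stripe's summed NoGo
exceeds its summed Go even when the stripe is used productively; the
unrectified Go-minus-NoGo sums carried by the trained networks are the
more sensitive readout of stripe preferences in that regime. Relatedly,
the over-allocated (8-stripe) control networks here learn more selective
output gating than the credit-assignment account motivating them
suggests: the distributed control inputs spread credit across stripes,
but the scalar pool architecture still resolves the competition well
enough that parallel multi-stripe read-out and non-responses, while
present, are less frequent than in networks with fully distributed
striatal populations.
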