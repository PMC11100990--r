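---
title: "Instance-based learning with generative-model memories and actions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-based learning with generative-model memories and actions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginger)
```

## The model family

This package implements a family of cognitive models of experiential decision
making built on Instance-Based Learning (IBL) theory, an account rooted in
ACT-R memory dynamics. An IBL agent stores every decision it makes as an
*instance* — the option's attribute values, the utility it experienced, and
the time steps at which that exact experience occurred — and values options by
retrieving and blending these instances.

Three equations drive the agent. The *activation* of instance $i$ at time $t$
combines power-law recency/frequency, partial matching against the query
option, and noise:

$$A_i(t) = \ln\!\Big(\sum_{t' \in T_i(t)} (t - t')^{-d}\Big) +
  \mu \sum_{j \in F} \omega_j \,(S_{ij} - 1) + \sigma\,\xi$$

where $S_{ij} \le 1$ is the similarity of attribute $j$ of instance $i$ to the
query. Activations are converted to *retrieval probabilities* by a
temperature-$\tau$ soft-max, and the *blended value* of an option is the
retrieval-probability-weighted mean of stored utilities:

$$P_i(t) = \frac{e^{A_i(t)/\tau}}{\sum_{i'} e^{A_{i'}(t)/\tau}},
\qquad V_k(t) = \sum_{i} P_i(t)\, u_i .$$

The agent chooses the option with the highest blended value, ties broken
uniformly at random.

On top of this core, two generative-model (GM) channels can be grafted:

* **Generative memories (GER)** — each option additionally carries a GM
  representation (a $\beta$-VAE diagonal-Gaussian posterior for visual
  stimuli, a text embedding for emails) as one more attribute, whose
  similarity $S_{ij} = \mathrm{Sim}_{GM}$ enters the partial-matching sum.
* **Generative actions (GIN)** — a utility-prediction network maps the GM
  representation directly to a value; crucially it is *trained to match the
  blended values of an internal teacher IBL model*, not the raw rewards.

The full **GINGER** model runs both channels and values each option by the
exact average of its GIN and GER values. Ablating the channels yields the
four-agent comparison (IBL, GER, GIN, GINGER) that the task simulators and
evaluation statistics in this package are built to serve.

## Parameters and defaults

All four agents run with the same fixed parameters — the ablation has zero
fitted parameters:

| parameter | meaning | default |
|---|---|---|
| $d$ | memory decay exponent | 0.5 |
| $\mu$ | mismatch penalty | 1 |
| $\omega_j$ | attribute weights | 1 |
| $\sigma$ | activation noise scale | 0.25 |
| $\tau$ | soft-max temperature | $\sigma\sqrt{2}$ |

The noise variate $\xi$ is logistic, $\xi = \ln((1-u)/u)$ with
$u \sim U(0,1)$, following the PyIBL convention; a standard-normal
alternative is available through `agent_params(noise_dist = "normal")`. The
temperature default $\tau = \sigma\sqrt 2$ is likewise the PyIBL convention;
both are configuration knobs rather than hard-coded constants.

The clock counts decisions: it starts at 0, advances by exactly one per
recorded outcome, and the "current time" in the activation equation is the
trial being decided (`clock + 1`), so all stored occurrences — including
prepopulated ones at time 0 — lie strictly in the past and every lag is at
least 1, keeping the base-level logarithm finite.

### Cold start

Unvisited options have no instances. We use optimistic prepopulation: a
default instance with the task's maximum reward (1.0) is inserted at time 0
the first time an option is queried. Optimism induces the systematic early
exploration that learning curves in bandit-style tasks require. Prepopulation
can be disabled (`prepopulation = NULL`), in which case valuing an option
with an empty memory is an error.

### Memory organization

With partial matching and transient stimuli (a bandit option is a
shape/color/texture combination that may never recur exactly), a hard
partition of memory by option would leave most query options without any
instances. Memory is therefore a single pool: blending for option $k$ runs
over all instances, and the similarity term performs the soft grouping — an
instance matching the query on every attribute is penalized by 0, a fully
mismatched one by $\mu \sum_j \omega_j$. Instances are deduplicated by
(attributes, utility); a repeat observation appends an occurrence time.
An instance that predates a stimulus dimension (the transfer task introduces
color and texture mid-run) scores similarity 0 on the missing attribute,
i.e. maximal mismatch.

## Generative representations

### $\beta$-VAE over rendered stimuli

Visual stimuli are rendered programmatically from their generative factors
(shape $\times$ color $\times$ texture, 27 combinations; gray/solid stand-ins
for factors not yet introduced). A dense variational autoencoder with one
hidden layer on each side and a 9-unit diagonal-Gaussian latent is trained on
the rendered set by full-batch Adam with the reparameterization trick. The
loss is summed squared reconstruction error plus $\beta$ times the KL
divergence of the posterior from the standard-normal prior; $\beta$ imposes
an information bottleneck, and raising it measurably costs reconstruction
accuracy (a property the test suite checks across seeds). Defaults:
latent 9, hidden 64, $\beta = 1$, 200 epochs, learning rate $10^{-2}$ —
small enough to train in about a second on one CPU, which is why experiments
train the encoder at run time instead of shipping weights.

### Similarity metrics

For Gaussian posteriors, KL divergence is the natural comparison but is
asymmetric and unbounded, while the activation equation wants a similarity
with maximum 1. We symmetrize and exponentiate:

$$\mathrm{Sim}_{GM}(p, q) = \exp\!\big(-\tfrac{1}{2}\,
  [KL(p\|q) + KL(q\|p)]\,/\,\lambda\big) \in (0, 1].$$

The scale $\lambda$ matters: a trained encoder separates distinct stimuli by
symmetrized divergences in the tens, so at $\lambda = 1$ the similarity of
every distinct pair underflows to 0 and $\mathrm{Sim}_{GM}$ degenerates into
an identity indicator, starving the GER channel of generalization. The task
wiring therefore calibrates $\lambda$ to the median pairwise symmetrized KL
over the task's stimulus set (`kl_scale_for_vae()`), placing mid-range pairs
near $e^{-1}$. A raw $-KL$ mode is available for fidelity experiments.

For text embeddings, similarity is the raw cosine, as is standard for
sentence embeddings; an optional $(1+\cos)/2$ rescale to $[0,1]$ is provided
but off by default since the activation equation only requires
$S_{ij} \le 1$.

### Synthetic email corpus

The phishing task runs on a synthetic corpus standing in for an expert-coded
email set: six binary expert features (mismatched sender, requesting
credentials, urgent language, making an offer, suspicious subject, link
mismatch), a ham/phishing label, and an embedding produced by a linear
latent-factor model $e = W[\text{features}, \text{latent}] + \varepsilon$
with $W$ fixed by the seed. Feature incidence is `base_rate` (0.2) under ham
and `base_rate + effect_strength` (0.6) under phishing, so embeddings are
statistically closer within class than between classes and a logistic
read-out recovers the label well above chance — the signal the GER and GIN
channels need. Corpus size defaults to 239 emails with a 10% seeded
pretraining split (24 emails, round-half-up). What the generator does *not*
emulate: real linguistic content, the anisotropic geometry of
language-model embedding spaces, label noise in expert coding, and
participant-specific email ordering. Passing tests therefore certify the
machinery and its contracts, not fidelity to any particular human corpus.

## The utility network and train-to-match

GIN's network is a fully connected ReLU regressor (two hidden layers of 64
units for the 9-dimensional visual representations; two of 128 for email
embeddings) with a linear output initialized at zero, trained by full-batch
Adam on mean squared error. Its targets are not rewards but the current
blended values of an internal teacher IBL model over hand-crafted features.

Three design choices here were genuinely open and were settled by
implementation experience on the deterministic sanity task (one option always
pays 1, others 0, noise off, where every agent should exceed 95% correct
after the first few trials):

* **Training set** — every *presented* option (not only chosen ones) enters
  the network's training set, since the teacher can value any option it is
  shown; this mirrors using the baseline model to predict utilities of
  stimulus options.
* **Refit timing** — the network is refit at the start of each trial, after
  the presented options are registered, at a budget of 100 epochs
  (learning rate $10^{-2}$) per refit, warm-started. Refitting *before*
  prediction lets the network inherit the teacher's optimistic prepopulated
  values for options first seen on the current trial; refitting only after
  feedback leaves first-seen options valued by generalization alone and
  measurably depresses learning. The teacher memory receives the same
  optimistic prepopulation as the plain IBL agent, so at full convergence
  the GIN policy coincides with the IBL policy.
* **Phishing input** — a ham/phishing decision cannot be distinguished by
  the email embedding alone, so the network input is the embedding
  concatenated with a 0/1 action indicator.

## Task simulators

*Contextual bandit.* Three options per trial; each of the 9 feature values
appears exactly once across the options (independent random permutations of
each dimension over the three positions), so exactly one option carries the
episode's feature of interest and its screen position is uniform. Targets pay
1 with probability 0.75, non-targets with 0.25. Episode lengths are uniform
on 20–25 trials; a fresh feature of interest is drawn each episode, never
repeating its predecessor. Chance level is 1/3 and a uniform-random policy
earns $\frac13 \cdot 0.75 + \frac23 \cdot 0.25 = \frac{5}{12}$ per trial.

*Transfer of learning.* Three 15-trial phases (45 trials): shape-only
options, then shape+color, then shape+color+texture. The feature of interest
lives in the newest dimension each phase, so earlier dimensions become
distractors; this is one faithful reading of a transfer design whose full
contingencies are specified elsewhere, and it is isolated behind
`transfer_task_spec()` for replacement.

*Phishing identification.* Emails are presented one at a time in a seeded
order; the agent chooses ham or phishing and earns 1 for a correct
categorization. All agents are pretrained on the same seeded 10% subset.

## Evaluation statistics

Model-behavior agreement uses the mean residual sum of squares between
aligned curves, $RSS/n$ with $RSS = \sum_i (y_i - p(x_i))^2$, and the
Bayesian Information Criterion $BIC = n \ln(RSS/n) + k \ln n$ with $k = 0$
fitted parameters — at $k = 0$ BIC is a strictly monotone transform of RSS,
so the two rankings always agree. Transfer performance uses jumpstart (mean
of the first $J$ rewards after a phase switch; the phrase "first third" is
ambiguous between three trials and a third of the phase, and we default to
$J = 3$ in parallel with the stated final-three asymptote, exposed as an
argument), episodic (phase mean) and asymptotic (mean of the final three)
metrics. Confidence bands are normal-approximation 95% intervals across
runs, clipped to $[0,1]$ for probability curves. Since participant data are
out of scope, reports compare against a saturating-exponential reference
curve with known parameters by default; any externally supplied curve in the
same CSV schema drops in.

## Reproducibility and problem sizes

Every stochastic component draws from R's RNG under seeds derived from a
master seed via a Lehmer-style mixing scheme (`derive_seed()`), keeping all
seeds positive 32-bit integers and runs bit-reproducible. The test suite and
acceptance script run at deliberately modest sizes chosen as this package's
own defaults for desk-scale verification: 16-pixel renders for encoder
fixtures, 30 runs of 3 bandit episodes for the learning-sanity check,
32-dimensional embeddings for phishing-scale tests (1536 remains the
faithful setting for the full task), and 10,000-draw Monte-Carlo checks of
the simulator-level rates.

## Known limitations

* The agents model group-level learning with default parameters; no
  per-participant fitting is provided, by design.
* The $\beta$-VAE is a dense network on small renders — adequate for the
  9-unit representations the models need, not a general image model.
* GM outputs are used only as representations and utility predictions; GM
  content generation (text or action content) is out of scope.
* The transfer task's reward contingencies are one plausible reading, kept
  behind its spec object so alternative contingencies can be substituted.
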