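---
title: "Channel-based federated learning with neuron pruning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-based federated learning with neuron pruning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelfed)
```

## The problem

Clinical prediction models are usually trained on pooled patient records,
but hospitals often cannot share those records. Federated learning keeps the
data where it is: each site trains a local copy of the model and only model
updates travel to a central server. Plain federated averaging (FA) still
reveals every parameter of every local model each round. The scheme
implemented here — stochastic channel-based federated learning (SCBFL) —
reveals far less: each client uploads only the gradient entries lying on its
most active *channels*, the paths through the network that changed most in
the last round of local training.

The driving application is binary mortality prediction from sparse
medication-exposure indicators: each admission is a 0/1 vector over the
hospital formulary (one indicator per medication) with a died/survived
label. Since such data cannot be redistributed, the package ships a
generator for synthetic cohorts with the same statistical silhouette, and
all shipped experiments run on those.

## Model and protocol

The learner is a dense feed-forward network with layer sizes
$(m_0, m_1, \dots, m_L)$: weight matrices $W_l$ of shape
$m_{l-1} \times m_l$, ReLU hidden activations, a single sigmoid output
neuron, trained by mini-batch SGD on binary cross-entropy. The reference
clinical architecture is $64$–$32$–$1$ with a dropout layer (rate $0.5$,
inverted scaling) on the second hidden layer.

One **global loop** consists of:

1. every client downloads the server weights (download rate 100%);
2. each client runs 5 local epochs (batch size 32, learning rate 0.01) and
   forms the gradient $G = W_{\text{after}} - W_{\text{before}}$ — bias
   changes are never uploaded;
3. **channel selection**: a channel $(t_1, \dots, t_L)$ names one neuron
   per layer. Its parameter set is the full input column into $t_1$ plus
   the single edge $(t_{l-1}, t_l)$ for each later layer, so the channel
   norm tensor $T$ has shape $m_1 \times \cdots \times m_L$. Each entry is
   the Euclidean norm of the gradient over the channel's parameters.
   Channels with norm at or above the descending $\lceil \alpha K \rceil$-th
   rank ($K$ = number of channels, $\alpha$ = update rate) are selected;
   every gradient entry not on a selected channel is set to zero, giving
   the processed gradient $\tilde G$;
4. the server adds, per weight position, `decay` (default 0.8) times the
   mean of the uploaded values of the clients that selected that position;
5. optionally, APoZ pruning (below), then the server is scored on the test
   cohort.

Because channels overlap (all channels with the same $t_1$ share that input
column), uploading a fraction $\alpha$ of channels generally uploads more
than $\alpha$ of the parameters; the package logs both fractions and the
cumulative uploaded-entry count, the "trans-information" a server observes.

### Design choices in the protocol

Several points the prose description leaves open were fixed as follows.

* **Channel entry sets.** The norm tensor is explicitly $L$-dimensional
  (one index per layer, none for the input), yet uploads must be able to
  carry input-layer weights, and overlapping channels are described as
  sharing neurons. The convention adopted — whole input column plus one
  edge per later layer — satisfies all three constraints. It is the
  package's single largest interpretive choice.
* **Quantile direction.** "$\alpha$-percentile" is read as *top $\alpha$
  fraction by norm*, so $\alpha = 0.1$ uploads roughly 10% of channels.
  The cutoff is a descending-rank order statistic, not an interpolated
  percentile; ties are inclusive, which is deterministic and
  order-independent but may select more than $\lceil \alpha K \rceil$
  channels when norms tie exactly.
* **Negative selection** (drop the bottom $1-\alpha$ instead of keeping
  the top $\alpha$) is provided for completeness; it coincides with
  positive selection for distinct norms and differs only at ties.
* **Multi-client aggregation.** The one-client description ("add
  $\tilde G$ to the weights") is extended to many clients as a mean over
  the clients that selected each position, then scaled by the decay
  factor. A mean keeps the update magnitude independent of the number of
  clients; the literal single-client reading is recovered with one client
  and decay 1, which is also how the centralized-equivalence test pins
  the implementation.
* **Biases stay local.** Bias changes are excluded from upload, so server
  biases carry no learned signal; consequently `client_sync()` does not
  overwrite client biases (doing so would discard learning every loop) and
  the server scores with its initial zero biases. Grafting mean client
  biases onto the server moves test AUC-ROC by under 0.002 in our runs, so
  this convention is immaterial for evaluation.
* **Decay** is a constant scalar on the aggregated upload. A
  recency-weighting interpretation (geometric weights across loops) is
  conceivable from the one-line description but is not implemented.

## APoZ pruning

The average percentage of zeros of hidden neuron $c$ is the fraction of
validation examples whose post-ReLU activation is exactly zero (scalar
dense activations, so the output dimension in the general formula is 1).
Zero is tested exactly: ReLU emits exact zeros, so no tolerance is needed.

At the end of each early global loop the *server* computes APoZ on the
central validation set, removes the
$k = \min(\max(1, \lfloor r \cdot \text{remaining} \rfloor),
\text{left-to-target})$ neurons with the highest APoZ — ranked jointly
across hidden layers, since the description imposes no per-layer quota —
and broadcasts the masks; every client shrinks identically, which keeps
gradient aggregation shape-consistent. Defaults: per-loop rate $r = 0.10$
of remaining neurons, overall target 47% of the original hidden neurons.
Two guards: at least one neuron is pruned per step while the target is
unmet (otherwise small rates stall), and a layer is never emptied (the
next-ranked neuron is taken instead). Structural removal is bit-exactly
equivalent to forcing the removed neurons' activations to zero, which the
tests verify directly.

## The synthetic cohort generator

`generate_cohort()` emulates a hospital-admission table: per-feature
prevalences drawn from Beta(0.3, 3) clipped to $[0.001, 0.5]$ (most
medications rare, none impossible, none majority), independent Bernoulli
exposures, and a mortality label drawn from
$\Pr(\text{death}) = \operatorname{sigmoid}(\beta_0 + x \cdot \beta)$ with
`n_informative` coefficients of magnitude `effect_scale` and random sign.
The default intercept $\beta_0 = -1.5$ targets roughly 18% mortality when
effects cancel, but realized prevalence varies considerably across seeds
because informative coefficients can land on common exposures — a feature,
not a bug, for stress-testing threshold-free metrics. A logistic-linear
outcome is the minimal model an MLP can learn and an ordinary `glm()` can
verify, which is exactly how the generator is tested.

`split_federation()` reproduces the reference layout: 60/10/30
train/validation/test (floored, remainder to train), training rows divided
into five near-equal shards. A `shard_skew` knob interpolates between IID
shards and label-sorted shards by ordering rows with a convex blend of a
random key and the label-sorted rank before cutting equal blocks, which
preserves exact shard sizes at every skew.

What the generator does **not** emulate: admission timing, repeated
admissions, dosage, missingness, inter-feature correlation (medications are
independent given nothing), and covariate shift between sites under the
default IID sharding. Passing tests therefore show the *algorithms* behave
as specified, not that the performance levels transfer to real
pharmacy-exposure data.

## Evaluation metrics

ROC and precision-recall curves are built from first principles: unique
scores in descending order serve as thresholds (prediction positive iff
score $\ge$ threshold), with sentinel rows pinning $(0,0)$ (precision
defined as 1 at zero predicted positives) and $(1,1)$. AUC-ROC is the
trapezoid integral, which the tests require to equal the exhaustive
pairwise Mann–Whitney statistic (ties counted $\tfrac12$) exactly on all
small instances. AUC-PR uses the average-precision step convention rather
than trapezoids, whose interpolation in PR space is known to be biased.
Single-class label vectors raise an error rather than returning NaN.

## Problem sizes and numerical choices

The shipped experiments (acceptance script and stochastic tests) use
cohorts of $n = 2000$ with 200 features (20 informative,
`effect_scale = 3`), 5 clients and 30 global loops, replicated over three
master seeds — large enough for stable AUCs, small enough for
minutes-scale runs; the full reference configuration (100 loops, arbitrary
cohort sizes, user CSVs) is available through the config file. Per-client
training seeds are derived as `master_seed + client + loop * n_clients`,
making every run bit-reproducible from its summary. Scores are clipped to
$[10^{-12}, 1-10^{-12}]$ inside the loss only; the rank count
$\lceil \alpha K \rceil$ is computed with a $10^{-9}$ guard against
floating-point overshoot when $\alpha$ is itself a ratio $k/K$.

On these synthetic conditions the channel scheme tracks federated
averaging closely (mean final AUC-ROC gap $\approx 0.03$ across the three
seeds at $\alpha = 0.3$) while transmitting strictly fewer gradient
entries, and pruning 47% of hidden neurons costs $\approx 0.02$ AUC-ROC
while removing about half the weight parameters — the same qualitative
pattern reported for the hospital cohort the method was developed on. Note
that at these loop counts neither algorithm has saturated (the true-model
ceiling on these cohorts is AUC-ROC $\approx 0.92$–$0.93$); longer runs
close most of the remaining gap.

```{r example, eval = FALSE}
cohort <- generate_cohort(2000, 200, 20, effect_scale = 3, seed = 1)
split <- split_federation(cohort, n_clients = 5, seed = 1)
run <- run_scbfl(split, federation_config(global_loops = 30, alpha = 0.3,
                                          master_seed = 1))
glance(run)
autoplot(run)
```

## Known limitations

* No network transport, asynchrony, client sampling, secure aggregation,
  or differential-privacy accounting — the privacy property is the sparse
  disclosure itself, not a formal $\varepsilon$ guarantee.
* Only full (100%) download of server weights is implemented.
* Pruning applies to hidden neurons only; input features are never pruned.
* Wall-clock speedups from pruning are hardware-bound and are deliberately
  not asserted anywhere; parameter counts stand in for them.
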