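---
title: "Methods: knowledge graph embeddings for microbial coculture interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge graph embeddings for microbial coculture interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microkge)
```

## The problem and the representation

Pairwise coculture screens measure how one bacterial strain (the *sender*)
changes the growth yield of another (the *receiver*) in a given
carbon-source environment. The effect is quantified on the log-ratio scale,

$$E_{S_2 \to S_1} = \log\frac{\mathrm{Coculture}(S_1 \mid S_2)}
                             {\mathrm{Monoculture}(S_1)},$$

and discretized into three interaction types: *positive* (growth
enhanced), *negative* (growth inhibited) and *neutral* (no detected
effect). `microkge` represents such a screen as a knowledge graph: strains
are entities, and each measurement becomes a triple
$(h, r, t)$ whose relation $r = (I, e)$ couples the interaction type $I$
with the environment $e$. A relation embedding is therefore *global* —
shared across all strain pairs that interact with type $I$ in environment
$e$ — while entity embeddings are strain-specific and capture interaction
tendencies across environments.

Three standard embedding models score a triple's plausibility:

* **TransE** — $\varphi(h,r,t) = -\lVert \mathbf h + \mathbf r - \mathbf t \rVert$
  (L1 or L2), a translation model;
* **DistMult** — $\varphi(h,r,t) = \sum_i h_i r_i t_i$, a symmetric
  bilinear model (it cannot distinguish sender from receiver, which is why
  it underperforms on directed interaction data);
* **SimplE** — $\varphi(h,r,t) = \tfrac12(\langle \mathbf h_h, \mathbf r,
  \mathbf t_t\rangle + \langle \mathbf h_t, \mathbf r^{-1}, \mathbf
  t_h\rangle)$, which restores asymmetry by giving every entity a
  head-role and a tail-role vector and every relation an inverse.

Training minimizes either the pairwise margin ranking loss
$\sum \max(0, \gamma - \varphi^+ + \varphi^-)$ (used with TransE) or the
pointwise logistic loss $\sum \log(1 + e^{-l\varphi})$ with $l = \pm 1$
(used with DistMult and SimplE), by plain mini-batch SGD with a constant
learning rate. Negatives come from one of two samplers:

* **classical** — replace the head or the tail (coin flip) with a uniform
  other entity; accidental true triples are *not* filtered, which mirrors
  common practice and matters little at typical graph densities;
* **interaction-based (INS)** — replace only the interaction-type
  component of the relation with one of the other two types, keeping
  head, tail and environment. In a dense, nearly complete interaction
  graph, classical corruptions often hit observed facts; INS corruptions
  are guaranteed false whenever each (pair, environment) cell carries one
  label, which is exactly the quantity the classifier must learn. This is
  why INS is the default sampler.

Interaction-type prediction for a pair in an environment scores the three
candidate relations and takes the argmax; ties break in the fixed
canonical type order (negative < neutral < positive) everywhere in the
package, which makes every downstream procedure deterministic.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `dim` | 32 | small graphs (tens of strains) need modest capacity; 16–100 all work |
| `learning_rate` | 0.05 | stable for sum-form batch losses at batch 128 |
| `batch_size` | 128 | a few dozen batches per epoch on ~10^3–10^4 triples |
| `epochs` | 100 | loss plateaus well before this on structured data |
| `margin` | 1 | conventional for translational models |
| `negatives_per_positive` | 1 | the convention in the cited model families; exposed for study |
| `ns_strategy` | `interaction_based` | see above |
| `neutral_band` | 0 | an effect of exactly 0 is neutral; widen only if the upstream pipeline thresholded detection |
| `k` (unseen strains) | 5 | caps the neighbourhood at a within-order scale; larger k dilutes the signal with distant relatives |

Initialization draws all coordinates i.i.d. uniform on
$[-6/\sqrt d, 6/\sqrt d]$ (the translational-embedding convention; the
source method states only "randomly initialized"), and TransE entity
vectors are re-normalized to the unit sphere at initialization and — by
default, controllable via `transe_normalize` — after every SGD step, as
in the original TransE recipe; whether the original study did so is
unstated, so it is a flag. `l2_reg` is implemented as multiplicative
weight decay after each step and defaults to 0.

Reproducibility uses a two-stream scheme: initialization is seeded with
`seed` and the shuffling/negative-sampling stream with `seed + 1`, so the
same initialization can be combined with different sampling streams and
vice versa.

## Splits and protocols

`split_kg` implements three protocols. The random 90/5/5 triple-level
split uses largest-remainder rounding, so a 100-triple graph yields
exactly (90, 5, 5). `holdout_receivers` moves every triple whose
*receiver* is held out into the test set — the model then never sees
growth measurements *of* those strains. `holdout_strain` removes the
strain in both roles (the unseen-strain protocol). Whether the original
90/5/5 split was stratified by relation is unstated; the split here is
plain triple-level random.

The relation vocabulary is either `observed_only` (exactly the (type,
environment) pairs with at least one triple — this reproduces observed
relation counts) or `full_grid` (all $3 \times |\mathcal E_{env}|$
combinations). INS can propose unobserved combinations, so training with
INS requires `full_grid`; the observed relation count remains reportable
from the triples themselves.

## Evaluation

Classification metrics are the standard one-vs-rest precision, recall and
F1 per type plus overall accuracy and the 3×3 confusion matrix;
zero-denominator cases are defined as 0 with a warning. Ranking metrics
follow the literal definitions: for each test triple both a head-side and
a tail-side rank over *all* entities (raw, unfiltered), giving

$$\mathrm{MRR} = \frac{1}{2N}\sum\left(\frac{1}{\mathrm{rank}^h} +
\frac{1}{\mathrm{rank}^t}\right), \qquad
\mathrm{Hits@}k = \frac{|E^h| + |E^t|}{2N}.$$

Whether the original ranks were filtered is not stated; raw ranking
matches the printed definition and is the default, with filtered ranking
behind a flag. Tied scores get the mean rank of the tied block: with
random untrained embeddings and 20 entities this yields MRR near 0.44
rather than the optimistic value "first-of-block" ranking would give,
matching the behaviour of random baselines on small entity sets.

Five majority baselines condition on nothing (A), the environment (B),
the receiver (C), the sender (D) or the (sender, receiver) pair (E); an
unseen stratum falls back to the global majority, and ties break
canonically. Entropy diagnostics report
$H = -\sum_c p(c)\log_2 p(c)$ and the effective class number $2^H$.

## The three downstream procedures

**Unseen strains.** A strain absent from the graph gets a *synthetic
embedding*: the $k$ phylogenetically nearest in-graph strains (Euclidean
distance in an externally supplied feature space, e.g. a PCA of 16S
distances) are aggregated with weights $w_j = 1/(1+d_j)$, renormalized to
sum to one — a convex combination, applied separately to each embedding
role for SimplE. The weight normalization formula is not printed in the
source description ("normalized" only); unit-sum normalization is chosen
because it makes the aggregate a weighted average and keeps it inside the
neighbours' convex hull.

**Environment transfer.** Each complete environment (all three relation
types present in the vocabulary) is embedded as the concatenation
$\mathbf v_e = (\mathbf r_1 | \mathbf r_2 | \mathbf r_3)$ in canonical
type order (for SimplE each block is relation | inverse, giving $6d$);
incomplete environments are excluded, mirroring the source protocol. The
transfer rule predicts a pair's interaction in a query environment by
copying its observed interaction in the nearest other environment
(Euclidean or cosine distance), falling back to the second nearest and so
on; an optional distance cap supports threshold analyses. Concatenation
order is fixed but immaterial for distances as long as it is consistent.

**Recommendation.** For a target strain, desired type and environment,
every candidate $c$ is scored as $\varphi(c, (I,e), t)$ (or with the
arguments reversed for the opposite effect direction) and ranked
descending; $S_{rec}$ is the argmax. Scores are min-max normalized within
the candidate set (the source states normalization without a formula; a
constant set maps to all 1). The ranking is invariant to candidate order,
with name-order tie-breaking.

## The synthetic world

The generator exists so that every stage is testable offline. Its
defaults state one world: a 20-strain × 40-environment screen
(`n_strains = 20`, `n_environments = 40`), latent traits of dimension 4,
8 environment archetypes (environments within an archetype share their
interaction structure up to noise — the redundancy among chemically
similar carbon sources that the transfer rule exploits), effect noise
`noise_sd = 0.3` and `neutral_band = 0.25` on a unit-variance effect
scale (giving a realistic minority neutral class), `phylo_signal = 0.8`,
and `missing_fraction = 0.01` (real screens drop a small fraction of
wells). The continuous effect is a bilinear trait interaction,
$E = u_s^\top M_{g(e)} u_r / m + \varepsilon$, with one random mixing
matrix per archetype: this produces environment-dependent but
pair-consistent structure. Missingness is uniform over (pair,
environment) cells, since nothing more structured is documented about the
real gaps. The Gaussian effect distribution is a modelling convenience,
not a claim about real effect-size distributions.

What a green test on this world does establish: that the estimator
recovers planted structure, that INS does not hurt and typically helps,
that phylogeny-weighted aggregation transfers information to held-out
strains when phylogeny determines traits, and that environment-similarity
transfer exploits archetype redundancy. What it does not establish:
performance on real screens, whose effect distributions are heavy-tailed,
whose missingness may be structured, and whose phylogeny-trait coupling
is far weaker than `phylo_signal = 1`.

One invariant deserves a caveat: with `phylo_signal = 1` and zero noise,
the phylogenetically closest pair of strains has the most similar
interaction-label profile *in expectation*, but label discretization
makes profile Hamming distance a noisy function of trait distance, and
the exact argmin coincidence holds in only ~60–80% of random worlds. The
test suite therefore asserts the robust form — a strong positive Spearman
association between phylogenetic distance and profile disagreement, with
the closest pair in the most-similar quartile — rather than the fragile
pointwise claim.

## Numerical choices and degenerate inputs

* Natural log for the coculture effect (the source writes "log" without a
  base); only the sign reaches the labels, so the base is inert
  downstream and configurable.
* Scores and gradients are computed in double precision; the analytic
  gradients of every model/loss combination are tested against central
  finite differences (step $10^{-5}$, relative error $< 10^{-6}$).
* The logistic loss uses an overflow-safe softplus
  ($\log(1+e^x) \to x$ for large $x$).
* The TransE gradient at an exact translation ($\mathbf h + \mathbf r =
  \mathbf t$, L2) is defined as 0 rather than left undefined.
* Duplicate records with identical labels collapse with a warning
  (replicate measurements are benign); conflicting labels for the same
  cell are an error.
* Empty record lists build an empty graph; `epochs = 0` returns the
  initialization unchanged; non-finite losses abort with a diagnostic
  rather than propagate NaNs.

## Known limitations

* No complex-valued or convolutional embedding models, no early stopping,
  no adaptive optimizers by default (plain SGD matches the source
  training loop).
* The unseen-strain protocol retrains once per held-out strain, which is
  the expensive but faithful variant of the n-fold procedure.
* Relation-side ranking is deliberately absent from MRR: ranks are
  defined over entity substitutions only.
* The random-donor baseline for the environment rule resamples a donor
  per query; per-pair resampling is not implemented, as the distinction
  is immaterial for median accuracies over many queries.
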