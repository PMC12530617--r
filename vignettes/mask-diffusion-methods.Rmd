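---
title: "Masked discrete diffusion for molecular graphs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked discrete diffusion for molecular graphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The generative model

`moldiff` generates 2D molecular graphs with a discrete denoising diffusion
model. A molecule with up to `n` heavy atoms is a triple `G = <A, C, E>` of
one-hot matrices: atom types (`n x d_A`), formal charges (`n x d_C`) and
bond types (`n x n x d_E`, symmetric, "none" on the diagonal). Three
bookkeeping categories make the representation closed under the model's
operations:

* **`<PAD>`** is an ordinary atom category. Every molecule is padded to the
  common size `n`, and padding is corrupted and predicted like any element,
  so the model learns the molecule-size distribution instead of sampling
  sizes from the data.
* **"none"** is an ordinary bond category indicating the absence of a bond.
* **`<MASK>`** is the absorbing state of the forward process, appended as
  the last category of every channel. Clean data never contains it.

### Forward corruption (mask-and-replace)

Each channel entry evolves under a Markov chain with column-stochastic
transition matrices `Q_t`: at step `t` an ordinary category is kept with
probability `alpha_t`, replaced by a uniformly chosen ordinary category
with total probability `K * beta_t`, and absorbed into `<MASK>` with
probability `gamma_t` (`alpha_t + K beta_t + gamma_t = 1`; the mask column
is the unit vector). Masking dominates; the small uniform component exists
so that the reverse process can also *revise* entries it has already
committed to, not only fill in masks.

Products of these matrices stay in the same three-parameter family, so the
cumulative `Qbar_t = Q_t ... Q_1` is available in closed form and is checked
against the explicit product in the tests. Corruption of a graph draws every
atom and charge row from `Qbar_t`'s column of its clean category and every
strictly-lower-triangular bond entry likewise, mirroring to the upper
triangle — the graph is undirected, so only one triangle carries free
variables.

The schedule is configuration, not data: the default `"linear-mask"`
schedule drives the cumulative mask mass linearly to 1 at `t = T`
(`mask_fraction_final = 1`, so the terminal state is deterministically
all-mask and the prior term of the bound is exactly zero), and sets the
per-step uniform mass to `uniform_weight = 0.05` of the per-step mask mass.
`T` defaults to 500 at production scale; the desk-scale presets in this
package use `T = 24` to `50`, which at the fixture sizes below leaves the
terminal distribution and the per-step unmasking granularity qualitatively
unchanged.

### Reverse process and training objective

The denoiser predicts the *clean* categories: given a noisy graph `G_t`, a
timestep and optionally a property value, it outputs distributions
`p(x0 | G_t)` over ordinary categories for every entry (never `<MASK>`).
The reverse transition mixes the closed-form posterior over that
prediction:

```
p(x_{t-1} | x_t)  =  sum_{x0}  q(x_{t-1} | x_t, x0) p(x0 | x_t)
```

Training minimizes the per-channel variational bound — the KL between
`q(x_{t-1}|x_t, x0)` and the mixture above, summed over entries, with the
`t = 1` term reduced to reconstruction — plus an auxiliary cross-entropy on
the clean categories, with default weights `(2, 1, 5)` for the bound and
`(2, 0.5, 2.5)` for the cross-entropy. The edge channel is up-weighted
because edges number `n^2` but are overwhelmingly "none"; the atom terms
carry double weight because failure analysis of reverse sampling shows
atom-identity and atom-count errors dominating, and reverse sampling
consumes the clean-category prediction directly, so atom-prediction
sharpness controls sample fidelity. All KL/log computations floor
probabilities at `1e-30`: absorbing-state posteriors contain exact zeros.

Timesteps are drawn stratified across each batch (one draw per stratum of
`1..T`, order shuffled). The marginal distribution per molecule stays
uniform — the estimator is unchanged — but the gradient variance drops
substantially, which at desk scale is the difference between converging in
hundreds rather than thousands of steps.

### The denoiser

A graph transformer operates on a node stream and an edge stream:

* node features: one-hot atom and charge categories (including `<MASK>`),
  `rni_dim = 8` random node initialization (RNI) features drawn fresh from
  a standard normal at every forward pass, a 16-dimensional sinusoidal
  embedding of `t / T`, and (for conditional models) a learned embedding of
  the standardized property value;
* per layer: pre-layer-norm multi-head attention over all node pairs whose
  scores receive an additive per-head linear bias from the edge features,
  a direct edge-to-node message in which every node aggregates its
  incident edge features (the strongest evidence about whether a row is a
  real atom and what bonds it carries — with only a scalar attention bias,
  padding/atom-count coordination trains far more slowly), a position-wise
  feed-forward block, and an edge update from the symmetric combination
  `[h_i + h_j, h_i * h_j, e_ij]`, all with residual connections;
* output heads: softmax distributions over ordinary categories for atoms,
  charges, and edges; edge logits are mirror-averaged before the softmax,
  which together with the symmetric edge stream makes
  `edge_probs[i,j,] == edge_probs[j,i,]` exact to the last bit.

Every operation is permutation-equivariant, and because the RNI features
are i.i.d., the model remains equivariant in distribution while gaining
expressive power beyond the 1-WL limit of anonymous message passing (RNI
lets attention distinguish otherwise-identical nodes, e.g. in rings). RNI
is active at training and at sampling. The sampler can additionally
average the prediction over `rni_samples` independent RNI draws per
reverse step (the model's predictive distribution is by definition the
RNI-marginal, of which a single draw is a noisy estimate); the default is
a single draw, which at the fixture scales tested is statistically
indistinguishable from averaging.

Weights use Xavier initialization. Training uses AdamW (learning rate
`1e-4`, weight decay `1e-4`, batch 128, 500 epochs, gradient norm clipped
to 1 at production scale), with linear warmup over the first tenth of the
step budget and cosine decay to 10% of the peak rate; checkpoints are
selected by best validation loss, evaluated with a fixed RNG substream so
values are comparable across epochs. The desk preset raises the learning
rate to `4e-3` and lowers the second Adam moment to `0.99`, both standard
adjustments for runs of a few hundred steps on tiny models. The whole network and its training
loop are implemented in R on a small reverse-mode autodiff tape
(`R/autodiff.R`) whose gradients are verified against numerical
differentiation in the test suite.

### Sampling, conditioning, optimization

Generation starts from the all-mask graph at `t = T` and repeatedly samples
`G_{t-1}` from the reverse distribution, edges on the lower triangle and
mirrored. At the final step the output is the argmax of `p(x0 | G_1)` over
ordinary categories, which makes a residual `<MASK>` in the output
impossible; at every other step categories are sampled, not maximized.
Decoding drops `<PAD>` nodes, keeps the largest connected component under
non-"none" edges (ties broken by lowest node index) and sanitizes with
RDKit; failures are counted as invalid generations, never raised.

Conditional models concatenate a property embedding to the node features;
the raw value is standardized by training-set mean and standard deviation
so properties of very different scales (logP vs TPSA) train identically.

Molecular optimization reuses a trained conditional model: the start
molecule occupies the first `n_s` rows (its canonical atom order, for
reproducibility — by equivariance the choice of rows is immaterial), and
after every reverse update the constrained atom rows, charge rows and the
leading `n_s x n_s` edge block are overwritten with the scaffold's values.
Generated molecules therefore always contain the start molecule as an
exact subgraph on those rows; atoms can be added but never removed.

## Numerical and design choices

* **Transition algebra.** The forward family is closed under products; the
  cumulative matrices use the closed-form recursion
  `abar_t = alpha_t abar_{t-1}`,
  `bbar_t = alpha_t bbar_{t-1} + beta_t abar_{t-1} + K beta_t bbar_{t-1}`,
  `gbar_t = 1 - abar_t - K bbar_t`, which matches the explicit product to
  `1e-12` and avoids accumulating `T` matrix multiplications.
* **Unreachable posteriors.** `q(x_{t-1} | x_t, x0)` is undefined when
  `x_t` is unreachable from `x0`; the package returns a flagged zero vector
  instead of raising, because the configuration cannot occur in on-policy
  sampling but must be defined for exhaustive oracle sweeps.
* **Degenerate inputs.** Graphs of size 1 have no free edges; all edge
  terms are empty sums/means defined as zero. A vocabulary with a single
  charge category (common for neutral corpora) makes the charge channel
  carry zero loss, which is correct and intended.
* **The exchangeability floor.** A permutation-equivariant predictor fed a
  row-symmetric input (e.g. the all-mask graph) must emit identical
  distributions for symmetric rows, so on any corpus whose graphs have
  exchangeable rows — which padding guarantees — the training loss has an
  irreducible floor equal to the entropy of the row assignment. This is
  not a defect: reverse sampling breaks the symmetry one entry at a time
  and still concentrates on the training molecules, as the recovery tests
  show. It does mean "loss goes to zero" is only a meaningful capacity
  check on inputs with no symmetric rows (the suite uses a zero-headroom
  two-atom graph for exactly this reason).
* **Tie-breaks.** Largest-component selection prefers the component whose
  lowest node index is smallest; argmax decoding uses first-index
  tie-breaking. Both are deterministic.
* **Hydrogens, stereochemistry, isotopes.** Graphs are heavy-atom only;
  sanitization infers implicit hydrogens. Stereo descriptors and isotopes
  are stripped on encode: the model neither sees nor generates them.
* **Aromaticity.** Aromatic bonds are a first-class bond category;
  perception is delegated to RDKit on encode and trusted on decode (a
  non-aromatizable decoded ring simply fails sanitization and counts as
  invalid).

## What the fixtures emulate — and what they do not

Training corpora are enumerated fixtures with exact reference
distributions: `"enumerated_chains"` builds all unbranched chains over a
small element set (no two adjacent heteroatoms, bounded heteroatom count,
lengths 2 up to `max_heavy_atoms`), deduplicated by canonical SMILES and
weighted uniformly; `"ring_mix"` adds plain carbon rings. The default
4-atom C/O chain fixture has exactly 8 molecules, so distribution-recovery
tests can measure total-variation distance against a known target, and its
logP values split cleanly into a hydrocarbon mode (~1.1-1.8) and an
oxygenated mode (~-0.4-0.6), giving conditional-generation tests a bimodal
property with an unambiguous direction.

These fixtures exercise every code path the production model uses —
padding, all bond orders via the vocabulary, conditioning, scaffold
clamping — but they do not emulate the chemical diversity, ring systems,
charge states or size distribution of MOSES/ZINC-scale corpora. Passing
the desk-scale tests therefore demonstrates correctness of the machinery
and learnability at small scale, not benchmark-level generation quality.

## Problem sizes used by the test suite

The suite trains three small models: a single-molecule model (graph size 5,
`T = 50`, 2 layers, width 64, batch 48, 500 optimization steps), a
distribution model on the 8-chain fixture (graph size 6, `T = 24`, the
same network, 1000 steps at batch 32), and a conditional variant of the
latter (~600 steps). These sizes were chosen so that each model trains in
a few minutes on one CPU core while still reaching the regime where the
sampler reproduces the training distribution; the vignette's claims about
recovery and total-variation distance are exactly the quantities the
acceptance tests and `scripts/acceptance.R` recompute at run time.

## Known limitations

* The architecture details of the reference graph transformer are fixed by
  this package's own design (edge-stream form, normalization placement);
  they are documented above rather than inherited from a published layer
  specification.
* Optimization can only add atoms to a scaffold, never remove them, and
  inherits the conditional model's property control — properties that
  would require deleting substructures cannot be improved.
* The R implementation favors clarity and testability; it is not a GPU
  training stack, and production-scale corpora are out of its intended
  range.
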