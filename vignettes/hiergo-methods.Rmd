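---
title: "hiergo: hierarchical, ontology-aware protein function prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hiergo: hierarchical, ontology-aware protein function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiergo)
```

## The problem

Protein function prediction is multi-label classification over the Gene
Ontology (GO): given a protein, estimate for every GO term $t$ the
probability that the protein carries that function. GO is not a flat label
set — it is a directed acyclic graph across three subontologies (molecular
function, biological process, cellular component) whose terms also carry
curated textual definitions. Models that treat terms as independent labels
cannot score a term that had no training annotations; yet the ontology
evolves continuously and newly introduced or sparsely annotated terms are
exactly where predictions would be most valuable. `hiergo` implements a
framework in which both the graph structure and the definition text of GO
terms enter the model, so that an unseen term can be scored purely from its
embedding — zero-shot.

The package implements the full stack in R: ontology handling, term
embeddings, the encoder–decoder model with training, CAFA-style
evaluation, attention-based residue attribution, and a synthetic data
generator that makes every claim testable offline on one CPU.

## GO term embeddings: semantics refined by structure

Each term's definition text is embedded by a frozen sentence encoder with
mean pooling over token vectors ($x_t \in \mathbb{R}^{d_t}$). Real
deployments plug in a biomedical sentence encoder through
`text_encoder_spec()`; the package ships a deterministic hash encoder
(`hash_test_encoder()`) whose token vectors are seeded by a stable FNV-1a
hash, so texts embed identically on any platform and cosine similarity
grows with token overlap. No model download is ever required.

A linear autoencoder then injects ontology structure: the encoder is the
projection $z_t = W_{emb} x_t$ (no bias, no nonlinearity), and three
linear–softmax heads are trained to recover, from $z_t$,

* the term's ancestor set (multi-hot over all terms, self-inclusive by
  default),
* its subontology (one of three), and
* its identity (one-hot),

with a weighted positive-class cross-entropy
$L = -\alpha_{anc}\sum_i y_{anc,i}\log \hat y_{anc,i}
     -\alpha_{sub}\sum_i y_{sub,i}\log \hat y_{sub,i}
     -\alpha_{id}\sum_i y_{id,i}\log \hat y_{id,i}.$

Notes on choices that were genuinely open:

* The ancestor head is softmax "as printed" even though the target is
  multi-positive; a sigmoid multi-label mode (`anc_mode = "sigmoid"`) is
  provided. The softmax variant has a positive loss floor of
  $k \log k$ for a term with $k$ ancestors, so "loss goes to ~0" sanity
  checks are only meaningful in sigmoid mode.
* The identity target is the one-hot term identity, not the input
  embedding itself.
* Head weights default to $\alpha = (1, 1, 1)$, configurable.
* Log arguments are clamped at $10^{-12}$.

Because the encoder needs only definition text, `embed_unseen_term()`
produces latents for novel terms without touching any parameter — this is
the zero-shot path, and the frozen-parameter contract is checksummed in
tests.

## The hierarchical encoder–decoder

Residue-level embeddings $X \in \mathbb{R}^{L \times d_{seq}}$ from any
(frozen) protein language model are projected
($H^{(0)}_{enc} = X W_{seq} + \mathbf{1} b_{seq}^\top$) and refined by
$N_{enc}$ standard post-norm self-attention layers. GO latents, arranged by
a *topological ordering* $\pi$ of the subontology, are projected likewise
and decoded by $N_{dec}$ layers of

1. causal self-attention under a lower-triangular mask (each term attends
   only to itself and terms before it in $\pi$ — i.e. to more general
   terms),
2. cross-attention with queries from GO positions and keys/values from
   residues (recorded per layer and head for interpretability),
3. a position-wise feed-forward block,

each with residual connections and layer normalization. A two-layer GELU
head with a sigmoid emits one probability per term; training minimizes
binary cross-entropy over true-path-propagated targets, with the GO latents
and residue embeddings frozen.

Orderings: `"hierarchical"` sorts terms by longest-path depth from the
aspect root with lexicographic ties. Plain shortest-path BFS levels can
place a parent *after* a child in a multi-parent DAG; longest-path levels
are the breadth-layering that actually guarantees every parent precedes
every child, which the causal mask semantics require. `"go_id"` is the flat
ablation (lexicographic id order, no hierarchical meaning). Ablation
architectures: `"encoder"` replaces the causal mask with full bidirectional
attention over GO positions; `"mlp"` concatenates the mean-pooled projected
protein embedding with each projected GO latent and applies the head.

No positional encodings are added by default: contextual residue
embeddings already carry positional information, and GO order enters
through the mask, not through position-tied parameters. (That is also what
makes zero-shot insertion well-defined: a held-out term can be placed at
its topological rank at test time without any retraining.) Sinusoidal
encodings can be switched on.

The whole network, including reverse-mode gradients, is implemented in
base R matrix algebra — this environment has no deep-learning framework
for R, and the model *is* the package's subject, so it is written out
rather than borrowed. Gradients are verified against central finite
differences in the test suite (relative error ~1e-9 across all parameter
groups). Adaptive-moment (Adam) updates, minibatch accumulation, seeded
shuffling, early stopping on validation BCE.

## Evaluation

* `fmax()`: CAFA protein-centric Fmax. Thresholds 0.01–1.00 in steps of
  0.01; precision averaged over proteins with at least one call at the
  threshold; recall averaged over proteins with at least one true term;
  ties resolve to the smallest threshold; no call anywhere means Fmax 0.
* `macro_aupr()` / `micro_aupr()`: step-wise interpolated area under the
  precision–recall curve, per term averaged (terms without positives
  excluded and reported) or over pooled pairs.
* `term_centric_auc()` / `per_term_auc()`: rank-statistic ROC AUC per term
  with half credit for ties, macro-averaged over terms that have both
  classes. A term-centric "AUC" is read as this macro average — the pooled
  (micro) reading is also computable from `roc_auc()` but the macro
  average is the headline number.
* Aspect roots are excluded from scoring by default (always true after
  propagation).

All metrics are tested against independent brute-force oracles
(exhaustive threshold sweeps, $O(n^2)$ pair counts).

## Residue attribution by attention rollout

Cross-attention weights say which residues each term looked at. Heads are
averaged per decoder layer, $\bar A^{(l)} = \frac{1}{H}\sum_h A_h^{(l)}$,
and layers are aggregated by the recursion
$R^{(1)} = \bar A^{(1)}$, $R^{(l)} = \tfrac12(\bar A^{(l)} + R^{(l-1)})$.
This equal-weight recursion (unlike multiplicative attention rollout)
keeps every row a probability distribution over residues by convexity; its
closed form is $R = \sum_l w_l \bar A^{(l)}$ with $w_1 = 2^{-(N-1)}$ and
$w_l = 2^{-(N-l+1)}$ for $l \ge 2$. Row $t$ of $R$ is the per-residue
profile for term $t$; `rollout_auroc()` scores it against a binding mask
(both the final $R$ and per-layer intermediates are available). Padding
positions are dropped before scoring. Binding masks are supplied as
BED-like TSV of 0-based half-open intervals; retrieval of real
binding-site databases is out of scope.

## The synthetic world

`simulate_dataset()` builds everything the method consumes, seeded and
bit-reproducible:

* **Ontology**: three aspects, one root each; non-root terms draw 1–2
  parents from strictly shallower levels of the same aspect. Depth
  assignment is weighted $3^{d-1}$ toward deeper levels, as in real GO
  (which widens toward the leaves); at the default 70 terms per aspect
  about 45–50 are leaves. Term ids are assigned in random order so that
  lexicographic order carries no hierarchical information — otherwise the
  flat-ordering ablation would not be a real ablation.
* **Definitions**: templated sentences embedding one unique signature
  token per term plus its parents' tokens (repeated, so that parental
  context dominates the mean-pooled embedding the way informative words
  dominate real GO definitions); internal terms additionally aggregate
  all descendants' tokens. Text similarity therefore tracks ontology
  proximity, the property the embedding module exploits. The token
  weighting matters mechanistically: a held-out term's *unique* token is a
  direction the model has mostly never trained against, so zero-shot
  transfer flows through the shared parental/ancestral components — text
  templates that bury those components in boilerplate, or that
  over-emphasize the unique token, measurably weaken zero-shot recovery
  while leaving seen-term accuracy high.
* **Proteins**: residue-embedding matrices (default 40–120 residues,
  $d_{seq} = 32$, unit-scale Gaussian background). Each protein draws 1–3
  leaf terms; for each, one disjoint window of 8 residues carries the
  leaf's motif vector plus noise at signal-to-noise ratio 3 (the window
  rows are exactly the motif at SNR $\infty$). Annotations are true-path
  propagated; windows are recorded as binding masks.
* **Motif vectors**: by default (`signature_mode = "text_linked"`) the
  motif of leaf $k$ is the unit-normalized image of its definition
  embedding under one fixed random linear map
  $s_k \propto P x_k$. This makes the text-to-motif relation a single
  global linear map: a model that learns it from training leaves can apply
  it to a held-out leaf whose definition it has only read. That linkage is
  the property that makes zero-shot recovery *possible at all* in this
  world. A strictly orthonormal signature set
  (`signature_mode = "orthonormal"`) is kept as a negative control: there,
  motifs carry no relation to text, a held-out leaf's unique token points
  at nothing, and no amount of training can recover its windows — which is
  informative about what a green zero-shot test does and does not
  establish. Real protein data is of course not linear in this sense; the
  synthetic world shows the machinery can exploit such signal, not that
  real signal has this form.
* **Zero-shot scenarios**: `make_zero_shot_scenario()` removes every
  association of the held-out leaves from the training annotations
  *before* propagation, keeps the test split fully propagated, and
  prepares a shuffled-definition control in which the held-out terms'
  definitions are deranged among themselves. Held-out terms remain in the
  ontology (the embedding modules may read their text — as with real GO
  releases), but never contribute a training label; at evaluation they are
  inserted at their topological ranks.

## Numerical and design notes

* Post-norm layer arrangement by default; widths `d = 128`, 4 heads,
  `N_enc = N_dec = 2`, feed-forward width `2d` as desk-scale defaults.
* One model per subontology; targets are upward-closed binary vectors.
* Training defaults: Adam, learning rate 1e-3 (3e-3 works well at desk
  scale and is used by the pipeline examples), batch 8, early stopping
  patience 10. Shallower 1-layer variants converge substantially faster
  on small synthetic worlds and are used in the smaller-scale zero-shot
  experiments.
* The autoencoder latent dimension trades structure recovery against
  zero-shot smoothness: large `d_z` (64) recovers ancestors almost
  perfectly; small `d_z` (~24) forces held-out latents into the span of
  trained directions, which measurably improves zero-shot transfer.
* Determinism: every stochastic step derives its stream from a single
  seed; repeated runs are bit-identical, and checkpoints round-trip
  exactly. OpenBLAS is pinned to one thread at load time (unless the user
  has set it) because thread spawning dominates at these matrix sizes.
* Degenerate inputs fail loudly: all-masked proteins, empty definitions,
  unknown term ids, cycles in the ontology, NaN losses.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(synthetic_config(seed = 1))
exp <- run_experiment(ds, aspect = "MF",
                      config = transformer_config(d = 128, n_heads = 4,
                                                  n_enc = 2, n_dec = 2),
                      tc = train_config(epochs = 25, lr = 3e-3, seed = 1))
exp$report
ro <- rollout_report(exp, ds)
mean(ro$auroc)
```

On the default synthetic world this reaches protein-centric Fmax around
0.93 and term-centric AUC around 0.99 on held-out proteins, with mean
rollout AUROC around 0.99 against the planted windows (exact values are
computed by the test suite and the acceptance script; nothing here is
hard-coded).

## Known limitations

* The synthetic world's linear text-to-motif link is far cleaner than any
  real sequence–function relation; passing tests demonstrate correct
  mechanics and that the architecture can exploit ontology-text signal,
  not benchmark-level performance on real data.
* The shuffled-definition control is not a pure "no signal" null: a
  deranged definition points at *another held-out term's* motif, so its
  per-term AUC sits slightly below 0.5 rather than at chance.
* No GPU path and no minibatch padding: proteins are processed one at a
  time (desk-scale lengths make this the simpler and faster choice in R).
* Evidence-code filtering, OWL reasoning, and real-data acquisition
  pipelines are out of scope.
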