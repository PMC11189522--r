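---
title: "Methods: similarity networks and a lightweight protein language model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity networks and a lightweight protein language model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
conventions implemented, the parameters that matter, what the synthetic
corpus generator does and does not emulate, and the numerical and design
choices that were genuinely open. The workflow it describes is the one used
to explore the sequence-function space of glycoside-hydrolase families such
as the GH29 α-L-fucosidases: build a sequence similarity network (SSN) over
redundancy-reduced sequences, read its connected components as putative
isofunctional groups, and train a small BERT-style protein language model
to assign arbitrary sequences to those groups.

## Pairwise identity

Every similarity decision in the package reduces to one number: the percent
identity of an optimal pairwise alignment. Alignments are computed with
affine gap penalties (BLOSUM62, gap open 11, gap extend 1 — protein BLAST's
defaults; a gap of length $L$ costs $11 + L$), in either global
(Needleman–Wunsch) or local (Smith–Waterman) mode. Identity is

$$\mathrm{identity} = \frac{\#\text{identical columns}}
{\#\text{aligned columns}},$$

where the denominator counts *every* column of the optimal alignment — gap
columns included, and in global mode terminal gap columns too. The
convention matters and is therefore stated explicitly: counting terminal
gaps penalises length differences the way a redundancy-reduction tool's
"identity over the full alignment" does.

Two modes, two uses:

* **Network edges use global identity.** Over full-length alignments the
  identity of two unrelated uniform-random proteins of length 200
  concentrates around 0.15 and essentially never reaches 0.40, so a 0.40
  edge threshold separates families cleanly. Local-footprint identity does
  *not* have this property: the optimal local alignment of two unrelated
  proteins is often a short segment with several identical residues, and
  around a quarter of random length-200 pairs exceed 0.40 identity over
  such footprints (a 3-residue perfect match is identity 1.0). Thresholding
  local identity would therefore wire unrelated families together; the
  published SSN methodology avoids this by thresholding a full-alignment
  score, and this package follows that substance by defaulting
  `build_ssn()` to global mode. Local mode remains available in
  `align_identity()` for footprint questions.
* **Redundancy reduction chooses per pair.** When two sequences differ in
  length by less than 20% the comparison is global; otherwise local, so a
  fragment can still be absorbed by its full-length relative.

Ties between co-optimal alignments are real: two alignments with the same
optimal score can have different identities. `align_identity()`
canonicalises the argument order (longer sequence first, then
lexicographic) so the function is exactly symmetric, and the test suite
checks it against an independently written exhaustive dynamic-programming
oracle that reports the score exactly and *bounds* the identical-column and
aligned-column counts over all co-optimal alignments.

## Redundancy reduction

`reduce_redundancy()` implements greedy incremental clustering in the
longest-first style of CD-HIT: sequences are visited in order of decreasing
length (ties by input order); each joins the first representative it
matches at ≥ 0.80 identity, otherwise it founds a new cluster. Two
consequences follow from the greedy order and the symmetry of identity:
every member sits at ≥ 0.80 to its representative, and all representatives
are mutually below 0.80. The k-mer prefilter heuristics of production
CD-HIT are deliberately not reproduced — at desk scale full alignment is
affordable and exact.

## The similarity network and its clusters

`build_ssn()` computes all-vs-all identities over the representatives and
keeps pairs at ≥ 0.40 (default) as edges. `find_clusters()` takes connected
components: components with ≥ 2 nodes are "main clusters", ranked 1..K by
decreasing size (ties by lexicographically smallest member id, making
cluster ids deterministic under input permutation); single-node components
are singletons. The minimal consistent reading of "main cluster" is ≥ 2
nodes; no larger size cutoff is imposed.

Each cluster carries a **convergence ratio**: realised edges divided by
$\binom{\text{size}}{2}$. A ratio near 1 means almost every member pair
clears the identity threshold — the classic signature of an isofunctional
cluster — whereas low ratios (the literature uses < 0.30 as a warning) flag
clusters that likely mix specificities. Singletons have no convergence
ratio and asking for one is an error.

`top_k_labels()` turns the partition into a supervised label space: members
of the K largest clusters (the published analysis used K = 45) are
labelled with their cluster rank; smaller clusters and singletons stay
unlabelled and are excluded from task training.

## The language model

The encoder is a standard bidirectional transformer over amino-acid
tokens: a 26-symbol vocabulary (20 residues, X, and PAD/MASK/CLS/EOS/UNK,
with PAD fixed at id 0), learned token and position embeddings, `n_blocks`
pre-norm blocks of multi-head self-attention plus a GELU feed-forward
(sigmoid-approximation GELU), a final layer norm, and a linear
masked-language-model head. Pre-norm rather than post-norm residuals were
chosen for optimisation stability at small scale; attention queries and
keys are restricted to non-padding positions so padding never leaks in.
The published-scale defaults (5 blocks, d_model 512, 8 heads, feed-forward
2048, max length 1024) give ≈ 16.5 M parameters, in the band of the ~20 M
reported for this architecture family; the exact hidden widths of that
model are unpublished, so the parameter count is a design band, not an
invariant — what is tested is that block parameters scale linearly with
block count.

**Pre-training** is masked language modelling: each residue position is
independently selected with probability 0.15 and corrupted with the
standard 80/10/10 scheme (MASK / random residue / unchanged); the published
description leaves the corruption rate open, so the BERT defaults its architecture cites are used and both the rate and
scheme are configurable. The corpus is split 95/5 into pre-training and
validation parts (`floor` convention, tested at n = 100 and 101);
validation corruption is drawn once and frozen so the validation loss
trajectory is comparable across epochs. Optimisation is Adam; the full run
is deterministic given one seed.

**The task head** consumes the encoder's per-residue states: a linear
projection to the head width, two self-attention layers, masked mean
pooling, three dense layers (GELU between, softmax after). With the
defaults chosen here (head width 192, hidden dims 512/256, 45 classes) the
head holds ≈ 0.64 M parameters, matching the published "~0.6 M" within the
uncertainty of its unpublished widths. The backbone is frozen by default
during task training — the published procedure freezes its external
language models, and its treatment of its own backbone is unstated, so
freezing is the default and co-training is exposed as
`freeze_backbone = FALSE` (gradients flow through the head into the
encoder). Frozen training caches the encoder states once, which is also
the main performance lever. Labelled data are split 80/20 stratified by
label ("randomly selected" leaves stratification open; stratification
prevents empty classes at desk-scale n and is seeded and overridable).
Labelled sequences longer than the tokenizer's maximum are truncated, not
dropped.

**Evaluation** reports accuracy and the exponential cross-entropy (ECE)
perplexity

$$\mathrm{ECE} = \exp\!\Big(\tfrac1n \sum_{i=1}^n
\mathrm{CE}(s_i, y_i)\Big), \qquad
\mathrm{CE}(s_i, y_i) = -\log p_i(y_i),$$

with the natural logarithm — forced by the published statement that the
range runs from 1 (deterministic correct predictions) to the number of
classes (uniform predictions over 45 clusters give exactly 45). The
true-label probability is clamped at $10^{-12}$ before the log so a
confidently wrong prediction contributes a large finite term rather than
an infinity. Note the upper end of the 1..K range describes models at
least as good as uniform; a model *worse* than uniform (confidently wrong)
can exceed K — the clamp bounds it at $e^{27.6}$ rather than K.

**Baselines.** The one-hot baseline trains the identical head on raw
per-position indicator vectors over the 21-letter alphabet instead of
learned states, with the same split and optimiser; it is the control that
shows what pre-training adds. A non-pre-trained encoder is obtained by
simply skipping `pretrain_mlm()` epochs (or co-training from scratch).

**Embeddings and projection.** `embed_sequences()` mean-pools the final
hidden states over non-padding positions (the head itself uses attention
pooling; mean pooling is the standard choice for a per-sequence vector
when the published account does not specify one). `project_2d()` maps
embeddings to the plane with a deterministic spectral neighbour embedding —
a Laplacian eigenmap on a symmetrised k-nearest-neighbour graph with
heat-kernel weights, taking the two smallest non-trivial eigenvectors of
the normalised graph Laplacian, with a fixed sign convention. Like other
neighbour-embedding methods used for such maps (UMAP, t-SNE) it preserves
local neighbourhoods; unlike them it is exactly reproducible with no
stochastic optimisation, which is worth more than fidelity to any
particular algorithm for a desk-scale visual check.

## The synthetic corpus generator

`generate_families()` draws K independent uniform-random ancestors and, for
each, members that substitute every site independently with probability
$p$ (a substituted site never redraws the ancestral residue). Two members
of one family then match per site with probability

$$q = (1-p)^2 + p^2/19,$$

e.g. $q \approx 0.724$ at $p = 0.15$ — comfortably above a 0.40 network
threshold and below a 0.80 redundancy cutoff, which is exactly the regime
the real pipeline operates in. Between families identity sits at the
random-protein background. Defaults are 10 families × 40 members, length
200, $p = 0.15$.

The generator deliberately does **not** emulate: indels (so all
within-family alignments are ungapped at the optimum), biased amino-acid
composition, tree-structured descent (every family is a star around its
ancestor), domain architecture, or length variation. Passing tests on this
corpus therefore demonstrate that the machinery — thresholds, graph
analysis, training loop, metrics — behaves as specified under controlled
identity structure; they do not demonstrate biological performance on real
family data, where cluster boundaries are far less crisp.

## Problem sizes and numerical choices

The test suite runs everything at desk scale, chosen so the whole suite
completes in well under half an hour on one CPU:

* alignment-oracle comparison: 20 sequences (length ≤ 60), all 190 pairs;
* redundancy contract: 4 families × 6 members, length 100, 5 seeds;
* network family recovery: 8 families × 25 members, length 200, 3 seeds;
* semi-supervised experiment: 10 families × 40 members, length 120, tiny
  encoder (2 blocks, d_model 64, 4 heads, feed-forward 256), 20
  pre-training epochs at learning rate $10^{-3}$, 40 head epochs at
  $2\times10^{-3}$, frozen backbone, 80/20 split, 3 seeds, with the
  one-hot baseline trained under identical settings;
* masked-LM sanity: one length-60 sequence repeated 100 times, 1 block,
  30 epochs.

Other conventions fixed here: splits use the `floor` convention
(`n_train = floor(f·n)`, at least one training item per class in the
stratified case); argmax ties in predictions resolve to the smallest
cluster id; equal-size clusters rank by smallest member id; Adam uses
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$; layer norm uses
$\epsilon = 10^{-5}$; parameters initialise from
$\mathcal N(0, 0.02^2)$ under the run's seed. Every stochastic stage of
the pipeline derives its own seed from the single global seed by hashing
the stage name, so one integer reproduces a whole run, and re-running any
stage from its inputs reproduces its artefacts byte-identically on the
same BLAS build.

## Known limitations

* The neural core is plain R matrices plus small C++ kernels; it is meant
  for desk-scale experiments (hundreds of sequences, d_model ≤ 512), not
  for pre-training on tens of thousands of real sequences.
* Identity on very short local footprints is noisy by construction; use
  global mode for thresholding decisions.
* The greedy redundancy reduction is order-dependent by design (that is
  the algorithm it mirrors); representative *sets* can differ between
  orderings even though the contract holds for all of them.
* ECE comparisons between models are only meaningful on the same test
  split; the pipeline shares splits via the global seed.
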