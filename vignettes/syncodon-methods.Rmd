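---
title: "Synonym-constrained codon language modeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synonym-constrained codon language modeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncodon)
```

## The problem

The genetic code maps 64 codons onto 20 amino acids and a stop signal, so
most amino acids are encoded by several synonymous codons. Which synonym a
gene uses is far from arbitrary: codon choice shapes translation speed,
mRNA stability and protein yield, and it varies systematically between
species. A language model trained on coding DNA therefore faces two
entangled "languages" at once — the protein language (which amino acid
belongs at a position) and the codon language (which synonym is used for
it).

A conventional masked language model (MLM) over codons is penalized for
predicting *any* wrong codon, including codons of a different amino acid.
Most of its gradient therefore goes into inferring amino-acid identity,
and the learned codon embeddings end up organized by amino acid rather
than by nucleotide-level features. `syncodon` implements the alternative
training objective this package is built around: **synonym-constrained
masking**. When a codon is masked, the model's output is restricted to
the masked codon's synonymous family, so the objective carries no
information about amino-acid identity at all and the model can only
improve by learning codon-level structure.

## The constrained objective

Let $f_\theta(x_M)_i \in \mathbb{R}^V$ be the logits at masked position
$i$ for the masked input $x_M$, over a vocabulary of $V = 69$ tokens (64
codons + 5 special tokens). The constraint is additive: a $V \times V$
matrix $C$ with $C[t, v] = 0$ when $v$ is a codon synonymous with codon
$t$ and $-\infty$ otherwise. For each masked position the row of $C$
indexed by the *true* codon is added to the logits,

$$z_{i,v} = f_\theta(x_M)_i[v] + C[x_i, v],$$

and the loss is the average negative log likelihood over the masked set
$M$:

$$\mathcal{L}_{\mathrm{MLM}} = -\frac{1}{|M|} \sum_{i \in M}
  \log \mathrm{softmax}(z_i)[x_i].$$

Because `exp(-Inf)` underflows to exactly zero in double precision, the
softmax places *exactly* zero probability outside the family — this is an
algebraic guarantee, not an approximation, and the package's tests assert
it with `identical()`. Two consequences follow and are also tested:

* a masked codon from a singleton family (ATG, TGG) contributes exactly
  zero loss;
* the gradient of the loss at constrained-out logit entries is exactly
  zero, so training never moves probability mass across families.

With uniform logits the per-position loss has the closed form
$\ln n_i$, where $n_i$ is the family size; these closed forms (e.g.
$\ln 6 \approx 1.7918$ for leucine) serve as oracles for the loss
implementation, and the corpus average of $1/n_i$ is the analytic
accuracy baseline of a constrained model that has learned nothing beyond
the family structure.

The row of $C$ is indexed by the true label, which is well defined during
training only. At inference the same mechanism conditions on a known
protein sequence instead: the user supplies the target amino acid per
position, which selects the same family row.

### Which family? Split boxes

One could read "synonymous" as the full amino-acid family or as the
codon box sharing the first two bases (serine splits into TC* and AG*).
The package defaults to full families — the constraint condition is
synonymy of the encoded amino acid — and offers
`genetic_code(split_boxes = TRUE)` for the box-level reading. The
genetic-code table itself comes from `Biostrings::getGeneticCode()`
(NCBI table 1 by default, pluggable id); the three stop codons form one
family, since RefSeq-style CDS carry a terminal stop that is tokenized
and maskable like any codon (only *internal* stops are rejected in
curation).

## Tokenizer and species-aware inputs

The tokenizer is a fixed 69-token vocabulary: `[CLS]`, `[SEP]`,
`[MASK]`, `[PAD]`, `[UNK]`, then the 64 DNA codons in lexicographic
order. A CDS is framed as `[CLS] codon ... [SEP]`; sequences beyond the
position limit are truncated from the right before the end token.

Species context enters through token-type embeddings. Rather than one ID
per species (tens of thousands), species are grouped by codon-usage
similarity:

1. per species, codon counts are reduced to an RSCU vector — for codon
   $j$ in a family of size $n_i$ with family total $T_i$,
   $\mathrm{RSCU}_{ij} = n_i X_{ij} / T_i$ (the classical convention),
   over the 59 codons in non-stop families of size $\ge 2$; zero-count
   families get the neutral value 1 so small species remain well defined;
2. a budget of cluster IDs (500 in the full-scale setting, plus one
   reserved "unknown") is allocated across taxon groups proportionally to
   CDS counts by largest remainder, each taxon getting at least one;
3. within each taxon, species are clustered by k-means on raw RSCU
   values (Euclidean distance; RSCU is already family-normalized, so no
   further standardization). We use `stats::kmeans` with 10 random
   restarts rather than a k-means++ initialization; with the restart
   count this is equally robust and keeps the implementation in base R.
   Clustering is per taxon with the pre-allocated k, which is how the
   ID-budget breakdown reads most naturally.

Unseen species map to the reserved unknown ID, so the model remains
usable without species information.

## Curation

`curate_cds()` applies, in order: validation (canonical A/C/G/T, length
divisible by three, no internal stop), per-species exact-duplicate
removal (first occurrence kept), optional taxon stratification, and a
seeded 98/2 train/test split (round-half-even on $n \times$ fraction).
Stratification caps every taxon group's *codon* total at a reference
group's total by removing whole records uniformly at random — sequences
are never truncated. Similarity clustering at 90% nucleotide identity /
80% coverage (MMSeqs2) is deliberately out of scope: it is an external
tool's job, and the pipeline accepts its representatives as input. The
ordering — validate, dedupe, (external clustering), stratify, split — is
a design choice; the split is performed last so the stratified corpus is
what gets partitioned.

## The encoder

The encoder is a bidirectional transformer with disentangled
content/position attention in the DeBERTa style: attention scores sum a
content-to-content term, a content-to-position term and a
position-to-content term over clipped relative distances, scaled by
$1/\sqrt{3 d_h}$; a single relative-position embedding table is shared
across layers, and no absolute-position embedding is added to the
inputs. Input vectors are the sum of the token embedding and the
sequence's token-type embedding. The language head is weight-tied:
logits are inner products of final hidden states with rows of the input
embedding table plus a per-token bias. Weight tying is what makes the
geometry of the input embeddings interpretable — the same rows score the
output — and the package asserts the tie directly (perturbing a row
changes both sides).

Three presets are provided: `desk` (2 layers, hidden 64, 4 heads — the
size exercised by tests and demonstrations), `ablation` (320/1280/6/5,
about 9M parameters) and `full` (768/3072/12/12, maximum 1024 positions,
counting the `[CLS]`/`[SEP]` tokens within the limit). The forward and
backward passes are written in R matrix algebra with the attention
kernels in RcppArmadillo; gradients are verified against central finite
differences in the test suite. Training uses AdamW (decoupled weight
decay on weight matrices and embedding tables only) under a linear
warmup over the first 10% of steps to the peak rate followed by cosine
decay to zero.

Masking uses pure mask-token replacement for every selected position
(default rate 0.15). The conventional 80/10/10 corruption is available
behind a flag but is not the default: replacing a masked codon by a
random *non-synonymous* codon interacts incoherently with a constraint
row indexed by the true label. Special tokens are never masked; the
terminal stop codon is maskable.

## Synthetic data: what it emulates and what it does not

The generators produce the statistical structure the method assumes,
at desk scale:

* `make_species_profiles()` draws taxon-level Dirichlet means per family
  and species-level profiles around them, so RSCU clustering has a
  planted, recoverable taxonomy. The default concentration (200) makes
  species clearly clusterable but visibly noisy.
* `sample_cds()` emits valid CDS (ATG start, single terminal stop) from
  a profile, optionally with a first-order wobble-base transition.
* `make_variant_library()` holds a protein constant and varies only the
  codons, with fitness $y = \beta \cdot \mathrm{GC3} + \varepsilon$. GC3
  is the declared codon-level feature because wobble-base composition is
  the axis along which the constrained model's own embedding analysis
  organizes; other features can be plugged in.
* `mutate_synonymously()` replaces a fraction of the degenerate codon
  positions (families of size $\ge 2$; the percentage base excludes
  ATG/TGG, which cannot change) by a uniformly chosen *different*
  synonym: level 1 changes 100% of degenerate positions and any level
  preserves the protein exactly. The count of mutated positions is
  `round(level * D)`.
* `make_demo_corpus()` plants *two* independent signals: a first-order
  amino-acid Markov chain (each residue prefers three successors with
  weight 8 against 1) and a cyclic wobble-base transition (A→C→G→T→A
  with probability 0.75). The protein-level chain is what gives an
  *unconstrained* objective something amino-acid-like to learn — with a
  uniform random protein it would have no reason to organize embeddings
  by amino acid, unlike models trained on real (predictable) proteins.
  The codon-level chain is invisible to the protein language and is what
  the *constrained* objective learns. Both parameters were fixed once as
  the planted-benchmark conditions.

None of this emulates mRNA secondary structure, ribosome dynamics, or
real expression measurements. A passing demonstration shows that the
training objective isolates codon-level signal when one exists; it says
nothing about how much such signal real libraries carry.

## The desk-scale demonstration

The ablation-style demonstration trains twin 2-layer models (hidden 64,
4 heads, dropout 0) on 2,000 demo-corpus CDS of 20 residues for 25
epochs at batch size 50, peak learning rate $3 \times 10^{-3}$ — one
twin with the constraint, one without. The peak rate is deliberately
higher than the $2 \times 10^{-4}$ of the full-scale configuration: a
~1,000-step run of a 100k-parameter model sits in a very different
optimization regime from an 82k-step run of a 102M-parameter model, and
at $2 \times 10^{-4}$ the small model barely leaves its initialization
within the step budget. Problem sizes were chosen so the whole
demonstration (both twins plus the embedding analysis) runs in minutes
on one CPU.

The demonstration then checks the qualitative claims:

* the constrained twin's masked accuracy exceeds the analytic uniform
  baseline $\overline{1/n_i}$ by a wide margin;
* its codon input embeddings separate significantly by wobble base
  (PERMANOVA) but show no amino-acid structure;
* the unconstrained twin's embeddings separate significantly by amino
  acid.

## Evaluation machinery

Frozen-embedding probing follows the standard protocol: mean-pooled
encoder states, a single affine head trained by Adam on MSE with both L1
and L2 penalties (defaults $10^{-4}$ each, learning rate $10^{-3}$,
100 epochs, batch 16 — all configurable), five-fold cross-validation
repeated over seeds (default 30), per-seed fold-averaged $R^2$, and
two-sided paired t-tests on the per-seed values. Pairing by per-seed
averages (rather than per-fold values) is the reading adopted for the
repeated-CV protocol. The t statistic is computed in closed form with a
hard error on zero-variance differences. $R^2$ on a held-out fold uses
the fold's own mean in $SS_{tot}$.

Target scaling is fitted on the whole dataset before cross-validation —
matching the protocol this package implements, which scales each dataset
once — with the caveat that this leaks distributional information across
folds; min-max scaling is the default and Yeo-Johnson (ML lambda via
`car::powerTransform`, then standardization) is for heavily skewed
targets.

The mutation-sensitivity scan fits probes on embeddings of unmutated
training folds and evaluates on mutated test folds at levels 10%–100%
(batch size 64), quantifying how much of the learned signal rides on
codon choice: an embedding that only sees the protein gives a flat
curve, one that encodes codon composition degrades.

## Embedding geometry

`extract_codon_embeddings()` reads the 64 codon rows of the input table
(no forward pass — these are the tied head rows). Grouping labels come
in three schemes: wobble base (4×16), suffix dinucleotide (16×4) and
amino acid (21 groups). PERMANOVA computes the pseudo-F from pairwise
squared Euclidean distances via the within-group decomposition, with a
seeded permutation p-value $(1 + \#\{F^* \ge F\})/(1 + B)$, $B = 999$ by
default. Significance is tested in the **full-dimensional** embedding
space, not in a 2-D projection — projections distort distances, and the
test needs none of them; a flag allows testing projected coordinates for
comparison. Amino-acid PERMANOVA drops the singleton groups (ATG, TGG),
since a group of one has no within-group distance.

For visualization, `project_2d()` offers PCA and an exact (all-pairs)
t-SNE with entropy-calibrated affinities, early exaggeration, momentum
and adaptive gains — at 64 points an exact implementation is both
simpler and more faithful than tree-approximated variants, and it
accepts any perplexity below $n$ (the conventional default of 30 is used
with the 64 codons). `perplexity_sweep()` re-projects across a grid of
perplexities and scores label separation by mean silhouette width, the
robustness check that a clustering pattern is not an artifact of one
perplexity setting.

## Numerical choices and degenerate inputs

* $-\infty$ is stored literally in the constraint matrix; added to
  finite logits it yields exact zeros after softmax. Rows for special
  tokens are all $-\infty$ (never prediction targets), and masking a
  special token is an error.
* Argmax ties in accuracy break to the lowest token id,
  deterministically.
* Largest-remainder allocation breaks remainder ties by order; the
  at-least-one floor takes from the largest allocation.
* k-means with $k$ equal to the number of distinct profiles returns the
  exact partition (one cluster per distinct profile) rather than calling
  `stats::kmeans`, which rejects that boundary case; identical RSCU
  vectors therefore always share a type ID.
* All stochastic steps (masking, dropout, shuffling, generators,
  permutation tests, CV splits) are seeded; runs are bitwise
  reproducible given the seed.
* Empty sequences tokenize to `[CLS] [SEP]`; `|M| = 0` batches are an
  error for the loss and are skipped by the training loop.

## Scripted use

The package surface is functions-first; `inst/cli/syncodon.R` provides a
thin Rscript wrapper (vocabulary/mask export, curation, synthesis,
mutation) for shell pipelines, and `scripts/acceptance.R` recomputes the
package's measured headline quantities from scratch (see the README).

## Limitations

* The full-scale configurations (102M parameters, 43.5M sequences) are
  represented as presets only; nothing here reproduces numbers that
  depend on GPU-scale pretraining, and the demonstration's statistics
  are qualitative analogues, not replications.
* Similarity-based redundancy removal is delegated to external tools.
* The alternative-code plumbing supports any NCBI translation table, but
  all defaults and tests use the standard code.
* The synthetic fitness model is linear in a single declared feature;
  real synonymous-variant libraries are richer in every way.
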