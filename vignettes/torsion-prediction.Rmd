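---
title: "Methods: evolutionary-signature features and recurrent torsion-angle regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary-signature features and recurrent torsion-angle regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(esiden)
```

# The model

`esiden` predicts per-residue backbone torsion angles (φ, ψ) from
sequence-profile features. The pipeline has three stages: feature
extraction, recurrent regression, and periodic-error evaluation.

## Features

For a chain of length L, seven blocks are concatenated in the fixed
order AA | PP | PSSM | RE | DC | PSSP | RBP (widths 20, 7, 20, 20, 1,
20, 144; total 232). The order itself carries no meaning — it is fixed
only so that serialized feature matrices and trained models are
mutually consistent.

**Relative entropy.** For MSA column i and amino acid a with observed
frequency $f_i^a$ and background $p^a$,
$$\mathrm{RE}_i^a = f_i^a \ln\frac{f_i^a}{p^a} +
  (1-f_i^a)\ln\frac{1-f_i^a}{1-p^a},$$
the KL divergence between the Bernoulli distributions $(f, 1-f)$ and
$(p, 1-p)$. It is nonnegative and zero exactly at $f = p$. We adopt the
standard convention $0 \ln 0 = 0$; a background with $p^a \in \{0, 1\}$
is rejected as a domain error. Gap characters are excluded from the
column counts and the remainder renormalized (with an optional additive
pseudocount per amino acid), so the features describe the residues
actually observed.

**Degree of conservation.** $D_i = \sum_{a=1}^{20} \mathrm{RE}_i^a$, an
exact row sum (verified to machine precision in the tests).

**Background distribution.** The default $p^a$ is the Robinson &
Robinson (1991) amino-acid frequency table, a standard choice for
profile methods; `background_mode = "pooled"` instead pools the non-gap
frequencies of the alignment at hand. Both are exposed because the
choice is genuinely open: a fixed table makes features comparable
across proteins, pooling adapts to compositionally biased families.

**PSSP.** The evolutionary statistical energy
$E(\tau) = \sum_{i<j} e_{ij}(\tau_i, \tau_j) + \sum_i h_i(\tau_i)$
reduces, when the pairwise couplings $e_{ij}$ are not considered, to an
independent-site model whose maximum-likelihood fields have the closed
form $h_i(a) = \ln \tilde f_i(a) - \frac{1}{20}\sum_b \ln \tilde f_i(b)$
under the zero-sum gauge, where $\tilde f$ are the pseudocount-smoothed
column frequencies. The PSSP is the per-row softmax of $h$, and
$\mathrm{softmax}(h_i) = \tilde f_i$ exactly — a parameter-recovery
identity the test suite checks at 1e−9. We deliberately use this closed
form rather than a full Potts optimization: it is deterministic,
testable, and the couplings are out of scope by design. Pairwise
inference (contact prediction) is explicitly a non-goal.

**Ramachandran basin potential.** Torsion observations
(left, center, right, φ, ψ) are binned on a 72×72 grid of 5°×5° cells.
Bins are half-open $[\ell, \ell+5)$ on the angle domain $[-180, 180)$,
with +180° wrapping to −180°, which removes boundary double-counting.
One map is kept per (left, center, right) triplet and one per center
residue; triplet maps with fewer than `min_triplet_count` (default 20)
observations fall back to the center map, since $20^3$ triplets are
sparse in small corpora. A per-bin pseudocount (default 1/5184, i.e.
one observation spread across the grid) makes every retained map a
proper probability distribution, and — when positive — guarantees a
backoff map for all 20 residues so downstream lookups never fail.
Secondary structure is not conditioned on (`ss_mode = "A"`). The
center-map = count-weighted-mixture-of-triplet-maps identity at zero
pseudocount is a tested invariant.

Each 72×72 map is reduced to 72×2 by embedding the 72 φ-rows as points
in the 72-dimensional ψ-space. The orientation (rows as points) is a
convention we fix and document because only the overall 72×72 → 72×2
shape is externally constrained. Two reducers are provided: t-SNE
(exact, with perplexity calibration by binary search, early
exaggeration, momentum gradient descent; implemented in-package since
no R t-SNE implementation is otherwise available here) and PCA
(`stats::prcomp`, first two components, with a deterministic sign
convention — the largest-magnitude loading of each component is made
positive). PCA is the default in tests and the serialized potential
records method and seed, because t-SNE's hyperparameters are an open
choice and bit-reproducibility is a hard requirement. Per residue the
embedding of its triplet key (or center backoff at the termini and for
unseen triplets) is flattened row-major to 144 values.

**Classic features.** Amino-acid one-hot uses alphabetical one-letter
order with `'X'` mapping to a zero row; the seven physicochemical
descriptors (steric parameter, polarizability, normalized van der Waals
volume, hydrophobicity, isoelectric point, helix and sheet
probability) come from the Meiler et al. (2001) table, with `'X'`
taking per-property means; PSSMs are read from PSI-BLAST ASCII output.

**Scaling.** All channels are min–max mapped to $[-1, 1]$. Bounds are
fitted on the training set only, persisted with the model, and
test-time values outside the bounds clip. One-hot channels are flagged
identity (they are in range by construction); constant channels pass
through with a warning. Dataset-level rather than per-protein scaling
is used so that a residue's features mean the same thing in every
chain.

## The network

The input L×232 matrix feeds, in parallel, a unidirectional LSTM and a
bidirectional LSTM; their per-position outputs are concatenated and fed
to a second bidirectional LSTM, then a 256-unit fully connected layer
with ReLU and dropout 0.8 (training only), then a 4-unit sigmoid
output layer. The four outputs per residue are
(sin φ, cos φ, sin ψ, cos ψ) affinely mapped to $[0, 1]$ via
$t = (x+1)/2$ — the sigmoid output range and the trigonometric target
range differ, and this explicit affine bridge is the cleanest
resolution. Decoding inverts the map and applies the two-argument
arctangent; the single-argument ratio $\arctan(\sin/\cos)$ would lose
the quadrant. Positions whose recovered (sin, cos) both lie within
1e−6 of zero are masked with a warning rather than decoded arbitrarily.

Hidden sizes are free parameters. The defaults (352 per LSTM direction)
give 6,620,292 learnable parameters by the analytic count
$4H(I{+}H{+}1)$ per LSTM direction plus the FC terms, matching the
intended "small" model scale of roughly 6.6M; everything is
configurable through `model_config()`. Weights initialize uniformly in
$\pm 1/\sqrt{H}$ with a +1 forget-gate bias offset, from the
configuration seed.

Variable-length chains are padded per batch, and the recurrent state is
multiplied by the per-step validity mask after every update. This
zeroes the state at padded steps in both directions, so padding can
never leak into real positions — a property the tests assert at 1e−6
for two different padded lengths. Training minimizes the MSE over
unmasked target entries only (terminal φ/ψ and structure gaps are
excluded from both the loss numerator and denominator; masked entries
contribute exactly zero gradient, asserted bitwise). The optimizer is
Adam at learning rate 0.001 with batch size 32, length-bucketed
batches, up to 5000 steps by default ("iterations" is read as optimizer
steps), dropout read as drop probability 0.8, and the best checkpoint
selected by validation MAE. All randomness — initialization, shuffling,
dropout, the validation split — derives from explicit seeds, and
identical seeds give bit-identical loss histories.

The entire network (forward, backpropagation through time, Adam) is
implemented in vectorized base R. Analytic gradients are verified
against central-difference numerical differentiation for every weight
tensor in the test suite.

## Evaluation

$$\mathrm{MAE} = \frac{1}{\sum_i L_i}\sum_{i=1}^{N}\sum_{j=1}^{L_i}
\min\left(|P_{ij}-E_{ij}|,\ 360^\circ - |P_{ij}-E_{ij}|\right)$$

pooled over all chains, separately for φ and ψ. Masked residues
(terminal angles, chain breaks) are excluded from both the numerator
and $\sum L_i$: the summation formally runs over all residues, but
undefined terminal angles cannot contribute an error term, and
excluding them from the denominator is the only self-consistent
reading. This choice is deliberate and documented here prominently.
`mae_by_class()` restricts the same statistic to residues of each
Q3/Q8 class; classes with no residues are reported as missing (`NA`),
never as zero. Labels are accepted as input from any assignment tool —
no secondary-structure assigner is implemented. The pooled MAE equals
the count-weighted mean of the class MAEs, an identity checked
numerically.

# The synthetic-data generator

The generator stands in for curated structure datasets, which require
database searches and downloads out of scope here. It emulates:

- **Segmental secondary structure** — helix/strand/coil segments of
  4–12 residues with class-mean angles (−63, −42), (−120, 130),
  (−75, 150) and wrapped-normal noise (default sd 8°), the classic
  Ramachandran basin centers.
- **Sequence–structure coupling** — each class draws residues from a
  class-specific alphabet (helix formers, β-branched/aromatic strand
  residues, turn/coil residues), so sequence genuinely predicts local
  conformation and the network has a learnable signal.
- **Backbone geometry** — coordinates are built from the prescribed
  torsions with ideal bond lengths/angles (N–CA 1.458 Å, CA–C 1.525 Å,
  C–N 1.329 Å; N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°) and a
  planar trans peptide (ω = 180°), via natural-extension-reference-frame
  placement. Build-then-extract round-trips reproduce the prescribed
  angles to better than 1e−3°.
- **Alignments with controlled conservation** — per column, a
  distribution drawn from a Dirichlet mixing the query residue (weight
  = the conservation parameter, default 0.85) with the background, from
  which rows are sampled i.i.d. with a 5% gap rate; MSA depth defaults
  to 30.
- **PSSMs** — synthetic log-odds $\mathrm{round}(2\log_2 \tilde f/p)$
  from the smoothed column frequencies, shaped like PSI-BLAST output.

The default study conditions are 50 chains of length 30–60. These
sizes keep every experiment in this package's test and acceptance runs
within minutes on a single CPU while remaining large enough for the
learning-sanity contrasts to be unambiguous.

What the generator does **not** emulate: real evolutionary covariation
between columns (columns are independent given the conservation
profile), realistic secondary-structure grammar, loops/cis-prolines,
side-chain-dependent Ramachandran fine structure, alignment errors, or
the depth and redundancy structure of real MSAs. Passing the
learning-sanity tests therefore shows the pipeline is wired correctly
and the network can exploit a genuine sequence→conformation signal; it
does not certify benchmark accuracy on real proteins, which requires
real training corpora and is outside this package's scope.

# Numerical choices and degenerate inputs

- Angles live in $[-180, 180)$; +180 wraps to −180 everywhere
  (binning, decoding, comparison).
- Dihedrals use the IUPAC sign convention via atan2, cross-checked
  against `bio3d` and an independent plane-normal implementation;
  coincident points or parallel consecutive bond vectors raise domain
  errors rather than returning NaN.
- Chain breaks are declared when the C–N peptide distance exceeds
  2.0 Å (the ideal bond is 1.33 Å); the spanning φ/ψ are masked.
- PDB altlocs resolve to the highest occupancy, ties by label order;
  nonstandard residues map to `'X'` (MSE to M); only the first model of
  multi-model files is read.
- All-gap columns with zero pseudocount, empty observation streams, and
  all-masked training sets raise errors instead of silently producing
  NaN statistics.
- Relative-entropy values within −1e−12 of zero (round-off at
  $f \approx p$) are clamped to 0 to preserve the nonnegativity
  invariant.
- Masked torsion entries carry a 0 sentinel but are excluded from every
  statistic by their mask; serialization writes them as `NA`.

# Known limitations

- Training in base R is practical for the toy problem sizes used here,
  not for corpus-scale training; the architecture and training loop are
  faithful, but large-scale fitting would need a compiled backend.
- The MSA row-gap trimming rule (drop rows with more than a fraction —
  default 0.5 — of gaps over query columns) is a simple, exposed stand-in
  for more elaborate alignment-filtering heuristics.
- The t-SNE reducer is exact and intended for the 72-point basin maps;
  it is not a general-purpose embedding tool.
- Q8 labels are consumed, never produced; pair with an external
  secondary-structure assigner if per-class breakdowns are needed.
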