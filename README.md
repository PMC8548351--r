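# esiden

Protein backbone torsion-angle prediction from evolutionary signatures,
in R.

## The problem

The backbone torsion angles φ and ψ largely determine a protein's local
conformation, and accurate per-residue (φ, ψ) predictions are valuable
structural constraints for tertiary-structure prediction and refinement.
`esiden` implements a sequence-to-sequence regression system for these
angles built on four evolutionary-signature features computed from a
protein's multiple sequence alignment (MSA) and from structure
statistics:

- **Relative entropy (RE)** — for column *i* and amino acid *a*, the
  binary Kullback–Leibler divergence between the observed column
  frequency f<sub>i</sub><sup>a</sup> and a background p<sup>a</sup>:
  RE<sub>i</sub><sup>a</sup> = f ln(f/p) + (1−f) ln((1−f)/(1−p)) (L×20).
- **Degree of conservation (DC)** — D<sub>i</sub> = Σ<sub>a</sub>
  RE<sub>i</sub><sup>a</sup>, a per-column conservation score (L×1).
- **Position-specific substitution probabilities (PSSP)** — the softmax
  of the site-field terms h<sub>i</sub>(a) of an evolutionary statistical
  energy E(τ) = Σ e<sub>ij</sub> + Σ h<sub>i</sub>, fitted in the
  independent-site closed form (pairwise couplings are not used) (L×20).
- **Ramachandran basin potential (RBP)** — (φ, ψ) probability maps on a
  72×72 grid of 5°×5° bins, conditioned on each residue and its left and
  right sequence neighbors with center-residue backoff, reduced to a
  72×2 embedding (t-SNE or PCA) and flattened to 144 values per residue
  (L×144).

Together with the classic features — amino-acid one-hot (L×20), seven
physicochemical properties (L×7), PSI-BLAST PSSM (L×20) — these form an
L×232 input matrix, min–max scaled to [−1, 1]. A recurrent network (a
unidirectional LSTM in parallel with a BiLSTM, concatenated into a
second BiLSTM, then a 256-unit ReLU layer with 80% dropout and a 4-unit
sigmoid output) regresses (sin φ, cos φ, sin ψ, cos ψ) per residue;
angles are decoded with the quadrant-aware arctangent atan2(sin, cos).
The default configuration has ~6.6M learnable parameters. The forward
pass, backpropagation through time, and the Adam optimizer (learning
rate 0.001, batch size 32, MSE loss on unmasked sin/cos targets) are
implemented natively in R — no deep-learning framework is required.

Accuracy is scored with the wrap-aware mean absolute error

MAE = (1/ΣL<sub>i</sub>) Σ<sub>i</sub> Σ<sub>j</sub>
min(|P<sub>ij</sub> − E<sub>ij</sub>|, 360° − |P<sub>ij</sub> − E<sub>ij</sub>|),

pooled over chains and optionally split by Q3/Q8 secondary-structure
class. Terminal φ/ψ and residues at chain breaks are masked throughout.

## Who it is for

Structural bioinformaticians who want an inspectable, fully seeded,
dependency-light implementation of profile-feature extraction and
recurrent torsion regression: readers for FASTA / aligned FASTA / A3M /
PDB backbones / PSI-BLAST ASCII PSSMs, the feature pipeline, the
network, the periodic-error evaluation, and a synthetic-data generator
that makes the whole system testable without any database downloads.

## Worked example

Using the packaged synthetic fixtures (a 25-residue chain with its
alignment and structure):

```r
library(esiden)

msa <- read_msa(system.file("extdata", "synthetic_chain.afa",
                            package = "esiden"), "afa")
msa
#> <aligned_msa> 21 rows x 25 columns (query: synthetic_chain)

fx <- evolutionary_features(msa)   # trims, profiles, computes RE/DC/PSSP
round(fx$dc[1:5], 3)
#> [1] 0.758 0.912 0.981 0.752 0.799

chain <- read_pdb_backbone(system.file("extdata", "synthetic_chain.pdb",
                                       package = "esiden"), "A")
ts <- extract_torsions(chain)
head(ts, 3)
#> # A tibble: 3 × 6
#>    resi aa      phi   psi phi_mask psi_mask
#>   <int> <chr> <dbl> <dbl> <lgl>    <lgl>
#> 1     1 N       0    156. FALSE    TRUE
#> 2     2 P     -70.3  136. TRUE     TRUE
#> 3     3 N     -77.3  145. TRUE     TRUE

set.seed(1)
noisy <- new_torsion_series(ts$phi + rnorm(25, sd = 12),
                            ts$psi + rnorm(25, sd = 12),
                            ts$phi_mask, ts$psi_mask)
mae(noisy, ts)
#> <eval_report> 1 chains: MAE(phi) 9.27 deg (n=24), MAE(psi) 6.45 deg (n=24)
```

The DC values are per-column conservation scores (nats); the
`torsion_series` tibble carries angles in degrees with terminal masks
(φ undefined at residue 1, ψ at the last residue); the evaluation
report pools the shorter-arc absolute error over the 24 unmasked
residues of each angle. End-to-end training runs on the seeded
synthetic dataset:

```r
toy <- make_toy_dataset(synthetic_spec(n_chains = 50, seed = 11))
cfg <- model_config(lstm1_hidden = 16, bilstm_hidden = 16,
                    bilstm2_hidden = 16, fc1_units = 64,
                    fc1_dropout = 0.2, seed = 5)
st <- train_model(build_model(cfg), toy$examples[1:40],
                  val_dataset = toy$examples[41:50], max_steps = 400)
preds <- lapply(41:50, function(i) predict(st$model, toy$examples[[i]]$x))
mae(preds, toy$torsions[41:50])
```

A command-line wrapper covering angle extraction, feature generation,
potential building, training, prediction and evaluation is installed at
`system.file("cli", "esiden.R", package = "esiden")`.

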