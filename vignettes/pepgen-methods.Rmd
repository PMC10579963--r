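---
title: "pepgen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepgen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepgen)
```

`pepgen` designs short peptides intended to occupy the pyrin-domain (PYD)
interface through which the NLRP3 inflammasome sensor recruits its ASC
adaptor. The pipeline has three computational legs: a generative sequence
model, physicochemical/spectroscopic screening, and a molecular-dynamics
contact statistic. This vignette explains each model, the parameters that
matter, and the choices made where the design was genuinely open.

## The sequence model

### Vocabulary and encoding

Peptides are strings over the 20 canonical amino acids. The model works on
a 22-token vocabulary: the residues in alphabetical order (indices 0–19),
a combined padding/start token `X` (20), and an end-of-sequence token `$`
(21). Every sequence is rendered as `X` + residues + `$`, right-padded with
`X` to a fixed window (longest sequence + 2 by default). Making `X` double
as the start token keeps the vocabulary at exactly 22 symbols, matching the
22-way softmax output; the explicit `$` gives sampling a termination
signal.

Targets for next-token training are the window shifted by one. Positions
whose target is the padding token are excluded from the loss by default:
with 9–15-residue peptides in a shared window, pad targets would otherwise
dominate the objective with trivially predictable classes and deflate the
reported loss. `model_config(include_pad_loss = TRUE)` restores the
all-positions loss for parity experiments with frameworks that do not mask.

### Architecture and training

The model is a unidirectional LSTM — one or two layers of `units` memory
cells with input, forget and output gates — followed by a dense layer with
22 outputs and a softmax. The production configuration is
`model_config()`: 2 × 256 units, dropout 0.30 and 0.45 on the first and
second layer outputs (applied only during training, with inverted
scaling), Adam at learning rate 0.02, and a 200-epoch budget. The forget
gate is initialized with a fixed bias of 1.0, which keeps early cell-state
gradients alive; the value is configurable. Weights are Glorot-uniform
initialized. Everything — initialization, epoch shuffling, dropout masks —
derives from the single integer `seed`, so a `(corpus, config, seed)`
triple reproduces weights, loss traces and samples bit-for-bit, and
checkpoints round-trip exactly (JSON header + little-endian doubles).

The loss is categorical cross-entropy in nats,
$L(t,y) = -\sum_{k=1}^{22} t_k \log y_k$, averaged over unmasked
positions. A uniform prediction therefore scores $\ln 22 \approx 3.091$,
which is also the natural sanity anchor for untrained models. Predicted
probabilities are not clipped: a zero probability at a target position is
an error unless an explicit `epsilon` is configured, because silent
clipping hides divergence.

The backward pass is full backpropagation through time, written against
the forward cache; it is verified in the test suite against central finite
differences (worst relative error observed ≈ 7 × 10⁻⁷ on a 2-layer
model). Adam uses the standard β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸ with bias
correction.

### Cross-validation

`cross_validate()` shuffles the corpus once with `base_seed`, splits it
into `k = 5` contiguous folds, and re-initializes the weights with
`base_seed + fold` for every fold so no residual knowledge carries over.
For each architecture in the grid the per-epoch validation losses are
averaged across folds, and the selected architecture minimizes the minimum
of that averaged curve — i.e. the best epoch of the fold-mean validation
loss. The canonical grid spans {24, 48, 128, 256, 512} units in one or two
layers; any list of `model_config()` objects is accepted.

### Sampling

Generation primes the recurrent state with `X` and draws tokens from the
softmax after dividing logits by `temperature` (default 1.0, not stated in
the underlying protocol; 1.0 samples the learned distribution unmodified).
`temperature = 0` is accepted as greedy argmax decoding. A draw terminates
at `$` or after `max_len` residues. Draws that contain a mid-sequence pad
token or are empty are discarded as invalid; exact duplicates and
training-set matches are removed by `dedupe_against()`, mirroring the
two stated retention filters (uniqueness and novelty) — no further
retention criterion is applied.

### The memorization fixture

A standard convergence check is that a small model memorizes a tiny
corpus. One subtlety dictates the fixture design: for $m$ distinct,
equally likely training sequences the cross-entropy cannot fall below the
corpus entropy $\ln m$ spread over the scored positions, i.e.
$\ln(m)/(L+1)$ per position for length-$L$ sequences (the $+1$ is the end
token). Ten distinct 9–15-mers therefore have a floor of ≈ 0.18 nats — no
model can go lower, however long it trains. The memorization fixture
consequently uses ten distinct sequences of length 28–32, whose floor is
≈ 0.075 nats; the 2 × 64 model reaches ≈ 0.076 within 500 epochs, i.e.
essentially perfect memorization. The companion check is distributional:
300 temperature-1 draws from the memorized model regenerate ≥ 9 of the 10
training sequences and > 90% of the draws are training sequences (a
deterministic greedy decode from the single shared start state can only
ever emit one sequence, so coverage is the meaningful statistic).

## Corpus preparation

`length_filter()` keeps peptides with 9–15 residues (closed bounds,
configurable — corpora with longer outliers can simply widen them).
`pairwise_identity()` is a global Needleman–Wunsch alignment with match
+1, mismatch 0 and a linear gap penalty of 1 per position, with identity
defined as matched positions over the shorter sequence length — the
CD-HIT-style denominator, switchable to alignment length.
`redundancy_reduce()` clusters greedily in order of decreasing length
(ties by id): a peptide joins the first representative exceeding the
identity threshold (strictly greater than 0.9 by default), otherwise it
founds a cluster; representatives are returned in corpus order. The
procedure is idempotent and never enlarges a corpus.

## Descriptors and the combined descriptor space

All descriptors are computed from sequence alone:

| descriptor | definition | default parameters |
|---|---|---|
| charge | Henderson–Hasselbalch sum over D, E, C, Y (−) and K, R, H (+) plus termini | pH 7.4, pKa table in `inst/extdata/pka_sidechains.csv` |
| isoelectric point | bisection of the charge on pH ∈ [0, 14] | tolerance \|q\| < 10⁻⁴ |
| Eisenberg hydrophobicity | mean consensus-scale value | scale in `inst/extdata/eisenberg_scale.csv` |
| hydrophobic moment | $\mu_H = \lvert\sum_i H_i e^{\,i\,\delta\,i}\rvert / N$ | δ = 100°/residue (α-helix) |
| aromaticity | fraction of F, W, Y | — |
| aliphatic index | $X_A + 2.9 X_V + 3.9 (X_I + X_L)$, mole percent | — |
| instability index | $(10/L)\,\sum$ Guruprasad dipeptide weights | table in `inst/extdata/instability_diwv.csv`; length-1 → 0 |
| charge density | charge / average molecular weight | Da⁻¹ |
| hydrophobic ratio | fraction in {A, C, F, I, L, M, V, W, Y} | set configurable |

The pH is physiological (7.4) because the screening context is
intracellular delivery; no pH was prescribed upstream. The pKa set is the
EMBOSS-style table and ships as an editable data file.

The *combined descriptor space* used for similarity is the six-feature
panel: charge, Eisenberg hydrophobicity, hydrophobic moment, length,
isoelectric point, aromaticity. Min–max scaling is fit on the reference
(training) table — constant columns are dropped with a warning, since they
carry no distance information — and queries are scaled with the same
parameters without clipping. Similarity is the Euclidean distance to the
*centroid* of the scaled reference set: a single well-defined summary
(a nearest-neighbour variant would reward memorization rather than
distributional match). Welch's unequal-variance t-test (two-sided, via
`stats::t.test`) compares feature distributions between sets;
`compare_descriptors()` defaults to raw feature values, with
`scaled = TRUE` available since the upstream description is ambiguous on
this point.

Two baseline generators calibrate the distances: `random_baseline()`
draws residues uniformly, and `helical_baseline()` places hydrophobic
residues on a 180° arc of an ideal 100°-per-residue helical wheel
(hydrophobic face from {A, F, I, L, M, V, W}, polar face from charged and
polar residues), which guarantees amphipathicity (μH > 0) by
construction. In a typical run, generated peptides from a motif-structured
corpus sit at mean scaled centroid distance ≈ 0.5–0.7 versus ≈ 1.0–1.1
for both baselines — the qualitative separation the design relies on.

## Calculated CD spectra

The CD stage follows the basis-set approach: a spectrum is the linear
combination $\theta(\lambda) = \sum_j f_j B_j(\lambda)$ of per-class
basis curves $B_j$ (mean-residue ellipticity, deg·cm²·dmol⁻¹) weighted by
secondary-structure fractions $f_j$ (each in [0, 1], summing to 1 within
10⁻⁶). Basis sets are plain whitespace-delimited text (header of class
names, rows of wavelength + values); three classes (helix/sheet/coil) are
the default but any published basis file with more classes loads.
Fractions can come from user data or from a DSSP-style string
(`H,G,I` → helix; `E,B` → sheet; rest → coil).

The filter compares candidates to a reference spectrum at a single
wavelength, default 220 nm — the canonical helix marker (negative bands
near 208/222 nm indicate helix; a 195 nm negative band indicates
disorder). "Stronger helical signal" means *more negative* ellipticity at
220 nm, so candidates whose ellipticity lies above the reference's are
removed; because the upstream wording ("ellipticity lower than") is
sign-ambiguous, `invert = TRUE` implements the opposite reading, and the
comparison wavelength is a parameter. The filter is order-preserving,
idempotent, and monotone (deepening a surviving band never removes it).
Interpolation between grid points is linear and exact on grid points;
out-of-range wavelengths are an error rather than an extrapolation.

Because this package deliberately excludes 3-D structure prediction, the
end-to-end pipeline needs per-candidate structure fractions from
somewhere: when none are supplied it assigns a helix fraction increasing
in the candidate's hydrophobic moment (amphipathicity being the
sequence-level correlate of helicity in this peptide class). This is a
synthetic stand-in, adequate for exercising the stage, and it is exactly
the place a user with predicted or measured structures should plug them
in.

## Contact-variance screening

Trajectories are consumed as multi-model PDB (one `MODEL`/`ENDMDL` block
per frame); the parser enforces an identical atom roster across models and
names the offending model on mismatch. A residue pair is *in contact*
when any heavy atom of one residue lies within 4.0 Å of a heavy atom of
the other — the threshold is closed (exactly 4.0 Å counts) and hydrogens
are excluded by default, both conventional for heavy-atom contact
definitions; a flag includes hydrogens. The per-frame count can be
restricted to positively charged peptide residues (R/K/H), since the
underlying observation ties inhibition to contacts of positive residues
with the PYD; both selections are provided and the all-residue mode is the
default.

The screening statistic is the *unbiased sample variance* (divisor
n − 1) of the per-frame contact count — "contact variance". Low variance
indicates a stable, persistent interface; the pass criterion is
variance ≤ 3 (closed cut-off). The divisor choice is explicit
(`population = TRUE` switches), as the cut-off sits where the two differ
little for typical frame counts. Binding energies (MMPBSA, kcal/mol) are
inputs, not computed; the energy criterion passes records whose *magnitude*
is at least 17 kcal/mol, i.e. ΔG ≤ −17 under the usual sign convention —
the threshold is quoted signless upstream, so the magnitude reading is
documented in the report header and tests. Records are never silently
dropped: every input returns with `passes_variance`, `passes_energy`, an
`energy_missing` flag, and `passes_both`.

Ranking orders passing records by most favorable energy, breaking ties by
lower contact variance and then lexicographic id — fully deterministic —
and keeps the top k = 20. `fuse_cpp()` prepends penetratin
(`RQIKIWFQNRRMKWKK`) to the final candidates; it is a pure string
operation.

`distance_stats()` complements the screen with the mean and standard
deviation across frames of the per-frame minimum heavy-atom distance for a
chosen residue pair, the usual way to report interface stability for
selected residues.

## Synthetic data: what it does and does not show

The `synth_*` generators exist so that every stage is exercised end to end
with no downloads, at the same *shapes* as the real analysis (corpus
≈ 10², 127-record screening pool with 57 planted low-variance series,
top-20 selection):

- `synth_corpus()` draws lengths uniformly in 9–15 and implants a fixed
  motif at a seeded position, optionally with composition bias elsewhere.
  This gives the LSTM learnable structure with a known answer, but it is
  far easier than real helical-peptide corpora: real sequence structure is
  distributed, not a single contiguous motif.
- `synth_contact_records()` *verifies at generation time* (by direct
  recomputation, resampling until satisfied) that exactly the requested
  number of series fall at or below the variance cut-off, which makes the
  downstream funnel test exact rather than statistical. Energies are drawn
  uniformly in −(8…26) kcal/mol to straddle the 17 kcal/mol threshold.
- `synth_trajectory()` builds a two-chain toy system whose frame-t contact
  count at 4.0 Å *equals* a requested schedule (scheduled pairs at 3.5 Å,
  others at 8 Å with 20 Å lateral spacing), so file-round-trip and
  variance computations have forced answers.
- `synth_basis()` produces smooth helix/sheet/coil-like curves (negative
  bands near 208/222, 216 and 198 nm respectively) on a 190–250 nm grid.

Passing tests on these fixtures demonstrates correctness of the
*computations* — alignments, losses, gradients, descriptors, spectra,
contacts, variances, thresholds, ranking — under known ground truth. It
does not demonstrate that a model trained on real PYD-binding peptides
generates active inhibitors, that calculated spectra match measured CD, or
that contact variance from toy trajectories predicts binding: those
depend on real corpora, structures and MD, which the package consumes but
does not fabricate.

## Numerical and degenerate-input conventions

- Softmax rows are validated to sum to 1 within 10⁻⁶ before a loss is
  computed; spectra fractions within 10⁻⁶ of 1.
- Bisection for pI stops at |charge| < 10⁻⁴ (or a 10⁻¹² pH bracket);
  corpora lacking any sign change on [0, 14] raise an error.
- Empty FASTA files read as empty corpora with a warning; an empty corpus
  encodes to an empty batch; `sample_peptides(n = 0)` and
  `random_baseline(0)` return empty corpora.
- `epochs = 0` returns the initialized model and an empty trace.
- Constant reference columns are dropped from the scaled distance space
  with a warning (a zero range admits no scaling).
- Series of fewer than 2 frames refuse a variance; `rank_top_k(k ≤ 0)` is
  a configuration error; unknown pipeline-configuration keys are rejected
  by full dotted name.
- The pipeline manifest contains no timestamps, so identical
  configurations reproduce byte-identical run directories.

## Problem sizes

The shipped demonstrations and checks use a 120-peptide motif corpus with
a 1 × 32-unit model (100 epochs) for the distribution-matching analysis
over five seeds, a 10 × (28–32)-mer corpus with a 2 × 64-unit model
(500 epochs) for memorization, 150-draw sampling runs, and the
127/57-record screening pool. These sizes were chosen so a complete run
takes about a minute on a single CPU while still exercising the same
funnel shape as a production run; all of them scale up by configuration
(the production model configuration remains `model_config()`'s default
2 × 256).

## Known limitations

- The LSTM is CPU-bound, single-threaded R; production-scale corpora
  (10³ sequences, 2 × 256 units, 200 epochs) train in hours, not seconds.
  The implementation favors exact reproducibility over speed.
- No 3-D structure prediction, docking, MD or MMPBSA — upstream tools must
  supply structures, trajectories (multi-model PDB only) and energies.
- The helix-fraction stand-in used by the pipeline's CD stage when no
  structure data are supplied is a heuristic, not a structure prediction.
- `pairwise_identity` is exact global alignment per pair; redundancy
  reduction is O(n²) alignments in the worst case and is intended for
  corpora of ~10³–10⁴ peptides, not proteome-scale sets.
- Checkpoints store weights and configuration, not optimizer state, so
  training cannot be resumed mid-run.
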