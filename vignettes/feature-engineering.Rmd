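---
title: "Feature engineering for siRNA off-target prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature engineering for siRNA off-target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siRNAfeat)
```

## The problem

Therapeutic siRNAs are ~21-nt double-stranded RNAs that load into Argonaute-2
(hAgo2) and silence genes by base-pairing with mRNAs. Partial complementarity
— especially through the seed region, guide positions 2–8 — silences
unintended genes. Chemical modifications (here: an amide-linked AG
dinucleotide at guide positions 3–4 and a glycol nucleic acid (GNA) monomer
at position 7) are used to suppress such off-target activity, but they are
"unnatural" chemistry that plain sequence encodings cannot represent. The
question this package addresses is *representational*: how should a
chemically modified siRNA, its target, and the siRNA–hAgo2 complex be turned
into fixed-length numeric features so that standard classifiers can predict,
per siRNA–gene pair, whether the gene is an off-target?

The package implements nine feature representations ("dataset variants"),
the label construction they share, a structural reproducibility metric, and
an imbalance-aware evaluation harness, plus synthetic generators that make
the whole pipeline testable without any external data.

## Labels

Off-target activity is quantified per gene as a log2 fold change,
log2(treated/control), from an RNA-Seq knockdown experiment. Two processing
rules apply:

* **Expression filter** (`select_top_genes`): only the top 20% of genes by
  mean expression are kept (fold changes of lowly expressed genes are too
  noisy to label). The count is `ceiling(0.2 * N)`; ties at the cutoff break
  by gene-id lexicographic order so the selection is reproducible. The
  filter is applied before pairing with siRNAs.
* **Binarization** (`binarize_labels`): label 1 iff |log2FC| **strictly**
  exceeds 0.25; a gene at exactly 0.25 is negative. The strictness matters
  only on the boundary but is part of the contract and is tested there.

After binarization the classes are imbalanced (most genes are not
off-targets); everything downstream is designed around that.

## The nine dataset variants

| Variant | Content | Width |
|---|---|---|
| D0 | modification fingerprints (96 bytes) + protein-residue displacements | 96 + match set |
| D1 | representative-atom x,y,z per residue | 3 × residues |
| D2 | simple numeric encoding of guide + target | 42 |
| D3 | positional circular fingerprints of guide + target | 1344 |
| D4 | gene-index byte triple + modification fingerprints | 99 |
| D6N/D6R | displacements vs pre-modeling base structure, RNA included (R = rescaled) | match set |
| D7N/D7R | displacements vs experimental reference, protein only (R = rescaled) | match set |

There are deliberately no variants 5 or 8; the enumeration mirrors the
design this package implements rather than renumbering it. Column order is
fixed within each variant (guide block, target block, gene-index block,
fingerprint block, structural block), so rebuilt tables are byte-identical.

### D2 — simple encoding

Each of the 21 guide and 21 target positions maps to an integer: A = 1,
C = 2, G = 3, U = 4. On the guide, modification codes override base codes:
the amide dimer's 5′ member is 5 and its 3′ member 6, and the GNA monomer
is 7. The vector is guide-first, both strands 5′→3′ (the target stored
5′→3′ of the mRNA region); neither choice affects learnability, but both
are fixed conventions so that feature *names* are stable. Widths: 21 + 21
= 42 features. (A count of 43 sometimes arises when the label column is
included in the tally; this package consistently reports 42 feature
columns plus a separate label.)

### Circular fingerprints (D0, D3, D4)

Extended-connectivity (Morgan-style) circular fingerprints hash each atom's
bonded environment and fold the hashes into a fixed-length bit vector.
`circular_fingerprint()` implements the standard construction on heavy-atom
graphs:

1. each atom starts from an invariant hash of (atomic number, degree,
   formal charge, summed bond orders);
2. for each radius iteration, an atom's identifier is rehashed with the
   sorted (bond order, neighbor identifier) pairs;
3. duplicate environments — identical bond sets — contribute a single
   identifier, chosen as the smallest hash so the result cannot depend on
   atom numbering;
4. every surviving identifier sets bit `id mod n_bits`.

The hash is FNV-1a (32-bit), chosen for determinism and portability; the
*contract* is deterministic, renumbering-invariant folded fingerprints, not
bit-compatibility with any particular cheminformatics library (hash
functions differ even across versions of the same library, so all
downstream widths and tests are counts and invariances, never bit
patterns). Folding can, rarely, make two different identifier sets produce
the same bit pattern; the progressive-substitution demonstration below
shows one such collision, which is expected behavior.

Fingerprint applications:

* **Modification block (D0/D4)**: the position 3–4 dinucleotide (AG or
  amide-AG) at 512 bits, radius 2, and the position-7 monomer (U or GNA-U)
  at 256 bits, radius 1, both bit-packed into unsigned bytes, big-endian
  within each byte (`compress_bits`; `[1,0,0,0,0,0,0,1]` → 129). This
  gives 64 + 32 = 96 byte features. Packing is exactly invertible
  (`unpack_bytes`), tested exhaustively over all 256 byte patterns.
* **Positional block (D3)**: every strand position is fingerprinted as an
  independent monomer at 32 bits, radius 1; the raw bits are the features:
  21 × 32 = 672 per strand, 1344 per pair. Target monomers are treated as
  RNA nucleotides. A GNA modification substitutes the glycol-U graph at its
  position; an amide dimer substitutes the dimer graph at both of its
  positions, since the dimer is the covalent unit spanning them. Radius 1
  on a standalone nucleoside-5′-monophosphate keeps each position's block
  independent of its neighbors, which the tests verify (changing position 7
  changes only bit block 7).

### D4 — gene-identifier bytes

Ensembl gene identifiers are assigned roughly sequentially, so nearby
numbers often belong to related genes. `encode_gene_id()` strips `ENSG` and
leading zeros, requires the remaining integer n < 2^24, and splits it into
three unsigned bytes ((n≫16)&0xFF, (n≫8)&0xFF, n&0xFF) named `gene_idx0/1/2`.
The split is exactly invertible (`decode_gene_index`), and versioned
identifiers (`.14` suffixes) are rejected rather than silently truncated so
that encoding and decoding remain bit-exact. This is an *identifier*
feature, not a biological one: it works by exploiting assignment order, a
useful but double-edged artifact discussed under limitations.

### Structural features (D0, D1, D6, D7)

Modeled siRNA–hAgo2 complexes are compared with a reference structure at
residue resolution, one representative atom per residue: Cα for protein,
C1′ for RNA (the conventional trace atoms).

* `superpose()` performs Kabsch least-squares rigid-body superposition over
  all matched protein residues (a global fit, not per-domain), matched by
  (chain, residue number). The rotation comes from the SVD of the 3×3
  cross-covariance with a reflection correction, so det(R) = +1 always;
  fewer than 3 matches or collinear coordinates are errors, not warnings.
* `residue_displacements()` then records the Euclidean distance per matched
  residue. RNA residues participate only when the reference provides them —
  experimental references often lack RNA residues, which is why the D7
  variants are protein-only while the D6 variants (aligned to a complete
  pre-modeling base structure) include RNA. Unmatched residues are dropped,
  never imputed.
* `extract_coordinates()` (D1) flattens representative-atom x,y,z in
  residue order — 3 features per residue, 2637 for an 879-residue complex.
* `rescale_columns()` (D6R/D7R) maps each column linearly onto 0–255
  (min→0, max→255), rounding half away from zero; constant columns map
  to 0. Rescaling preserves within-column rank order.

### Reproducibility metric

`sigma_rsd()` scores the consistency of a structure-generation pipeline:
given n ≥ 2 replicate displacement tables from the same starting point, it
computes per protein residue the relative standard deviation (sample
standard deviation across replicates divided by the mean) and sums over
residues. Identical replicates score exactly 0; residues with zero mean
contribute 0 rather than NaN; a common rescaling of all displacements
leaves the score unchanged. The sample (n−1) standard deviation is used.
An alternative reading of the same idea — RSDs of the full inter-residue
Cα–Cα distance matrix rather than of per-residue displacements — is a
documented alternative that this package does not implement; the
displacement form is bounded, cheaper, and matches the displacement
features it accompanies.

## The evaluation harness

AutoML ensembling is out of scope; instead a fixed harness makes results
interpretable and reproducible:

* **Splits** (`split_indices`): stratified 90/10 and 95/5 holdouts and
  stratified k-fold; class proportions preserved to within one example,
  deterministic per seed.
* **Learners** (`evaluate_model`): gradient-boosted trees (xgboost, 50
  rounds, depth 6, eta 0.3), random forest (100 trees), and k-NN (k = 15,
  capped at n−1), each with fixed, documented hyperparameters and
  single-threaded fits.
* **Metrics**: confusion counts at a 0.5 threshold plus precision, recall,
  specificity, accuracy, F1, and the TP/FP ratio. Degenerate denominators
  yield NA, not errors — an all-negative predictor has undefined precision
  and an undefined TP/FP ratio, and its accuracy equals the negative
  prevalence.
* **AUPRC** (`auprc`): the step-wise average-precision estimator,
  sum over distinct thresholds of precision × recall-increment. "AUPRC"
  has two common estimators (average precision and trapezoidal
  interpolation); average precision was chosen because interpolating
  precision linearly between PR points is known to be optimistic. The
  tests pin the implementation against a brute-force average-precision
  oracle exactly and confirm it stays within 0.1 of the trapezoidal
  integral. Under class imbalance AUPRC is the headline metric: a
  label-independent scorer achieves AUPRC ≈ positive prevalence, which the
  tests verify at prevalence 0.29.
* **Feature importance** (`feature_importance`): mean decrease in impurity
  from a 75-tree random forest, z-score normalized across features and
  ranked; constant features get importance 0.

## Synthetic generators: what they emulate, and what they do not

All tests and the acceptance script run on synthetic fixtures:

* `monomer_library()` builds heavy-atom graphs for the four
  nucleoside-5′-monophosphates (23/21/24/21 heavy atoms for A/C/G/U, the
  real formulae), the AG dinucleotide with either a phosphodiester or an
  amide internucleotide linkage, a glycol-U with an acyclic three-carbon
  backbone, and an all-carbon copy of the guanosine-monophosphate topology
  for the substitution demonstration. Connectivity, elements and bond
  orders are what fingerprints at radius ≤ 2 see; 3D coordinates are
  irrelevant and not modeled.
* `make_structure_replicates()` emulates replicate modeling runs: a
  deterministic helical toy complex (default 52 protein + 8 RNA residues)
  is deformed once per seed by a fixed per-residue Gaussian field (default
  0.5 Å) playing the role of the systematic model-versus-reference
  difference, and each replicate adds an independent random rigid motion
  plus per-residue noise of scale σ. The deformation term is essential:
  without it, displacement means and standard deviations both scale with
  σ and the reproducibility metric would be blind to the noise level;
  with it, ΣRSD increases monotonically in σ, which the tests check at
  σ ∈ {0.01, 0.1, 1.0} Å. With σ = 0 all replicates coincide and ΣRSD is
  0. Default sizes (60 residues, 10 replicates) keep the structural suite
  around a minute; the D1 width check uses a purpose-built 879-residue
  complex in a single test.
* `make_label_table()` draws log2 fold changes from a two-component
  mixture — null genes from Normal(0, 0.08), off-targets from a
  sign-symmetric Normal(0.5, 0.15) — with the mixture weight solved in
  closed form so the expected positive fraction after binarization equals
  the requested prevalence (default 0.29, a realistic off-target
  imbalance for a genome-wide screen; it is a modeling choice, not a
  measured value). Unreachable prevalences raise an error rather than
  silently clamping.
* `make_sequence_labelled_set()` labels pairs by seed-region G+C content
  with 10% label noise, giving sequence representations real signal. On
  it, the positional-fingerprint representation (D3) performs at least as
  well as the simple encoding (D2), asserted as a soft statistical test
  (10 seeds, n = 400, GBT, margin 0.05).

What passing these tests does **not** show: that any variant predicts real
off-target activity. The generators have no thermodynamics, no
position-specific seed biology, no hAgo2 physics, and labels that are
independent of the structural fixtures. The tests establish that every
representation is computed exactly as specified, is deterministic, and
carries signal when signal exists — the preconditions for a fair comparison
on real data, not the comparison itself.

## Numerical choices

* Fingerprint hashing: FNV-1a over little-endian byte streams, all
  arithmetic in doubles below 2^53, so results are identical across
  platforms. Environment deduplication keys on sorted bond-index sets;
  among duplicates the smallest hash is kept (a numbering-free tie-break).
* Rescaling rounds half away from zero (`floor(x + 0.5)` on non-negative
  values); constant columns map to 0.
* `sigma_rsd` uses the sample standard deviation and defines 0/0 as 0.
* Superposition conditioning: the second singular value of the
  cross-covariance must exceed 1e-8 of the largest, otherwise the point set
  is collinear and the rotation is not identifiable.
* Splits use `round()` per class with a minimum of one evaluation example
  per class.
* All generator functions save and restore the caller's RNG state, so
  fixture generation never perturbs user code's random streams.
* Fingerprints are memoized on graph content; strand-level featurization
  of thousands of pairs reuses the handful of distinct monomer
  fingerprints.

## Known limitations

* The circular fingerprint does not perceive aromaticity or
  stereochemistry; Kekulé bond orders stand in for aromatic systems. For
  fixed monomer libraries this only relabels environments consistently,
  but imported molecules with alternative Kekulizations would fingerprint
  differently.
* The gene-index feature encodes database assignment order. It can cluster
  related genes, but it will not transfer across annotation releases and
  can leak dataset structure; treat its importance scores with suspicion.
* Structural features are residue-resolution (one atom per residue) and
  assume pre-relaxed structures; no energy terms, solvent, or trajectory
  physics are computed here.
* The harness's learners use fixed hyperparameters by design; absolute
  scores on real data would improve with tuning, but comparisons between
  representations are the intended use.
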