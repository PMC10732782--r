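---
title: "Predicting phosphosites with a stacked gradient-boosting classifier"
author: "PhosphoStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phosphosites with a stacked gradient-boosting classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhosphoStack)
```

## The problem

Protein phosphorylation — the reversible addition of a phosphate group to
serine (S), threonine (T) or tyrosine (Y) residues — regulates signaling,
metabolism and stress responses, and in plants experimental coverage is
deep only for a handful of species. A practical predictor must therefore
(i) learn from experimentally supported sites against a vastly larger
negative background (every unmodified S/T/Y), (ii) emphasise recall, since
downstream use is screening candidate sites for experimental follow-up,
and (iii) scale to genome-wide annotation that can be displayed in a
genome browser.

PhosphoStack implements this as four cooperating pieces: site-table
curation, a stacking classifier over protein-language-model residue
embeddings, a homology-transfer step that rescues predicted false
positives with alignment evidence, and codon-level GFF3 export.

## Input representation

Each candidate site is represented by the concatenation of two vectors of
equal length $D$: the embedding of the site's own residue and the mean
embedding over all residues of the protein. The residue half carries local
context; the protein-average half carries global protein identity. The
embeddings are used exactly as produced — no centring or scaling — so the
classifier sees the embedding geometry unchanged.

The embedding backend is a contract: any source of per-protein $L \times
D$ matrices works. The package ships a deterministic synthetic backend
(a pure function of protein id, position, residue letter and seed, so
fixtures are reproducible bit-for-bit) and a reader for pre-computed
containers produced by a real protein language model such as a 1024-wide
transformer encoder. Computing real embeddings is deliberately out of
scope; the loader validates matrix row counts against the FASTA.

## The classifier

Two gradient-boosted tree base classifiers are trained on identical
features and differ only in their sample weights:

* **equal weights** — every sample weighs 1; the base learns the dominant
  negative class well and is precise but conservative;
* **balanced weights** — class weights proportional to inverse class
  frequency, normalised to mean sample weight 1
  ($w_+ = n/(2 n_+)$, $w_- = n/(2 n_-)$, so $w_+/w_- = n_-/n_+$); the
  base is recall-oriented. Only the weight ratio affects the tree loss;
  the normalisation merely fixes the scale.

A logistic meta-learner consumes exactly the two positive-class
probabilities, in fixed order (equal, balanced). To keep the meta-learner
honest it is trained on *out-of-fold* base probabilities from a stratified
5-fold cross-validated pass: each sample's meta-features come from bases
that never saw that sample. After the meta-pass, both bases are refit on
100% of the training data for inference — the standard stacking recipe.
The meta-learner itself uses balanced class weights, which pushes its
operating characteristic toward recall; fitted by weighted IRLS
(`glm` with a quasi-binomial family, which gives the same point estimates
as a binomial fit with non-integer prior weights).

On the synthetic fixtures this construction reproduces the design
signature the method is built for: the stack's recall is at or above the
better base's recall at every probability threshold, at a small precision
cost (the test suite checks this as a median over five seeds).

### Hyperparameters

| parameter | default | range | role |
|---|---|---|---|
| `nEstimators` | 300 | 50–2000 | boosting rounds per base |
| `depth` | 3 | 2–10 | tree depth |
| `learningRate` | 0.05 | 0.05–0.5 | shrinkage |
| `nFolds` | 5 | ≥ 2 | meta-training folds |
| `threshold` | 0.5 | 0–1 | hard-call cutoff (strictly greater-than) |

The defaults are conservative (shallow trees, slow learning, many
rounds), which suits the high-dimensional low-signal regime of embedding
features. `tuneBase()`/`tuneStack()` search the three ranges above by
seeded uniform random search, maximising validation F1 at threshold 0.5,
with `nEstimators` and `depth` rounded to the nearest integer and the full
evaluation trace retained. The search strategy sits behind a `method`
interface so a model-based optimizer can be plugged in without changing
callers. Tuning is intended to be run separately per base classifier and
separately for the S/T and the Y model. After tuning, the recommended
(and default) practice is to refit the final model on train + validation;
out-of-fold meta-features are generated with the tuned parameters
throughout.

### Determinism

All randomness (fold assignment, search points, fixture generation) flows
from explicit integer seeds; two trainings with the same data and seed
produce identical predictions on a fixed platform (the tree library runs
single-threaded here for exact reproducibility).

## Data preparation

Evidence rows are validated against the FASTA: the protein must exist,
contain only the 20 canonical amino acids, the 1-based position must be
inside the sequence, and the stated residue letter must match the
sequence. Failures are never repaired — they land in a rejection log with
a reason (`no_sequence`, `noncanonical_sequence`, `out_of_range`,
`residue_mismatch`, `not_sty`). Duplicate evidence for one (protein,
position) collapses to a single site with concatenated source tags.
Negatives are the complement: every S/T/Y not labeled positive, exactly
once.

Splitting is stratified on (residue letter, label) with
largest-remainder allocation after a seeded shuffle, so each stratum's
60/20/20 proportions are exact to within one site. The stratification
unit is the site: two sites of one protein may land in different splits,
which mirrors common practice for this data layout but does permit
protein-level information sharing between splits — a `byProtein` flag
assigns whole proteins to one split for the stricter protocol. Strata
with fewer than three sites go to training with a warning. S and T sites
are split separately and then combined for the S/T model; Y sites form
their own model.

## Homology transfer

Many "false positives" are really unannotated true sites. The transfer
step asks, for each candidate site, whether its sequence neighbourhood
matches an experimentally supported site elsewhere:

1. extract a 31-residue window centred on the site (edge sites keep the
   first/last 31 residues, with the centre offset tracking the distance
   from that edge; proteins shorter than 31 contribute whole);
2. align the window against the reference proteins;
3. walk the alignment traceback (btop syntax: match run-lengths,
   substitution letter pairs, gap codes) and map the window centre to its
   aligned subject position — a centre outside the local alignment or
   opposite a gap is unaligned;
4. the candidate becomes an *inferred positive* when the mapped position
   is an experimentally supported site on the subject protein.

Self-matches — same protein id *and* same position — are excluded by
default; a different site on the same protein is legitimate evidence. By
default the aligned subject residue must have the same letter as the
query residue (an S site is not allowed to match a reference T site);
`requireResidueMatch = FALSE` relaxes this. Both choices are deliberate
strict readings of an under-specified rule and are surfaced prominently
in the configuration. Matches are deduplicated and sorted, so annotations
are independent of hit ordering.

Two aligner backends satisfy one contract. The built-in backend is
Smith–Waterman local alignment (BLOSUM62, gap open 11 / extend 1 — the
defaults of the common external tool) via `Biostrings::pairwiseAlignment`,
run score-only first and re-run with traceback for reported hits; because
a local aligner always returns *some* hit, a minimum raw score (default
50) plays the role of the external tool's default e-value report cutoff.
On random 31-mers against unrelated proteins, raw scores run ~15–35, so
50 separates genuine homology cleanly; it is exposed in
`transferConfig()`. The external backend shells out to the `diamond`
binary with `--masking none --ultra-sensitive --max-target-seqs 100` and
parses its tabular output (including the btop column); it fails loudly
when the binary is absent.

Merging inferred positives into a confusion matrix is pure algebra:
with $P = TP + FN$ original positives and $IP$ promoted false positives,
post-merge precision is $(TP+IP)/(TP+FP)$ and post-merge recall
$(TP+IP)/(P+IP)$ — both are never below their pre-merge values for any
$IP \ge 0$.

## Evaluation

Hard calls use strict inequality (probability $> $ threshold). Precision,
recall and F1 are computed at full precision, displayed at two decimals
(round-half-even). The $F_\beta$ score
$(1+\beta^2)PR/(\beta^2 P + R)$ expresses "recall is $\beta$ times as
important as precision"; the crossover utility reports the smallest
$\beta$ on a grid (default 0.1–3.0, step 0.1) at which one method's
$F_\beta$ reaches another's, with ties counting as reached. ROC curves
sweep all distinct scores with ties grouped; AUROC uses the trapezoidal
rule (and equals the Mann–Whitney statistic, which the tests verify).
The precision–recall area uses the step-wise rectangular rule by default
because linear PR interpolation is optimistically biased; a `linear`
option exists for comparison with tools that interpolate.

Degenerate cases (no positive calls, single-class truth) return 0 with a
warning or error explicitly rather than NaN.

## The synthetic fixtures

The generators produce everything the pipeline consumes — FASTA, site
TSV, embedding container, homolog proteome, gene models — as pure
functions of a config and seed. They emulate the *structure* of a plant
phosphoproteomics dataset: ~10% positives among S/T/Y residues (strong
class imbalance), uniform amino-acid composition, protein lengths 50–80
by default (~2,000 sites from 210 proteins, the size used in the
classifier property tests; smaller sizes elsewhere keep the default suite
fast).

Class signal is planted by adding `delta` times the first standard basis
vector to positive-site embedding rows. The offset is axis-aligned by
design: tree ensembles partition feature space along axes, so an
axis-aligned effect makes the Bayes separation
($\mathrm{AUROC} = \Phi(\delta/\sqrt2)$, ≈ 0.92 at $\delta = 2$)
attainable by the intended learner; a diffuse direction of the same norm
is provably equivalent for a linear model but measurably harder for
trees. `delta = 0` produces exactly the no-signal null (negative rows are
bit-identical across `delta`).

Homolog proteomes substitute residues independently (default rate 0.1)
but never at planted positive positions, so transfer ground truth is
exact. Gene models place each protein's $3L$ coding bases into 1–3 exons
on a random strand with 30–300-base introns.

What passing fixture tests does **not** show: real phosphosites have
sequence motifs, kinase specificity, disorder preferences and
non-uniform composition; real embeddings are anisotropic and correlated
across positions; real homology has domain structure rather than uniform
point mutations. The fixtures validate the machinery and its statistical
behaviour under controlled signal, not biological performance.

## Genome export

A residue index $i$ maps to CDS bases $3i-2..3i$ in translation order;
on the minus strand the walk runs from the 3′ end. Codons that span an
intron become two genomic blocks (block lengths always sum to 3),
written as two GFF3 lines sharing one `ID` — the discontinuous-feature
convention. Display attributes follow the browser rules: `blue` for
alignment-inferred sites, `red` for predicted sites (probability > .5),
`pink` when both apply, and `bold=true` above .9. Sites that are neither
predicted nor inferred are omitted from the track by default. The phase
column is consumed when reading gene models but written as `.`; attribute
values are percent-encoded per the GFF3 reserved set. A reader
re-merges the track and the inverse coordinate walk recovers every
site's (protein, position) — the round-trip test.

## Problem sizes and runtime

The test suite trains stacks on ~500–2,000-site fixtures (seconds per
fit), runs transfer on 20–40-protein proteomes, and checks exhaustive
oracles on peptides ≤ 15 residues; the complete suite runs in about two
minutes on one CPU. These sizes were chosen to make the statistical
properties (signal AUROC, null AUROC, recall dominance, transfer recall)
stable across seeds while keeping iteration fast.

## Known limitations

* No kinase-specific or multi-class prediction; one probability per site.
* No probability calibration beyond the logistic meta-learner.
* The built-in aligner is quadratic per pair; genome-scale transfer
  should use the external aligner backend.
* Isoforms sharing coordinates are treated as distinct proteins.
* The site-level split permits protein-level leakage unless `byProtein`
  is enabled.
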