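---
title: "Separating cancer-associated from normal m6A sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating cancer-associated from normal m6A sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicrossnet)
```

## The scientific problem

N6-methyladenosine (m6A) is the most abundant internal mRNA modification,
and its deposition is broadly remodeled in tumors. Given base-resolution
m6A site catalogs observed across many cancer and normal conditions, two
questions arise:

1. **Which sites are cancer-associated?** For one cancer type, positives
   are sites seen in cancer but not the matched normal tissue and
   negatives the reverse (set-difference labels). In the pan-cancer
   setting, a site is called cancer-associated when it occurs across
   cancer conditions significantly more often than across normal ones.
2. **What distinguishes those sites?** The local RNA sequence turns out to
   carry almost no class signal; genome-derived context (metagene
   position, secondary structure, isoform structure, exon architecture)
   carries most of it. The package quantifies that contrast with a
   sequence-only convolutional baseline versus an integrated deep cross
   network (DCN), and then attributes the integrated model's decisions to
   individual genomic features with Shapley values.

Because the original analysis rests on a large corpus of MeRIP-seq
experiments that cannot be shipped or reprocessed at desk scale, the
package includes a first-class synthetic generator that reproduces the
*statistical structure* of that data regime, so every stage is exercised
end to end by tests with known ground truth.

## Pan-cancer site selection

For each site, presence/absence across `K_c` cancer and `K_n` normal
conditions gives a 2x2 table `(a, b; c, d)` (present/absent x
cancer/normal). `fisher_association()` computes the two-sided Fisher
exact p-value by full enumeration of the hypergeometric distribution at
the observed margins, using the probability-mass criterion (sum over all
tables whose probability does not exceed the observed table's); this is
the convention of the standard exact-test implementations, and the suite
verifies agreement with `stats::fisher.test()` to 1e-10. The odds ratio
is the sample `(a d)/(b c)`; when any cell is zero the Haldane-Anscombe
0.5 correction is added to every cell **for the odds ratio only** — the
p-value always comes from the uncorrected enumeration. The correction
matters because an infinite odds ratio would pass any threshold
vacuously, while the corrected one still reflects the strength of the
margins.

P-values are adjusted by the Benjamini-Hochberg step-up procedure
(`bh_adjust()`, delegating to `stats::p.adjust`). Positives are sites
with `log2(OR) > 2` and adjusted p `< 0.05` (both strict, as printed
thresholds usually are); the negative pool uses the mirrored criterion
`log2(OR) < -2`, adjusted p `< 0.05`. The symmetric negative rule is a
documented assumption: the negative class is described qualitatively as
"commonly present in normal tissues, rarely in cancer", and symmetry is
the minimal formalization. A flag (`adjusted = FALSE`) thresholds raw
p-values instead, since the Methods text and the figure caption of the
source analysis disagree on whether adjustment applies; the adjusted
reading is the default. Finally `balance_sample()` draws negatives 1:1
with the positives, uniformly without replacement under a seed.

A confidence pre-filter (`filter_high_confidence()`, default "at least 2
independent studies") mirrors how base-resolution atlases are pruned
before any labeling.

## Feature encoding

Each site contributes a 41-nt window centered on the methylated A
(one-hot rows A, C, G, U; T read as U; N as an all-zero row) and a
52-feature genomic vector laid out by `feature_schema()`:

| group | indices | content |
|---|---|---|
| region dummies | 1–13 | 5'UTR, CDS, 3'UTR, start/stop codon (+/-1 nt), exon, intron, constitutive/alternative exon, junction +/-50 nt, lncRNA exon, sncRNA, first exon |
| region lengths | 14–19 | gene, transcript, 5'UTR, CDS, 3'UTR, containing exon |
| clustering | 20–25 | site counts within +/-100 / +/-1000 nt, distance to nearest site (raw and log), A count near the site, DRACH count in the window |
| conservation | 26–29 | phastCons / fitCons, site and window mean (external columns) |
| structure | 30–31 | struct_hybridize, struct_loop (external columns) |
| gene attributes | 32–44 | housekeeping, sncRNA host, lncRNA, ten m6A regulator-binding flags (external where noted) |
| transcript properties | 45–48 | isoform count, GC content, exon count, protein-coding flag |
| relative positions | 49–52 | metagene position on transcript, 5'UTR, CDS, 3'UTR |

Conservation, structure and binding flags are *consumed* as external
columns — computing them belongs to phastCons/fitCons, RNA folding and
CLIP processing pipelines, not here. For real catalogs,
`annotate_sites()` computes the remaining features against a GFF3
transcript model: every gene is first resolved to its single longest
transcript, all distances are taken in transcript (sense) coordinates,
and GFF's 1-based closed coordinates are converted to the internal
0-based half-open convention at the I/O boundary only. A site outside a
region gets relative position 0 there *with the region dummy at 0*, so
the sentinel cannot be confused with a true 5'-end position. Metagene
relative position is region-local distance to the region's 5' end over
region length, in [0,1].

Continuous features are z-scored with statistics fitted on the training
split only; binary features pass through; a zero-variance feature maps to
0 with a warning. Splits are stratified 8:1:1 train/val/test, seeded.

## The deep cross network

With `x` the concatenation of the flattened one-hot block (164) and the
52 normalized genomic features (sequence first, 216 inputs total):

- embedding: `x_e = W_e x + b_e`, width 128;
- deep branch: affine + ReLU stack `h = ReLU(W h + b)` through widths
  (64, 64), then a final affine layer to a single dimension;
- cross branch: `x_c = W_c (x_e ⊙ x_e) + b_c + x_e` — elementwise
  square, linear map, bias and residual. With zero weights the layer is
  the identity, and the suite pins that contract;
- output: `out = deep(x_e) + (w_p x_c + b_p)`, `y = sigmoid(out)`.

The deep branch ends in a scalar while the cross branch keeps the
embedding width, so "summing the branch outputs" is ill-typed as stated
in the source description; the package resolves it with a learned scalar
projection `(w_p, b_p)` of the cross output. This is the single largest
architectural judgment call in the package and is deliberately the
smallest one available. One cross layer is used, matching the printed
cross equation.

Training minimizes mean binary cross-entropy (predictions clipped to
`[1e-7, 1 - 1e-7]`) with mini-batch Adam (learning rate 0.001, betas
0.9/0.999, eps 1e-8, batch 64, 10 epochs, per-epoch seeded shuffling).
Weights are fan-in-scaled uniform; biases start at zero. The returned
parameters are those of the epoch with minimum validation loss
(`select = "last"` disables checkpointing); validation-loss selection is
a documented choice where the source only says validation loss was
monitored. Gradients are analytic backpropagation, verified against
central finite differences to a relative error below 1e-4.

The number of deep layers is not pinned down by a "hidden dimension of
64" alone; the default stack (64, 64, 1) is a configurable choice.

The sequence-only baseline is a small 1-D CNN over the one-hot window:
two convolution blocks (kernel 5; 32 then 64 channels; ReLU), global
max-pooling over positions, dense sigmoid head, trained with the same
recipe. No baseline architecture was printed; this is the smallest
standard design that can learn positional motifs.

## Shapley attribution

The Shapley value of feature `i` is its average marginal contribution
over all coalitions, with coalition value `v(S)` defined as the model
output with features outside `S` replaced by background-row values,
averaged over a background set of `B = 100` training rows (configurable;
smaller budgets are used where many samples are explained). The
reference distribution is not stated by the source, which names only its
explainer family; background-replacement averaged over training draws is
that family's standard convention and is recorded in the report
metadata.

`exact_shapley()` enumerates all `2^F` coalitions (guarded at `F <= 15`)
and is the test oracle; `sampled_shapley()` is a permutation estimator
whose per-permutation contributions telescope, so the efficiency
identity `sum(phi) = f(x) - v(empty)` holds exactly for both. Attribution
runs over the 52 genomic features with each sample's sequence block held
fixed (the reported signatures are genomic; `whole_input = TRUE` attributes
jointly). Features are ranked by mean |phi| with ties broken by schema
index; the beeswarm export carries per-feature sign concordance
(correlation of phi with the raw feature value). Which split to explain
is not pinned by the source; the default is the test split.

## Evaluation and transfer testing

AUROC is computed in the Mann-Whitney form (ties half-credited) and, via
`roc_curve()`, as the trapezoidal area under the tie-grouped ROC curve;
the two agree to 1e-12 and both are checked against an O(n^2) pair
enumeration. Cross-condition transfer fills `M[i, j]` = AUROC of model
`i` on the held-out *test* split of condition pair `j` (never the full
dataset, to keep the diagonal honest), and conditions are clustered by
average linkage on `d = 1 - (M + M')/2`, with the raw matrix always
available so other linkages can be applied. The clustering method behind
the original figure is unnamed; average linkage on symmetrized
1 - AUROC is the documented stand-in.

## The synthetic generator: what it emulates, and what it does not

`generate_catalog()` plants three site populations: `pan_positive` sites
occur in each cancer condition with `p_high` (default 0.9) and each
normal condition with `p_low` (0.1); `pan_negative` sites the reverse;
`background` sites with `p_background` (0.5) everywhere. Defaults are
n_sites = 4000 and 10 + 10 conditions — small enough for minutes-scale
test runs while leaving a few hundred sites per class after selection.
Planting fractions default to 0.2 positive / 0.3 negative: the negative
pool must dominate the positive set for 1:1 sampling, as it does in real
catalogs where normal-enriched sites far outnumber cancer-enriched ones.
Per-condition occurrence rates for real sites are not published, so
these probabilities are calibration choices, not measured values.

Windows fix the DRACH core at the center (methylated A at 0-based
index 20, core at 18–22) and draw the flanking 36 nt uniformly;
`sequence_effect > 0` mixes in class-dependent base frequencies, giving a
tunable way to *falsify* the sequence-is-insufficient claim — at 0 a
sequence-only model cannot beat chance in expectation. Genomic features
follow class-conditional families per `default_feature_effects()`: the
five planted signatures are positives sitting late in the CDS
(`rel_pos_cds` ~ Beta(6,2) vs Beta(2,2)), early in the 3'UTR
(Beta(2,6)), `struct_hybridize` at rate 0.7 vs 0.3, isoform counts
1 + Poisson(4) vs 1 + Poisson(2), and constitutive-exon membership 0.3
vs 0.7 — i.e. a CDS/3'UTR-boundary enrichment with structural and
isoform effects, the directions reported for real pan-cancer sites. All
other 47 features are drawn identically across classes. Study support is
1 + Poisson(1), so the "at least 2 studies" filter has ~37% of sites to
remove.

The generator does **not** simulate read-level MeRIP-seq data, peak
calling, genomic coordinate realism, linkage between features (each is
drawn independently given the class), or batch effects between
conditions. Passing tests therefore demonstrate that the machinery
recovers planted structure of the right shape — not that real cancer
epitranscriptomes behave this way.

## Numerical and design notes

- Exact-test ties: probability comparisons use a relative tolerance of
  1e-7, absorbing floating-point noise between mathematically tied
  tables (the convention of standard implementations).
- All randomness flows from explicit seeds; each pipeline stage derives
  its own seed as a hash of the global seed and stage name, so toggling
  one stage never shifts another's stream. No wall clock or OS entropy
  is used anywhere, and identical configs reproduce byte-identical
  artifacts (`run_all()` manifests record md5 digests).
- Degenerate inputs fail loudly: single-class condition vectors,
  identical cancer/normal site sets, empty positive selections,
  negative pools smaller than the positive set, non-finite model
  parameters and malformed BED records are all typed errors.
- Problem sizes in the shipped tests: the end-to-end recovery runs use
  4,000 sites with 10 + 10 conditions over ten seeds; transfer
  clustering uses four condition pairs of 1,200 sites; attribution in
  the end-to-end runs uses 60 explained samples, 10 permutations and a
  20-row background, which is ample for a stable top-10 mean-|phi|
  ranking (the ranking averages over samples).

## Known limitations

- The learned scalar projection reconciling the cross branch with the
  scalar deep branch is an interpretation of an underspecified
  combination step; alternatives (summing after projecting both branches
  to the embedding width, say) would change parameter counts.
- Attribution defaults hold the sequence block fixed; interactions
  *between* sequence and genomic features are therefore credited to the
  genomic side.
- The clustering features (site counts within fixed windows) use window
  sizes that were never printed; +/-100 and +/-1000 nt are defaults.
- Real-data headline numbers (specific AUROCs and site counts) depend on
  the original 167-dataset corpus and are out of reach by design; the
  package's claims are the oracle equivalences and planted-recovery
  properties exercised by the test suite.
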