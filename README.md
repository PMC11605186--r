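# epicrossnet

An R package for separating **cancer-associated from normal
N6-methyladenosine (m6A) sites** with an interpretable deep cross network
over sequence plus genome-derived features, and for identifying shared
pan-cancer epitranscriptomic signatures via Fisher's-exact-test site
selection and Shapley-value attribution.

## Who this is for

Computational epigenomics groups working with base-resolution m6A
catalogs observed across many conditions (e.g. MeRIP-seq-derived site
lists for cancer cell lines and matched normal tissues) who want to

- label sites as cancer-associated, per cancer type or pan-cancer;
- test whether local RNA sequence alone can discriminate them (it
  largely cannot) versus sequence plus genomic context;
- attribute the trained model's decisions to interpretable genomic
  features.

A first-class synthetic-data module generates condition catalogs,
DRACH-centered 41-nt windows and 52-feature genomic tables with planted
class structure, so the entire pipeline is testable end to end without
any external download.

## Methods at a glance

**Pan-cancer selection.** For each site, presence across `K_c` cancer and
`K_n` normal conditions forms a 2x2 table (a, b; c, d). A two-sided
Fisher exact p-value is computed by full hypergeometric enumeration
(probability-mass criterion), BH-adjusted across sites, and positives are
selected at `log2(OR) > 2` and adjusted `p < 0.05` (Haldane–Anscombe 0.5
correction for zero cells, applied to the odds ratio only). Negatives use
the mirrored criterion and are down-sampled 1:1.

**Models.** Inputs are the flattened one-hot window (41x4) concatenated
with 52 normalized genomic features. The deep cross network embeds the
input (`x_e = W_e x + b_e`, width 128), runs a deep ReLU stack ending in
a scalar and a cross layer `x_c = W_c (x_e ⊙ x_e) + b_c + x_e`, sums the
branch outputs (the cross branch through a learned scalar projection) and
applies a sigmoid. Training: mean binary cross-entropy, Adam (lr 0.001),
10 epochs, batch 64, minimum-validation-loss checkpointing. The
sequence-only baseline is a small two-block 1-D CNN with global
max-pooling.

**Interpretation.** Shapley values
`phi_i = sum_S |S|!(F-|S|-1)!/F! (v(S+i) - v(S))` with background-row
masking: exact subset enumeration up to 15 features (the test oracle) and
permutation sampling for the full 52-feature model. Features are ranked
by mean |phi|; a beeswarm-style long table carries signed per-sample
values and sign concordance.

**Evaluation.** AUROC in the Mann–Whitney form (ties half-credited),
equal to the trapezoidal area under the tie-grouped ROC curve;
cross-condition transfer matrices (train on pair i, test on pair j's
held-out split) with average-linkage clustering on symmetrized
1 − AUROC.

## Worked example

```r
library(epicrossnet)

gp       <- generator_params(n_sites = 4000, sequence_effect = 0, seed = 1)
catalog  <- generate_catalog(gp)                 # sites x conditions, windows
features <- generate_features(catalog, gp)       # N x 52 genomic table

assoc   <- catalog_association(catalog)          # Fisher + BH per site
labeled <- balance_sample(select_pan_cancer(assoc), seed = 1)
ds      <- encode_labeled_dataset(catalog, features, labeled, seed = 1)

fit_seq <- train_model(ds, "sequence_cnn", seed = 1)
fit_int <- train_model(ds, "integrated",   seed = 1)
ps <- predict_split(fit_seq, ds, "test"); auroc(ps$scores, ps$labels)
#> [1] 0.4717291
pi <- predict_split(fit_int, ds, "test"); auroc(pi$scores, pi$labels)
#> [1] 0.9255424

rep <- attribute_model(fit_int, ds, n_permutations = 10,
                       background_size = 20, n_samples = 60, seed = 1)
head(rep$ranking, 5)
#> [1] "rel_pos_cds"       "rel_pos_utr3"      "isoform_num"
#> [4] "struct_hybridize"  "constitutive_exon"
```

Read: with no planted sequence signal the sequence-only baseline sits at
chance (AUROC 0.47), the integrated model separates the classes (0.93),
and the five genomic features planted by the generator are exactly the
five top-ranked by mean |Shapley value| — the pipeline recovers both the
performance contrast and the signature identities it was built to
detect. `run_all(run_config(...))` executes the same flow as a single
orchestrated, manifest-writing run.

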