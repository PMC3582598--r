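---
title: "Multi-label subcellular localization from GO term frequencies: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label subcellular localization from GO term frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goloc)
```

## The model

A protein's Gene Ontology annotations carry localization signal across all
three ontologies: cellular component terms directly, biological process
and molecular function terms indirectly (a kinase annotated to a nuclear
signalling process is probably nuclear). `goloc` turns this into a
multi-label classifier in three steps.

**GO-term retrieval.** Each protein is mapped to one or more *accession
keys*: its own UniProtKB accession (`mode = "ac"`), the accessions of its
top `n` BLAST homologs (`mode = "seq"`, for proteins whose own accession
has no GOA entry), or both (`mode = "ac+seq"`). Each key is looked up in a
GAF-derived annotation table; a key absent from the table contributes the
empty term multiset, and a protein none of whose keys resolve gets an
all-zero vector rather than an error. For novel proteins whose top
homologs are unannotated, `first_annotated_key()` walks down the homolog
ranking until an annotated accession is found.

**GO vectors over a selected subspace.** The feature space is spanned by
the `T` distinct GO terms observed across the training proteins' retrieval
results — not the full ontology, which is two orders of magnitude larger
and mostly irrelevant to any one dataset. Coordinates are either raw
occurrence counts (`vector_mode = "tf"`) or their 0/1 quantization
(`"binary"`). Counts are informative because the same GO term is often
annotated to one protein under several GOA entries, and co-localized
proteins tend to repeat terms to a similar depth; quantizing to 0/1
discards that part of the signal (demonstrated below). No normalization is
applied by default — raw counts are already on a common scale and the
linear kernel handles magnitude through the margin.

**One-vs-rest SVMs with a multi-label decision rule.** For `M` classes,
`M` independent binary soft-margin SVMs are trained. A protein located in
several compartments is a *single* training instance whose transformed
label is `+1` for each of its classes — duplicating it across classes
would put identical vectors on both sides of other classes' margins. At
query time the per-class score fuses the per-key SVM outputs with equal
weights (`1` for the lone key in accession-only mode, `1/n` over homolog
keys, `1/(n+1)` when the true accession joins them); the printed form of
the score places the bias inside the weighted sum, which, because the
weights sum to one, contributes the bias exactly once — the implementation
follows that form verbatim. Every class with a strictly positive score is
predicted; if none is positive the top-scoring class is returned (ties:
smallest class index, deterministically), so predictions are never empty.
The number of predicted locations therefore emerges from the whole
training set rather than from a nearest neighbour or a tuned threshold.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `C` | 0.1 | soft-margin penalty of every binary SVM (dimensionless) |
| kernel | linear | `rbf` (`sigma` in feature-space distance units; `K = exp(-||x-y||^2 / 2 sigma^2)`) and `polynomial` (degree `d >= 2`) are available |
| `n` | 1 | homologs per protein in the `seq` modes |
| `vector_mode` | `"tf"` | term frequency vs 1-0 coordinates |
| `rebuild_subspace` | `TRUE` | rebuild `T` inside every cross-validation fold |

The small default `C` reflects the geometry: GO vectors usually have more
dimensions than there are training proteins, so the classes are separable
and a wide margin generalizes better than a hard fit. The linear default
reflects the same fact — in our experience (and in the non-linear kernel
options exposed here) small-`sigma` RBF kernels overfit this regime badly.
One homolog is the sweet spot: additional homologs mostly add annotation
noise from more distant relatives.

## Cross-validation and the subspace question

`loocv()` iterates over *actual* proteins — each protein is one fold, no
matter how many locations it has; iterating over (protein, location) pairs
would place identical vectors in the training folds of conflicting
classes. Within each fold the GO subspace is rebuilt from the training
proteins only, so no term identity leaks from the held-out protein; since
the held-out protein can then carry terms outside the fold's subspace,
those terms are dropped from its query vector, exactly as they would be
for a genuinely novel protein. `rebuild_subspace = FALSE` freezes a single
global subspace instead — cheaper, with a single global `T`, at the cost
of that mild leakage; both behaviours are exposed because neither is
canonical.

## The evaluation metrics

A protein in `k` locations counts as `k` *locative* proteins and one
*actual* protein. Locative accuracy credits every true location recovered
anywhere in the predicted set; actual accuracy requires exact set
equality. The degenerate predictor that assigns every class to every
protein makes the difference vivid: on any dataset shaped like the
6-class viral benchmark (165/39/3 proteins with 1/2/3 locations) it scores
100% locative and exactly 0% actual accuracy, since no true set has six
elements. Both metrics, per-class and per-multiplicity breakdowns, and the
over/equal/under-prediction distribution are computed by
`evaluate_predictions()`; the evaluator tolerates empty predicted sets
(scored as under-prediction) so the lookup baseline's *unpredictable*
proteins can be evaluated too, even though the SVM path never produces
them.

## The table-lookup baseline

`predict_lookup()` implements the two-tier direct lookup: a protein's GO
terms are matched first against each class's *essential* cellular
component terms, and only if none matches against the *child* terms
(direct `is_a`/`part_of` descendants; `occurs_in` descendants are
biological-process terms and excluded). All classes matched within the
winning tier are returned; a term that is a child of two compartments
yields both, which is the over-prediction failure mode that motivates the
SVM approach. The packaged `virus_lookup_table()` covers the six viral
classes with 7+20+5+2+2+3 explicit terms; users can supply their own table
in the same four-column TSV format.

## What the synthetic generator emulates

`generate_dataset()` produces GAF files, BLAST-tabular homolog maps and
label files with controllable structure, so the entire pipeline — parsers
included — is testable without touching GOA or Swiss-Prot:

* **class signatures** — each class owns `n_signature` GO terms;
  `signature_overlap` of them come from a block shared by all classes, so
  at full overlap only annotation depth distinguishes classes;
* **annotation depth** — occurrence counts are `1 + Poisson(depth - 1)`,
  optionally per class (`depth_by_class`), emulating repeated GOA entries;
* **noise** — with probability `noise_rate` a signature-term annotation is
  dropped, and each term of a disjoint noise pool is added; the pool being
  disjoint keeps the separability dial interpretable;
* **homologs** — synthetic accessions carrying each annotation with
  probability `fidelity`, emitted in real outfmt-6 form;
* **determinism** — per-protein substreams are derived from the master
  seed, so datasets are byte-identical across runs and independent of
  generation order.

Defaults (8 signature terms/class, depth 3, pool 40, noise 0.1, fidelity
0.9, 1 homolog) are chosen as a realistic GOA-like annotation density with
mild corruption. `virus_fixture()` fixes the shape of the 6-class viral
benchmark (207 proteins, multiplicities 165/39/3) with disjoint noise-free
signatures: leave-one-out cross validation over it reaches an actual
accuracy of 1.0 with TF vectors, a linear kernel and `C = 0.1`, the
pipeline's parameter-recovery check.

What passing these tests does *not* show: real GO annotations live on a
DAG with correlated, hierarchically redundant terms; real annotation
depth varies by curation effort, not only by class; real homolog quality
varies continuously with E-value. Synthetic accuracy numbers therefore
say nothing about accuracy on real proteomes — they validate the
machinery, not the biology.

## Numerical choices and degenerate inputs

* The per-class SVMs are solved by libsvm (via `e1071`) with scaling
  disabled; scores are computed in-package from the extracted dual
  coefficients and bias, and for linear kernels the equivalent primal
  weight vector is stored — dual-form and weight-form scores agree to
  `1e-9`, a standing test.
* Subspace terms are kept in strict lexicographic order, making models
  reproducible regardless of input order.
* Fusion weights must sum to 1 within `1e-12`.
* A class with no positive (or no negative) training instance becomes a
  constant `-Inf` stub: it can never be predicted, and an all-stub model
  is an error.
* A query resolving to no keys (or to keys with no annotations) scores
  each class at its bias; the prediction is flagged `zero_vector` so
  callers can route such proteins to a back-up predictor if they have one.
* Argmax ties in the fallback branch break to the smallest class index.

## Known limitations

* GO qualifiers and evidence codes are not filtered by default
  (`exclude_not` drops `NOT`-qualified rows); no stance is taken on
  which evidence codes are trustworthy.
* No GO-DAG reasoning: ancestors are not propagated, term similarity is
  ignored, and the subspace treats terms as unrelated coordinates.
* Running BLAST is out of scope; homology evidence must be supplied as
  outfmt-6 output or a precomputed homolog map.
* No probability calibration on the SVM scores; the decision rule is a
  hard sign test.

## Problem sizes used in the test suite

The statistical property tests (noise monotonicity of LOOCV accuracy over
noise rates 0/0.2/0.5, and the TF-vs-binary comparison under fully shared
signatures with class-specific depths) run five seeds of a 60-protein,
4-class configuration; the parameter-recovery check runs the full
207-protein virus-shaped fixture once. These sizes were chosen to exercise
the pipeline end-to-end while keeping the default suite fast to iterate
on.
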