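---
title: "Disease-specific ranking of missense variants: model and methods"
author: "pathmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-specific ranking of missense variants: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmm)
```

## The problem

Exome and genome sequencing produce thousands of non-synonymous single
nucleotide variants (missense substitutions) per individual. Generic
deleteriousness predictors separate disease-causing from neutral variants
reasonably well, but a study of one disease — say, musculoskeletal
disorders — also needs to separate variants relevant to *that* disease from
pathogenic variants of *other* diseases, which a conservation-only method
cannot do: a mutation damaging a cardiac protein looks exactly as
"deleterious" as one damaging a muscle protein. `pathmm` implements the
profile-HMM scoring framework of the FATHMM family together with a
disease-specific weighting scheme that makes this separation possible.

## The score

A substitution at residue $i$ of a protein, replacing wild-type amino acid
$w$ by mutant $m$, is scored

$$
S \;=\; \ln \frac{(1 - P_w)\,(W_n + 1)}{(1 - P_m)\,(W_d + 1)}
$$

where

* $P_w, P_m$ are the emission probabilities of the wild-type and mutant
  residues at the profile-HMM match state aligned to residue $i$, taken
  from the **most informative model** covering the site (below);
* $W_d, W_n$ are the model's **pathogenicity weights**: the relative
  frequencies of pathogenic-side and neutral-side training substitutions
  that map onto the model, $W_d = d/(d+n)$, $W_n = n/(d+n)$.

Lower scores are more damaging. High wild-type conservation ($P_w \to 1$)
and a mutation-intolerant model ($W_d \to 1$) both push $S$ down; the $+1$
in the weight factors keeps the score finite for any weights in $[0,1]$,
and $1-P$ terms are floored at $10^{-9}$ so $S$ is finite even for
point-mass emissions. A model with no mapped training data gets
$W_d = W_n = 0$, and the score degrades gracefully to the pure conservation
ratio $\ln[(1-P_w)/(1-P_m)]$.

The weights-only baseline `naive_score()` is $\ln[(W_n+1)/(W_d+1)]$: every
variant on a model shares it, so it ranks models, not sites.

### Model selection

Each residue is covered by the protein's full-length ab initio profile and
by any domain-family profiles (SUPERFAMILY, Pfam-A, Pfam-B) annotated over
it. Among these candidates the package selects the one whose covering
match-state emission distribution has the largest Kullback–Leibler
divergence from the background amino-acid composition — the model that is
most informative *about this particular position*. Informativeness is
deliberately position-local, not a model-wide average: $P_w$, $P_m$ and the
informativeness then all refer to the same match state. Exact ties are
broken by a fixed source priority (`pfam_a` > `superfamily` > `pfam_b` >
`ab_initio`, then model id), so selection is deterministic and independent
of candidate order. The default background is the Swiss-Prot/TrEMBL average
composition (`aa_background()`); a uniform background is available.

### Weighting schemes

* **inherited**: $d$ counts every disease-labelled training substitution
  mapping onto the model, $n$ counts neutral polymorphisms. This is the
  whole-spectrum scheme: it separates pathogenic from neutral but not one
  disease from another.
* **disease_specific**: for a chosen concept (one of 17 root disease
  concepts, `disease_concepts()`), $d$ counts only substitutions tagged
  with that concept; *everything else* — other diseases' mutations included
  — feeds $n$. Other-disease mutations are thereby treated as neutral with
  respect to the concept under study, which is precisely what lets the
  score penalize only variants in concept-susceptible proteins and domains.

"Relative frequencies" is read per model: $W_d = d/(d+n)$ within the
model's own mapped substitutions. A variant increments the counts of
*every* model covering its position (the ab initio profile plus any
domains), matching the mapping semantics of the scoring step.

When training variants are scored in-sample, each variant's own unit
contribution is first removed from its models' counts (leave-one-out,
`loo = TRUE` in `predict()`), eliminating self-training bias; `loo_adjust`
plus `weights_from_counts` is exactly equivalent to re-estimating the
weights on the dataset minus that variant (property-tested).

## Evaluation conventions

### Class-normalized statistics

Benchmark sets are heavily imbalanced (tens of thousands of negatives per
thousand positives), so the six reported statistics — accuracy, precision,
specificity, sensitivity, NPV, MCC — are computed on **class-normalized**
confusion cells: with sensitivity $s = tp/(tp+fn)$ and false-positive rate
$f = fp/(fp+tn)$, the cells $tp' = s$, $fn' = 1-s$, $fp' = f$, $tn' = 1-f$
are substituted into the standard formulas. Sensitivity and specificity are
unchanged; accuracy becomes $(s + (1-f))/2$; precision, NPV and MCC become
independent of class imbalance. Every normalized statistic is invariant
under independently rescaling the positive and negative class counts
(property-tested), and `check_reference_benchmarks()` confirms that all 96
statistics of the packaged published benchmark table are recovered from
their raw counts at 2 decimal places under this convention — the raw
formulas do not recover them (e.g. raw precision 0.57 where the table
prints 0.95). Display rounding is half-away-from-zero (`round_half_up()`),
matching the table. MCC is defined as 0 when its denominator vanishes
(degenerate classifiers).

### ROC and AUC

`roc_auc()` sweeps all distinct score thresholds, grouping tied scores into
a single step; the trapezoidal area equals the Mann–Whitney concordance
probability with ties counted one half (the ROCR/pROC convention; verified
against both a brute-force pairwise oracle and pROC). Orientation is
lower-score-is-positive throughout.

### Cross-validation

`kfold_cv()` partitions **proteins**, not variants, into $k$ folds by a
seeded shuffle, re-estimates weights from the training folds only, and
scores held-out variants. Folding by protein prevents weight leakage
between training and test through shared models; the published analysis
does not state its fold unit, and this is the leakage-safe reading. Weights
are fully re-estimated per fold for the same reason. Per-fold statistics
can be `NA` when a small fold lacks one class; the pooled confusion matrix
and AUC over all held-out variants are the headline numbers.

### Classification threshold

The published work never states the cut-off behind its confusion matrices,
so the default threshold is 0 — the natural sign boundary of a log-odds
style score — and a score exactly at the threshold classifies as
*tolerated* (strict inequality). Benchmark recovery therefore starts from
printed confusion counts, never from re-scoring; published AUC values are
likewise reproduced only as shipped reference numbers, because the
underlying per-variant scores of the compared methods were never published.

## The synthetic study generator

Real training resources (HGMD disease mutations, Swiss-Prot neutral
polymorphisms, SUPERFAMILY/Pfam profiles) are licensed or bulky, so the
package ships a fully seeded generator (`fixture_config()`,
`simulate_dataset()`) that emulates their *shape*; identical configurations
are bit-identical.

**Profiles.** Match-state emissions are drawn from a symmetric Dirichlet
with per-residue concentration $20/\textrm{sharpness}$: sharpness 20 is the
flat Dirichlet, and the point-mass limit (per-state KL $\to \ln 20$ against
a uniform background) is approached as sharpness grows. Domain families are
**shared** across proteins: each disease concept owns a couple of families,
every protein is assigned one concept and carries at least one instance of
that concept's family plus optional background-family instances, packed
without overlap. Backbone (ab initio) emissions over an annotated instance
are re-drawn around a background-flattened blend of the family's emissions
— a model trained on fewer homologs — so the sharper family wins
informativeness selection at covered positions. This sharing is essential:
under protein-level cross-validation a held-out protein's ab initio model
never has training counts, and only shared families let held-out variants
inherit trained weights, exactly as Pfam/SUPERFAMILY models do in the real
data.

**Mutations.** With probability `weight_bias` (default 0.9) a
concept-tagged mutation is planted inside an instance of its concept's
family; other-disease mutations do the same within their own concepts'
disjoint families; neutral polymorphisms are placed uniformly across
proteins. Disease mutations prefer conserved positions (sampling weight
$\propto$ KL$^2$) and strike the consensus residue, replacing it by one of
the ten least probable residues; neutral polymorphisms prefer diverse
positions (weight $\propto e^{-2\,\textrm{KL}}$), their wild-type is drawn
from the emission distribution itself, and their mutant in proportion to
the remaining emissions — a plausible polymorphism. The wild-type
conventions matter more than they look: forcing the consensus residue for
*all* classes makes every zero-weight score non-positive (any classifier
built on it calls everything damaging), while drawing disease wild-types
from the emissions gives a median $P_w$ equal to the collision probability
(about 0.14 at the default sharpness) and erases the conservation signal.

**Default study conditions.** 600 proteins of length 110–150 with 2–3
domain instances of 25–40 states (roughly one variant per protein, the
sparsity of the real per-protein counts), 200 variants per class
(focal-concept / other-disease / neutral), three concepts in play,
backbone sharpness 40, family sharpness 100. Families are kept moderately
conserved on purpose: near-point-mass families make the $\ln(1-P_w)$
spread (±2 nats) swamp the roughly 1.3-nat weight separation and the
concept-vs-rest AUC collapses toward the conservation-only level. Under
these conditions the disease-specific fit reaches concept-vs-rest AUC
above 0.85 (typically ≈0.95), strictly exceeds the inherited weighting on
the same data, and its 20-fold CV pooled MCC tracks the leave-one-out MCC
within ±0.05 — the qualitative pattern of the published benchmark.

**Balanced-weights condition.** The weights-only baseline degrades when the
weights carry no signal; the conservation-bearing score should not. This is
probed with `weight_bias = 0` (no concept targeting), `domain_sharpness =
sharpness` (one conservation landscape across all models, so the
conserved/diverse placement preference is orthogonal to model membership
and per-model counts stay balanced), and 100 proteins rather than 600:
with only ~1 training variant per model the leave-one-out adjustment
itself biases the naive score (removing a positive's own count tilts its
model neutral-ward), which is an artefact of sparse counts, not of the
weighting scheme. Under this condition the naive AUC sits at chance
(0.5 ± 0.05) while the weighted score stays above 0.6 on conservation
alone.

**What the generator does not emulate**: real phylogenies and site-rate
heterogeneity, HMMER-trained emission correlations between neighbouring
states, insert states and transitions, multi-concept phenotype structure
beyond single tags, and the UMLS phenotype-to-concept annotation pipeline
(concept labels are consumed as given). Passing the synthetic benchmarks
therefore demonstrates correctness of the estimator and its evaluation
machinery under the planted generative model, not clinical performance on
real variant data.

## Numerical choices

* Emission probabilities are floored at $10^{-9}$ after parsing and
  $(1-P)$ terms at $10^{-9}$ in the score, so all logarithms are finite.
* Only the 20 canonical amino acids are modelled; profiles or substitutions
  with degenerate symbols are rejected.
* HMMER3 `*` fields (probability zero) are accepted on input; the writer
  emits negative natural logs at full precision so a write/read round trip
  preserves emissions to within $10^{-9}$.
* Model-selection ties are resolved by source priority then model id;
  boundary scores classify as tolerated; report rounding is half-up to
  2 dp.
* Weight estimation is exact integer counting — no pseudocounts beyond the
  score's built-in $+1$.

## Problem sizes

The shipped tests run the full pipeline on the default 600-protein /
600-variant synthetic study (about 5 s to generate and fit, under a minute
for the whole suite's simulations); the statistic-recovery and oracle
checks are instantaneous. These sizes were chosen as the smallest at which
the planted-signal and cross-validation behaviour is stable across seeds.

## Limitations

Dominating pathogenicity weights remain a structural caveat of the method
itself: in proteins or domains strongly associated with the studied
concept, the weights can overwhelm the conservation term and mark neutral
variants in diverse regions as damaging. The per-variant output therefore
always carries the conservation measure (`informativeness`, and `Pw`/`Pm`)
alongside the score so such predictions can be inspected, and the method is
best used to rank candidates genome-wide rather than to interrogate a
single pre-chosen gene.
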