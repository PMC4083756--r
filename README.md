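# pathmm

Disease-specific ranking of missense variants with profile hidden Markov
models.

Generic deleteriousness predictors can tell pathogenic from neutral
variants, but a study of one disease also needs to separate variants
relevant to *that* disease from pathogenic variants of other diseases —
a distinction conservation alone cannot make. `pathmm` implements the
profile-HMM scoring framework of the FATHMM family with a disease-specific
weighting scheme over 17 root disease concepts, for researchers
prioritizing candidate missense variants in whole-exome/whole-genome
studies.

## The score

A substitution replacing wild-type residue *w* by mutant *m* is scored

```
S = ln[ (1 − Pw)(Wn + 1) / ((1 − Pm)(Wd + 1)) ]
```

* `Pw`, `Pm` — emission probabilities of the wild-type and mutant residues
  at the profile-HMM match state aligned to the variant, taken from the
  most informative covering model (largest Kullback–Leibler divergence
  from the background amino-acid composition at that position; candidates
  are the protein's ab initio model plus any annotated SUPERFAMILY/Pfam
  domains).
* `Wd`, `Wn` — the model's pathogenicity weights: relative frequencies of
  pathogenic-side and neutral-side training substitutions mapping onto it.
  Under the **inherited** scheme the pathogenic side is all disease
  mutations; under the **disease-specific** scheme it is only mutations
  tagged with the chosen concept, and other diseases' mutations count as
  neutral.

Lower scores are more damaging; the default classification threshold is 0.
Training variants are scored with leave-one-out weight adjustment.
Evaluation uses class-normalized confusion statistics (accuracy, precision,
specificity, sensitivity, NPV, MCC computed after rescaling each class to
unit mass), tie-aware trapezoidal ROC/AUC, and protein-level k-fold
cross-validation.

## Worked example

Everything below runs offline on a seeded synthetic study (profiles,
domain annotations and concept-labelled variants) from the package's own
generator:

```r
library(pathmm)

cfg <- fixture_config(seed = 42)          # 600 proteins, 200 variants/class
sim <- simulate_dataset(cfg)

fit <- pathmm(sim$variants, sim$profiles,
              scheme = "disease_specific", concept = "metabolic")
fit
#> Pathogenicity-weight model (profile-HMM conservation + weights)
#>   scheme:   disease_specific (metabolic)
#>   training: 600 substitutions on 389 proteins
#>   weights:  399 models (10 domain)

summary(fit)
#> Leave-one-out performance (disease_specific, metabolic, threshold 0)
#>   n = 600 (200 positives)
#>   tp=192 fp=146 tn=254 fn=8
#>   accuracy=0.797  precision=0.725  specificity=0.635  sensitivity=0.96
#>   npv=0.941  mcc=0.629  auc=0.957
```

The fitted object behaves like any R model: `coef(fit)` returns the
per-model weight table, `predict(fit)` the scored variants (most damaging
first after sorting by score), `plot(fit)` the leave-one-out ROC curve:

```r
scored <- predict(fit)
head(scored[order(scored$score), ], 5)
#>  protein_id substitution        model_id    Pw       Pm    Wd     Wn score prediction
#>        P226         M19I fam_metabolic_1 0.703 5.56e-07 0.934 0.0659 -1.81   damaging
#>        P259         M13R fam_metabolic_1 0.703 1.65e-06 0.934 0.0659 -1.81   damaging
#>        ...
```

The top-ranked variants all fall in a metabolic-susceptible domain family
with a heavy disease weight (`Wd = 0.93`) and strike a conserved consensus
residue (`Pw = 0.70`, mutant probability ~1e-6): both terms of the score
agree. Cross-validation at the protein level confirms the in-sample
numbers are not an artefact of self-training:

```r
cv <- kfold_cv(sim$variants, sim$profiles,
               weight_scheme("disease_specific", concept = "metabolic"),
               k = 20, seed = 42)
#> pooled 20-fold CV: MCC 0.603, AUC 0.964   (vs LOO MCC 0.629, AUC 0.957)
```

Real data enter through plain-text formats: HMMER3 ASCII profiles
(`read_hmmer3_profile()`, `load_profile_dir()`), a TSV domain-annotation
table, and a variant TSV (`read_variant_table()`) with columns
`protein_id`, `substitution` (e.g. `R175H` or `p.Arg175His`), `label`
(`disease`/`neutral`) and semicolon-separated `concepts`. A thin CLI over
the same functions ships at `inst/cli/pathmm.R` (subcommands `simulate`,
`weights`, `score`, `benchmark`, `cv`, `benchmark-check`).

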