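---
title: "Modelling cytotoxicity from heterogeneous assay panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cytotoxicity from heterogeneous assay panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cytobayes` builds binary cytotoxicity classifiers from panels of
heterogeneous screening data. This vignette is the package's account of the
science: the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic data generator emulates and
deliberately does not, and the design choices made where the design was
genuinely open.

## The learner

### Laplacian-corrected naive Bayes

Training data are molecules with sparse binary features (circular-fingerprint
feature identifiers, plus one categorical token per binned continuous
descriptor) and a toxic/non-toxic label. With `A` toxic and `I` non-toxic
molecules, the baseline rate is `P(active) = A/(A+I)`. The raw per-feature
estimate `A_D/(A_D + I_D)` is unreliable for rarely sampled features, so each
feature is augmented with `K = 1/P(active)` virtual samples at the baseline
rate:

```
P_corr(active|D) = (A_D + P(active)·K) / ((A_D + I_D) + K)
```

As the number of molecules containing `D` approaches zero the estimate
converges to `P(active)` — an unsampled feature is assumed to carry no
information. `laplace_probability()` implements exactly this quantity, and
its convergence at `T_D = 0` is asserted in the tests.

### The score and its threshold

`score_bayes()` reports the sum over a molecule's present features of
`log(P_corr(active|D) / P(active))`, i.e. the log of the product of corrected
relative likelihoods. The log-relative form was chosen over the raw
probability product because it makes 0 the natural neutral point (a molecule
with no informative features scores exactly 0), it matches the "score above
zero means flagged" convention for triage use, and summing logs is
numerically stable for molecules with hundreds of features. Features unseen
at training time contribute 0 rather than an imputed penalty.

The default classification threshold is 0. Because the neutral point is only
natural, not optimal, `choose_threshold(method = "best_split")` is also
provided: it maximizes Youden's J over thresholds placed midway between
adjacent distinct scores, ties resolved toward the lower threshold so that
borderline compounds are flagged rather than cleared.

### Descriptor binning

Continuous descriptors enter as quantile-bin tokens learned from the training
data (`n_bins = 10` by default, recorded in the model). Quantile bins were
chosen over fixed-width bins because screening collections have heavy-tailed
lipophilicity and weight distributions; ten bins resolve the monotone
descriptor–toxicity trends seen in practice without fragmenting small
training sets. Values outside the training range are clamped to the extreme
bins; a missing descriptor simply contributes no token (no imputation). The
assumption of class-conditional feature independence is inherited from the
naive Bayes family; correlated descriptors (lipophilicity, weight, rotatable
bonds) therefore multiply their evidence, which is acceptable for a ranking
tool but means scores are not calibrated probabilities.

## Labelling rules

All three rules use a strict `value > cutoff` comparison, and for both
readout types (percent inhibition in %, pIC50 in −log10 molar) higher values
mean more cytotoxic.

* `label_fixed(ds, cutoff)` — the potency convention (e.g. pIC50 > 5.5, or
  4.64 for sparser panels).
* `label_top_fraction(ds, fraction = 0.20)` — equalizes hit rates across
  assays with incomparable dose ranges. The toxic count is
  `ceiling(fraction·n)` (never zero, so tiny assays keep a non-degenerate
  class structure), and boundary ties break by ascending compound id so the
  labelling is deterministic.
* `label_mean_ksd(ds, k = 3)` — the conservative hit-calling rule for
  single-concentration screens. Whether the historical convention used
  sample or population SD is not recorded anywhere we know of; sample SD
  (n−1) is the default with `sd_type = "population"` available. With k = 3
  on an approximately normal readout this flags roughly the top 0.1%.

`filter_min_actives(labelled, 10)` is the gatekeeper for network
construction: below ten actives neither a trustworthy model nor a meaningful
per-assay ROC is available.

## Evaluation choices

* **Ties in the ROC score.** `roc_auc()` uses midranks, the Mann–Whitney
  estimate of P(random active outranks random inactive) with ties counting
  one half. This equals the trapezoidal area under the tie-grouped ROC curve
  and is verified in the tests against brute-force pair counting.
* **Cross-validation.** `kfold_cv()` draws plain random folds
  (unstratified), matching the historical "k equal-sized random sets"
  protocol; stratification would mask the fold-to-fold variance that
  motivates multiple-fold validation in the first place. The reported spread
  is the sample SD over folds. A fold whose test set lacks one class yields
  an undefined AUC, reported and excluded from the mean with a warning.
* **Cutoff scan.** `cutoff_scan()` trains one model per candidate
  percent-inhibition cutoff and scores against confirmed actives from the
  follow-up assay. The default grid is −20..100 in 1% steps (121 models);
  negative cutoffs are included because normally-distributed single-point
  readouts extend below zero. The default `eval_mode = "full"` trains on the
  whole screen and scores every compound; `"cv"` uses out-of-fold scores
  instead. Grid points leaving fewer than two compounds in either class are
  skipped with a recorded reason; ties in the optimum resolve to the lowest
  cutoff (cheaper confirmation load).
* **Truth tables.** Sensitivity, specificity and accuracy with undefined
  (zero-denominator) values reported as `NA` rather than propagated as
  `NaN`. The constant-classifier identities — the all-toxic baseline's
  accuracy equals the prevalence, the all-non-toxic baseline's equals one
  minus it — are asserted exactly in the acceptance tests.

## Prediction networks

`cross_roc_matrix()` fits one model per assay on its full labelled data
(full-data fits, not CV-fold models) and evaluates it on every other assay
in the same readout category; percent-inhibition and IC50 networks are built
separately because follow-up IC50 sets are hit-enriched and chemically
narrower than primary screens. `build_network()` draws an edge only when
both directed ROC scores reach the threshold. Open choices and their
resolutions:

* **Threshold comparison.** The boundary convention is ambiguous between
  "at least" and "strictly above" 0.60 in common usage; the default is
  `>= 0.60` with `strict = TRUE` available.
* **Shared compounds.** Compounds present in both the training and test
  assay are kept by default (overlap is typically small and removing it
  changes the test-set labelling base); `exclude_overlap = TRUE` enables the
  stricter protocol.
* **Merging.** `merge_component()` defaults to the largest component and the
  `any_toxic` label policy — a compound toxic in any member assay is toxic
  in the merged set, which is the alert semantics of a triage tool and makes
  the merge order-independent. `majority` and `keep_duplicates` are
  provided.

`merged_model_pipeline()` chains the whole procedure: networks for both
panels, component merges, k-fold CV of the percent-inhibition, IC50 and
combined models, and a 16×16 score-agreement table of the two sub-models on
a 10% + 10% holdout. The combined model's CV ROC is expected to fall between
the two sub-models' scores when they are distinguishable; when the
sub-models differ by less than the fold-level noise this ordering is not
statistically resolvable, and mixing sets with very different baseline hit
rates can shift weights toward the larger set (the unbalanced-merge effect).

## Featurization

FCFP-style fingerprints are proprietary, so the package uses a documented
stand-in: the Morgan algorithm at radius 3 (diameter 6) with pharmacophoric
feature atom invariants, computed by RDKit through a bundled Python bridge.
Feature identifiers are unfolded 32-bit hashes carried as character strings
(they exceed R's integer range); folding to a power-of-two width ≥ 1024 is
available for memory-constrained runs. Presence/absence semantics (not
counts) are used, the standard choice for this model family. Fractional
polar surface area is TPSA divided by the Labute approximate total surface
area, clamped to [0, 1] because the fragment-based TPSA can slightly exceed
the area estimate for very small polar molecules. Conclusions depend on
feature-based circular fingerprints generically, not on any vendor's bit
identities, but feature ids are only comparable within one toolkit version.

## The simulator: what it emulates, and what it does not

`generate_universe()` builds an abstract compound collection organised as
SAR series: each molecule's feature set is its series' scaffold features
(30, sampled without replacement across series so scaffolds never collide)
plus 40 private decoration features from a 2^20 space. Toxicity is
series-level — a toxic series acts through one of `n_mechanisms` mechanisms
and its members draw latent potencies uniformly from [0.3, 0.95], so every
toxic series spans weak-to-potent members as real series do. Descriptors are
drawn per molecule with a mild upward lipophilicity/weight shift for
toxic-series molecules (`lipo_tox_shift = 1.2` log units), emulating the
well-established lipophilicity–cytotoxicity correlation; setting it to 0
isolates fingerprint-driven behaviour.

`generate_assay()` produces percent inhibition as
`baseline + 100·potency·[mechanism detected] + N(0, noise_sd)` clipped to
[−20, 100]; the defaults (baseline 1.2%, SD 9.8%) are the observed moments
of a large public primary cytotoxicity screen. `generate_ic50_followup()`
submits the top compounds of a primary screen plus a few fillers to a
potency assay (`pIC50 = 4 + 3·potency + N(0, 0.15)`), reproducing the
hit-rate enrichment of confirmation assays.

Fixed scenarios package the regimes the pipeline must handle:

* `scenario_followup()` — a *diverse, sparse-hit* primary HTS (50 series of
  30, 12% of series toxic) plus its follow-up. This is deliberately not the
  default enriched universe: the near-flat ROC-versus-cutoff curve is a
  property of primary screens where most measurements are baseline noise
  and every toxic series keeps labelled members at any cutoff in the
  plateau; in an enriched panel the curve visibly tilts.
* `scenario_chain()` — assays A (series 1–10), B (6–15), C (11–20) with
  every even series toxic through one mechanism, so both overlap regions
  contain toxic series deterministically. The descriptor–toxicity shift is
  turned off here so that cross-assay transfer is fingerprint-driven only;
  a universal descriptor signal would short-circuit the planted
  non-transitivity (A–B and B–C mutually predictive, A–C not).
* `scenario_panels()` — three overlapping percent-inhibition screens
  (top-20% labels) and three IC50 confirmation campaigns with their own,
  partially different footprints (pIC50 > 5.5 labels). The complementary
  footprints matter: if the IC50 sets were strict subsets of the
  percent-inhibition compounds, the combined training set would collapse
  onto the percent-inhibition set and the three-model comparison would be
  vacuous.

The generator is fully deterministic under its seed and emits the same
assay-table and feature-table formats as the readers, so simulated and real
data are interchangeable everywhere. What it does **not** emulate: real
chemistry (features are abstract integers; an optional path through the
RDKit featurizer exists for end-to-end structure tests), dose–response
curve shapes, plate/batch effects, assay-technology covariates, and
correlated scaffold hopping between series. A green simulator test
therefore establishes that the machinery recovers planted structure of the
assumed kind — not that any particular real assay pair will be mutually
predictive.

## Numerical and degenerate-input conventions

* Tanimoto similarity of two empty feature sets is 0, flagged with an
  attribute (no evidence is not identity); within-class similarity of a
  singleton class is `NA` ("undefined").
* Fitting requires both classes present; `p_active ∈ {0, 1}` raises a
  degenerate-training error at fit time rather than producing infinite
  weights.
* Percent-inhibition values outside [−20, 100] are kept but flagged, and
  the default cutoff grid spans the same range so they remain classifiable.
* Model JSON files carry a schema version; mismatches and missing fields
  are explicit errors, never silent defaults. Weights are recomputed from
  the stored exact integer counts on load, so a round-tripped model scores
  bit-identically.
* All randomness (folds, simulator, holdout draws) flows through explicit
  integer seeds, and seeded helpers restore the caller's RNG state.

## Known limitations

* Naive-Bayes scores are uncalibrated; use them to rank and triage, not as
  probabilities.
* The cutoff-scan assumes the follow-up actives are the true actives of the
  whole screen; compounds never submitted to confirmation are invisible to
  the optimisation.
* Cross-prediction ROC scores on small assays (near the 10-active floor)
  carry large sampling error, and edges near the 0.60 threshold are
  correspondingly unstable.
* The merged-model interval ordering is a statistical regularity of panels
  with distinguishable difficulty, not an identity; at desk-scale panel
  sizes it can be unresolvable within cross-validation noise.
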