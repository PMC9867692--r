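---
title: "Methods: multi-task perioperative risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task perioperative risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`periopnet` predicts nine postoperative complications (acute kidney
injury stages, prolonged ICU stay, mechanical ventilation, sepsis,
wound, cardiovascular and neurological complications, venous
thromboembolism, and in-hospital mortality) from two input families:

* **preoperative** features available at admission: 341 continuous,
  42 binary and 19 nominal variables plus admission day/month;
* **intraoperative** minute-resolution physiological series: 12
  channels (vital signs, ventilator settings, anesthetic gas) of
  varying sampling density, plus end-of-surgery blood loss, urine
  output and duration.

Models are trained at three *prediction points*: preoperative only,
intraoperative only, and postoperative (both families). Because the
motivating clinical registry is protected, the package ships a seeded
synthetic cohort generator with *planted* risk structure, so every
claim about discrimination, attribution and uncertainty can be
verified against a known ground truth.

## Synthetic cohort with planted structure

`cohort_spec()` fixes the study conditions; `plant_truth()` draws the
hidden generative parameters; `generate_cohort()` materializes
encounters:

* Continuous features are Gaussian with latent standard scores; each
  outcome has five planted linear drivers (two drawn from a shared
  support reused across outcomes, two private continuous, one binary).
* Each intraoperative channel is an AR(1) process on its own sampling
  grid. Each outcome is additionally driven by one planted temporal
  *motif* — a level shift after 40% of surgery, a linear trend, or a
  variability burst in the middle half — whose presence enters the
  outcome's latent score.
* Outcome intercepts are calibrated by bisection on a 50,000-draw probe
  so that observed prevalences match the configured targets (the
  defaults span 33.3% down to 1.6%).
* Encounters receive strictly increasing surgery dates; 20% of
  preoperative values are masked missing-completely-at-random.

`split_chronological()` reproduces the deployment-faithful design:
the earliest 70% of encounters form the development set, the latest
30% the validation set, and *all* preprocessing statistics come from
the development partition only (`fit_feature_dictionary()`).

```{r tiny-cohort}
library(periopnet)
spec <- cohort_spec(200, seed = 11L, prevalence_targets = rep(0.3, 9))
cohort <- generate_cohort(spec, plant_truth(spec))
split <- split_chronological(cohort)
dict <- fit_feature_dictionary(split$development)
dev <- prepare_tensors(split$development, dict)
val <- prepare_tensors(split$validation, dict)
dim(dev$preop$numeric)
dim(dev$intraop[[1]]$series)
```

## Preprocessing contracts

* Continuous features are percentile-capped at the development 1st/99th
  percentiles, median-imputed, and z-normalized; binary features are
  median-imputed. Every one of the 383 value columns is paired with a
  presence-mask column recording pre-imputation missingness, giving the
  766-column numeric block.
* The 13 low-cardinality nominals are one-hot encoded with an explicit
  `missing` level, so each feature's block sums to one per row. The 6
  high-cardinality nominals become 0-based integer codes for embedding
  lookup; unseen validation levels map to the `missing` code (with a
  message).
* Admission day-of-week and month are encoded on the unit circle
  (sine/cosine pairs), so December and January are adjacent.
* Each intraoperative channel is resampled to the one-minute grid:
  linear interpolation strictly inside the observed range, edge-value
  extension outside it, duplicate measurements averaged, empty channels
  filled with the development median. Values are z-normalized with
  pooled development channel statistics and concatenated with their
  12 presence masks into the `T x 24` series.

## Architecture

The preoperative sub-model embeds each high-cardinality nominal
(embedding tables), passes the numeric/one-hot/cyclic block and the
concatenated embeddings through parallel fully connected rectified
layers, and fuses them into a fixed-width representation.

The intraoperative sub-model runs a bidirectional GRU over the
`T x 24` series. The GRU uses the candidate-gate convention with the
reset gate applied to the hidden projection,

$$ n_t = \tanh(W_n x_t + b_n + r_t \odot (U_n h_{t-1} + c_n)), \qquad
   h_t = (1 - z_t) \odot n_t + z_t \odot h_{t-1}, $$

and each of the nine outcomes owns an additive attention head over the
concatenated forward/backward states $m_t$:

$$ s_{kt} = v_k^\top \tanh(W_k m_t + b_k), \qquad
   \alpha_{k} = \mathrm{softmax}(s_k \text{ over valid } t), \qquad
   c_k = \textstyle\sum_t \alpha_{kt} m_t . $$

The three normalized statics are appended to each context. At the
postoperative point the preoperative representation and the per-task
contexts are concatenated; nine sigmoid heads emit the risks. The
recurrence, sequence reversal and attention are implemented in
C++ (RcppArmadillo); all gradients are derived by hand and verified
against central finite differences in the test suite.

## Training

`train_model()` minimizes the sum of per-task class-weighted binary
cross-entropies; the positive-class weight is `n_negative/n_positive`
on the development labels. Optimization uses hand-written Adam with
weight decay on non-embedding weight matrices, dropout after the fully
connected layers and on attention contexts, and mini-batches ordered by
sequence length within shuffled pools to bound padding. A seeded 10%
internal holdout drives patience-based early stopping with best-weight
restoration.

```{r train, eval = FALSE}
cfg <- model_config(phase = "postop")      # full-scale study conditions
model <- train_model(build_model(cfg, model_layout(dev)), dev)
head(predict_risk(model, val))
```

## Introspection

* `mc_dropout()` repeats stochastic forward passes with the training
  dropout masks active and reports per-encounter, per-task mean risk
  and trial variance; `summarize_uncertainty()` aggregates to the
  (outcome, prediction point) table.
* `integrated_gradients()` attributes the pre-sigmoid task logit along
  the straight path from the zero baseline (the cohort mean in
  normalized space) using a midpoint Riemann sum, doubling the step
  count until the completeness residual is within `max(1e-3, 1%)` of
  the logit difference. Embedded nominals are attributed by path
  integration in embedding space. `aggregate_attributions()` folds
  masks, one-hot and cyclic columns into their source features and
  ranks mean absolute attributions.

## Evaluation

`auroc()` (rank statistic with tie correction), `auprc()`
(step-integrated precision), `youden_threshold()` (exhaustive
`sensitivity + specificity - 1` maximization, ties toward the lowest
threshold), `bootstrap_ci()` (percentile intervals with single-class
resample redraw), `nri()` (continuous and categorical net
reclassification with the asymptotic normal test), and
`auroc_ci_width()` (the Hanley–McNeil closed form) are all
hand-implemented against exhaustive oracles in the test suite.

```{r eval-example}
scores <- c(0.9, 0.8, 0.3, 0.2, 0.7, 0.1)
labels <- c(1, 1, 0, 0, 0, 1)
auroc(scores, labels)
auroc_ci_width(n = 20293, prevalence = 0.016, auroc = 0.80)
```

## Desk-scale caveats

The full study conditions (64-wide layers, 50-epoch budget, tens of
thousands of encounters) are the `model_config()` and `cohort_spec()`
defaults. The bundled analysis drivers and the acceptance checks run
reduced widths (32) and an epoch cap of 10 so everything fits a single
CPU. At that budget the deep models remain under-trained relative to
the information planted in the generator: the model-free oracle on the
synthetic truth supports validation AUROCs above 0.94, while the
reduced-width, 10-epoch network reaches roughly 0.71–0.81, and
per-feature attribution rankings remain noisy for the weaker seeds.
The package reports these honestly rather than rescaling the planted
effects to mask the gap; the phase ordering (postoperative >
preoperative discrimination on motif-driven outcomes) is stable at
desk scale.
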