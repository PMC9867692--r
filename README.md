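# periopnet

Multi-task deep learning for postoperative complication risk from
perioperative data.

`periopnet` predicts nine postoperative complications — acute kidney
injury (`aki`), cardiovascular, neurological and wound complications,
sepsis, venous thromboembolism (`vte`), prolonged ICU stay, prolonged
mechanical ventilation, and in-hospital mortality — at three prediction
points:

* **preop** — static admission features only (341 continuous, 42 binary,
  19 nominal variables plus admission day/month);
* **intraop** — minute-resolution intraoperative physiology only
  (12 channels plus blood loss, urine output and duration);
* **postop** — both input families at end of surgery.

The deep model is a hand-implemented multi-task network: embedding
tables for high-cardinality nominals, fully connected preoperative
fusion, a bidirectional GRU over the `T x 24` intraoperative series
(values + presence masks) with a per-outcome additive attention head,
and nine sigmoid outputs trained jointly with class-weighted
cross-entropy, Adam, dropout and patience-based early stopping. The
recurrence and attention kernels are C++ (RcppArmadillo); every
gradient is derived by hand and checked against finite differences in
the test suite. Alongside it the package provides random forest and
gradient-boosted-tree baselines on summary features, Monte Carlo
dropout uncertainty, integrated-gradients attribution, and evaluation
utilities (AUROC/AUPRC, Youden operating points, bootstrap confidence
intervals, continuous/categorical net reclassification improvement,
Hanley–McNeil confidence-interval widths).

Because the motivating clinical registries are protected, the package
ships a **seeded synthetic cohort generator with planted risk
structure** (linear preoperative drivers plus intraoperative temporal
motifs), so discrimination, attribution and uncertainty claims can be
verified against a known ground truth. See the methods vignette
(`vignettes/perioperative-risk-models.Rmd`) for the full design.

## Worked example

```r
library(periopnet)

spec   <- cohort_spec(n_encounters = 200, seed = 11L,
                      prevalence_targets = rep(0.3, 9))
cohort <- generate_cohort(spec, plant_truth(spec))
split  <- split_chronological(cohort)      # chronological 70/30
dict   <- fit_feature_dictionary(split$development)
dev    <- prepare_tensors(split$development, dict)
val    <- prepare_tensors(split$validation, dict)

dim(dev$preop$numeric)        # 140 x 766 (383 values + 383 masks)
dim(dev$intraop[[1]]$series)  # T x 24    (12 channels + 12 masks)

cfg   <- model_config(phase = "postop", fc_dim = 16, rnn_hidden = 8,
                      attention_dim = 8, embed_dim = 4,
                      max_epochs = 3, seed = 1L)
model <- train_model(build_model(cfg, model_layout(dev)), dev)
head(predict_risk(model, val))            # tidy (encounter, outcome, probability)

mc <- mc_dropout(model, val, n_trials = 50, seed = 1L)  # uncertainty
ig <- integrated_gradients(model, val, i = 1, task = 1) # attribution
compute_metrics(predict_risk_matrix(model, val)[, 1], val$labels[, 1])
```

A single driver, `run_experiment()`, executes the whole design
(generate → split → preprocess → train deep + baselines → uncertainty
→ attribution → metrics → NRI) and writes every table plus a manifest
with file checksums.

## Results at desk scale

The numbered drivers under `analysis/` run the full workflow on a
synthetic cohort of 4,000 encounters (seed `20240101`) with reduced
widths (32) and a 10-epoch cap so everything fits on one CPU. From
that run, validation AUROC by model and prediction point:

| outcome        | deep preop | deep intraop | deep postop | RF postop | GBT postop |
|----------------|-----------:|-------------:|------------:|----------:|-----------:|
| aki            |      0.530 |        0.686 |       0.689 |     0.775 |      0.794 |
| cardiovascular |      0.570 |        0.675 |       0.719 |     0.774 |      0.799 |
| mortality      |      0.686 |        0.691 |       0.662 |     0.758 |      0.828 |
| neuro          |      0.573 |        0.509 |       0.532 |     0.855 |      0.880 |
| prolonged_icu  |      0.541 |        0.534 |       0.569 |     0.857 |      0.894 |
| prolonged_mv   |      0.680 |        0.679 |       0.640 |     0.775 |      0.802 |
| sepsis         |      0.514 |        0.643 |       0.671 |     0.749 |      0.769 |
| vte            |      0.611 |        0.673 |       0.688 |     0.789 |      0.790 |
| wound          |      0.540 |        0.516 |       0.547 |     0.756 |      0.810 |

Net reclassification of the deep postoperative over the preoperative
predictions is positive for the motif-driven outcomes, e.g.
cardiovascular NRI 0.61 (p = 5.4e-18), AKI 0.54 (p = 3.6e-14), sepsis
0.36 (p = 1.5e-4), VTE 0.43 (p = 8.0e-4). Monte Carlo dropout mean
predictive variance (×10³) at the postoperative point ranges from 2.1
(neuro) to 9.5 (prolonged_mv).

An honest caveat: at this reduced budget the deep network is
under-trained relative to the planted signal — the model-free oracle
on the synthetic truth supports validation AUROCs above 0.94, a
10-epoch run at the registered large-scale settings (10,000
encounters) reaches 0.71–0.81, and per-feature attribution rankings
remain noisy for weaker seeds. The package reports this gap rather
than rescaling the planted effects to hide it; the qualitative
ordering (postoperative ≥ preoperative discrimination on motif-driven
outcomes) is stable.

## Reproducing

```sh
# unit, property and acceptance tests against the installed package
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "periopnet",
                               load_package = "installed")'

# headline quantities as JSON (fully seeded; ~8 min on one CPU)
Rscript scripts/acceptance.R --seed 1 --out acceptance.json

# full analysis workflow (run from the repository root; ~20 min)
Rscript analysis/01_simulate.R
Rscript analysis/02_prepare.R
Rscript analysis/03_fit_deep.R
Rscript analysis/04_fit_baselines.R
Rscript analysis/05_introspect.R
Rscript analysis/06_evaluate.R
```

All randomness flows from the seeds above; tables land in
`results/tables/`. Two acceptance expectations are deliberately red at
the registered settings (postoperative AUROC ≥ 0.85 on all nine
outcomes, and ≥ 80% top-3 recovery of the planted top driver by
integrated gradients); they document the optimization-budget gap
described above rather than a defect in the implementations, which are
verified independently by the unit and property tests.
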