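# apneanet

Minute-by-minute sleep apnea detection from a single-lead ECG, in R.

Sleep apnea (SA) — repeated interruption of breathing during sleep — is
common, underdiagnosed, and a risk factor for stroke and cardiovascular
disease. Full polysomnography is the clinical gold standard but is
expensive and scarce; a single-lead ECG from a cheap wearable carries
enough cardiorespiratory information to screen for SA at home, because
apneic episodes impose a cyclic bradycardia–tachycardia swing on the
RR-interval series and modulate the R-wave amplitude.

`apneanet` is for physiological-signal researchers and engineers who
want a complete, dependency-light, end-to-end pipeline:

* **I/O** for WFDB format-16 records, EDF signals, plain-text per-minute
  apnea annotations, and respiratory event tables, including the rule
  that labels a minute apneic when scored events occupy **more than 5 s**
  of it;
* **preprocessing**: Hamilton-style R-peak detection with local-maximum
  refinement, RR/amplitude artifact cleaning by running medians, and
  cubic-spline resampling of ±2-minute context windows into two aligned
  900-point channels;
* **model**: a stacked spatio-temporal network — repeated blocks of
  1-D convolution, max-pooling, dropout and a bidirectional GRU, with
  dot-product attention `a = softmax(F Bᵀ) B` over the last block's
  forward/backward stacks and a 2-way softmax head. The network,
  backpropagation (including BPTT through the BiGRU) and the
  bias-corrected Adam optimiser are implemented in base R, and every
  layer is verified against literal reference implementations of its
  defining equations;
* **training**: seeded mini-batch Adam on binary cross-entropy with
  best-on-validation checkpointing, minority oversampling and
  fine-tuning for a second cohort;
* **evaluation**: per-segment accuracy/recall/specificity/precision/F1
  and rank-statistic AUC; per-recording apnea–hypopnea index
  `AHI = 60·N/T` with SA diagnosed when AHI > 5 (strictly), and
  cohort-level MAE and Pearson correlation of predicted vs. reference
  AHI;
* **synthetic data**: a generator that plants apnea episodes as cyclic
  RR/amplitude modulation in rendered ECG with known beat times, so the
  entire pipeline is testable offline.

## Worked example

Simulate a small cohort, preprocess, fit the small one-block
configuration, and evaluate on two held-out recordings:

```r
library(apneanet)
dir <- file.path(tempdir(), "sa-demo")
man <- generate_dataset(8, dir, seed = 7, duration_s = 1800)

windows <- list()
for (rec in man$records) {
  ecg <- read_wfdb_record(file.path(dir, rec$record_id))
  lab <- read_apnea_minute_labels(file.path(dir,
                                  paste0(rec$record_id, ".apn.txt")))
  windows[[rec$record_id]] <- preprocess_record(ecg, lab)
}

fit <- apnea_net(do.call(c, windows[1:6]),
                 spec = model_spec(n_blocks = 1, filters = 8, units = 8),
                 control = train_control(epochs = 5, learning_rate = 0.01,
                                         batch_size = 16, seed = 7))
print(fit)
#> Sleep-apnea segment classifier (conv-BiGRU-attention)
#>   blocks: 1, filters: 8, GRU units: 8, parameters: 159,026
#>   trained 5 epoch(s) on 130 windows (26 validation)
#>   best validation accuracy: 0.962 (epoch 2)

test_w <- do.call(c, windows[7:8])
ev <- evaluate_per_segment(fit, test_w)
cat(sprintf("held-out: accuracy %.1f%%, F1 %.1f%%, AUC %.3f (n = %d)\n",
            100 * ev$metrics$accuracy, 100 * ev$metrics$f1, ev$auc, ev$n))
#> held-out: accuracy 98.1%, F1 97.0%, AUC 1.000 (n = 52)

rec <- evaluate_recording(predict(fit, windows[["sim07"]], type = "class"),
                          record_id = "sim07")
print(rec)
#> <recording 'sim07': 8/26 apneic minutes, AHI 18.46 -> SA>
```

Each recording is 30 simulated minutes; 26 interior minutes have full
±2-minute context, so each yields 26 windows. The fitted object answers
`print()`, `summary()` (layer table + history), `predict()` (`"prob"` or
`"class"`), `plot()` (loss and validation-accuracy curves) and `coef()`
(weight arrays). The AHI of 18.46 events/hour for `sim07` is well above
the diagnostic threshold of 5, so the recording is called SA.

The full-scale configuration — `model_spec()` with its defaults of three
blocks, 128 filters/units and `train_control()`'s 40 epochs — matches
the published architecture and is what
`inst/scripts/apnea_st.R` (`simulate` / `preprocess` / `build` / `train`
/ `evaluate`) drives from the shell against real WFDB cohorts.

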