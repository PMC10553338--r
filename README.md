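# pcctcardiac

Desk-scale simulation and analysis of **photon-counting micro-CT (PCCT)
cardiac phenotyping in the mouse** — the full chain from a beating,
iodine-enhanced digital left ventricle to cohort-level cardiac statistics,
written for imaging scientists who want every stage of such a pipeline as
tested, inspectable R code.

## What the package does

The pipeline mirrors a contrast-enhanced small-animal PCCT study:

1. **Spectral phantoms** — a dynamic thorax slice whose left ventricle (LV)
   follows a raised-cosine volume cycle between the diastolic (DLVV) and
   systolic (SLVV) volumes at a murine heart rate (300–600 bpm), filled with
   iodinated blood (iodine K-edge at 33.2 keV), plus a static detectability
   phantom of calcium cylinders (0.5–2.5 mm; 10/20/40 mg/mL) in an iodine
   background. Attenuation follows the two-basis photoelectric/Compton model
   `mu(E) = [pe (30/E)^3 + cs KN(E)] · step(E)` with a multiplicative K-edge
   step.
2. **Photon-counting acquisition** — an 80 kVp filtered-bremsstrahlung
   spectrum binned at thresholds 25/34/50/60 keV, a sparse parallel-beam
   projector whose backprojector is its exact transpose, 10 ms views
   (100 Hz view rate) and Poisson counting noise.
3. **Intrinsic cardiac gating** — no ECG anywhere: the difference between
   the measured projections and reprojections of an ungated reconstruction
   isolates motion; the dominant spectral peak in the 300–600 bpm band gives
   the heart rate and signal peaks delimit the cardiac cycles, binned into
   10 phases.
4. **Reconstruction** — ramp-filtered backprojection and a multi-channel
   split-Bregman solver minimizing
   `sum_{t,e} [ ||R x(t,e) − y(t,e)||² / 2 + lambda(t,e) TV(x(t,e)) ]`
   with the add-residual-back strategy, temporal bilateral filtration across
   cardiac phases and rank-sparse kernel regression across energy bins.
5. **Material decomposition** — sensitivity matrix `M` calibrated from vials
   of known concentration, per-voxel solution of `X = C M` by weighted least
   squares, and orthogonal subspace projection (iterative removal of
   negative bases) so concentrations are non-negative.
6. **Detectability** — `CNR = (mu_signal − mu_background) / sd_background`
   for every cylinder in the single-energy image and the decomposed calcium
   map, with Rose-criterion (`CNR > 3`) flags.
7. **Segmentation** — a pure-R 2D U-Net (im2col convolutions, exact
   hand-written backpropagation, Adam) trained with the composite loss
   `BCE + (1 − soft Dice)`, intensity/zoom/rotation augmentation, a
   validation-plateau learning-rate schedule, and precision-recall-balanced
   threshold selection.
8. **Cardiac statistics** — `SV = DLVV − SLVV`, `EF = 100·SV/DLVV`,
   `CO = SV·HR`, `CI = CO/weight`; cohort bookkeeping for the 123-mouse
   APOE2/3/4/KO × HN × diet × sex design; the 1.5 IQR age-outlier rule;
   factorial linear models `response ~ Sex*Age*Weight*HN*Genotype` with an
   aliasing-tolerant type-II ANOVA; Tukey-adjusted post hocs via emmeans;
   Cohen's f; point-biserial diet–weight correlation.

## Worked example

```r
library(pcctcardiac)

# a synthetic subject with truth EF = 45%
seg <- train_pipeline_segmenter(seed = 1)   # ~6 min on 1 CPU
cfg <- pipeline_config(seed = 7,
                       phantom = list(dlvv_ml = 0.045, slvv_ml = 0.02475),
                       segmentation = list(model = seg$model, threshold = 0.5))
res <- run_pipeline(cfg)

res$phantom$truth$ef_pct   # 45.4039  (truth, from the rendered masks)
res$gating$heart_rate      # 450.0653 bpm (truth 450, no ECG used)
round(res$record[, -1], 4)
#   dlvv_ml slvv_ml   hr_bpm weight_g  sv_ml  ef_pct co_ml_min ci_ml_min_g
#    0.0441  0.0248 450.0653       30 0.0193 43.7677    8.6919      0.2897
```

The run writes NIfTI volumes, the gating trace, the sensitivity matrix,
per-phase LV masks and a `cardiac_metrics.csv` under `cfg$outdir`, together
with a `manifest.json` recording the seed fan-out. The printed record says:
the gated, reconstructed, decomposed and segmented subject comes back with
an ejection fraction within ~1.6 percentage points of the ground truth and
a heart rate within 0.1 bpm, with stroke volume, cardiac output and cardiac
index derived by the standard identities.

Cohort-level analysis on the packaged group table:

```r
cs <- summarize_cohort(cohort_counts())
cs$total                  # 123 animals
cs$summary                # male/female counts, %HN, %HFD per APOE isoform

rec <- derive_metrics(simulate_cohort(seed = 1))
fit <- fit_factorial_model(rec, "co_ml_min")
head(fit$anova)           # type-II F tests, HN-within-KO aliasing dropped
```

## Command line

A thin CLI over the exported functions lives at
`inst/cli/pcct-cardiac.R` (subcommands `simulate`, `gate`, `cnr`, `cohort`,
`stats`, `run`; see `--help`-style usage in the file header).
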