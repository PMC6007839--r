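# fluoroperm

Estimation of the permeability of the human corneal epithelium to
fluorescein (P<sub>dc</sub>, nm/s) from multi-drop ocular spot-fluorometry,
with everything needed to exercise the pipeline end-to-end on synthetic
data generated from known ground truth.

The epithelial barrier admits hydrophilic tracers such as fluorescein only
slowly, and its permeability is a sensitive marker of ocular-surface
health. A confocal spot fluorometer of high axial resolution cannot detect
the tiny stromal accumulation left by a single dilute drop, and a
concentrated drop cannot be tracked in the tears because of inner-filter
(concentration) quenching. The multi-drop protocol splits the two jobs:

- a **probe drop** (2 μL, 0.35% w/v — below the ≈0.38% quenching
  threshold) characterizes tear clearance, which follows a single
  exponential, F<sub>dP</sub>(t) = F⁰<sub>dP</sub> e<sup>−k<sub>d</sub>t</sup>,
  fitted by nonlinear least squares with the plateau fixed at zero;
- **n loading drops** (2 × 6 μL, 2%) drive measurable dye into the stroma;
  their tear AUC is never measured but scaled from the probe drop by drop
  mass and dilution:
  AUC<sub>dL</sub> = (F⁰<sub>dP</sub>/k<sub>d</sub>) · (M<sub>L</sub>/M<sub>P</sub>) · (V<sub>iP</sub>+V<sub>d</sub>)/(V<sub>iL</sub>+V<sub>d</sub>).

Permeability then follows in closed form from the corrected stromal
fluorescence F<sub>s</sub> read at the end of the protocol:

```
Pdc = kd · Q · ICF · Fs / (n · F0dP) · (MP/ML) · (ViL + Vd)/(ViP + Vd)
```

where Q = 1.06·CCT − 50 μm is the stromal thickness derived from OCT
pachymetry and ICF = δ/t<sub>d</sub> (≈47 for a 280 μm focal diamond over a
3 μm tear film) corrects for the instrument seeing the whole stromal depth
but only a sliver of the tear film. The package implements these closed
forms, the decay fitting with QC, cohort-table I/O and per-eye
recomputation, Monte Carlo uncertainty propagation (Weibull/normal
parameter distributions), and synthetic-data generators: noisy tear
traces, whole cohorts with hidden truth, and axial depth scans with
Beer–Lambert inner-filter quenching and a box axial response.

The deposited per-eye subject table is not redistributable here;
`synthetic_s1_cohort()` builds a deterministic, clearly-synthetic stand-in
calibrated to the published cohort statistics so that the cohort pipeline
remains fully exercisable.

## Worked example

```r
library(fluoroperm)

protocol <- protocol_config()          # 2 uL/0.35% probe, 2 x 6 uL/2% loading, Vd = 7 uL
trace <- generate_trace(206.51, 0.0142, noise_cv = 1/44, seed = 1)
fit <- fit_decay(trace)
fit
#> <decay_fit> F0 = 204.74 mV, kd = 0.01398 /s (t1/2 = 49.6 s), R2 = 0.9997, n = 25

cohort <- compute_pdc_records(synthetic_s1_cohort(protocol), protocol)
summarize_cohort(cohort$pdc_nm_s, n_subjects = 29)
#> <cohort_summary> n = 49 eyes (29 subjects): mean 0.54 +/- 0.544 (SE 0.0777),
#>   median 0.32, range 0.07-2.59
```

The fitted intercept and rate recover the generating values to ~1%, and the
cohort permeability summary reads: mean 0.54 nm/s with an SD as large as the
mean (a strongly right-skewed distribution), median 0.32 nm/s, and a
49-eye range of 0.07–2.59 nm/s.

The numbered scripts under `analysis/` run the full study narrative and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # synthetic cohort + traces from known truth
Rscript analysis/02_fit_clearance.R       # decay fits + QC vs hidden truth
Rscript analysis/03_compute_permeability.R# per-eye Pdc + cohort summary
Rscript analysis/04_monte_carlo.R         # 10,000-draw uncertainty propagation
Rscript analysis/05_depth_scan.R          # axial resolution + quenching scans
```

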