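# srmkit

Rapid development of scheduled SRM/MRM assays from shotgun-proteomics
spectral libraries.

## What it is for

Moving from a discovery (shotgun) proteomics experiment to a targeted
SRM/MRM assay on a triple quadrupole normally costs weeks of method
development: picking peptides and fragment ions, measuring retention
times on the assay gradient, and sizing acquisition windows so the
instrument never has to watch too many transitions at once. `srmkit`
automates that path for anyone who has identification results (PSM
tables + MGF peak lists) and wants a ready-to-import transition list:

1. **Spectral library construction** — PSMs are grouped by (modified
   sequence, charge); each entry gets the median retention time, the
   union of protein accessions, and the fragment pattern of its
   best-annotated spectrum (y/b ions matched within ±0.1 Da).
2. **Target selection** — assay-suitable peptides (6–25 residues, fully
   tryptic, unmodified, proteotypic, 2+/3+) are ranked by library
   intensity; the top 5 peptides per protein and top 6 y-ions per
   peptide (index ≥ 3) become transitions.
3. **Retention-time transfer** — ≥ 12 landmark peptides spanning the
   gradient anchor an empirical retention index (iRT; 0 at the earliest
   landmark, 100 at the latest). A new gradient is calibrated by
   remeasuring just the landmarks and fitting
   `rt = intercept + slope × iRT` by least squares with one 3σ outlier
   pass. Predicted RTs for all targets follow from the line.
4. **Dynamic-MRM scheduling** — each transition is acquired in a window
   centred on its predicted RT. A sweep line computes the concurrency
   profile; a schedule passes only if the maximum concurrency stays
   strictly below the limit (default 200) and the per-transition dwell
   time (`cycle / concurrency − overhead`) stays above a floor.
   Infeasible target lists split round-robin into several methods.
   Exports: Agilent-style dMRM CSV, unscheduled CSV, Skyline-style
   transition list.

A seeded simulator (random proteomes, in-silico tryptic digestion,
hydrophobicity-driven retention times, lognormal fragment intensities,
noisy gradient transfer) exercises the complete pipeline without any
instrument data and underpins the test suite and benchmarks.

## Worked example

```r
library(srmkit)
res <- run_pipeline(run_config(list(n_proteins = 10L, seed = 1L)),
                    out_dir = "demo_run")
#> library: 466 entries
#> landmarks: 12 reference peptides
#> calibration: slope 0.18039 min/iRT, r^2 0.99999, 12 points
#> targets: 299 transitions, 50 peptides
#> schedule: 1 method(s), max concurrency 30
#> validation: PASS

res$calibration
#> <rt_calibration> rt = 1.1707 + 0.180390 * irt | r^2 0.99999, residual sd 0.0158 min, n 12, rejected 0
res$schedules[[1]]
#> <mrm_schedule> 299 transitions on destination (20 min), cycle 1.00 s, max concurrency 30 (limit < 200)
```

The run simulates a 10-protein proteome, builds a 466-entry library on a
120-min gradient, anchors the iRT scale on 12 landmarks, calibrates a
20-min destination gradient from simulated landmark measurements
(slope 0.180 min per iRT unit ≈ 18 min of elution span over the 0–100
index; residual sd 0.016 min reflects the configured 0.02-min
measurement noise), selects 50 peptides × ~6 transitions, and validates
the schedule: at most 30 transitions are ever concurrent, comfortably
below the limit of 200, so the method fits a single run. `demo_run/`
then contains the library and target TSVs, the calibration report, the
Skyline-style list, the dMRM method CSV and a manifest:

```text
Compound Name,ISTD?,Precursor Ion,MS1 Res,Product Ion,MS2 Res,Fragmentor,Collision Energy,Cell Accelerator Voltage,Ret Time (min),Delta Ret Time,Polarity
NEQLHPVDEMELESEHEK.3y4,FALSE,731.6637,Unit,542.2569,Unit,180,21.5,4,2.46,0.40,Positive
```

A thin command-line front end with the same functionality lives at
`inst/cli/srmkit.R` (verbs `simulate`, `build-lib`, `landmarks`,
`calibrate`, `select`, `run`).

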