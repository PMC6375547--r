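---
title: "From shotgun spectral libraries to scheduled SRM methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From shotgun spectral libraries to scheduled SRM methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(srmkit)
```

## The problem

Targeted proteomics on a triple quadrupole (SRM/MRM) measures a fixed set
of *transitions* — precursor m/z → fragment m/z pairs — and delivers the
sensitivity, dynamic range and throughput that discovery (shotgun)
experiments lack. The price is method development: choosing which peptides
represent each protein, which fragment ions to monitor, and *when* each
transition should be acquired. In a scheduled (dynamic) MRM method every
transition is only acquired inside a retention-time window around the
peptide's expected elution, which multiplies the number of targets a run
can carry — provided the retention times are predicted accurately on
whatever gradient the assay will use.

`srmkit` implements this workflow end to end: build a spectral library
from annotated shotgun results, select assay-suitable peptides and their
most intense fragments, transfer retention times to a new gradient by an
empirical iRT-style linear calibration anchored on landmark peptides, and
emit a concurrency-validated dynamic-MRM transition list. A seeded
simulator generates random proteomes and in-silico tryptic libraries so
the whole pipeline can be exercised and benchmarked without instrument
data.

## Mass and fragment arithmetic

All masses are monoisotopic. A peptide's neutral mass is the sum of its
residue masses, modification deltas and one water (18.010565 Da); an ion
of charge $z$ has

$$ m/z = \frac{M + z \cdot m_p}{z}, \qquad m_p = 1.0072765\ \mathrm{Da}. $$

b-ions carry the first $k$ residues, y-ions the last $k$ residues plus
water, for $1 \le k \le L-1$; the full-length "fragment" is rejected.
Carbamidomethylation of cysteine (+57.02146 Da) is treated as an always-on
fixed modification, applied implicitly to every `C` — this mirrors routine
alkylation during sample preparation and keeps modified-sequence strings
clean. Variable modifications (in practice oxidised methionine,
+15.99491 Da) are written explicitly in a Skyline-compatible bracket
dialect, e.g. `PEPM[+15.99491]IDE`.

```{r}
p <- peptide("PEPTIDE", charge = 2)
c(mass = peptide_mass(p), mz = precursor_mz(p),
  y3 = fragment_mz(p, "y", 3), b2 = fragment_mz(p, "b", 2))
```

## Spectrum annotation and library construction

`annotate_spectrum()` matches every theoretical y/b ion (fragment charge
1+, plus 2+ for precursors of 3+ and above) to the most intense observed
peak within a tolerance (default 0.1 Da, a typical quadrupole-TOF MS/MS
search tolerance). Peak assignment is exclusive: when two theoretical ions
claim the same peak the nearer one in m/z wins, exact ties go to the y
series, and the loser retries on the remaining peaks (deferred
acceptance). With spectra whose peaks sit near single theoretical
positions — the realistic regime — this makes annotation grow
monotonically as the tolerance is widened; in adversarial spectra where
one peak lies between two theoretical ions, exclusivity necessarily picks
one of them, and monotonicity is not meaningful.

`build_library()` groups PSMs by (modified sequence, precursor charge).
Per entry:

* retention time = **median** of the contributing PSM RTs (robust to a
  single mis-assigned PSM, unlike the mean);
* fragment pattern from the single PSM whose annotated intensity sum is
  largest (a "best replicate" policy: averaging spectra across replicates
  can blend different interference patterns);
* protein accessions = union over PSMs; `n_spectra` = group size.

PSMs whose spectrum reference resolves to no MGF spectrum are skipped and
counted; an input in which *no* PSM resolves is an error. The library TSV
(one row per fragment) round-trips through `write_library_tsv()` /
`read_library_tsv()` with m/z and RT at 4 decimals, and reading
cross-checks each fragment m/z against the value recomputed from the
sequence, warning on rows off by more than 0.01 Th.

## Selecting assay-suitable targets

`selection_rules()` encodes the usual filters, all overridable:

| parameter | default | why |
|---|---|---|
| length | 6–25 residues | shorter peptides are unspecific, longer ones ionise and transmit poorly |
| missed cleavages | 0 | assay peptides should be fully cleaved products, even if the search allowed 1 |
| variable modifications | excluded | modification stoichiometry is variable, so modified forms quantify poorly |
| precursor charges | 2+, 3+ | 1+ tryptic peptides fragment poorly; 4+ ions are rare and unstable on a QqQ |
| proteotypic | required | a peptide mapping to several proteins cannot quantify any one of them |
| fragment series / index | y, index ≥ 3 | y-ions dominate beam-type CID of tryptic peptides; y1/y2 are low-specificity |
| peptides per protein | 5 | the customary top-N for a quantification panel |
| fragments per peptide | 6 | enough for identification plus quantifier/qualifier redundancy |

Peptides are ranked per protein by **summed annotated fragment intensity**
(the "library pick intensity"), fragments by relative intensity. All ties
break deterministically (peptides: shorter sequence, then modified
sequence, then lower charge; fragments: lower index, then y before b), so
selection is byte-reproducible under any input row order. Fragments whose
m/z falls within 0.2 Th of the precursor are excluded as
precursor-interference risks.

## The iRT scale and gradient transfer

Retention-time transfer is empirical, not sequence-based: a set of
landmark peptides anchors a dimensionless retention index, and any new
gradient is calibrated by remeasuring only the landmarks.

* `pick_landmarks()` requires landmarks to be reliably detectable (summed
  fragment intensity above the median by default) and picks the eligible
  entries nearest to an $n$-point grid over the eligible RT range
  (default $n = 12$), so the earliest and latest eligible peptides are
  always included and the picks tile the whole gradient.
* `assign_irt()` fixes the scale at 0 for the earliest and 100 for the
  latest landmark, linear in RT between — so on the calibration run,
  iRT is an affine function of RT and every entry's iRT follows from the
  least-squares reference line.
* `calibrate()` fits measured RT $= a + b \cdot \mathrm{iRT}$ by ordinary
  least squares with one robust pass: points with residuals beyond 3
  residual-SDs are dropped and the line refit once (never below 3 points;
  one pass keeps the estimator deterministic). A non-positive slope means
  the gradient order is inverted and is rejected.
* `predict_rt()` evaluates the line; negative predictions are clipped to
  zero and flagged. Extrapolation beyond the landmark span is permitted
  but flagged, because short gradients compress the elution range.

Because iRT is affine in the source RT and calibration inverts an affine
map, the composition *library → iRT → new gradient* is exact whenever the
true transfer is affine and measurements are noiseless — the package
checks this round trip to below 1e-9 min. Under measurement noise the
prediction error is driven by the uncertainty of the fitted line, so it
shrinks with the square root of the landmark count and grows toward the
gradient ends.

## Scheduling and feasibility

Each target receives the window
$[\hat t - \Delta/2,\ \hat t + \Delta/2]$ intersected with the gradient
(full width $\Delta$, matching the vendor "Delta Ret Time" column;
boundary-clipped windows are flagged, windows entirely outside are dropped
with a report). `concurrency_profile()` computes the number of
simultaneously active transitions by a sweep line over window starts and
ends under a half-open $[s, e)$ convention — windows that merely touch do
not overlap. Feasibility has two faces:

* **concurrency**: strictly fewer concurrent transitions than the limit
  (default 200 — validation uses `<`, not `≤`);
* **dwell**: with $k$ concurrent transitions and cycle time $T$, each
  transition receives $T/k$ minus a per-transition interscan overhead
  (default 0.5 ms); the minimum dwell must stay at or above a floor
  (default 5 ms), below which ion statistics degrade.

When a single method fails, `split_methods()` distributes targets
round-robin in RT order over the smallest number of methods that all
pass. Collision energies default to vendor-style linear ramps
(2+: $0.031\,m/z + 1$; 3+: $0.036\,m/z - 4.8$ V, configurable); exports
cover scheduled (dMRM) and unscheduled (fixed 25-ms dwell) vendor CSVs and
a Skyline-style transition list.

## What the simulator emulates — and what it does not

`generate_proteome()` draws random sequences at typical database residue
frequencies (K+R ≈ 11%, giving realistic tryptic peptide lengths);
`digest()` cleaves after K/R not before P with configurable missed
cleavages; `simulate_library()` retains 6–25-mers, assigns 2+ to peptides
of ≤ 14 residues and 3+ above, maps each peptide's Kyte–Doolittle
hydropathy sum affinely onto the central 5–95% of the gradient plus
Gaussian jitter (default sd 0.1 min), and draws i.i.d. lognormal y-ion
intensities. `simulate_transfer()` maps source RTs through
$a + b\,t + c\,t^2$ (curvature default 0; a nonzero value stress-tests
the linear calibration) and adds Gaussian noise only to the landmark
*measurements* — the ground truth stays deterministic, so prediction
error can be attributed entirely to calibration. `detection_rate()` then
scores the fraction of targets whose true destination RT falls inside
the scheduled half-open window.

The simulator deliberately omits peak shapes, ion suppression, matrix
interference, intensity-dependent detectability and nonlinear
chromatography beyond the quadratic term. Passing simulation benchmarks
therefore demonstrates that the *computational* chain — digestion,
annotation, indexing, calibration, scheduling — is correct and
well-conditioned; it does not certify detection rates on real matrices,
where co-eluting background transitions are the dominant failure mode.

## Benchmark conditions

The packaged benchmarks (see `scripts/acceptance.R`) run at desk scale on
seeded synthetic data: a 60-protein proteome (mean length 400) on a
120-min gradient, from which the 500 most intense peptides carry 4 y-ion
transitions each — selection uses a minimum length of 7 so every peptide
has a full set of four y-ions of index ≥ 3. Scheduling uses 0.4-min
windows and a 1-s cycle; gradient transfer maps the library onto a 2-min
gradient (slope 2/120, intercept 0.2 min) with 0.02-min landmark noise,
12 landmarks, and 50 transfer-noise seeds. Statistical examples in the
test suite that concern sampling distributions (slope-recovery within 3
standard errors; residual-SD bands) are asserted at the 95% level over
200 fixed-seed replicates, since individual replicates exceed such bands
with small but nonzero probability by construction.

## Numerical choices and degenerate inputs

* Proton 1.0072765 Da, water 18.010565 Da, monoisotopic residue masses.
* Entry keys are (modified sequence, charge); duplicate keys are invalid.
* An empty peak list annotates to an empty fragment set, not an error.
* Landmark grids resolve collisions to the next-nearest unused entry with
  a distinct RT; landmark sets spanning zero RT range are rejected.
* The robust calibration pass is skipped when the first-pass residual SD
  is below 1e-9 min, so numerically exact fits never reject points.
* Zero or absent peak areas are excluded from group comparison rather
  than zero-imputed (zero would fabricate infinite fold changes), and the
  group test is a plain Welch t-test on log2 areas — not a moderated
  statistic — which the report header states explicitly.
* All generators take explicit seeds and restore the caller's RNG state;
  `run_pipeline()` reruns byte-identically under a fixed seed and config.

## Worked example

```{r}
dir <- tempfile("srmkit_demo_")
res <- run_pipeline(run_config(list(n_proteins = 10L, seed = 1L)),
                    out_dir = dir)
res$calibration
res$schedules[[1]]
list.files(dir)
```

The manifest records the resolved configuration hash, seed, stage counts
and validation status, so a method file can always be traced back to the
exact inputs and settings that produced it.

## Known limitations

* Fragment annotation covers the y/b series only (no a-ions, neutral
  losses or isotope peaks), matching what QqQ assays monitor.
* Proteotypicity is judged against the library's own protein map; a
  peptide unique in the library may still be shared in the full proteome.
  Cross-checking against a FASTA is advisable for real panels.
* The concurrency check counts per transition (conservative); instruments
  that schedule per precursor will see lower effective concurrency.
* Calibration is strictly linear; strongly curved transfers should be
  handled by splitting the gradient range or measuring more landmarks.
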