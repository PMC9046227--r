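---
title: "Methods: plate-based immunometabolic profiling with immunoplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-based immunometabolic profiling with immunoplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoplate)
```

immunoplate implements the computational layer of a 96-well immunometabolic
profiling workflow for macrophages and related immune cells: fast
supernatant pre-screening (nitrite, arginase, glucose, lactate), then the
deeper techniques — extracellular flux, SCENITH translation profiling,
fluorescent metabolic probes and substrate-utilization plates — with a
shared plate-map/tidy-table data model and the paired statistics the
design calls for. This vignette explains the models, the tunable
parameters, and the design decisions, in the package's own words.

## Data model

Plates are 96-well (rows A–H, columns 1–12), addressed `"A1"`–`"H12"` and
sorted row-major. A `plate_layout` maps wells to subject (mouse/donor),
stimulus (naive, LPS, LPS+IFNg, IL4, or custom), treatment, replicate and
role (`sample`, `standard`, `blank`, `unstained`, `empty`); unlisted wells
are `empty`. Plate maps are JSON; measurements are tidy long CSV
(`well,quantity,time_min,value`), chosen over vendor exports for
testability — a `col_map` argument in `read_tidy_measurements()` renames
vendor-style columns at read time. The layout supports an `exclude` flag
per well, but no automatic edge-well policy is applied: whether edge wells
are trustworthy is an assay-level judgement we leave to the user.

Instrument constants for the flux equations live in `xf_constants()` with
XFe96 defaults (CCF 0.61, chamber volume 2.28 µl, K~vol~ 1.60, P/O 2.75).
The buffer factor deliberately has no default: it is a property of the
assay medium, measured per experiment, and silently defaulting it would
corrupt every proton-efflux number downstream.

## Extracellular flux

A standard run cycles mix/measure and injects glucose, oligomycin, FCCP and
antimycin A + rotenone (+ Hoechst), defining five phases:
`pre_glucose, glucose, oligomycin, fccp, aa_rot`. `segment_phases()`
summarizes each phase by its **last measurement cycle** (the steady-state
convention of vendor analysis software), switchable to the phase mean; the
FCCP phase uses the **maximum** OCR cycle by default, since the uncoupled
peak is what maximal respiration means and the FCCP response often decays
within the phase.

Normalization to post-run Hoechst counts is
`rate / (count_well / mean(count))` over included wells; zero or missing
counts exclude the well with a warning. Because the count factor is
mean-centred, the count-weighted plate mean of normalized rates equals the
raw plate mean exactly.

The stress-test algebra (the package spells it out so the implementation is
self-contained, rather than delegating to vendor software): non-mitochondrial
OCR is the Rot/AA plateau; basal respiration = glucose-phase OCR − non-mito;
maximal = FCCP OCR − non-mito; spare = maximal − basal; ATP-linked =
glucose-phase − oligomycin OCR; proton leak = oligomycin − non-mito.
Analogously for ECAR: non-glycolytic acidification is the pre-glucose ECAR,
glycolysis the glucose response above it, capacity the oligomycin ECAR above
it, reserve their difference. Negative derived values are floored at zero
and flagged — except glycoPER (below), where a negative value is a
diagnostic for a misconfigured buffer factor and must stay visible.
Whether "basal respiration" should be corrected for non-mitochondrial OCR
is a convention choice; both the corrected value (`basal_respiration`) and
the uncorrected glucose-phase OCR (`basal_ocr_total`) are emitted, and the
ATP equations use the uncorrected one, matching their printed form which
subtracts only the Rot/AA OCR.

The ATP-rate decomposition:

$$\mathrm{mitoPER} = \mathrm{CCF}\,(\mathrm{OCR}_{basal} - \mathrm{OCR}_{Rot/AA}), \qquad
\mathrm{totalPER} = \mathrm{ECAR} \cdot BF \cdot Vol \cdot K_{vol}$$
$$\mathrm{glycoATP} = \mathrm{glycoPER} = \mathrm{totalPER} - \mathrm{mitoPER}, \qquad
\mathrm{mitoATP} = (\mathrm{OCR}_{basal} - \mathrm{OCR}_{Rot/AA}) \cdot 2 \cdot P/O$$

so totalATP = glycoATP + mitoATP identically, and mitoATP/mitoPER is the
constant 2·(P/O)/CCF wherever mitoPER ≠ 0 — both identities are asserted
over random inputs in the tests. The ECAR entering totalPER is the
glucose-phase (basal) ECAR, switchable.

## SCENITH

Protein synthesis consumes most cellular ATP, so puromycin incorporation
under metabolic inhibitors reads out ATP-synthesis pathway usage. Per
sample, viable-event median fluorescence (median, not mean, and dead events
excluded first — hence the viability flag requirement) is computed for
control (C), 2-deoxyglucose (DG), oligomycin (O) and the combination (DGO);
then

$$\text{glucose dependency} = 100\,\frac{C - DG}{C - DGO}, \qquad
\text{mito dependency} = 100\,\frac{C - O}{C - DGO},$$

with glycolytic capacity and FAO/AAO capacity as the complements to 100.
The parameters are scale-invariant (any common gain cancels), and the
complementarity identities hold exactly by construction. Values outside
[0,100] — routine small excursions in noisy data — are clamped and flagged
rather than rejected; C ≤ DGO is an error because the denominator is
undefined. Harringtonine (full translation arrest) background subtraction
is supported but off by default, since the upstream protocol does not state
it; when on, H is subtracted from all conditions with flooring at zero.
Gated subsets (`profile_by_subset()`) reuse the same machinery per marker
gate; subsets are population summaries, not single-cell readouts, and
gates below the event minimum (default 100 viable events per condition,
below which the median is unstable) are flagged and skipped.

## Pre-screening assays

All four quantifications are linear-calibration inversions, invariant to a
shared additive offset on samples and blanks:

* **Griess nitrite**: OD540 against a nitrite standard curve fit by
  ordinary least squares (the simplest defensible choice; the fit quality
  gate is configurable, default R² ≥ 0.95). Concentrations below blank clip
  to zero with a `below_blank` flag.
* **Arginase**: the classical formula
  `[urea] · (V_total · 10^6) / (V_tested · t · 1000)`. The urea unit is not
  stated by the upstream protocol; the package takes urea in mM with
  volumes in µl and time in minutes, yielding U/L as in the classical
  assay. The urea standard-curve procedure is likewise unspecified, so the
  function accepts urea concentrations (from any curve) as input.
* **Glucose consumption**: single-point GOD-PAP calibration (one standard
  is pipetted in the protocol; multi-point curves are accepted when
  provided), consumption = medium-without-cells minus supernatant. Apparent
  production is reported negative with a `production?` flag, never silently
  truncated.
* **Lactate**: LDH converts lactate to NADH; fluorescence rises to a
  plateau. The endpoint is the first post-start cycle changing by less than
  1% of the current signal from the previous cycle (the protocol says only
  "until a stable read", so the 1% per-cycle tolerance is a package
  decision, configurable); never-stabilizing traces use the last cycle with
  an `unstable` flag.

## Substrate plates

`max_rate()` reproduces the maximum color-formation-rate contract: slide a
30-minute window across the 1–4 h interval, fit an ordinary least-squares
slope at each anchor, return the maximum (floored at zero with a flag).
The 1–4 h interval is fixed by the upstream protocol; the 30-minute fit
span (a handful of reader cycles) is a package decision, as the vendor
algorithm is proprietary. Per-substrate comparisons are two-sided paired
Student's t tests against a reference condition (unpaired fallback with a
flag when subjects do not match), with Sidak adjustment across the
substrate family alongside the raw p values.

## Statistics

"Paired analysis" with more than two groups is read as randomized-block
(repeated-measures) ANOVA — the subject enters as a block factor and
incomplete subjects are dropped with a warning. Dunnett many-to-one
comparisons take their contrast correlation from the fitted model's
contrast covariance: for balanced designs this is the classical
equicorrelated case, evaluated by Dunnett's two-dimensional quadrature over
the shared normal factor and the residual scale (fixed 64-node
Gauss–Legendre grids; deterministic, accurate to ~1e-6 against reference
multivariate-t integration); unbalanced designs use seeded quasi-Monte-Carlo
multivariate-t integration (1e5 points). Both routes are cross-checked
against each other and against an independent reference implementation in
the tests, and the family-wise type-I error is calibrated at 0.05 under a
10^4-replicate null simulation. Two-way designs get main-effect and
interaction F tests plus Sidak-adjusted pairwise contrasts of one factor
within each level of the other, computed in a cell-means parametrization so
the standard errors are exact under blocking. Significance stars follow the
usual figure convention (\*, \*\*, \*\*\* at 0.05, 0.01, 0.001). Each assay
is treated as its own multiplicity family; no correction is applied across
assays.

## The synthetic-data generator

The generators exist so that every analysis stage has a ground truth. The
phenotype presets encode the qualitative biology of macrophage activation —
M(LPS±IFNγ) shift to glycolysis (high ECAR and glucose dependency,
suppressed and collapsed respiration, high nitrite), M(IL-4) upregulate
respiration, spare capacity, arginase and fatty-acid uptake — with numeric
values that are package choices (the upstream work reports figures, not
parameter tables). The test suite asserts only the orderings, not the
numbers.

Noise has three components, all multiplicative/lognormal because every
signal is positive: a per-measurement read CV (default 0.05, typical of
modern plate readers), a per-subject random effect (SD 0.05 on the log
scale, shared by all of a subject's wells — this paired structure is why
the statistics block on subject), and a per-well plating factor (CV 0.15,
the dominant component on manually seeded 96-well plates) that scales both
the Hoechst count and every rate of the well. Plating dominating read noise
is precisely the regime in which Hoechst normalization is worth doing, and
the tests assert that normalization shrinks the pooled within-condition SD
of every flux parameter. For parameters whose true value is near zero
(spare capacity under LPS+IFNγ), the plating factor contributes mostly
noise-scaled rather than mean-scaled variance, so the reduction is real but
small — pooling within-condition variances across stimuli is what makes the
comparison well-powered.

Two constructions make zero-noise inversion exact, which is the module's
core testability contract: NADH kinetics rise as lag/ramp/plateau traces
that reach the plateau exactly (so the stability endpoint recovers the
amplitude exactly), and SCENITH viable-event draws are rescaled so their
sample median equals the condition's true median exactly (the spread stays
lognormal, event σ = 0.5). Condition medians are constructed by inverting
the dependency algebra, so computed dependencies equal the presets
identically at zero noise. Dead events (preset dead fraction per phenotype)
carry depressed intensities and `viable = FALSE`.

What the generator does **not** emulate: optical artifacts, injection-port
failures, edge effects, compensation spillover, drift within a run, or
non-lognormal outlier wells. Passing recovery tests therefore demonstrates
the correctness of the algebra and estimators under realistic magnitudes of
well/subject/plating variation, not robustness to instrument pathology.

## Problem sizes and numerical choices

Default simulated experiments use 4 phenotypes × 6 subjects × 3 replicate
wells (flux and pre-screen; 72 sample wells per plate), 5 inhibitor
conditions × 5000 events per well (SCENITH, one synthetic plate per
subject), and an 8-substrate panel (substrate plates, one plate per subject
× phenotype). Recovery properties are evaluated over 50 seeds; Dunnett
calibration over 10^4 null replicates. These sizes make the full suite run
in a few minutes while leaving the Monte-Carlo margins (binomial SE ≈ 0.002
at 10^4 replicates) far tighter than the asserted tolerances.

Ties and degenerate inputs: all-identical groups yield an undefined F
(flagged) with adjusted p = 1; constant regressors and single replicates
are errors; zero counts exclude wells rather than propagating infinities;
negative derived parameters floor at zero with flags, except glycoPER as
discussed. The Dunnett p is clipped to be at least the raw p, guarding the
monotonicity invariant against quadrature round-off.

## Known limitations

* Raw O2/pH-to-rate deconvolution, FCS parsing/compensation and image
  segmentation are out of scope: traces arrive as rates, event tables as
  gated events, counts as numbers.
* Glucose quantification trusts a single-point calibration when only one
  standard is given, inheriting its error.
* The two-way contrast family is fixed to "factor A within levels of
  factor B"; other families require calling the one-way machinery directly.
* Substrate-plate chemistry (dye kinetics, permeabilization efficiency) is
  not modelled; only the maximum-rate contract is reproduced.
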