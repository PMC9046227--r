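# immunoplate

Computational toolbox for 96-well immunometabolic profiling of macrophages
and other immune cells. It turns raw plate-shaped instrument readouts —
absorbance/fluorescence endpoints, kinetic traces, extracellular-flux (OCR/ECAR)
traces, flow-cytometry event tables and Hoechst cell counts — into metabolic
parameters and group statistics, and ships a synthetic plate-experiment
generator with known ground truth so the whole pipeline is testable without
instruments.

## What it computes

**Pre-screening assays** (`quantify_griess`, `arginase_activity`,
`glucose_consumption`, `lactate_from_nadh`, driver `analyze_prescreen`):
Griess nitrite via a linear standard curve, arginase activity as
`[urea] * (V_total * 10^6) / (V_tested * t * 1000)` (U/L), glucose consumption by
single-point GOD-PAP calibration against cell-free medium, and lactate from
NADH-formation kinetics with a stability-based endpoint rule.

**Extracellular flux** (`segment_phases`, `normalize_rates`,
`mito_parameters`, `glyco_parameters`, `atp_rates`, driver
`analyze_xf_plate`): the five-phase glucose → oligomycin → FCCP →
antimycin A/rotenone stress test. Rates are normalized to post-run Hoechst
counts, `rate / (count_well / mean(count))`; the standard stress-test algebra
yields basal/maximal respiration, spare capacity, ATP-linked respiration,
proton leak, glycolysis, glycolytic capacity and reserve; and the ATP
production-rate decomposition uses the XFe96 equations

    mitoPER  = CCF * (OCR_basal - OCR_Rot/AA)          CCF  = 0.61
    totalPER = ECAR * BF * Vol_chamber * K_vol         Vol  = 2.28 ul, K_vol = 1.60
    glycoATP = glycoPER = totalPER - mitoPER
    mitoATP  = (OCR_basal - OCR_Rot/AA) * 2 * P/O      P/O  = 2.75

with the buffer factor BF (mM/pH) measured per assay medium.

**SCENITH** (`summarize_events`, `scenith_parameters`, `scenith_profiles`,
`profile_by_subset`): translation (puromycin incorporation) as an
ATP-synthesis proxy under metabolic inhibitors. With viable-event median MFIs
under control (C), deoxyglucose (DG), oligomycin (O) and both (DGO):
`glucose dependency = 100 (C-DG)/(C-DGO)`, `mito dependency = 100 (C-O)/(C-DGO)`,
and the complementary glycolytic and FAO/AAO capacities (`100 - dependency`).

**Fluorescent probes** (`delta_mfi`, `inhibitor_validation`,
`potential_independence_check`): ΔMFI = stained − unstained for 2NB-DG,
BODIPY C16, MitoTracker Green and TMRM, with the hard-coded
probe↔inhibitor validation pairings (phloretin, lipofermata, FCCP).

**Substrate plates** (`max_rate`, `substrate_rates`, `compare_substrates`):
sliding-window least-squares maximum color-formation rate in the 1–4 h
window, and per-substrate paired t tests with Sidak adjustment.

**Statistics** (`anova_dunnett`, `anova_twoway_sidak`, `linregress`):
paired (randomized-block) or ordinary one-way ANOVA with Dunnett many-to-one
comparisons (analytic equicorrelated quadrature, multivariate-t integration
for unbalanced designs), two-way ANOVA with Sidak-adjusted cell contrasts,
and simple linear regression for cross-technique correlations.

## Worked example

```r
library(immunoplate)

# ATP-rate decomposition of one well: glucose-phase OCR 100, Rot/AA OCR 20,
# basal ECAR 50, measured buffer factor 2.4 mM/pH
atp_rates(100, 20, 50, xf_constants(buffer_factor = 2.4))
#>   mito_per total_per glyco_per glyco_atp mito_atp total_atp flags
#> 1     48.8    437.76    388.96    388.96      440    828.96

# simulate a full stress-test plate (4 phenotypes x 6 mice x 3 replicates)
# and recover the parameters
sim <- generate_xf_experiment(noise = noise_free())
res <- analyze_xf_plate(sim$traces, sim$counts, sim$layout)
subset(res$summary, select = c(stimulus, basal_respiration, glycolysis))
#>   stimulus basal_respiration glycolysis
#> 1      IL4               100         15
#> 2      LPS                50         45
#> 3 LPS+IFNg                40         60
#> 4    naive                80         20
```

The mitoPER of 48.8 is the CO2-corrected OXPHOS acidification
(0.61 × 80), mitoATP is 80 × 2 × 2.75 = 440 pmol ATP/min, and glycoATP is
whatever proton efflux the mitochondria cannot account for. In the
simulated plate the classically activated states (LPS, LPS+IFNγ) show the
expected glycolytic shift and M(IL-4) the oxidative one.

The end-to-end pipeline (simulate → analyze → report) runs with
`run_pipeline(list(out_dir = "out", seed = 1))` or from the shell via
`Rscript inst/cli/immunoplate.R run --seed 1 --out out`.

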