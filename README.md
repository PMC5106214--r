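# sir3coop

Quantitative analysis of cooperative binding of the budding-yeast
silencing protein Sir3 to nucleosome pairs.

Heterochromatin spreads when SIR complexes coat nucleosome arrays, and
the Sir3 dimer is the subunit that reads the chromatin template. Whether
Sir3 engages nucleosomes one at a time or bridges neighbouring
nucleosomes is distinguishable by binding measurements: bridging predicts
cooperative, high-affinity association with di-nucleosomes (DiN) but not
mono-nucleosomes (MonoN), mono-phasic DiN dissociation kinetics, and a
strongly super-proportional preference for nucleosome pairs at
physiological Sir3 concentrations. `sir3coop` implements the full
analysis chain behind those comparisons:

* **Equilibrium titrations** (`fit_hill()`, `fit_two_site()`): Hill fits
  of EMSA fraction-unbound or min-max-normalized BLI signal,
  `f_unbound = 1/(1+([S]/K_D)^n)`, and the two-identical-independent-sites
  saturation model `Θ = x/(1+x)`, `x = [S]/K_D`, whose Hill-equivalent
  coefficient is exactly 1. Uncertainties are ±1 SD from the fit
  covariance.
* **BLI kinetics** (`fit_exponential()`, `select_model_order()`,
  `derive_kon()`): linear-drift baseline correction, mono-/bi-exponential
  phase decomposition with fast-first reporting, model order chosen by an
  extra-sum-of-squares F-test (α = 0.01) *and* a runs test on residual
  signs (α = 0.05), and `k_on = (k_obs − k_off)/(i·[S])` in M⁻¹s⁻¹.
* **Boltzmann occupancy** (`occupancy_probabilities()`,
  `selectivity_ratio()`): state free energies `ΔG/RT = −n·ln([S]/K_D)`
  and multi-state probabilities `p_i ∝ exp(−ΔG_i/RT)`, quantifying how
  cooperativity converts a 12-fold affinity ratio into a 50–76-fold
  preference for nucleosome pairs.
* **Subtelomeric ChIP ensembles** (`aggregate_at_anchors()`,
  `normalize_to_control()`, `qpcr_fold_enrichment()`): RPM-normalized
  bedGraph tracks aggregated at ≤ 32 oriented subtelomere anchors
  (C-ACS or chromosome end), control-normalized per base, plus ΔCT qPCR
  fold enrichment against *cup1*.
* **Synthetic assays** (`sim_config()`, `simulate_titration()`,
  `simulate_sensogram()`, `simulate_coverage()`, `simulate_qpcr()`):
  seeded generators defaulting to the reference parameter tables
  (`sir3_equilibrium_params()`, `sir3_kinetic_params()`), so the entire
  pipeline is exercised without external data.
* **Pipeline stages** (`run_config()`, `run_equilibrium()`,
  `run_kinetics()`, `run_occupancy_report()`, `run_ensemble()`,
  `run_qpcr()`, `run_pipeline()`): manifest-driven reports with a JSON
  run summary.

## Worked example

Simulate a noisy DiN titration at the reference parameters
(K_D = 0.12 µM, n = 1.9), refit it, and evaluate what the fitted
cooperativity buys at nuclear Sir3 concentrations:

```r
library(sir3coop)

cv <- simulate_titration(sim_config(seed = 42), K_D = 0.12, n = 1.9,
                         protein_label = "Sir3", template_label = "DiN")
fit_hill(cv)
#> Hill fit: Sir3 / DiN (BLI_normalized_signal)
#>   K_D = 0.123 +/- 0.003 uM; n = 1.84 +/- 0.073; rss = 0.0299
```

The fit recovers the generating affinity and cooperativity within one
standard deviation. Feeding the packaged three-state system (unmodified
DiN and MonoN with BLI parameters, acetylated MonoN at its EMSA
affinity) into the Boltzmann calculator:

```r
st <- default_binding_states()
occupancy_probabilities(st, S = 0.6)
#> Boltzmann occupancy at [S] = 0.6 uM:
#>   DiN          p = 0.9778   dG/RT = -3.058
#>   MonoN        p = 0.01527   dG/RT = +1.101
#>   acMonoN      p = 0.006892   dG/RT = +1.897

selectivity_range(st$DiN, st$MonoN, 0.4, 0.8)
#>      low     high
#> 50.20628 76.09850
```

At 0.4–0.8 µM Sir3, bound protein is 50–76-fold more likely to sit on an
unmodified nucleosome pair than on an isolated nucleosome; with the same
affinities but no cooperativity (both n = 1) the preference would be a
concentration-independent 11.7-fold. Kinetic model selection on a
synthetic MonoN association trace shows the biphasic character that
distinguishes mono-nucleosome binding:

```r
tr <- simulate_sensogram(sim_config(seed = 42), amplitudes = c(0.51, 0.49),
                         rates = c(0.25, 0.04), phase = "association")
select_model_order(fit_exponential(tr, 1), fit_exponential(tr, 2))
#> Model selection: order 2 (F-test p = 8.73e-144, runs-test p = 8.89e-39, rss ratio = 14.4)
```

## Documentation

The methods vignette (`vignettes/sir3coop-methods.Rmd`) describes the
models and their assumptions, fitting and model-selection conventions,
what the synthetic generators do and do not emulate, numerical policies
for degenerate inputs, and known limitations.
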