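---
title: "Quantifying cooperative Sir3-nucleosome binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cooperative Sir3-nucleosome binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sir3coop)
```

## The scientific question

Heterochromatin in budding yeast spreads when the SIR complex (Sir2/3/4)
coats nucleosome arrays. The reader subunit Sir3 is a dimer with two
nucleosome-binding BAH domains, and the central quantitative question this
package addresses is *how* that dimer engages chromatin: one nucleosome at
a time, or as a bridge across neighbouring nucleosomes. The two
architectures make different, measurable predictions about equilibrium
binding curves, dissociation kinetics, and the selectivity of Sir3 for
nucleosome pairs over isolated nucleosomes. `sir3coop` implements the
complete analysis chain that discriminates them: equilibrium isotherm
fitting, sensogram decomposition, Boltzmann occupancy calculation, and
subtelomeric ChIP-seq ensemble aggregation, together with seeded synthetic
generators that emulate each assay so the whole chain is testable without
any external data.

## Equilibrium binding models

Titrations come from two readouts. EMSA quantifies the *disappearance* of
the free nucleosome band, i.e. the fraction unbound; BLI quantifies the
appearance of bound signal, min-max normalized to `[0, 1]`
(`normalize_minmax()`). Both are fit with the Hill equation

$$f_\mathrm{unbound} = \frac{1}{1 + ([S]/K_D)^n}, \qquad
  A_\mathrm{norm} = \frac{([S]/K_D)^n}{1 + ([S]/K_D)^n},$$

where $[S]$ is protein concentration (free ligand approximated by total,
as appropriate for nucleosomes at low-nanomolar concentrations titrated
with micromolar protein), $K_D$ is the concentration at the transition
midpoint, and $n$ is the Hill coefficient -- a purely phenomenological
steepness descriptor, not a binding stoichiometry. Values of $n$ near 1
mean non-cooperative binding.

The explicit non-cooperative alternative is the saturation of two
identical, independent sites (the two faces of one nucleosome core).
With the per-site macroscopic constant $K_D$ and $x = [S]/K_D$, the
binding polynomial of two independent sites is $(1+x)^2$ and the
fractional saturation is

$$\Theta = \frac{x + x^2}{1 + 2x + x^2} = \frac{x}{1+x},$$

which is exactly non-cooperative: a Hill fit to data generated by this
model returns $n = 1$ identically, and the package's tests assert this
equivalence. (An algebraically distinct "two-site" expression with
denominator $1 + x + x^2$ would carry residual apparent cooperativity of
$n \approx 1.3$ at the midpoint and would contradict the model's own
premise of independence; the package deliberately uses the independent-sites
polynomial, whose midpoint, limits and Hill-equivalence are all exact.)

### Fitting conventions

* Optimizer: Levenberg-Marquardt (`minpack.lm::nls.lm`) with tight
  convergence tolerances (`ftol = ptol = 1e-15`), so that noiseless
  self-consistency tests recover generating parameters to machine-level
  accuracy.
* Initialization: $K_D$ starts at the measured concentration nearest
  half-response and $n$ at 1; bounds are $K_D \in (0, 100]$ uM and
  $n \in (0, 6]$. These starts carry no directional prior about
  cooperativity.
* Uncertainties: $\pm 1$ SD from the Jacobian-based covariance at the
  optimum (68% confidence), the convention used for the reference
  parameter tables. No bootstrap by default.
* Replicates are pooled before fitting (all points enter one
  least-squares problem), not averaged per concentration.
* Hill coefficients from EMSA curves are computed but tagged
  `n_confidence = "low"`: gel artifacts and non-specific DNA binding
  distort EMSA transition shapes, so cooperativity calls rest on BLI data
  only. A practical threshold of $|n - 1| \le 0.15$ (about 1.5 reported
  SD) is treated as "non-cooperative" in interpretation.
* Concentrations are micromolar everywhere inside the package; unit
  conversions happen only at I/O boundaries.

## BLI kinetics

Association and dissociation phases are fit with exponential rate
equations: association $A(1 - e^{-k_\mathrm{obs} t})$ (no constant term),
dissociation $A e^{-k_\mathrm{off} t} + B$ with a free baseline, each in
mono- or bi-phasic form. Before fitting, the linearly rising nonspecific
baseline measured on an empty sensor is subtracted
(`estimate_drift()`, `correct_baseline()`). For bi-phasic fits the fast
phase is reported first and amplitudes as percent of the summed
amplitude; dissociation time constants are $\tau_i = 1/k_{\mathrm{off},i}$
and the summary residence time is the amplitude-weighted mean
$\sum_i f_i \tau_i$.

Model order is decided by two diagnostics that must agree
(`select_model_order()`): an extra-sum-of-squares F-test at
$\alpha = 0.01$ for a substantial rss decrease, and a Wald-Wolfowitz runs
test on the order-1 residual signs at $\alpha = 0.05$ for systematic
(periodic) misfit. The double gate is conservative: a bi-phasic call
requires both a quantitatively better fit *and* structured order-1
residuals. Bi-exponential fits whose two rates collapse within 5% (or
whose minor amplitude vanishes) are treated as effectively first order.
Because the bi-exponential model nests the mono-exponential one, the
order-2 fit is additionally restarted from the order-1 optimum, so its
rss can never exceed the order-1 rss.

Association rate constants follow from
$k_\mathrm{on} = (k_\mathrm{obs} - k_\mathrm{off}) / (i\,[S])$ with $i$
the presumed number of binding sites on the template, reported in
$\mathrm{M}^{-1}\mathrm{s}^{-1}$; rates are paired phase-by-phase
(fast with fast, slow with slow). When $k_\mathrm{obs} < k_\mathrm{off}$
the negative result is flagged with a warning, never clamped.

## Boltzmann occupancy and selectivity

Given apparent parameters $(K_{D,i}, n_i)$ per nucleosome state, the
free energy of the bound state relative to unbound is carried in RT units,

$$\Delta G_i / RT = -n_i \ln([S]/K_{D,i}),$$

and state probabilities follow the Boltzmann distribution
$p_i = e^{-\Delta G_i/RT} / \sum_j e^{-\Delta G_j/RT}$ (log-sum-exp
stabilized). Working in RT units removes temperature and the gas/Boltzmann
constant from every ratio; 303.15 K (the 30 C of the BLI assays) matters
only if energies are exported in absolute units, which the package does
not do by default.

The packaged three-state system (`default_binding_states()`) uses the
BLI-derived parameters for the unmodified di-nucleosome (0.12 uM, $n$ 1.9)
and mono-nucleosome (1.4 uM, $n$ 1.3) states, and the EMSA affinity
(4.0 uM) with $n = 1$ assumed for the H4K16-acetylated state, since EMSA
Hill coefficients are unreliable. With these inputs the di- over
mono-nucleosome selectivity $\ (S/K_{D,a})^{n_a}/(S/K_{D,b})^{n_b}$
evaluates to about 50-fold at 0.4 uM and 76-fold at 0.8 uM -- the
estimated intranuclear Sir3 concentration range -- while the $n = 1$
counterfactual with the same affinities is a concentration-independent
11.7-fold. That gap *is* the quantitative contribution of cooperativity
to the selective recognition of nucleosome pairs:

```{r occupancy}
st <- default_binding_states()
selectivity_range(st$DiN, st$MonoN, 0.4, 0.8)
selectivity_ratio(binding_state("DiN", 0.12, 1),
                  binding_state("MonoN", 1.4, 1), 0.6)
```

The calculation is per-site Boltzmann weighting only: no competition for
a finite Sir3 pool across genomic sites is modelled.

## Subtelomeric ensemble profiles

Coverage tracks (bedGraph in, expanded to per-base arrays) are scaled to
reads per million, then aggregated at a set of up to 32 subtelomeric
anchors (`aggregate_at_anchors()`). Each anchor carries an orientation --
the direction toward the centromere -- so that profile offsets are
negative toward the chromosome end and positive toward the centromere
regardless of arm. Anchors at the C-ACS (the ARS consensus in the core X
element) use a two-sided 14-kb window; chromosome-end anchors use a
one-sided window toward the centromere. Two telomeres (TEL01R, TEL13R)
are excluded by default, matching the 30-subtelomere convention for this
genome. Windows running off a chromosome are truncated, with per-offset
anchor counts recorded. The summed profile is normalized per base to a
sir3-deletion control; zero-control bins are rescued with a pseudocount
equal to the smallest positive control value in the window (scale-free)
and flagged. The published C-ACS coordinate list is not distributed with
the package: the anchor table is user-supplied, and the shipped synthetic
genome exists to validate the machinery, not to reproduce any particular
genome-browser figure.

ChIP-qPCR fold enrichments use the delta-CT method:
$E = 2^{CT_\mathrm{ref} - CT_\mathrm{target}}$ per biological replicate
against the *cup1* reference, then the replicate mean, then the ratio to
the deletion control. Averaging per-replicate enrichments (rather than
averaging CTs first) was chosen so replicate scatter propagates into the
reported SD; the two policies differ in the mean itself whenever CTs
scatter, and the tests pin the chosen one.

## Synthetic data: what it emulates, and what it does not

The generators (`simulate_titration()`, `simulate_sensogram()`,
`simulate_coverage()`, `simulate_qpcr()`) default to the reference
parameter tables (`sir3_equilibrium_params()`, `sir3_kinetic_params()`)
as generating truths, so parameter-recovery tests double as regression
checks against the published estimates. Conditions that the assays state
directly are used as-is: 12-point logarithmic titration grids with 2-3
pooled replicates (>30 points per curve), linearly drifting sensogram
baselines, 30 usable subtelomeres. Magnitudes the assays do not quantify
are fixed once at field-plausible values and documented here: titration
noise SD 0.03 response units, sensogram noise 1% of total amplitude,
subtelomeric domains decaying over 3 kb at 50-fold peak-to-background
over a Poisson background of 1 read/base. All generators are pure
functions of a single seeded configuration (`sim_config()`), with a
documented substream offset per generated object.

Synthetic data reproduces the *models* plus idealized noise; it does not
reproduce ligand depletion, sensor crowding, inner-filter effects, gel
artifacts, mappability structure, or the heterogeneity of real
subtelomeres. Passing recovery tests therefore demonstrates correctness
of the estimators under the stated noise models, not robustness to every
artifact of the physical assays.

## Numerical and degenerate-input policies

* Flat titrations (response range < 0.05) and short curves (< 5 points)
  are rejected with diagnostics rather than fitted.
* Zero-residual fits: the covariance of a perfect fit is numerically
  singular; standard errors are then reported as `NA` rather than a
  fabricated zero-adjacent number.
* Rate ties in bi-exponential fits break toward order-1 reporting.
* The fast minor association phase of the Sir3-delta-wH/di-nucleosome
  scenario (11% amplitude, rates 2x apart) is intrinsically
  ill-determined -- the reference table itself prints no uncertainty for
  it -- so recovery tests assert only on rates reported with
  uncertainties.
* Sensogram generation samples at 2 Hz but never fewer than 100 points
  per trace, as an instrument acquiring short steps would.

## Problem sizes used by the test and acceptance suites

Stochastic checks run 100 seeded replicates per scenario: 6 equilibrium
BLI parameter sets (36-point curves), 12 kinetic scenarios, and 2 model
selection scenarios. These sizes give medians stable to well under the
tolerances asserted (1 reported SD for equilibrium parameters, 5% for
rates, 95/100 for order selection) while keeping the full suite in the
tens of seconds.

## Interfaces

The package's functions are its interface: titrations, sensograms, anchor
tables and CT tables are plain delimited text, and the `run_*()` stage
functions (driven by `run_config()` / `read_run_config()` YAML) turn
input manifests into the parameter, kinetic, occupancy, ensemble, and
qPCR report tables, plus a JSON run summary with the package version,
configuration hash, and per-stage timing. A shell wrapper would add
nothing beyond `Rscript -e` around these calls, so none is shipped.

## Known limitations

Free ligand is approximated by total protein throughout, so affinities
are apparent, not depletion-corrected. Kinetic fits are per-trace; no
global multi-concentration fitting is performed, matching the averaging
convention of the reference tables. The occupancy model treats binding
sites independently and ignores pool depletion. The ensemble module
starts from coverage tracks: read mapping, deduplication and
demultiplexing are upstream of the package.
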