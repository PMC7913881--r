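---
title: "Models and methods: HcdE 7-hydroxycoumarin reductase kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: HcdE 7-hydroxycoumarin reductase kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcdkin)
```

# The system

HcdE is a zinc-dependent alcohol-dehydrogenase-type ene-reductase from
*Pseudomonas mandelii* 7HK4 that catalyzes the NADPH-dependent reduction of
the C3–C4 double bond of 7-hydroxycoumarin (umbelliferone, 7HK), giving
7-hydroxy-3,4-dihydrocoumarin. The dihydrocoumarin lactone hydrolyzes in
aqueous buffer to 3-(2,4-dihydroxyphenyl)propionic acid, which feeds the
lower degradation pathway. This package implements the quantitative layers
of that story: the steady-state rate law and its mechanistic justification,
the spectrophotometric assay arithmetic, parameter estimation with
identifiability diagnostics, RT-qPCR relative quantification of the
pathway genes, and the ion-mass bookkeeping for the pathway intermediates —
all fed by seeded synthetic-data generators so that every stage is testable
without any measured dataset.

# The rate law

The catalytic cycle is ping-pong: the reductive half-reaction loads the
enzyme with hydride from NADPH, and the oxidative half-reaction transfers
it to 7HK,

$$
E_0 + \mathrm{NADPH}
  \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} E_1
  \xrightarrow{k_{\mathrm{NADPH}}} E_2, \qquad
E_2 + \mathrm{7HK}
  \underset{k_{-2}}{\overset{k_2}{\rightleftharpoons}} E_3
  \xrightarrow{k_{\mathrm{7HK}}} E_0 + \mathrm{NADP^+} + \mathrm{7HKH_2},
$$

with a dead-end branch in which 7HK binds the enzyme–NADPH charge-transfer
complex,

$$
E_1 + \mathrm{7HK}
  \underset{k_d}{\overset{k_a}{\rightleftharpoons}} E_i .
$$

Writing $A$ = [NADPH], $B$ = [7HK], the closed-form initial-velocity
expression is

$$
v \;=\; \frac{E_0\, k_{bim}\, k_{\mathrm{NADPH}}\, A\, B}
  {k_{\mathrm{NADPH}} A + k_{bim} B
   \left(K_{m,\mathrm{NADPH}} + A + AB/K_i\right)},
$$

with $k_{bim} = k_{\mathrm{7HK}}/K_{m,\mathrm{7HK}}$ the bimolecular
specificity constant of the oxidative half-reaction,
$K_{m,\mathrm{NADPH}} = (k_{-1}+k_{\mathrm{NADPH}})/k_1$, and
$K_i = k_d/k_a$ the dissociation constant of the dead-end complex.

**The inhibition term.** We write the substrate-inhibition contribution as
$AB/K_i$, i.e. $K_i$ a dissociation constant in concentration units. This
is forced by dimensional analysis ($K_i = k_d/k_a$ has units of
concentration, and the denominator of the rate law must carry units of
concentration throughout) and by the physics: inhibition must strengthen
with $B$ and vanish as $K_i \to \infty$. The package represents "no
inhibition" by the explicit sentinel `k_i = Inf`, never by a large float.

**Relation to the full mechanism.** Solving the clamped-substrate
steady-state balance of the five enzyme species exactly gives

$$
v_{\mathrm{full}} = \frac{k_{\mathrm{NADPH}} E_0}
 {\dfrac{K_{m,\mathrm{NADPH}}}{A} + 1 + \dfrac{B}{K_i}
  + \dfrac{k_{\mathrm{NADPH}}}{k_{bim} B}
  + \dfrac{k_{\mathrm{NADPH}}}{k_{\mathrm{7HK}}}},
$$

which is the closed form plus exactly one extra denominator term
$k_{\mathrm{NADPH}}/k_{\mathrm{7HK}}$. The closed form is therefore an
approximation valid when the oxidative chemistry is fast
($k_{\mathrm{7HK}} \gg k_{\mathrm{NADPH}}$); at an excess ratio of 100 the
neglected term is 1/100 of a denominator that is at least 1, so agreement
is better than 1% everywhere. The identity
$1/v_{\mathrm{full}} - 1/v_{\mathrm{closed}} =
1/(k_{\mathrm{7HK}} E_0)$ is asserted exactly in the tests.

# Units

Everything internal is mM and seconds; `as_mM()`/`from_mM()` convert at the
boundary. User-facing functions take the units the bench uses: enzyme in
nM, substrates in µM, velocities in µM/s, $k_{bim}$ in mM⁻¹s⁻¹, $K_i$ in
mM. Unit round trips are tested to 1e-12 relative.

# The mechanism simulator

The mass-action ODE system (9 species, 7 elementary processes) is induced
mechanically from the scheme above; NADP⁺ release is lumped into the
$k_{\mathrm{7HK}}$ turnover step as the scheme writes it. Whether NADP⁺
release in fact precedes 7HK binding cannot be resolved at the
steady-state level — the lumped and sequential readings give the same
steady-state velocity — so the lumped form is used. Integration uses
`deSolve::lsoda` with `rtol = 1e-10`, `atol = 1e-14`; trajectories conserve
total enzyme, total nicotinamide (free NADPH + free NADP⁺ + cofactor bound
in E1, E2, E3, Ei) and total coumarin (free 7HK + product + 7HK bound in
E3, Ei) to better than 1e-9 relative, which the tests assert.

The clamped-substrate steady state is **not** obtained by long
integration: with buffered substrates the enzyme-species balance is linear,
so `steady_state_velocity()` solves the 5×5 system exactly and returns
$k_{\mathrm{7HK}}[E_3]$. Integration is retained as an independent
cross-check: the instantaneous turnover flux after the enzyme transient
(a few times $1/k_{\mathrm{NADPH}} \approx 37$ ms) must match, and does.

**Macro→micro degeneracy.** The macroscopic set fixes only three
combinations of the eight elementary constants. `micro_from_macro()`
resolves the rest with documented free choices: `commitment`
$= k_{-1}/k_{\mathrm{NADPH}} = 4$ (moderately reversible cofactor binding),
`excess` $= k_{\mathrm{7HK}}/k_{\mathrm{NADPH}} = 100$ (chosen so the
closed form's neglected term stays below 1%), an arbitrary dead-end
on-rate `ka = 1` mM⁻¹s⁻¹, and $k_{-2} = k_{\mathrm{7HK}}$ (any positive
value preserves the macro round trip, which is exact by construction and
tested). `excess <= 2` warns, because there the closed form visibly
degrades — that regime is used deliberately in tests to measure the
neglected term.

**Initial-rate window.** `initial_velocity()` and `initial_rate()` fit a
least-squares slope over the window in which conversion of the limiting
substrate stays below 5% (at least 5 points), standard initial-rate
practice. The window cap and the minimum point count are arguments.

# Fitting

`fit_rate_law()` estimates $(k_{bim}, k_{\mathrm{NADPH}},
K_{m,\mathrm{NADPH}}, K_i)$ by Levenberg–Marquardt
(`minpack.lm::nls.lm`) on **log-parameters**, which enforces positivity
and conditions a problem whose parameters span five orders of magnitude.
Total enzyme is fixed at its known value (99 nM in the canonical design),
not estimated — floating it would trade off exactly against
$k_{\mathrm{NADPH}}$.

*Weighting.* Relative (proportional-error) weighting is the default:
velocities across the design span more than an order of magnitude, and the
synthetic noise model is itself proportional, so constant absolute weights
would let the high-velocity cells dominate. Absolute weighting is
available.

*Multi-start.* Eight starts: a marginal-slope heuristic (a
$v \le k_{\mathrm{NADPH}} E_0$ bound for the catalytic constant, the
low-7HK linear regime for $k_{bim}$, the geometric mean of the NADPH
levels for $K_m$, the top of the 7HK range for $K_i$) plus seven
deterministic log-spaced perturbations spanning ±2 decades. The best
converged start wins; per-start objectives are kept in the result.

*Uncertainty.* Standard errors come from the finite-difference Gauss–Newton
curvature at the optimum (delta method back to the natural scale);
`bootstrap_ci()` does case resampling of replicates within each
concentration cell (the design stays fixed), refitting from the original
optimum, deterministic given its seed. `profile_likelihood()` re-optimizes
the remaining parameters along a grid.

**Identifiability of $K_i$.** On the routine design (7HK ≤ 150 µM) the
inhibition term is at most $150\,\mu M / 22\,mM \approx 0.7\%$ of the
denominator — below the 3% noise — so $K_i$ is structurally present but
practically unidentifiable: its profile is monotone-flat above ~10 mM and
the point estimate runs away to the upper boundary, which the fit flags
(`k_i_identifiable = FALSE`). The canonical recovery experiment therefore
uses the **extended design**, appending a 7HK series at 0.5, 2, 8, 24 and
60 mM, where inhibition suppresses the velocity severalfold. This series
is a reconstruction of the high-concentration inhibition observations (the
multi-mM range in which the substrate inhibition was established), not a
tabulated dataset; it is labelled as such in the generator metadata.

# Synthetic data

The generators define the study conditions:

* **Velocity grid** — 8 log-spaced NADPH levels over 5–200 µM × 8
  log-spaced 7HK levels over 5–150 µM, triplicates, 99 nM enzyme; the
  extended variant appends the five multi-mM 7HK levels above. The true
  level placement within the ranges is unknown; log spacing is the
  assumption a kineticist would make for a design spanning above and below
  $K_m$.
* **Noise** — proportional 3% CV plus an additive 0.005 µM/s floor,
  Gaussian, truncated at zero with the truncation count reported. No error
  model is reported for the original assay; these are typical
  plate/cuvette bench magnitudes and are stated here as assumptions, not
  measurements.
* **Absorbance traces** — the mechanism ODE integrated at the standard
  assay condition (160 µM NADPH, 60 µM 7HK), NADPH mapped through
  Beer–Lambert at 365 nm (ε = 3500 M⁻¹cm⁻¹, 1 cm), Gaussian read noise
  (SD 0.002 AU).
* **Ct tables** — per-gene baseline Ct drawn once from U(26, 32), 16S
  reference at Ct ≈ 12, induction shifting Ct down by
  $\log(\mathrm{fold})/\log(\mathrm{efficiency})$, replicate noise
  N(0, 0.3 cycles) on every measurement including the reference. The
  programmed structure: hcd-cluster genes 1000× under 7-hydroxycoumarin
  and 3-(2,4-dihydroxyphenyl)propionic acid, 100× under 7-methylcoumarin;
  xenA38 only 2–3×; xenA45 never detected (all-NA Ct).
* **Activity panel** — replicate velocities at the standard assay
  condition with programmed fold reductions (1, 1.6, 2, 3.4, 17) for
  7-hydroxy-, 6,7-dihydroxy-, 6-hydroxy-, 6-methyl- and unsubstituted
  coumarin.

Every generator is a deterministic function of (configuration, seed) and
restores the caller's RNG state.

What the generators deliberately do **not** emulate: enzyme inactivation or
cell lysis over long incubations, membrane-transport limitation (the
mechanism proposed for why whole cells tolerate substrates that inhibit
the pure enzyme), correlated pipetting errors across a plate row,
instrument drift, and amplification-efficiency differences between genes
(efficiency is fixed at 2.0 and configurable). Passing tests therefore
demonstrate that the analysis recovers truth under the stated statistical
model, not that the model captures every failure mode of real bench data.

# qPCR conventions

Relative amount is $\mathrm{efficiency}^{C_{t,ref} - C_{t,gene}}$ against
the 16S reference in the same condition. Replicates are averaged **on the
Ct scale** and then transformed — geometric-mean semantics on amounts,
which is the natural scale for a quantity that is exponential in the
measured cycle number; the SD of per-replicate amounts is reported as
dispersion. Fold change is the ratio of replicate-mean amounts, condition
over glucose baseline, equivalent to
$\mathrm{efficiency}^{-\Delta\Delta C_t}$ on Ct means. Undetermined Ct is
a missing value that yields amount 0 with `detected = FALSE` — never an
imputed Ct = 40, which would fabricate a finite abundance for a transcript
that was not observed. All amounts are invariant to a global Ct shift
(tested), so plate-wide threshold offsets cancel.

# Masses and stoichiometry

The compound registry carries the seven pathway intermediates plus the
pyridine side product, with molecular formulas. Nominal adduct masses are
sums of the mass numbers of the most abundant isotopes ±1, matching the
integer "Da" values an ESI instrument reports; monoisotopic adducts use an
embedded IUPAC/CODATA isotope-mass table and the proton mass 1.007276 u.
No external mass database is needed for CHNOS(P, Na, K, Cl) formulas.

Conversion yield uses **average** molecular weights, as bench
stoichiometry does: 59 mg of 7-hydroxycoumarin (MW 162.14) converts
theoretically to 66.3 mg of 3-(2,4-dihydroxyphenyl)propionic acid
(MW 182.18), so a 50 mg isolation is 75.4% of theoretical. That is the
number this package computes and asserts; it is stated here as the
package's own stoichiometric result.

# Numerical choices, tie-breaks, degenerate inputs

* Residual evaluation during fitting clamps parameters to
  $[10^{-12}, 10^{12}]$ so that line-search excursions in log space return
  finite residuals instead of raising errors.
* The relative-weighting denominator adds $10^{-6}\max|v|$ to avoid
  division blow-up where the model predicts a near-zero velocity.
* Rank-deficient designs (fewer than two levels of either substrate) are
  rejected before fitting; traces shorter than the initial-rate window
  error out with advice to refine the early grid.
* Zero-substrate or zero-enzyme inputs give exactly zero velocity (not a
  numerical near-zero); `initial_rate` of a constant trace is exactly 0.
* The no-inhibition sentinel `Inf` propagates through the macro↔micro
  round trip (`ka = kd = 0` microscopically) and YAML serialization.

# Problem sizes

The canonical runs are desk-scale by design: 312 velocities
(8 × 13 × 3) for the recovery experiment, a 6 × 6 grid for the oracle
comparison, 200 bootstrap resamples, 50 Monte-Carlo seeds for the
bias/RMSE and qPCR-recovery properties, and trajectories of ≤ 500 time
points. The full test suite runs in well under a minute on one core.

# Known limitations

* The rate law is initial-velocity only; no progress-curve (global)
  fitting, no product inhibition, no reversibility of the oxidative step.
* The 340 nm panel coefficients are composite reaction coefficients
  (substrate + cofactor difference absorbance); the package applies them
  as single-ε conversions exactly as the assay defines them and makes no
  attempt to deconvolve the mixture spectra.
* Pathlength defaults to 1 cm and must be set explicitly for plate-reader
  geometries.
* $K_i$ recovery depends entirely on the reconstructed multi-mM series;
  with only the routine design the package reports non-identifiability
  rather than a number.
* Amplification efficiency is assumed, not calibrated from standard
  curves; per-gene efficiencies can be supplied but default to 2.0.
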