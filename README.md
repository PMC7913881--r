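# hcdkin

Steady-state kinetics and supporting analyses for **HcdE**, the
NADPH-dependent alcohol-dehydrogenase-type ene-reductase that initiates
7-hydroxycoumarin (umbelliferone) degradation in *Pseudomonas mandelii*
7HK4 by reducing the C3–C4 double bond of the lactone ring. The package is
aimed at enzyme kineticists and microbial-physiology groups who want the
quantitative core of that system as tested, reproducible code: the rate
law, its mechanistic oracle, the assay arithmetic, parameter estimation
with identifiability diagnostics, qPCR relative quantification, and the
pathway ion-mass bookkeeping.

## The model

HcdE follows a ping-pong bi-substrate cycle with pseudo-competitive
substrate inhibition: 7-hydroxycoumarin (7HK) at high concentration binds
the enzyme–NADPH charge-transfer complex E1 into a dead-end complex Ei
with dissociation constant K_i. With A = [NADPH], B = [7HK]:

    v = E0 · k_bim · k_NADPH · A · B
        ─────────────────────────────────────────────
        k_NADPH·A + k_bim·B·(Km_NADPH + A + A·B/K_i)

* `k_bim` — bimolecular specificity constant of the oxidative
  half-reaction, k_7HK/Km_7HK (mM⁻¹s⁻¹)
* `k_NADPH` — rate constant of NADPH oxidation, the catalytic constant (s⁻¹)
* `Km_NADPH` — Michaelis constant for NADPH at saturating 7HK (µM)
* `K_i` — dead-end dissociation constant k_d/k_a (mM); `Inf` = no inhibition

An exact clamped-substrate steady-state solution of the full mass-action
mechanism (9 species, 7 elementary steps, solved as a linear system and
cross-checked by stiff ODE integration) serves as the independent oracle:
it equals the closed form up to one neglected denominator term
k_NADPH/k_7HK, below 1% at the default rate-constant hierarchy. The
methods vignette (`vignettes/hcde-kinetics.Rmd`) derives and discusses all
of this.

## Worked example

```r
library(hcdkin)

# the HcdE parameter point, at the 99 nM assay enzyme load
p <- kinetic_params(e_total_nM = 99, k_bim = 1490, k_nadph = 27,
                    km_nadph_uM = 20, k_i_mM = 22)

# velocity at the standard assay condition (160 uM NADPH, 60 uM 7HK)
rate_ping_pong(p, nadph_uM = 160, s7hk_uM = 60)
#> [1] 1.869569

# mechanism oracle at the same condition (mM/s -> uM/s)
micro <- micro_from_macro(p)
from_mM(steady_state_velocity(micro, 0.16, 0.06, p$e_total), "uM")
#> [1] 1.856584

# closed-loop recovery: simulate the kinetic experiment, then fit it
design  <- velocity_design(extended = TRUE)   # 7HK series up to 60 mM
dataset <- generate_velocity_dataset(design, p, seed = 42)
fit     <- fit_rate_law(dataset, e_total_nM = 99)
print(fit)
#> Rate-law fit (relative weighting, objective 0.274613)
#>                      estimate        se
#> k_bim [mM^-1 s^-1] 1486.95368 9.9073240
#> k_NADPH [s^-1]       27.12286 0.1450931
#> Km_NADPH [uM]        20.19033 0.1869200
#> K_i [mM]             21.97051 0.2595600
```

The two velocities differ by 0.7% — the quasi-steady-state error of the
closed form. The fit recovers all four generating parameters within ~1%
from 312 noisy velocities (3% CV); K_i is only identifiable because the
design extends into the multi-mM inhibition range, and on the routine
5–150 µM design the fit flags it as unidentifiable instead.

## Analysis workflow

Numbered drivers under `analysis/` run the pipeline end to end and write
tidy tables under `results/`:

1. `01_simulate.R` — synthetic velocity grids, A365 depletion traces, Ct
   table
2. `02_fit_kinetics.R` — rate-law fit, bootstrap intervals, K_i profile on
   both designs
3. `03_mechanism_oracle.R` — closed form vs mechanism steady state over
   the assay grid, integrated time course
4. `04_expression_qpcr.R` — relative RNA amounts and fold changes vs the
   glucose baseline (16S reference)
5. `05_pathway_ions.R` — registry adduct m/z, observed-ion assignment,
   conversion-yield stoichiometry

`reproduce(seed, out_dir)` runs the same stages from R and writes a single
JSON report.

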