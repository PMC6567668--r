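# soyco2

Analysis chain for growth-chamber studies of C3 photosynthetic
**down-regulation under elevated CO₂**, with soybean defaults spanning the
400–1600 ppm range. The package is written for plant ecophysiologists who
measure A–Cᵢ gas-exchange curves, stomatal impressions and tissue chemistry
across CO₂ treatments and want the whole chain — curve fitting, spatial
statistics, dose–response optima, treatment tables — reproducible in R.

## What it computes

**FvCB curve fitting.** Net assimilation follows the
Farquhar–von Caemmerer–Berry model with infinite mesophyll conductance
(C_c = C_i): A is the minimum of the Rubisco-limited and
RuBP-regeneration-limited rates,

    A_c = Vcmax (Ci − Γ*) / (Ci + Kc (1 + O/Ko)) − Rd
    A_j = J    (Ci − Γ*) / (4 Ci + 8 Γ*)        − Rd

with 25 °C kinetic constants Γ* = 42.75 μbar, Kc = 404.9 μbar,
Ko = 278.4 mbar, O = 210 mbar. `fit_aci()` enumerates every admissible
transition between the two limbs (≥ 3 points each side) and solves each
partition by exact least squares — the model is linear in (Vcmax, J, Rd)
once the partition is fixed — keeping the partition with minimal SSE. At
saturating light the fitted J is reported as Jmax; `jmax_from_j()` offers
the non-rectangular-hyperbola correction when light was not saturating.

**Stomatal morphometrics.** Density (mm⁻²), shape index
SSI = 100·√SA/SP (≤ 100/(2√π) ≈ 28.21 %, the circular maximum), area index
SAI = density × mean stomatal area (unit-converted, with an explicit
`scale` hook for table conventions that fold in extra normalisation), and
signed percent changes with half-away-from-zero rounding.

**Stomatal spatial pattern.** Ripley's K̂ with translation edge correction,
the L-transform L̂(d) − d = √(K̂/π) − d (negative ⇒ regular, positive ⇒
clustered), pointwise Monte Carlo CSR envelopes conditional on the observed
count (100 replicates, 95 % by default), per-scale classification, and
point-process simulators (binomial CSR, sequential-inhibition hard-core,
Thomas cluster) for nulls and controls.

**Dose–response and ANOVA.** Quadratic fits with vertex optimum
x_opt = −c₁/(2c₂) (extrapolated vertices flagged), linear fits, one-way and
balanced two-way fixed-effects ANOVA.

**Tissue chemistry.** C/N, TNC = soluble sugar + starch, and
mean ± SD treatment tables per tissue.

**Synthetic studies.** `generate_study()` builds a complete seeded study
with the 7-treatment × 5-pot design — per-pot A–Cᵢ curves over the 12-step
cuvette ladder (50…1600 ppm), hard-core stomatal fields in 0.16 mm²
windows, per-stoma morphology, anatomy and chemistry drawn around built-in
soybean trait profiles — together with the generating truth, so parameter
recovery is testable end to end.

## Worked example

```r
library(soyco2)

# fit a noisy A-Ci curve generated from known truth
p     <- fvcb_params(vcmax = 100, j = 150, rd = 1.5)
curve <- generate_aci_curve(p, noise_sd = 0.5, seed = 42, growth_co2 = 400)
fit_aci(curve)
#> FvCB fit (12 points): Vcmax = 98.12, Jmax = 150.73, Rd = 1.15
#>   transition Ci = 350.0 ubar, SSE = 2.091, R2 = 0.9987

# classify the spatial pattern of a regular (hard-core) stomatal field
pat <- simulate_hardcore(40, ppwindow(400, 400), r_min = 30, seed = 1)
ripley_analysis(pat, seed = 2)
#> Ripley analysis: n = 40, 101 distances up to 200 um
#>   scales: 12 regular, 89 random, 0 clustered
#>   longest regular run: 16-38 um

# full synthetic study -> report
study  <- generate_study(study_config(seed = 1))
report <- run_pipeline(study, seed = 1)
report$dose_response$vcmax
#> Quadratic fit (n = 35): y = 93.96 + 0.05794 x + -4.939e-05 x^2, R2 = 0.919
#>   vertex (maximum): x_opt = 586.5
```

The fitted Vcmax/Jmax/Rd sit within a few percent of the generating truth
(100/150/1.5) despite 0.5 μmol m⁻² s⁻¹ noise; the hard-core field is
declared regular only at scales near its 30 μm inhibition radius; and the
recovered Vcmax dose–response places an interior maximum near the 600 ppm
peak built into the generator's profile.

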