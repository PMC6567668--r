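---
title: "Models and methods behind soyco2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind soyco2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soyco2)
```

soyco2 implements the analysis chain of a growth-chamber CO₂
dose–response study on a C3 crop: biochemical curve fitting, stomatal
morphometrics and spatial statistics, dose–response optima, and tissue
chemistry summaries, all drivable from a seeded synthetic-study generator.
This vignette records the models, the tunable parameters, the numerical
choices, and what the synthetic data can and cannot tell you.

## The FvCB model and its estimation

Net assimilation is modelled as the minimum of two limitation limbs
(Farquhar–von Caemmerer–Berry), with mesophyll conductance taken as
infinite so that the chloroplastic CO₂ equals the intercellular Cᵢ:

$$A_c = \frac{V_{cmax}\,(C_i - \Gamma^*)}{C_i + K_c(1 + O/K_o)} - R_d,
\qquad
A_j = \frac{J\,(C_i - \Gamma^*)}{4C_i + 8\Gamma^*} - R_d,
\qquad A = \min(A_c, A_j).$$

Assumptions worth stating:

* **Cᵢ in μmol mol⁻¹ is treated as μbar** (≈ 1 atm chamber pressure); a
  conversion is a one-line rescale if barometric data exist.
* **Kinetics are fixed 25 °C defaults** (Γ\* = 42.75 μbar, K_c = 404.9 μbar,
  K_o = 278.4 mbar, O = 210 mbar), configurable per fit. No Arrhenius
  temperature scaling: the measurements this package targets are made at
  25 °C leaf temperature.
* **No TPU limb.** Triose-phosphate limitation, when present at high Cᵢ,
  will be absorbed into the RuBP limb and slightly bias J downward.
* **J is reported as Jmax** because curves are taken at saturating light
  (1500 μmol m⁻² s⁻¹ PPFD); `jmax_from_j()` (θ = 0.9, α = 0.3 defaults)
  inverts the non-rectangular hyperbola for sub-saturating light and is
  deliberately opt-in.

### Fitting by exhaustive partition least squares

`fit_aci()` must decide which points belong to which limb. Rather than
free-knot nonlinear optimisation, it enumerates every transition between
consecutive observed Cᵢ with at least 3 points per limb. *Conditional on a
partition the model is linear in (V_{cmax}, J, R_d)*:

$$A_i = V_{cmax}\,x_{c,i}\,[i \in \text{rubisco}] + J\,x_{j,i}\,[i \in \text{rubp}] - R_d,$$

so each candidate is solved by exact QR least squares — no starting values,
no convergence tolerance, no seed sensitivity — and the minimal-SSE
partition wins, ties breaking toward the lower transition Cᵢ. This is the
same objective a multi-start optimiser would minimise, solved exactly; it
is why noiseless curves round-trip to machine precision and why two runs
can never disagree.

R_d handling: fitted jointly by default, constrained to [0, 10]
μmol m⁻² s⁻¹ by active-set boundary refits, or fixed to a separately
measured dark respiration (`rd = "measured"`). Both policies exist because
measured R_d and fitted R_d are both defensible and the choice genuinely
affects V_{cmax} by a few percent at low Cᵢ coverage; the default keeps
the fit self-contained.

## Stomatal morphometrics

Shape index SSI = 100·√SA/SP is bounded above by 100/(2√π) ≈ 28.21 %
(isoperimetric inequality; equality for circles). Tables can aggregate SSI
as mean-of-per-stoma-ratios or ratio-of-means; both are reported, the
per-stoma mean is the default (printed tables match it more closely), and
the two differ by under 10 % for realistic size dispersion (CV ≤ 0.3).

Area index SAI = density × mean stomatal area is implemented literally
with the μm²→mm² conversion, giving values of order 0.1–1.5 % for soybean
densities. Published tables sometimes print SAI tens of times larger
(an unstated per-field normalisation); the `scale` argument reproduces
such conventions *explicitly* — the package never silently rescales, it
surfaces the discrepancy. Percent changes round half away from zero so a
+36.5 % contrast prints as +37.

## Ripley's K, envelopes and classification

For a pattern of n points in window W,

$$\hat K(d) = \frac{|W|}{n(n-1)} \sum_{i \ne j} w_{ij}\,\mathbf 1(d_{ij} \le d),$$

with translation edge-correction weights
\(w_{ij} = |W| / [(w-|\Delta x|)(h-|\Delta y|)]\) (an uncorrected variant is
retained for oracle tests). The L-transform \( \hat L(d) - d = \sqrt{\hat K/\pi} - d \)
is zero in expectation under CSR; negative values indicate regularity.

Numerical conventions, each of which someone will eventually ask about:

* **Distance grid** 0–200 μm in 2 μm steps; distances beyond half the
  shorter window side are truncated (translation-correction validity).
* **Window default 400 × 400 μm** (= 0.16 mm², the standard microscope
  field), configurable per field.
* **Envelopes are pointwise**, conditional on the observed n (binomial
  CSR, not Poisson), from 100 seeded replicates at α = 0.05.
* **Envelope quantiles use type-6 (Weibull) plotting positions.** With
  100 replicates the default type-7 estimator pulls the 2.5/97.5 %
  quantiles inward, so a fresh CSR pattern would exceed the band ~7 % of
  the time; type 6 restores ~5 % two-sided exceedance. The suite measures
  this rate empirically over 200 seeded trials.
* **Duplicate coordinates are jittered** by ≤ 0.01 μm with a warning
  (digitised stomata can repeat; K is undefined at zero distances).
* Pointwise envelopes understate *global* type-I error across the whole
  grid; simultaneous (rank) envelopes are out of scope, so per-scale
  labels should be read scale-by-scale, not as one joint test.

Classification labels each scale regular/random/clustered by envelope
position and reports the longest contiguous regular run, the quantity that
summarises short-range stomatal inhibition. Hard-core (sequential
inhibition) and Thomas cluster simulators provide positive and negative
controls; hard-core patterns with r_min = 30 μm are detected as regular at
scales ≤ r_min in ≥ 90 % of seeded runs.

## Dose–response and ANOVA

Quadratic fits are plain OLS; the optimum is the vertex −c₁/(2c₂),
labelled maximum/minimum by the sign of c₂ and **flagged (not dropped)**
when it falls outside the observed dose range extended by half its width —
an extrapolated vertex is a modelling smell, not an error. One-way and
balanced two-way fixed-effects ANOVA delegate to `stats::aov()`; only
balanced complete designs are accepted for the two-way analysis, which is
what a chamber design produces and what keeps sums-of-squares types out of
the user's way. p-values are per-trait with no multiplicity correction,
matching the field's reporting convention at p < 0.05.

## The synthetic-study generator

`generate_study()` emulates the full design: 7 CO₂ treatments
(400–1600 ppm) × 5 pots, a 12-step cuvette ladder (50, 100, 150, 200, 300,
400, 600, 800, 1000, 1200, 1400, 1600 ppm), two leaf surfaces, 0.16 mm²
stomatal fields, three tissues. Its anchors:

* **FvCB truth follows quadratic profiles**: V_{cmax} peaking at 600 ppm
  (110 μmol m⁻² s⁻¹ vertex, curvature 5×10⁻⁵), J_{max} declining from
  400 ppm (180 vertex), R_d gently peaking at 900 ppm — so the recovered
  dose–response must show an interior V_{cmax} optimum between 400 and
  800 ppm. Between-pot variation is a 5 % CV multiplier.
* **Assimilation noise is Gaussian, sd 0.5 μmol m⁻² s⁻¹** — typical
  IRGA-scale scatter; at that level the fitted V_{cmax} median relative
  error stays below 5 %.
* **Stomatal fields**: counts are Poisson draws at the per-treatment
  density means of the built-in trait tables × window area; coordinates
  come from hard-core inhibition (30 μm adaxial, 20 μm abaxial) so that
  small-scale regularity is really present; infeasible packings fall back
  to CSR with a warning.
* **Morphology**: per-stoma areas are lognormal at the table mean/SD;
  SSI is drawn truncated-normal and the perimeter derived as
  100·√area/SSI, which keeps every synthetic stoma isoperimetrically
  valid by construction.
* **Anatomy and chemistry**: Gaussian draws at the table means/SDs,
  floored at small positive values. Two table SDs that print with an
  obviously displaced decimal point (an order of magnitude above every
  neighbouring cell, exceeding their own means) are carried at the
  plausible corrected magnitude, since a generator SD larger than the mean
  would produce negative cell dimensions.
* **Determinism**: every stage derives an independent substream from the
  single config seed; same seed ⇒ byte-identical study and report.
* **Problem sizes**: the default is 3 microscope fields per surface per
  pot and the pipeline classifies up to 2 fields per treatment × surface
  cell; a physical study would image ~30 fields. These defaults keep a
  full simulate → report cycle around a couple of seconds and are plain
  arguments (`fields_per_surface`, `max_ripley_fields`) when the full
  design is wanted.

What passing tests on this generator do **not** show about real data: the
generator draws independent Gaussians around fixed treatment means, so it
has no within-pot correlation structure, no chamber effects, no
heteroscedasticity across the CO₂ ladder, no digitisation error in
stomatal coordinates, and its stomatal regularity is exactly hard-core
rather than the softer inhibition of real epidermal development. Recovery
results here demonstrate the estimators are correct and calibrated, not
that any particular field dataset satisfies their assumptions.

## Known limitations

* No TPU limitation, temperature response, or mesophyll-conductance
  fitting in the FvCB stage; no stomatal-limitation partitioning.
* Ripley analysis is homogeneous-K only: no inhomogeneous K, no pair
  correlation g(r), no simultaneous envelopes.
* Two-way ANOVA requires balance; unbalanced field data must be
  aggregated first.
* The SAI convention mismatch described above means cross-study SAI
  comparisons need the `scale` factor pinned down explicitly.
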