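---
title: "Models and methods in gcflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gcflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcflux)
```

gcflux implements the quantitative backbone of studies of the
neutrophil-elastase / alpha-1-antitrypsin / corticosteroid-binding-globulin
(NE/AAT/CBG) axis: how protease cleavage of a carrier protein shifts the
plasma partitioning of glucocorticoids, and how steady-state stable-isotope
tracer dilution measures the downstream consequences in vivo. This vignette
describes the models, their assumptions, the defaults and why they were
chosen, and what the synthetic-data generators do and do not emulate.

## 1. Equilibrium partitioning of plasma glucocorticoid

Plasma cortisol distributes among a high-affinity, saturable carrier (CBG),
a low-affinity, effectively nonsaturable albumin pool, and a small free
fraction — in healthy humans CBG carries more than 85% of total cortisol
and only about 5–10% is free. With free concentration $F$, saturable sites
$i$ with capacity $B_{max,i}$ and dissociation constant $K_{d,i}$, and
nonsaturable bound:free ratios $n_j$, conservation of total steroid $T$
gives the scalar balance

$$F\Big(1 + \sum_j n_j\Big) + \sum_i \frac{B_{max,i}\,F}{K_{d,i}+F} = T .$$

The left-hand side is strictly increasing in $F$, zero at $F=0$ minus $T$,
and at least $T$ at $F=T$, so the root is unique and bracketed on
$[0, T]$. `solve_free()` finds it by bisection to $10^{-12}$ absolute
tolerance (200-iteration cap — far more than the ~48 halvings the
tolerance requires, so hitting the cap is reported as an error rather than
silently returned). The residual is then folded back into the free pool so
that free plus bound reproduces the total to machine precision. Tests
verify the solver against two independent oracles: an exhaustive
$10^6$-point grid search on $[0,T]$ and `stats::uniroot()` at
$10^{-14}$ tolerance.

**Reference parameter set.** The studies this package supports report CBG
binding capacity (a control-group mean of 336.8 nmol/L) but not the Kd of
CBG, the albumin partition ratio, or the in-assay total cortisol. The
package pins a reference set — CBG $B_{max}$ 336.8 nmol/L, $K_d$
10 nmol/L, albumin $n$ = 1.74, total cortisol 200 nmol/L
(`reference_serum()`) — chosen so the solved partition lands inside the
physiological bounds (85.8% CBG-bound, 5.19% free). These are package
constants, not measured claims; every one is overridable.

**Cleavage.** NE cleaves the reactive centre loop of CBG, lowering its
steroid affinity. `apply_cleavage()` moves a fraction of the intact
capacity to a `CBG_cleaved` site whose Kd is `affinity_ratio` times the
intact value (default 10; the literature agrees the affinity falls but
does not pin the factor). Total capacity is conserved; the free fraction
is non-decreasing in both the cleaved fraction and the affinity ratio.
Fully cleaving the reference set raises free cortisol from 10.4 to
38.7 nmol/L (5.2% to 19.3%), a 3.7-fold rise.

**Reporter.** Free steroid maps to a transcriptional reporter signal
through a sigmoid-Emax (Hill) curve, `reporter_response()` — the standard
minimal monotone pharmacodynamic link. Its parameters (basal 1, Emax 4,
EC50 10 nmol/L, Hill 1 in the generator) are arbitrary-unit choices that
only need to preserve ordering, which is all the in-vitro readout asserts.

**Non-goals.** Temperature dependence of affinities, multi-steroid
competition, cooperative binding, and CBG synthesis/clearance dynamics are
out of scope; the model is a single-steroid snapshot at equilibrium.

## 2. Protease and serpin model

NE dose is kept in the supplier's activity units ("U"), bridged to molarity
by a single configurable constant (`units_to_umolar`, default 1 µM per U).
AAT inhibition is modelled stoichiometrically — serpins inhibit
essentially irreversibly with ~1:1 stoichiometry — so the surviving
activity is $\max(0, (E - \mathrm{SI}\cdot[\mathrm{AAT}])/E)$. At the
defaults, 100 µM AAT is a large excess over a 4 U (4 µM) dose and fully
restores vehicle behaviour, while the dose at half the stoichiometric
point leaves exactly half the activity. Endpoint inhibition is what the
in-vitro design measures; a kinetic association model would add a rate
constant the data cannot constrain.

Cleavage of CBG by the surviving activity is pseudo-first-order:
$1-\exp(-k\,E_{act}\,t)$. The rate constant defaults to $\ln 10/40$ per
U·min so that the headline 4 U, 10-minute exposure cleaves 90% of intact
CBG — a deliberate package calibration making that condition nearly
saturating, consistent with the large observed capacity loss, while
keeping lower doses on the rising part of the curve.

`treat_serum()` composes the steps in protocol order: AAT pre-incubation
commits first (sequential, not competitive — the protocol pre-incubates
enzyme and inhibitor before serum exposure), then cleavage, then the
equilibrium re-solve. Vehicle is the bitwise identity.

`binding_capacity_of()` reports what a ligand-saturation assay sees:
capacity of sites whose Kd is below a high-affinity cutoff (default twice
the intact Kd), so cleaved CBG no longer counts. This convention makes
"capacity" a model quantity directly comparable to the assay readout.

## 3. Steady-state tracer dilution

A primed (0.92 µmol), constant-rate (17.2 nmol/min) D4-cortisol infusion
with arterialised and venous sampling every 30 min from 60 to 270 min.
All estimators operate on the closed 180–270 min steady window:

* **Steadiness** — the percent CV (n−1 SD over mean, ≥3 samples) of the
  per-timepoint D4:cortisol and D4:D3 ratios must both be ≤ 5%.
* **Clearance** — $CL = F / \bar C_{D4}$ (L/min).
* **Rates of appearance** — $Ra = CL \cdot \bar C_x$; for cortisol this
  is tracer dilution by endogenous production, for D3-cortisol a specific
  measure of regeneration by 11β-HSD1. The identity
  $Ra_{cort}\cdot C_{D4} = F\cdot C_{cort}$ holds to machine precision
  and rests on the standard assumption that tracer and tracee share
  clearance.
* **Net balance** — venous minus arterial concentration per analyte
  (positive = release into the vein), reported as a concentration
  difference, not a flux, because plasma flow is not measured in this
  design. The free-cortisol balance uses the per-site free fractions and
  is absent (never zero) when a free fraction is missing.

Subjects failing steadiness are flagged, retained in outputs, and excluded
from rate estimates and group summaries. The priming dose affects only the
simulated approach to plateau, never the estimators. Non-steady-state
(compartmental) estimation and tracer-purity corrections to the D4/D3
channels are out of scope.

## 4. Assay reductions

* Ultrafiltration free fraction: `100 × cpm(filtrate)/cpm(retentate)`,
  optional background subtraction of both (off by default — the protocol
  does not state it), clipped at 100% with a warning.
* Equilibrium dialysis: `100 × dialysate/serum`.
* Saturation assay: specific cpm → fmol via specific activity → nmol/L in
  assay → × dilution (default 1:500) for undiluted serum. Occupancy
  correction (divide by $L/(K_d+L)$ at the 2 nmol/L tracer) is off by
  default: the assay is defined as a capacity measurement at its stated
  tracer concentration.
* Relative expression by the efficiency-corrected ratio method:
  $E_t^{\Delta Ct_t}$ over the geometric mean of the reference-gene terms,
  with per-sample Ct the mean of a triplicate that must have SD < 0.5
  cycles and calibrated efficiencies in (1, 2.2]. The "mean of two
  housekeeping genes" is aggregated geometrically — the standard choice
  for multiplicative Ct quantities; an arithmetic mean of ratios would
  break the exact inversion property the tests assert.

## 5. Metabolic phenotyping

HOMA-IR is `insulin(mU/L) × glucose(mM) / 22.5`. Some sources print the
insulin unit as "mg/dL", which is not a usable insulin unit; the package
standardises on mU/L with the conventional 6.945 pmol/L-per-mU/L
conversion and requires an explicit unit tag. The group index is the mean
of per-subject indices, not the index of group means. GTT AUC is absolute
trapezoidal area (no baseline subtraction — the protocols do not state
one). kITT is the negated log-linear slope ×100 on a configurable window
defaulting to 0–30 min (windows are rarely reported; 0–30 min is the
conventional linear range); exact exponential decay is recovered for any
window, and rising glucose yields a flagged negative value rather than an
error.

## 6. Synthetic cohorts and what they do (not) show

All generators are seeded and regenerate bit-identically; every dataset is
accompanied by its ground truth (pre-noise values, per-subject rates,
effect multipliers). Noise is multiplicative lognormal with unit mean —
concentrations are positive and assay errors scale with level — at 3% CV
for plasma assays and 8% for tissue corticosterone.

**Serum panel** (`gen_serum_panel()`): vehicle / NE 4 U / NE+AAT 100 µM
arms, n = 4 replicates, for mouse and human serum, with 5% between-replicate
CBG variability. Human CBG is drawn around 336.8 nmol/L; mouse constants
(CBG 500 nmol/L, Kd 25 nmol/L, corticosterone 150 nmol/L) are plausible
rodent values chosen once.

**Tracer study** (`gen_tracer_study()`): n = 16/group. Arterial D4 follows
the one-compartment approach to plateau $F/CL$ (prime bolus $prime/V_d$
decaying at $CL/V_d$; $CL$ lognormal around 1.1 L/min, 12% between-subject
CV; $V_d$ 35 L), with concentrations placed exactly on their steady values
from 180 min so the window is flat by construction. Endogenous cortisol
declines from 400 toward 250 nmol/L with a 45-min time constant.
D3-cortisol is a group-dependent fraction of D4 (0.30 control, ×0.75 in
the AAT-deficient group); free fraction 5% (×1.3 in the deficient group,
×1.05 venous); muscle release terms +5/+12 nmol/L cortisol, +0.2/+0.6 D4,
+0.05/+0.15 D3 for control/deficient. The 3% measurement CV is split into
a shared per-draw component (75% of variance) and an analyte-specific
remainder: isotopologue channels are quantified in the same injection, so
their errors are strongly correlated — which is precisely why tracer
*ratios* are the steadiness currency. With fully independent errors the
ratio CV would sit so close to the 5% criterion that a realistic cohort
could not reliably pass it, contradicting routine experience with this
design. Group magnitudes encode effect *directions* only.

**Mouse cohort** (`gen_mouse_cohort()`): genotype × sex × surgery arms,
n = 7 per arm, weekly weights over 10 weeks, GTT/ITT curves, insulin,
depot corticosterone and serum NE/AAT. Effect multipliers default to 0.6
(knockout male weight gain) and 0.7 (knockout male gWAT corticosterone),
with no genotype effect in females or after adrenalectomy.

Passing recovery tests on these cohorts shows the estimators are correct
under the stated noise model; it does not validate the model against real
plasma (no diurnal rhythm beyond the single cortisol drift, no LC-MS/MS
batch structure, no dropout or cannulation failure, no between-subject
variance structure beyond lognormal scatter).

## 7. Numerical choices and problem sizes

Bisection tolerance $10^{-12}$ absolute; grid oracle $10^6$ points;
equality of vehicle and fully-inhibited treatments is asserted bitwise;
steadiness CVs use the n−1 SD; window endpoints are inclusive. The test
suite exercises 1,000 random compositions for mass conservation, 250
random dose pairs for treatment monotonicity, and 20 seeds × 16 subjects
for clearance recovery (group means within 2% of truth); these sizes give
stable verdicts in well under a minute each while keeping the full suite
fast.

## 8. The pipeline

`run_pipeline()` executes simulate → equilibrium → tracer → assay →
phenotype as selected by a single YAML/JSON config whose `constants` block
holds every pinned default in one visible, overridable place (CBG Kd 10,
albumin ratio 1.74, affinity ratio 10, k_cleave ln10/40, SI 1, CV
threshold 5, window [180, 270], insulin conversion 6.945). Each run writes
a manifest (seed, constants, per-file checksums); identical config and
seed give byte-identical outputs, and partial outputs are removed on
failure. A thin command-line wrapper ships in `inst/scripts/gcflux.R`.
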