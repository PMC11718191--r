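# gcflux

Quantitative tools for the neutrophil elastase / alpha-1-antitrypsin /
corticosteroid-binding-globulin (NE/AAT/CBG) axis: how protease cleavage
of the main plasma glucocorticoid carrier raises the biologically active
free fraction, and how steady-state deuterated-cortisol tracer dilution
measures glucocorticoid turnover and tissue release in vivo.

It is written for endocrinologists and physiologists who work with
protein-bound hormones, tracer infusion studies, and routine metabolic
phenotyping, and who need the underlying arithmetic as tested, reusable
functions rather than spreadsheet formulas.

## What it computes

**Equilibrium partitioning.** With free concentration *F*, saturable
carriers *i* (capacity *B*<sub>max,i</sub>, dissociation constant
*K*<sub>d,i</sub>) and nonsaturable bound:free ratios *n*<sub>j</sub>,
total steroid *T* satisfies

    F (1 + Σ n_j) + Σ B_max,i F / (K_d,i + F) = T

`solve_free()` finds the unique root by bracketed bisection (the balance
is strictly increasing in *F*). `apply_cleavage()` moves CBG capacity to
a low-affinity cleaved form; `treat_serum()` composes stoichiometric
serpin inhibition of NE, pseudo-first-order CBG cleavage, and the
equilibrium re-solve.

**Tracer kinetics.** For a primed constant infusion at rate *F* with
steady arterial tracer concentration *C*<sub>D4</sub>:
clearance *CL* = *F*/*C*<sub>D4</sub>; rate of appearance
*Ra* = *CL* · *C* (cortisol: total production; D3-cortisol: regeneration
by 11β-HSD1); steadiness requires CV ≤ 5% of the D4:cortisol and D4:D3
ratios over the 180–270 min window; arterio-venous net balance is
venous − arterial concentration (positive = release).

**Assay reduction and phenotyping.** Ultrafiltration/dialysis free
fractions, radioligand saturation binding capacity, efficiency-corrected
relative qPCR expression (Pfaffl) with triplicate QC, HOMA-IR, GTT AUC,
kITT, and unit conversions.

**Synthetic cohorts.** Seeded generators (`gen_serum_panel()`,
`gen_tracer_study()`, `gen_mouse_cohort()`) emit every input the pipeline
consumes together with its ground truth, so all estimators are testable
end-to-end without any external data.

## Worked example

```r
library(gcflux)

# Reference human serum: CBG 336.8 nM (Kd 10 nM), albumin ratio 1.74,
# total cortisol 200 nM
solve_free(reference_serum())
#> Glucocorticoid partition of 200 nmol/L total
#>   free : 10.38 nmol/L (5.19%)
#>   CBG_intact   171.6 nmol/L (85.8%)
#>   albumin      18.06 nmol/L (9.03%)
```

CBG carries 85.8% of total cortisol and 5.19% is free — inside the
physiological bounds (>85% CBG-bound, 5–10% free). Treating the same
serum with 4 U of neutrophil elastase for 10 minutes cleaves 90% of the
CBG and more than triples the free fraction:

```r
ne <- treat_serum(reference_serum(), protease_treatment(ne_units = 4))
#> NE 4 U: 90.0% cleaved, free fraction 17.43%
```

Adding 100 µM AAT to the enzyme before serum exposure restores the
vehicle partition exactly. The simulated two-group tracer study is
analysed the same way a real one would be:

```r
sim <- gen_tracer_study(seed = 1)          # 16 controls, 16 AAT-deficient
analyze_study(sim$samples)
#> Steady-state tracer study: 32 subjects (32 steady), status 'ok'
#> Group means (steady subjects):
#>    group n_steady clearance_L_min ra_cortisol_nmol_min ra_d3_nmol_min
#>  AAT_def       16           1.097                272.8          3.885
#>  control       16           1.102                275.8          5.166
```

All subjects meet the 5% CV steadiness criterion; clearance is matched
between groups while D3-cortisol production (11β-HSD1 regeneration) is
lower in the AAT-deficient group — the effect structure the generator
encodes. Ground truth lives in `sim$truth` for recovery checks.

The full pipeline (simulate → equilibrium → tracer → assay → phenotype)
runs from one config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "gcflux"))
```

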