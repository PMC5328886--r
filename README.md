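# abdopv

Modelling of abdominal and airway pressure–volume (P-V) curves from
stepwise intra-abdominal inflation experiments, for researchers in
respiratory and abdominal mechanics and for intensive-care physiologists
studying intra-abdominal hypertension (IAH).

Rising intra-abdominal volume (IAV) raises intra-abdominal pressure (IAP)
and, through the diaphragm, peak airway pressure (pPAW). `abdopv` fits two
candidate equations to measured (pressure, volume) points:

- the **Venegas sigmoid** `V = a + b / (1 + exp(-(P - c)/d))` (4
  parameters, asymptotes at both ends), and
- the **exponential elastic-recoil** model `V = v + k·ln(P - p)` (3
  parameters, single-ended), with closed-form inverse
  `P = p + exp((V - v)/k)` and analytic compliance `dV/dP = k/(P - p)`,

selects the better description by root-mean-square volume error, corrects
injected gas volumes for compression (Boyle: `V × 1033/(1033 + IAP)`),
estimates abdomino-thoracic transmission by pooled regression of ΔpPAW on
ΔIAP, and tabulates the predicted effect of adding 500 mL at each WSACS
grade of IAH. A synthetic porcine cohort generator (7 virtual pigs, 1-L
air steps, inflation stopped above an IAP of 40.8 cmH₂O) makes every
stage testable without animal data.

## Worked example

```r
library(abdopv)

cohort <- simulate_cohort(cohort_config(seed = 42))
report <- pv_report(cohort, seed = 42)
report
```

```
Pressure-volume pipeline report
  7 animals, 28 fitted curves (models: both)
  IAP-curve winners by RMS:  exponential = 4, venegas = 3 
  mean IAP curve: v=1.381 k=2.590 p=3.647
Abdomino-thoracic transmission (pooled OLS, n = 78)
  delta pPAW = -0.18 + 0.42 x delta IAP,  R^2 = 0.98, p = <2e-16
Predicted effect of an additional 500 mL intra-abdominal volume
    grade   given IAP pPAW IAV (L) IAV+d (L)   IAP after        dIAP
 baseline   5.0 (3.7) 19.9     0.0       0.5   4.4 (3.2) -0.7 (-0.5)
        I 16.3 (12.0) 26.5     8.0       8.5 19.0 (14.0)   2.7 (2.0)
       II 21.8 (16.0) 28.7     8.9       9.4 25.6 (18.8)   3.9 (2.8)
      III 28.5 (21.0) 31.2     9.7      10.2 33.9 (24.9)   5.3 (3.9)
       IV 35.3 (26.0) 33.5    10.3      10.8 42.1 (31.0)   6.8 (5.0)
 CAB mL/mmHg dpPAW
           -   0.1
         252   1.1
         176   1.4
         128   1.8
         101   2.1
```

Reading the output: each virtual animal's IAP and pPAW curves were fitted
with both equations; the exponential model wins on most (here 4 of 7) IAP
curves by RMS. The pooled regression recovers the generating transmission
slope (0.43; here 0.42): roughly 40% of an IAP rise reaches the airway.
The grade table evaluates the cohort's mean fitted curves: adding 500 mL
at baseline changes pressures by ~0 cmH₂O, while the same 500 mL at grade
IV (35.3 cmH₂O / 26 mmHg) raises IAP by ~7 cmH₂O and pPAW by ~2 cmH₂O,
with abdominal compliance (CAB) falling monotonically across grades — the
convexity of the exponential P-V relationship. The pressure columns show
cmH₂O with mmHg in parentheses (1 mmHg = 1.3595 cmH₂O).

Individual pieces are available directly: `pv_fit()` (with `coef`,
`predict`, `plot`, `residuals` methods), `compare_pv_fits()`,
`boyle_correct_step()`, `transmission_regression()`, `grade_table()`,
`derive_default_iap_params()` (the anchor-derived default IAP curve),
`read_cohort()`/`write_cohort()` for the CSV schema, and a thin command
line at `inst/cli/abdopv` (`simulate`, `fit`, `transmission`,
`grade-table`, `report`).

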