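# sultpbpk

Pediatric physiologically based pharmacokinetic (PBPK) modelling of
intravenous acetaminophen (APAP), built around the age-dependent ontogeny
of the hepatic sulfotransferases (SULT1A1, SULT1A3, SULT2A1, SULT1E1) that
dominate APAP conjugation in early life.

The package is aimed at pharmacometricians and DMPK scientists who want an
open, fully tested counterpart to simulator-based pediatric APAP analyses:
every stage — ontogeny regression, in vitro–in vivo extrapolation (IVIVE),
population simulation, exposure verification, drug–drug-interaction (DDI)
sensitivity — is an exported, unit-tested R function.

## What it implements

**Ontogeny.** SULT abundance (pmol/mg cytosolic protein) versus postnatal
age *a* is modelled by three-phase piecewise functions, e.g. for SULT1A1

```
abundance(a) = 107.8 + 88.6 a            a < 1.83 y
             = 370.1 + 6.99 (a − 1.83)   1.83 ≤ a ≤ 12.6 y
             = 445.2                     a > 12.6 y
```

with relative activity `abundance(a) / abundance(20 y)` as the multiplier
on adult in-vitro Vmax.  `fit_ontogeny()` provides the regression
machinery used to derive such models (five candidate forms, profiled
breakpoints, multi-start least squares, AIC selection).

**IVIVE.** Thirteen Michaelis–Menten pathways (3 UGT, 4 SULT, 6 CYP) are
scaled to whole-liver intrinsic clearance via protein-per-gram-liver,
liver weight and an active hepatic scalar, combined with the well-stirred
model `CLh = Qh·fu·CLint/(Qh + fu·CLint)` and GFR-scaled renal clearance.
A single global calibration factor anchors the adult linear-range
prediction to the reference IV clearance (19.7 L/h).

**Simulation.** A minimal PBPK model (one compartment, `V = 0.8 L/kg ×
BW`, concentration-dependent clearance) is integrated with `deSolve` for
repeated IV infusion regimens in virtual cohorts, with non-compartmental
analysis (`nca()`) and fold-error verification (0.5–2.0 band) against
published clinical exposure values, plus Km/Vmax perturbation sweeps
(`run_sweep()`) emulating competitive inhibition, mechanism-based
inhibition and induction.

## Worked example

```r
library(sultpbpk)

lib <- builtin_ontogeny_library()
evaluate_abundance(lib$SULT1A1, 0)        # 107.8 pmol/mg at birth
100 * relative_activity(lib$SULT1A1, 0)   # 24% of the adult level

model <- apap_model()
run_fm_report(c(7/365.25, 1, 7), model = model)  # pathway fractions
```

The pathway-contribution report (family totals, percent of total systemic
clearance) shows sulfation dominating neonatal clearance and
glucuronidation overtaking it during childhood:

```
   age    pathway   fm
 0.019 SULT_total 66.0
 0.019  UGT_total 26.1
 0.019  CYP_total  3.5
 0.019      renal  4.4
 1.000 SULT_total 42.8
 1.000  UGT_total 42.6
 7.000 SULT_total 36.9
 7.000  UGT_total 49.2
```

A full verification run (100 adults at 5 and 20 mg/kg 2-h infusions;
10 pediatric trials per group at 12.5 mg/kg, 48 h) joins predictions to
observed clinical values and flags each fold error against the 0.5–2.0
acceptance band:

```r
run_verification("results", seed = 1, model = model)
```

```
 population dose_mg_per_kg parameter predicted observed fold_error within_bounds
      adult            5.0      cmax      4.62     4.74      0.975          TRUE
      adult            5.0   auc_inf     17.91    18.40      0.973          TRUE
      adult           20.0      cmax     18.69    17.80      1.050          TRUE
      adult           20.0   auc_inf     73.26    82.50      0.888          TRUE
    neonate           12.5      cmax     32.83    19.90      1.650          TRUE
    neonate           12.5   auc_tau     96.21    65.60      1.467          TRUE
     infant           12.5      cmax     23.44    21.90      1.071          TRUE
     infant           12.5   auc_tau     55.50    43.30      1.282          TRUE
      child           12.5      cmax     16.71    24.30      0.688          TRUE
      child           12.5   auc_tau     42.62    37.80      1.127          TRUE
```

Exposure units are µg/mL (Cmax) and µg·h/mL (AUC).  All ten predictions
fall within the conventional 2-fold band of the observed values; the
neonatal bias (~1.5-fold) and its roots in the printed ontogeny inputs are
discussed in the methods vignette (`vignettes/sult-ontogeny-pbpk.Rmd`).

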