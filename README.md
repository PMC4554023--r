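# astigvec

Power-vector analysis of corneal astigmatism for cataract surgery planning:
how much do automated keratometry (AK) and ray-traced total corneal
refractive power (TCRP, 3 mm and 4 mm zones) disagree, and which of them
better predicts the postoperative refractive astigmatism — especially in
corneas with a high irregularity index (IR)?

## Who it is for

Researchers comparing keratometry modalities and anyone who needs the
underlying primitives: Jackson power vectors, vertex-distance conversion,
surgically induced astigmatism (SIA) adjustment, and ocular residual
astigmatism (ORA). Because per-eye clinical data of this kind are rarely
shareable, the package ships a synthetic cohort generator with the same
statistical structure, so the whole analysis is runnable and testable
without patient data.

## The model

An astigmatic cylinder `C` (positive-cylinder convention) with flat
meridian `A` is represented in double-angle Cartesian space by the Jackson
coefficients

    J0  = (C / 2) cos(2A)
    J45 = (C / 2) sin(2A)

Differences between astigmatism measurements are Euclidean distances in
(J0, J45) space: the discrepancy between TCRP and AK for one eye is
`ΔTCRP–AK = sqrt(ΔJ0² + ΔJ45²)`, and ORA is the same distance between a
preoperative keratometry vector and the postoperative refractive
astigmatism after it has been (a) moved from the spectacle to the corneal
plane meridian-by-meridian with `Fc = F / (1 − d·F)` (vertex distance `d` =
0.012 m), and (b) adjusted for an assumed SIA flattening vector. A 0.40 D
temporal incision flattening the horizontal meridian has flattening vector
`(J0, J45) = (0.20, 0)`; assumed SIAs of 0, 0.20 and 0.40 D give the RA,
RA1 and RA2 refraction variants, and crossing them with the three
keratometry sources yields nine ORA values per eye.

Eyes are classified with-the-rule (WTR) when the steep AK meridian lies in
45–135° and against-the-rule (ATR) otherwise, and split into low/high
irregularity groups at the cohort median IR (grouping 1) or mean + 2 SD
(grouping 2).

## Worked example

```r
library(astigvec)

cohort <- generate_cohort(sim_params(n = 207, seed = 20150403))
report <- analyze_cohort(cohort)
print(report)
#> Cohort analysis report: 207 eyes
#>   WTR: 105  ATR: 102  excluded (zero cylinder): 0
#>   IR thresholds: median 0.0381 mm, mean+2SD 0.0792 mm
#>   mean delta TCRP3-AK 0.448 D, TCRP4-AK 0.404 D
```

The synthetic cohort reproduces the structure the analysis expects: ~68 y
mean age, IR ≈ 0.042 ± 0.019 mm, ATR eyes older than WTR eyes, and a mean
TCRP3–AK discrepancy near 0.45 D. In its high-IR subgroup (grouping 2,
n = 7 here) the mean ORA computed from TCRP3 (0.27 D) and TCRP4 (0.29 D)
is well below the mean ORA computed from AK (0.87 D): ray-traced
keratometry predicts the postoperative refraction better in irregular
corneas, which is the qualitative finding the generator is built to
exercise.

The same pipeline as a scripted workflow:

```sh
Rscript analysis/01_simulate.R            # -> results/cohort.csv
Rscript analysis/02_analyze.R             # -> results/report/*.csv, summary.json
Rscript analysis/03_parameter_recovery.R  # -> results/recovery.csv
```

`analyze_cohort()` returns the per-eye table (deltas, labels, nine ORA
columns) plus summary tables: WTR vs ATR comparison, low vs high IR
comparisons under both groupings, ORA by group, paired AK-vs-TCRP ORA
contrasts within the high-IR subgroup, and log-linear regressions of IR on
age + irregular astigmatism and of each delta on age + IR + AK magnitude.

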