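# morphorec

Skeletal material reaching anthropologists, paleontologists, and forensic
scientists is routinely fragmented. When a bone's shape is recorded as 3D
landmark coordinates, damage means missing landmarks. `morphorec`
implements and evaluates the **regression method (RM)** of digital
reconstruction: every missing landmark coordinate is predicted by a
multiple linear regression on all present coordinates, trained across an
undamaged reference sample aligned by generalized Procrustes analysis
(GPA) with surface semilandmarks slid to minimize thin-plate-spline (TPS)
bending energy.

The package is organized as an analysis workflow over a zygomatic-like
30-landmark scheme (7 fixed sutural landmarks, 23 surface semilandmarks)
and answers two questions by simulation:

1. Is RM more accurate than the common fallback of substituting the mean
   (consensus) shape? Accuracy is the partial Procrustes distance
   d(true, predicted) compared against d(true, reference mean) with a
   two-sample t-test.
2. How does accuracy change with the extent and location of damage? Three
   damage cases — Case 1: landmarks {1, 2} (zygomatic process), Case 2:
   {4, 5, 7} (orbital margin), Case 3: semilandmarks {16–21} (zygomatic
   body) — are compared by one-way ANOVA and Tukey HSD on
   d(true, predicted).

Every target reconstruction is strict leave-one-out: the target is removed,
the remaining 149 specimens are re-aligned and re-slid, the regression is
trained on them, and the target is damaged, standardized against that
reference, and reconstructed.

Because real reference collections cannot ship with the package, a seeded
synthetic generator provides study-scale data with the structure the method
relies on: a smooth 30-landmark template, low-rank spatially correlated
shape variation, short-range surface relief at the semilandmarks,
population mean offsets (Italian / African American analogs, 119 + 31
specimens), rigid-motion/scale nuisance, and per-landmark digitization
noise. TPS and wide-CSV readers (`read_tps()`, `read_csv_wide()`) ingest
real landmark files with the same downstream pipeline.

## Worked example

The numbered scripts under `analysis/` run the whole study and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate_sample.R        # 150 specimens, wide CSV + TPS
Rscript analysis/02_align_and_screen.R       # GPA + sliding + outlier screen
Rscript analysis/03_damage_study.R           # the 3-case x 30-target study
Rscript analysis/04_population_subsample.R   # Italian-subsample replicate
```

Step 3 prints (seeds fixed in the scripts):

```
  case_name      t    df         p mean_d_true_pred mean_d_true_mean
1     Case1 -22.02 42.20 9.172e-25          0.01562          0.09430
2     Case2 -19.24 33.42 1.178e-19          0.01468          0.09062
3     Case3 -13.39 32.51 8.829e-15          0.02471          0.09503
ANOVA: F(2,87) = 17.83, p = 3.25e-07
         pair       diff         p
1 Case2-Case1 -0.0009406 8.682e-01
2 Case3-Case1  0.0090923 1.310e-05
3 Case3-Case2  0.0100330 1.662e-06
```

Reading: in every case the reconstruction error (`mean_d_true_pred`,
~0.015–0.025 in Procrustes distance units) is far below the distance to
the mean shape (~0.09) — regression clearly beats the mean-shape template
(t ≈ −13 to −22, p ≪ 0.01). Across cases, accuracy depends on the damage:
the two small scenarios are statistically indistinguishable (Tukey
p = 0.87) while the six contiguous missing semilandmarks of Case 3
reconstruct significantly worse than either (p < 1e-4). Step 4 shows the
same pattern holds within the single-population Italian subsample.

Programmatic equivalent:

```r
library(morphorec)
model  <- default_population_model(seed = 42)
ds     <- generate_dataset(model, c(Italian = 119, AfricanAmerican = 31))
report <- run_study(ds, cases = default_cases(), n_targets = 30, seed = 43)
print(report)
write_study_report(report, "results/full_sample_study")
```

`vignettes/reconstruction-accuracy.Rmd` documents the model, the
algorithms, the generator's assumptions, and the numerical design choices.

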