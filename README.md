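# suvvar

Statistical technical variation of SUV metrics in PET.

Even a perfectly standardized PET protocol cannot repeat itself exactly:
radioactive decay is a Poisson process, so two reconstructions of the same
object at the same activity differ. `suvvar` quantifies this irreducible
floor — the *statistical technical variation* — for the common SUV metrics
(SUVMax 2D/3D, SUVMean 2D/3D, SUVPeak) as a function of lesion size, from a
single acquisition. Intended users are medical physicists characterising a
scanner/reconstruction combination and methodologists studying SUV
repeatability.

## Method

One acquisition of length `T` (default 150 s) is partitioned into disjoint
frames of shorter reconstruction length RL (`[0,RL), [RL,2RL), ...`), giving
statistically independent subsets: 37 frames at RL = 4 s down to 5 frames at
RL = 30 s, fourteen subsets in all. For each subset, sphere and metric, the
coefficient of variation across frames is

    CoV = 100 * SD / mean   [%]

and the inverse square-root law of counting statistics

    SD2 = SD1 * sqrt(RL1 / RL2)

extrapolates each subset's CoV to the full reconstruction length
(RL2 = 150 s), yielding 14 estimates whose mean and SD summarise the
expected full-length variation. Welch t-tests compare the estimate
populations between adjacent sphere sizes and between metrics.

A built-in NEMA image-quality phantom simulator (six spheres of 10–37 mm at
a nominal 10:1 sphere:background ratio, 4 mm voxels, F-18 decay, Poisson
count noise with PSF-correlated texture) stands in for the scanner, so the
whole chain is testable end to end; externally reconstructed frame stacks
(NIfTI + JSON sidecars) are equally accepted.

## Worked example

```r
library(suvvar)
res <- run_pipeline(default_run_config(), "run1")   # ~4 min, 1 CPU
subset(res$aggregate$summary, sphere_id %in% c("10mm", "37mm"))
```

    metric sphere_id rl2_s n_estimates mean_estimate sd_of_estimates
     Max2D      10mm   150          14         4.955           1.636
     Max3D      10mm   150          14         4.667           1.568
    Mean2D      10mm   150          14         4.618           1.575
    Mean3D      10mm   150          14         4.438           1.331
      Peak      10mm   150          14         3.825           1.421
     Max2D      37mm   150          14         1.930           0.521
     Max3D      37mm   150          14         1.605           0.581
    Mean2D      37mm   150          14         1.211           0.307
    Mean3D      37mm   150          14         0.898           0.304
      Peak      37mm   150          14         1.749           0.467

Reading: for the 10 mm sphere the expected CoV of any SUV metric at the
full 150 s reconstruction is about 4–5%, while for the 37 mm sphere it is
about 1–2% — the technical floor shrinks with object size, and averaging
metrics (SUVMean) sit below max-seeking ones. Each value is the mean of 14
extrapolations (one per subset); the SD column is the spread of those
estimates. `run1/` also receives the per-subset CoV table, the 13-fold
cross-estimates, a metrics-by-spheres summary table, Welch comparison and
KS normality reports (CSV/JSON), and a run manifest.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/suvvar.R run      --out-dir run1 --seed 1
Rscript inst/cli/suvvar.R simulate --out-dir frames --seed 1
Rscript inst/cli/suvvar.R metrics  --in-dir frames --out-dir run2
Rscript inst/cli/suvvar.R estimate --metrics run2/metrics.csv --out-dir run2
```

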