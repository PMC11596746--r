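# kinelisa

Kinetic image analysis for ELISA on a centrifugal microfluidic disk.

In a conventional ELISA the TMB substrate reaction is stopped with acid and
the yellow product's optical density is read on a plate reader. On a
spinning disk imaged with a rotation-synchronized strobe, `kinelisa`
quantifies the *developing* blue color directly from the image series — no
stop reagent — so a calibration curve is available within about two minutes
of substrate injection. The package is for developers of camera-based
microfluidic immunoassay readers and for anyone who needs a fully synthetic,
ground-truthed benchmark of such a pipeline.

## Method

Per chamber, the mean color signal I(t) over a fixed circular ROI is modeled
as `I(t) = S(t) · λ · j(t)`: chemistry `S(t)`, a static position-dependent
illumination factor `λ` (the strobe is lateral), and per-frame strobe jitter
`j(t)`. The **ratio from the substrate-injection value**, `I(t)/I(0)`,
cancels `λ` exactly, which is why it is the default metric; because TMB
develops toward blue, the red channel's ratio falls most sensitively.
Remaining single-frame flashes are flagged by a **>5 %-per-second
relative-change rule** and interpolated away, traces are smoothed with a
**trailing 30 s moving average**, and at each read time the signal is fitted
by OLS against log10(concentration) over the nonzero standards:

    signal(t) = intercept(t) + slope(t) · log10(c),   R²(t) = 1 − SSres/SStot

The earliest read time whose R² ≥ 0.95 is *sustained* to the end of the run
is reported, and the limit of detection is the concentration whose fitted
signal equals blank mean − 3 SD (minus because the red ratio decreases).
CIELAB / hue metrics (standard CIE conversion, white point 0.9505 / 1.0 /
1.089, no gamma decoding by default) are available for metric comparison via
`compare_metrics()`.

A seeded generator (`generate_assay()`) renders synthetic assays — chambers
developing from colorless toward blue with saturating-exponential kinetics
and Langmuir dose dependence, under static illumination gradients, strobe
jitter and flashes — with full ground truth, so every stage is testable
without instrument data. See the methods vignette
(`vignettes/kinelisa-methods.Rmd`) for the model, parameter defaults and
design decisions.

## Worked example

```r
library(kinelisa)

cfg   <- synthetic_config(seed = 42)          # 5 standards: 0,1,10,100,1000 ng/mL
assay <- generate_assay(cfg)

series <- build_series(assay$frames, cfg$rois, channel = "R", transform = "ratio")
traces <- lapply(series, function(s) moving_average(correct_artifacts(s)))

standards <- data.frame(chamber_id = names(cfg$standards),
                        concentration_ng_per_ml = unname(cfg$standards))

r2 <- r2_trajectory(traces, standards, seq(0, 180, by = 5))
earliest_reliable_time(r2)
#> [1] 10

t_sat   <- saturation_time(cfg)               # 180 s
signals <- vapply(traces, value_at, numeric(1), t_query = t_sat)
round(signals, 4)
#> chamber_1 chamber_2 chamber_3 chamber_4 chamber_5
#>    0.9955    0.9917    0.9572    0.8424    0.7775

fit_calibration(standards, signals, t_read = t_sat, metric = "R:ratio")
#> <calibration_model> t_read = 180 s: signal = 1.0058 + -0.075742 * log10(c), R^2 = 0.9637

blanks <- value_at(traces$chamber_1, seq(120, 180, by = 10))
estimate_lod(fit_calibration(standards, signals, t_read = t_sat), blanks)
#> <lod_estimate> LOD = 1.581 ng/mL (blank 0.99375 +/- 0.001, k = 3)
```

Reading the output: the red ratio at saturation falls monotonically with
concentration (0.996 at blank down to 0.777 at 1000 ng/mL); the log-linear
fit explains 96% of that variance; R² stays above 0.95 from 10 s onward on
this low-noise synthetic run; and a blank this quiet puts the detection
limit near 1.6 ng/mL. The generator's own log-linear slope is
`generator_loglinear_slope(cfg)` = −0.0784, recovered here within 4%.

The same pipeline runs from a shell (`exec/kinelisa` after install, or
`Rscript exec/kinelisa` from the source tree):

```sh
kinelisa simulate --out fixture --seed 42
kinelisa extract  --fixture fixture --out signals.csv
kinelisa analyze  --signals signals.csv --standards fixture/standards.csv --out report
kinelisa report   --dir report
```

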