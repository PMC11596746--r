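---
title: "Methods: kinetic image analysis for a centrifugal microfluidic ELISA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic image analysis for a centrifugal microfluidic ELISA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinelisa)
```

## The measurement problem

In a sandwich ELISA the HRP label turns the TMB substrate from colorless to
blue; conventionally the reaction is stopped with acid after a fixed time and
the yellow product's optical density (OD) is read on a plate reader. On a
centrifugal microfluidic disk the chambers are instead photographed while the
disk spins, using a strobe synchronized to the rotation. Two optical
confounds dominate such images:

* **static, position-dependent illumination** — the strobe sits laterally,
  so each chamber receives a different but constant fraction of the light
  depending on its position on the disk;
* **frame-to-frame strobe jitter** — flash intensity varies a little on
  every exposure, with occasional much larger flashes.

`kinelisa` turns a timestamped frame series into per-chamber kinetic traces
and time-resolved calibration curves that are robust to both confounds,
allowing quantification while the color is still developing — no stop
reagent, and a read within roughly two minutes of substrate injection.

## Signal model

Let $I_c(t)$ be the mean pixel value of a color channel over chamber $c$'s
ROI at time $t$. We model

$$I_c(t) = S_c(t)\; \lambda_c\; j(t),$$

where $S_c(t)$ is the chemistry-driven signal, $\lambda_c$ the static
illumination factor of the chamber's position, and $j(t)$ the per-frame
strobe factor. Three transforms of $I_c(t)$ are supported: *raw*
($I_c(t)$ itself), *difference* ($I_c(t) - I_c(0)$), and *ratio*
($I_c(t)/I_c(0)$), where $I_c(0)$ is the value when TMB enters the chamber.
Only the ratio cancels $\lambda_c$ exactly:

$$\frac{I_c(t)}{I_c(0)} = \frac{S_c(t)}{S_c(0)} \cdot \frac{j(t)}{j(0)},$$

which is why the ratio metric is the default and the raw/difference metrics
exist mainly for comparison (`compare_metrics()` reproduces that screen:
concordance CV below 2% across replicate chips plus agreement on the
discordant chip). Because TMB develops toward blue, the red channel falls
most sensitively while blue barely moves; `R:ratio` is therefore the default
metric.

The reference value $I_c(0)$ is estimated as the mean of the first
`n_ref = 3` frames at or after the reference time. A single frame would put
one draw of $j(t)$ in the denominator of every later point; averaging three
frames reduces that variance at negligible cost in kinetic bias (the trace
moves by well under 1% over 3 s at the default kinetics).

### Color spaces

RGB pixel values (8-bit, scaled to $[0,1]$) can also be projected to CIELAB:
$X Y Z = M\,(R,G,B)^\top$ with the standard sRGB-primaries matrix
(rows $0.4124\,0.3576\,0.1805$; $0.2126\,0.7152\,0.0722$;
$0.0193\,0.1192\,0.9505$), then

$$L^* = 116 f(Y/Y_n) - 16,\quad
  a^* = 500\,[f(X/X_n) - f(Y/Y_n)],\quad
  b^* = 200\,[f(Y/Y_n) - f(Z/Z_n)],$$

with $X_n = 0.9505$, $Y_n = 1$, $Z_n = 1.089$ and the standard CIE piecewise
$f$: cube root above $(24/116)^3$, else $(841/108)x + 16/116$. Hue is the
four-quadrant $\arctan(b^*/a^*)$ mapped to $[0, 360)$ degrees; the
two-argument form is used because the plain ratio is sign-ambiguous between
opposite quadrants.

Two deliberate choices here:

* **No gamma decoding by default.** The conversion is applied directly to
  pixel values/255, matching the instrument's analysis chain, which feeds
  JPEG pixel values straight into the matrix. `rgb_to_xyz(gamma_decode =
  TRUE)` linearizes first for users who want colorimetrically linear input;
  every downstream stage is agnostic to the choice.
* **Hue transforms respect the branch cut.** The hue *difference* series is
  the wrapped angular difference in $(-180, 180]$; the hue *ratio* divides
  the reference-unwrapped hue ($h_0$ + wrapped difference) by $h_0$, so a
  chamber hovering near 0/360 does not produce spurious 360-degree jumps.
  Hue is an angle, so its ratio is not physically meaningful across
  chambers; it is provided for completeness of the metric grid.

## Kinetic conditioning

Large single-frame flashes hit one frame but not the reference, so they
survive ratio normalization. Two steps:

1. **Artifact correction** (`correct_artifacts()`): a point is flagged when
   its relative change from the last *accepted* value exceeds 5% per second
   of elapsed time. Comparing against the last accepted (rather than the
   last raw) value means the second frame of a two-frame flash is also
   caught, and makes the operation idempotent: replaced points lie on the
   chord between flanking accepted points, whose per-second slope already
   passed the test. Flagged points are replaced by linear interpolation
   between accepted neighbors (default) or by holding the last accepted
   value (`method = "hold"`); interpolation preserves trace length and
   timestamps, which the R-squared trajectory needs. Flagged points at the
   trace end hold the last accepted value. The threshold is scaled by the
   actual inter-frame interval, so frames need not be 1 s apart.
2. **Trailing moving average** (`moving_average()`): each value becomes the
   mean over the window $(t - 30\,\mathrm{s}, t]$. The window is trailing
   (causal), not centered, so the smoothed value at time $t$ uses only
   frames already captured — the readout works in real time during an
   assay. The cost is a lag bias proportional to the local slope of the
   trace (about slope $\times$ 15 s); at the default kinetics this bias is
   largest early in the run and negligible near saturation, where the
   calibration is read. It is also shared across chambers in proportion to
   their kinetic amplitude, so it perturbs the calibration's slope far less
   than it perturbs any single trace.

## Time-resolved calibration

For standards of known concentration the signal at read time $t$ is fitted
by ordinary least squares against $\log_{10}$ concentration over four
decades. $R^2 = 1 - SS_{res}/SS_{tot}$ (not squared Pearson correlation), so
a zero-variance degenerate fit is reported as `NA` rather than a silent 1.
The blank (0 ng/mL) is excluded from the fit — its log is undefined — and
supplies the LOD instead: the concentration whose fitted signal equals the
blank mean $\pm\, 3$ SD, the sign chosen toward increasing concentration
(minus for a falling-signal metric such as the red ratio). $k = 3$ is the
conventional multiplier and is a parameter.

`r2_trajectory()` refits at every grid time, and `earliest_reliable_time()`
returns the first grid time from which $R^2 \ge 0.95$ *is sustained to the
end of the grid*. A single-point crossing does not count: image-analysis
values fluctuate, and a read time certified by one lucky frame would not be
reproducible. Absence of a sustained crossing is a valid result (`NA`), and
`cmd_analyze()` then falls back to the last grid time and says so in the
report.

A four-parameter logistic is the usual alternative over wider dynamic
ranges; with five standards (four nonzero) the log-linear form is the most
parsimonious model whose single quality number ($R^2$) can drive the
read-time rule, so it is the default and the only fitted form.

## What the synthetic generator emulates — and what it does not

`generate_assay()` renders chambers whose red channel follows

$$\mathrm{ratio}(t) = 1 - A(c)\,(1 - e^{-k t}),
\qquad A(c) = A_{max}\frac{c}{c + c_{50}},$$

blue constant, green halfway (configurable), under per-chamber static
illumination, per-frame jitter, occasional large flashes, and Gaussian pixel
noise. The saturating exponential with a Langmuir-type dose dependence is
the simplest kinetic form with the qualitative features that matter here:
fast early change, a stable concentration ordering, and red-channel
specificity. It is *not* a mechanistic model of HRP–TMB kinetics.

Default study conditions (chosen once; all are `synthetic_config()`
arguments):

| parameter | default | why |
|---|---|---|
| standards | 0, 1, 10, 100, 1000 ng/mL | the standard series the assay design uses |
| frame interval / duration | 1 s / 180 s | one strobe frame per rotation batch; run covers saturation |
| rate $k$ | 1/60 s$^{-1}$ | development 95% complete at 180 s, consistent with a usable read around 100 s |
| $A_{max}$, $c_{50}$ | 0.25, 50 ng/mL | a strong but unclipped red drop; dose response spans the standards |
| illumination | 1.00 → 0.72 across chambers | lateral strobe: monotone positional falloff |
| jitter sd / flash prob / flash amplitude | 1% / 0.08 / U(0.10, 0.30) | small routine flicker plus occasional large flashes |
| pixel noise sd | 0.008 | ≈ 2 counts of 8-bit sensor noise |

Frames are kept as floating-point arrays in memory; 8-bit quantization
happens at PNG write time (or with `quantize = TRUE`). That is why the
noise-free invariants (ratio trace equal to the analytic formula to 1e-9;
illumination factors cancelling to 1e-12) can be asserted exactly, and it is
also a limit of what passing tests show: a real camera quantizes, compresses
(JPEG), vignettes smoothly rather than per-chamber, blurs with motion, and
drifts thermally. PNG fixtures exercise quantization; JPEG mode exercises
compression; the remaining effects are out of scope, so test results bound
algorithmic behavior, not instrument performance.

Problem sizes used by the test suite and the acceptance script — 48 × 200 px
frames, 5 chambers, 181 frames, 20 seeds for the stochastic properties — are
the package's reference conditions for desk-scale verification; all scale up
through the config.

## Numerical choices and degenerate inputs

* ROI membership: pixels whose (0-based, row-major) integer center lies
  within the radius; ties on the boundary are included ($\le r^2$). The
  generator draws chamber disks 2 px larger than the analysis ROI so mask
  edges never sample background.
* `value_at()` interpolates linearly and refuses extrapolation — a read time
  outside the recorded trace is an error, not a guess.
* A trace whose every point after the first is flagged cannot be corrected
  and errors out; a ratio series with a zero reference value errors at
  construction.
* All randomness in the generator flows from one integer seed, and the RNG
  state of the caller is restored afterwards; identical config + seed is
  byte-identical output.
* The artifact rule needs strictly positive values (it is a relative
  change); use it on ratio traces, not difference traces.

## Known limitations

* The log-linear calibration is read on the smoothed traces, so the small
  trailing-window lag enters the fitted intercept near the start of the run;
  read times near saturation are unaffected.
* The LOD follows the blank + 3 SD convention and carries no confidence
  interval.
* Chamber ROIs come from a geometry config; there is no auto-detection or
  tracking, which a chip with manufacturing variance might need.
* Hue-based metrics are carried through the machinery but are a poor match
  for a colorless-to-blue transition, where lightness and chroma change
  together; they exist so that the metric comparison can demonstrate this.
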