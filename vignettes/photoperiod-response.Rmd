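---
title: "Modelling the photoperiod response of barley flowering time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the photoperiod response of barley flowering time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photothermal)
```

## The model

Long-day cereals such as barley flower faster as days lengthen, but only up
to a point. The classical description of this behaviour is bi-linear: the
mean flowering time (expressed in thermal time, degree-days above a 0 °C
base, so that temperature effects are factored out) declines linearly with
photoperiod $P$ until a *threshold photoperiod* $T$, beyond which extending
the day gains nothing. `photothermal` parameterises this as the continuous
hinge

$$\mu(P) = I + S \cdot \max(0,\, T - P),$$

with three directly interpretable parameters:

* $I$ — **intrinsic earliness** (°Cd): the plateau, the minimum thermal
  time to heading once the photoperiod requirement is saturated;
* $S$ — **photoperiod sensitivity** (°Cd per hour): how much each hour of
  day length below the threshold delays flowering;
* $T$ — **threshold photoperiod** (h): where the decline meets the
  plateau.

Observations are modelled as $y = \mu(P) + \varepsilon$ with Gaussian
residuals and a per-genotype residual SD $\sigma$ (a shared-$\sigma$
structure is a switch away). The hinge form was chosen over verbal or
spline descriptions of the same shape because it makes the three
biological quantities *the* parameters of the mean function, so allele
effects on earliness, sensitivity and threshold read directly off the
fit.

Why this matters practically: speed-breeding protocols for long-day crops
conventionally run 22-h days. If a genotype's threshold is 20 h — as lines
carrying the recessive *ppd-H1* allele show — the last two lit hours buy
no acceleration, and genotypes carrying the dominant *Ppd-H1* allele are
already saturated at 16 h. Fitting $T$ per genotype therefore translates
directly into genotype-tailored photoperiods and lighting savings.

## Estimation

The threshold enters the likelihood non-linearly (and non-smoothly: the
gradient in $T$ jumps wherever $T$ crosses an observed photoperiod), so
generic hill-climbing from a single start is unreliable. Instead the fit
profiles $T$:

1. for any fixed $T$, the conditional model is linear in $(I, S)$, solved
   in closed form with the physical constraint $S \ge 0$ (flowering never
   slows as days lengthen);
2. the profiled residual sum of squares is evaluated on a 0.1-h grid over
   the admissible $T$ range and refined continuously (Brent) around the
   grid optimum;
3. $\sigma$ is the ML estimate from the residuals.

The procedure is deterministic, uses no random numbers, and is invariant
to record order; tests verify it against an independent grid-search oracle
built on `lm()`. A Bayesian treatment of the same mean function is a
natural alternative (weakly-informative priors: Normal on $I$,
half-Normal on $S$, Uniform on bounded $T$ would be the obvious choices),
but point estimation here must be exactly reproducible for testing, so the
deterministic ML path is the default and only backend.

Standard errors come from the usual nonlinear-LS linearisation at the
optimum — the Jacobian columns are $\partial\mu/\partial I = 1$,
$\partial\mu/\partial S = \max(0, T-P)$ and
$\partial\mu/\partial T = S\cdot[P < T]$ — and 95% intervals are Wald
intervals. These conditional-on-structure SEs slightly understate
threshold uncertainty very close to a tested photoperiod; the parameter
recovery study below shows calibration is nonetheless comfortable at the
3-SE level.

**Identifiability.** With observations at photoperiods
$\{16, 18, 20, 22, 24\}$ h, a threshold in $(16, 18)$ leaves only one
photoperiod on the declining arm: $S$ and $T$ then trade off along a ridge
($S(T-16)$ constant) and only their product is estimable. The fitter
flags thresholds at the bounds and reports a non-identifiable $T$
(`NA`, with a warning) whenever the profiled sensitivity is zero. The
default $T$ bounds are $[12, 24]$ h: the experiment only informs the
range it tested ($\ge 16$ h), and any estimate below 16 h is an
extrapolation, flagged as such.

## Model variants and selection

Genotypes can be fitted independently (`full`: $I, S, T, \sigma$ per
genotype), with a threshold common to all genotypes (`shared_T`), or as
flat responders (`flat`: $S = 0$, $T$ dropped). Variants are ranked by
BIC. BIC was preferred over small-sample-corrected AIC because variant
choice here is a question of which structure generated the data, not of
predictive loss, and in simulations at realistic sizes (flat truth,
$n = 100$) BIC selects the flat variant in ~99% of runs, where AICc's
extra-parameter penalty is too light and sits at ~95%. AICc remains
available via `criterion = "AICc"`. Ties are broken by parameter count,
then variant name, so rankings are deterministic.

## Classification and recommended photoperiods

`classify_response()` calls a genotype **responsive** when the 95%
interval of $S$ lies entirely above a near-zero band (default
2 °Cd h⁻¹ — roughly a tenth of a day of flowering delay per extra hour,
chosen as the magnitude below which a response has no practical breeding
consequence; configurable) *and* the threshold estimate lies above the
shortest tested photoperiod. It calls a genotype **flat_saturated** when
the straight-line slope fitted across the whole tested range is
indistinguishable from zero (95% interval inside the band). That
range-wide slope — not the hinge's local slope — is the right quantity
for the flat call: a hinge fitted to flat noise can park its breakpoint
anywhere, and its local slope interval then reflects the arbitrary
breakpoint, not the data's overall trend. Everything else is
**indeterminate**. Two caveats are recorded in the output: a flat call
cannot distinguish true insensitivity from a threshold below the tested
range without shorter-day data, and classifications at low replication
are honestly indeterminate — at the tent design's 10 plants per
photoperiod with $\sigma = 25$ °Cd, a zero slope's interval reaches
~2.4 °Cd h⁻¹, above the band.

`recommend_photoperiod()` then maps classes to settings: responsive →
the tested photoperiod nearest the estimated threshold (ties upward);
flat_saturated → the shortest tested photoperiod; indeterminate → a
conservative 22-h default, flagged. Nearest rather than next-longer is
deliberate: a threshold estimated at 20.2 h run at 20 h costs
$S \times 0.2 \approx 9$ °Cd (under half a day), while stepping up to
22 h costs two lit hours every day of every cycle.

## The synthetic experiment

`design_spec()`/`generate_phenotypes()` emulate the growth-tent study
that motivates the package: 7 genotypes — four HEB lines covering the
*ELF3* × *PPD-H1* allele factorial, plus Bowman and its *elf3* and
*PhyC-e* near-isogenic lines — at 16/18/20/22/24-h photoperiods, 5
replicates × 2 experiment repetitions, constant 20 °C. Each plant's
thermal time is its genotype's hinge mean plus Gaussian noise, truncated
at 1 °Cd (no non-physical flowering times). The default generating
parameters are an *illustrative fixture*, not measured values: responsive
genotypes break at $T = 20$ h with $S = 45$ °Cd h⁻¹ (30 for the
*PhyC-e* line, which dampens sensitivity), *Ppd-H1* and *elf3* genotypes
are flat, and the wild *ELF3* allele lowers $I$ in a responsive
background. $\sigma = 25$ °Cd throughout (~1.2 days at 20 °C — a typical
within-line spread for heading dates under controlled conditions; the
source study reports no variance estimates, so this is a stated
assumption). Gaussian residuals match the downstream t-test analyses; a
repetition (run/year) offset exists but defaults to 0.

What the generator does *not* emulate: block/tent spatial effects (the
randomized-block structure is recorded but generates no effect by
default), light-intensity or spectral variation, photoperiod ×
temperature interaction, and outlier contamination. Passing tests on
synthetic data therefore demonstrate that the estimation machinery
recovers the truth under the stated noise model — not that real tent data
are this clean.

## Contrasts, qPCR and energy

`photoperiod_contrasts()` runs the two treatment questions as two-sample
Student's t-tests per genotype (16 h vs 20 h: is there still a response?
20 h vs 22 h: does the speed-breeding standard add anything?). "Student"
is taken in its classical pooled-variance meaning, with a Welch switch;
repetitions are pooled by default (stratification available); no
multiplicity adjustment is applied, mirroring how such screens are
usually reported. Degenerate zero-variance groups return $t = 0, p = 1$
(identical) rather than erroring.

`relative_expression()` implements the ΔCt method, $2^{-\Delta Ct}$
against a reference gene (*HvTubA* by default) measured in the same
sample — no calibrator sample (ΔΔCt) and no primer-efficiency correction.
Technical duplicates collapse to their detected mean; undetected wells
are excluded and flagged, never imputed, and group comparisons run on
$-\Delta Ct$ (log2 relative expression), where variances are stable,
flagging undetected-dominated cells as untestable.

The energy module encodes the lighting arithmetic that motivates
genotype-tailored photoperiods, from a published horticultural LED
benchmark: a 0.65-kW fixture over 8 sq ft, 3,000 h/yr for 15 years,
consumes 29,250 kWh lifetime. Cutting a 22-h photoperiod saves
100/22 ≈ 4.54% of lighting cost per hour (truncated to two decimals —
the convention that reproduces the headline figure); annual per-fixture
savings use 365-day arithmetic (0.65 × Δh × 365: 237.25 kWh for 1 h,
474.5 for 2 h, 1,423.5 for 6 h), which is the convention the headline
kWh figures follow — the 3,000 h/yr figure is kept only for the lifetime
benchmark, because the two duty-cycle conventions are mutually
inconsistent. Facility costs scale by exact (non-integer) fixture count
× tariff: a 10,000 sq ft facility at £0.22/kWh saves £130,487.50/yr at
20 h (£130,000 at the nearest £1,000) and £391,462.50/yr at 16 h. Note
the commonly quoted ~£392,000 for the 16-h case is not reproducible from
these inputs by any rounding path we could identify; the package reports
the derived value. Rounding conventions are fixed per quantity (truncate
the per-hour %, half-up integers for %, half-up kWh, nearest £1,000 for
facility reporting) so printed figures are bit-reproducible.

## Numerical and reproducibility choices

* Thermal time accumulates **daily means above base** (base 0 °C), the
  standard degree-day convention; a per-reading integration switch
  exists. Day boundaries follow the log's timestamps at UTC midnight;
  partial first/last days contribute pro rata, which makes accumulation
  exactly additive over adjacent windows. Gaps beyond twice the cadence
  warn and assume linear coverage.
* All CSVs carry a `#schema=photothermal-v1` first line, comma-separated,
  "." decimals; round-trips are lossless.
* Every stochastic stage is seeded from one integer; the pipeline's
  outputs contain no timestamps, so a configuration reproduces its
  bundle byte for byte.
* Threshold profile grid: 0.1 h (finer than any biological claim), with
  continuous refinement; grid ties resolve to the smallest $T$.

## Problem sizes used in the shipped checks

Simulation-based checks run at sizes chosen to make their Monte-Carlo
error small relative to what they assert: parameter recovery at 50
plants/photoperiod, $\sigma = 10$ °Cd, 200 seeds; model selection at 20
plants/photoperiod (100 total), 100 seeds per truth; t-test calibration
at 1,000 simulated flat genotypes and power at 200 seeds; the
classification demonstration at 100 plants/photoperiod, where a flat
line's range-slope interval sits well inside the near-zero band. The
generator-convergence property uses 500 replicates against a 3-SE bound.

## Known limitations

* No photoperiod × temperature interaction; thermal time isolates the
  photoperiod response but does not model it.
* Thresholds below the tested range are extrapolations and flagged;
  nothing below 16 h is empirically identified by the emulated design.
* Wald intervals on $T$ near a tested photoperiod are approximate;
  a profile-likelihood interval would be the next refinement.
* The qPCR module assumes perfect primer efficiency and a single
  reference gene.
* No mixed-model treatment of the block design; contrasts mirror the
  plain t-test analysis they replicate.
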