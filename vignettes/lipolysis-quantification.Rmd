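---
title: "Quantifying in vitro lipolysis: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in vitro lipolysis: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipolyzer)
```

## The measurement problem

When a dietary oil is digested by pancreatic lipase, two complementary
readouts quantify how far hydrolysis has progressed:

1. **pH-stat titration.** Released free fatty acids (FFA) acidify the
   digestion cell; an autotitrator holds the pH constant with NaOH, and the
   cumulative titrant volume tracks hydrolysis in real time.
2. **HPLC-ELSD of the residual triacylglycerols (TAG).** The undigested TAG
   remaining at a later time point is separated on a reversed-phase C18
   column and quantified against a co-injected internal standard
   (triundecanoin) with an evaporative light-scattering detector.

`lipolyzer` implements the computations behind both readouts, plus peak
annotation by partition number, emulsion droplet/stability metrics, and a
seeded synthetic-data generator that makes every stage testable end to end.

## pH-stat model

sn-1,3-specific pancreatic lipase liberates two of the three fatty acids of
a TAG, so the fraction of titratable acids released is

$$\mathrm{FFA}(\%) = \frac{V_{NaOH}(t)\, m_{NaOH}}
  {(w_{lipid}/M_{lipid}) \times 2} \times 100,$$

with $V_{NaOH}(t)$ the cumulative titrant volume (L), $m_{NaOH}$ its
molarity (mol/L), $w_{lipid}$ the oil mass (g) and $M_{lipid}$ the mean
molar mass of the oil (g/mol). The factor 2 is kept exactly as the assay
defines it; `ffa_release_percent()` exposes it as an advanced argument
because complete hydrolysis of di- and monoacylglycerols can push apparent
release above 100% — such values are reported with a warning, never
truncated, since they are diagnostic of over-titration.

$M_{lipid}$ is rarely reported with a digestion protocol, so
`mean_oil_molar_mass()` derives it from the GC fatty-acid composition:
area percentages of the known acids are renormalized and treated as acyl
mole fractions (for C16–C18-dominated oils, FAME area % is within ~1% of
mole %, well inside the precision that matters here), and the oil is
modelled as three average acyls esterified to glycerol. The function
refuses compositions with more than 10% unknown area rather than guess.

The **initial rate** is the micromoles of FFA released during the first
minute, expressed as a concentration change per second:
$\mathrm{rate} = \mathrm{FFA}_{\mu mol}(60\,\mathrm{s}) / V_{total} / 60$
in mM/s. The titrant volume at exactly 60 s is obtained by linear
interpolation between the bracketing samples — titration logs are sampled
densely enough (seconds) that the interpolation error is far below the
instrument resolution; using the nearest sample instead would make the
rate depend on the logging grid.

## ELSD power-law quantification

An ELSD responds to analyte mass as a power law, $A = aC^b$, so with an
internal standard the calibration is

$$A_{TTGS}/A_{IS} = a\,(C_{TTGS}/C_{IS})^b .$$

`fit_power_calibration()` fits this on the log-log scale, where the model
is a straight line, multiplicative detector noise becomes approximately
homoscedastic, and the estimate has a closed form; $R^2$ is reported on the
same scale. A direct nonlinear refinement (`method = "direct"`) is
available for users who prefer least squares on the original scale; with
clean dilution-series data the two agree to many digits.

Inverting the calibration and scaling by the sample bookkeeping gives the
TAG mass in a lipolysis product, normalized to a common amount of starting
oil (150 mg by default):

$$m_{TTGS} = \left[\frac{A_{TTGS}/A_{IS}}{a}\right]^{1/b}
  C_{IS}\, m_{LP} / C_S \times \frac{150}{m_a},$$

and the lipolysis rate after $t$ minutes is the fractional TAG loss
$\bigl(1 - m_{TTGS}(t)/m_{TTGS}(0)\bigr) \times 100$.

Two consequences of this algebra are load-bearing and are asserted by the
test suite:

* **The coefficient $a$ cancels.** Only the exponent $b$ affects the rate,
  so a rate can be computed from any calibration with the right exponent.
* **Uniform area rescaling at one time point cancels.** The internal
  standard normalizes injection-to-injection response drift by design.

The rate formula is implemented by evaluating the mass equation at both
time points and taking the ratio, each time point normalized by its *own*
IS area. Written out as a single expression the published form of this
substitution is easy to typeset wrongly (the IS time indices are the usual
casualty); deriving it from the mass equation keeps the implementation
unambiguous. Rates outside [0, 100] are reported with a quality flag
rather than clamped — a negative rate is evidence of noise or a
normalization error and should be seen, not hidden.

For **per-species rates** the same equations are applied with the peak
area of one annotated species and that species' own exponent. Peaks
labelled `"Unknown"` are excluded from per-species work but included in
the total-TAG area: they are TAG, merely unannotated.

## Partition-number annotation

On reversed-phase C18, TAG species elute in order of partition number
$PN = CN - 2\,ND$ (total acyl carbons minus twice the double bonds).
`enumerate_plausible_species()` forms all acyl 3-multisets above an
abundance threshold — $\binom{k+2}{3}$ of them for $k$ acids — and
`annotate_peaks()` assigns PN groups to peaks in elution order. Within a
PN group, co-eluting species cannot be distinguished by retention alone;
the group is labelled by its most abundant member, where abundance is
estimated as the multinomial product of acyl fractions. That
random-distribution estimate is a tie-breaking heuristic only: real oils
(and especially interesterified ones) deviate from it, which is exactly
why it is never used quantitatively. TAG species are modelled as
*unordered* acyl triples — positional (sn-1,2,3) isomerism affects lipase
kinetics but no computation here depends on it, and ELSD cannot resolve
it. Atomic masses are fixed IUPAC constants in one table so molar-mass
arithmetic is reproducible to the last digit.

## Emulsion metrics

The Sauter mean diameter $d_{32} = \sum n_i d_i^3 / \sum n_i d_i^2$
summarises a droplet size distribution by the diameter carrying the
surface area, which is what lipase adsorption sees. For stability scans,
the change in backscattering is averaged over a zone — the top 3 mm of the
scanned column for creaming, the bottom 5 mm for clarification — and the
zone mean is regressed on time; the slope, in %/h, is the creaming or
clarification rate. The zone mean is unweighted and the slope is ordinary
least squares over all scan times rather than an endpoint difference:
with 37 scans over 3 h, OLS is substantially more noise-robust and equals
the endpoint slope exactly when the ramp is linear. The liquid level is
taken as the highest scanned height of each scan.

## The synthetic-data generator

Laboratory inputs for this pipeline (titration logs, integrated peak
tables, size distributions, backscatter grids) are rarely deposited, so
the package ships forward models of every input type with known ground
truth. Each generator is the exact inverse of its analysis operation at
zero noise, which turns every stage into a round-trip test:
`analyze(generate(truth)) == truth` to at least 1e-9.

The default configuration (`default_simulation_config()`) uses the study
design points of a four-oil digestion experiment — soybean oil (SBO),
pomegranate seed oil (PGO), their 1:1 blend (PHY) and the
interesterified oil (IO):

* oil-level calibrations $y = 0.4568x^{1.4353}$ (SBO),
  $0.9241x^{1.4759}$ (PGO), $0.32x^{1.5251}$ (PHY),
  $0.4538x^{1.4306}$ (IO), and species-level calibrations for L-L-L,
  L-L-O, CLn-CLn-CLn and CLn-CLn-P;
* true total lipolysis rates 80.4 / 66.5 / 74.8 / 77.0% and species rates
  77.1, 75.5, 65.3 and 70.3%;
* first-order FFA-release kinetics
  $F_{max}(1 - e^{-kt})$ — the simplest curve with the fast-then-slow
  shape of product-inhibited interfacial lipolysis; $F_{max}$ and $k$ are
  solved (by `uniroot` on the two-anchor equation) so the curve passes
  exactly through the measured initial rates (0.094–0.134 mM/s) and
  10-min releases (71.8–93.8%);
* lognormal droplet diameters with geometric SD 1.3 (typical of a
  sonicated fine emulsion), median chosen so the designed $d_{32}$ equals
  the measured 0.26–0.31 µm;
* backscatter ramps at the measured creaming/clarification slopes
  (e.g. 7.06 and −2.12 %/h for PGO). Creaming slopes for PHY and IO were
  not reported numerically and default to values between the SBO and PGO
  slopes, consistent with their reported intermediate behaviour.

Area noise is multiplicative lognormal with configurable CV (unit mean),
because ELSD response is strictly positive with roughly constant relative
error; the internal-standard areas receive noise too, since IS
normalization is part of what the pipeline must be robust to. All
randomness flows from the single config seed (peak tables, PSD and scans
draw from fixed offsets of it), so identical configs give byte-identical
outputs.

What the generator deliberately does **not** emulate: retention-time
drift, peak overlap and integration error, baseline artefacts, detector
saturation, back-titration lag, or mechanistic interfacial kinetics.
Passing round-trip tests therefore validates the *computations*, not the
chromatographic practice upstream of them.

## Numerical and design choices

* Calibration requires ≥ 3 strictly positive points; non-positive values
  are an error (the log is undefined, and a zero area in a dilution series
  indicates a failed injection, not a datum).
* `invert_calibration()` maps area ratio 0 to concentration 0, so a fully
  hydrolysed species yields exactly 100%.
* A species present at $t$ but absent at 0 min cannot have a rate and is
  skipped with a warning; a species without a calibration curve is an
  error, not a silent fallback to the oil-level curve.
* Whether totals should use the oil-level or a species-level exponent is
  left to the caller: both are supported, with the oil-level curve the
  default for the `"total"` selector.
* Zone boundaries (3 mm creaming, 5 mm clarification) are arguments with
  assay-standard defaults.
* Problem sizes in the shipped tests: 601-point titration grids, 2–7 peak
  tables, 200 noise replicates at 1% CV, 20 000 simulated droplets —
  small enough to run in seconds, large enough that Monte-Carlo checks
  have negligible sampling slack.

## Limitations

The package starts from *integrated* peak areas and logged titrant
volumes; peak detection, retention alignment and electrode behaviour are
out of scope. Per-species quantification inherits the annotation's
assumption that PN order is strictly monotone in retention and that
co-eluting isobaric species share a peak. The printed $R^2$ values of
real calibrations (0.95–0.999) cannot be recomputed without the raw
dilution-series areas and are carried only as metadata on the stored
curves.

## A worked run

```{r example, eval = FALSE}
cfg <- default_simulation_config("PGO", seed = 1)
dir <- tempfile()
files <- simulate_to_files(cfg, dir)
report <- run_pipeline(list(
  phstat = list(log = files[["titration"]], molarity = 0.05,
                oil_mass_g = 0.3,
                oil_molar_mass = mean_oil_molar_mass(cfg$oil)),
  quantify = list(t0 = files[["peaks_t0"]], tt = files[["peaks_tt"]],
                  calibration = files[["calibration"]]),
  emulsion = list(psd = files[["psd"]], scan = files[["scan"]])))
report
```
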