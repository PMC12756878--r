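---
title: "Precision OXPHOS analysis: models, corrections and design choices"
author: "oxygraphR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision OXPHOS analysis: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxygraphR)
```

## The measurement model

High-resolution respirometry records the oxygen concentration $C(t)$ (µM,
equal to nmol/mL) in a closed, stirred chamber holding a mitochondrial
preparation. While the chamber is closed, the sample's volumetric oxygen
flux is the negative slope of the concentration,

$$ J_V(t) \;=\; -1000\,\frac{dC}{dt} \;-\; \big(a_0 + b_0\,C(t)\big)
\quad [\mathrm{pmol\,s^{-1}\,mL^{-1}}], $$

where the factor 1000 converts nmol mL$^{-1}$ s$^{-1}$ to
pmol s$^{-1}$ mL$^{-1}$ and $a_0 + b_0 C$ is the instrumental background
(sensor consumption and back-diffusion), modelled as linear in oxygen as is
conventional for polarographic oxygraphs. `estimateFluxSeries()` computes
the slope by local least squares over a centered window (default 40 s,
configurable) restricted to the surrounding uninterrupted closed-chamber
segment; windows never straddle a reoxygenation or a titration-spike
window. Samples inside open intervals or spike windows, or closer than
half a window to a segment edge, are masked rather than extrapolated.

A substrate–uncoupler–inhibitor titration (SUIT) protocol drives the
preparation through a sequence of coupling states — routine ($R$), leak
($L$), OXPHOS capacity ($P$), electron-transfer capacity ($E$) — and
pathway states (NADH-linked N, succinate-linked S, fatty-acid-oxidation F,
glycerophosphate Gp, and their combinations at the Q-junction). A *mark* is
an analyst-chosen window $[t_0, t_1)$ on the steady part of a state;
`markRate()` aggregates the valid flux samples in the window (mean by
default, median for spike-contaminated marks) and records the mean oxygen
concentration for the oxygen-matched Complex IV assay.

## Corrections

- **Residual oxygen consumption (rox).** After full inhibition of the
  electron transfer system, the remaining flux is non-mitochondrial.
  `baselineCorrectRox()` subtracts it from every $R'/L'/P'/E'$ total;
  auxiliary rates (rox, ren, chb, CIV) remain totals. The operation
  recomputes the corrected column from totals, so it is idempotent, and
  negative corrected rates are reported and flagged rather than clamped —
  a leak rate slightly below rox is informative, not an error.
- **Fatty-acid oxidation.** F-pathway OXPHOS capacity is the
  octanoylcarnitine flux after cytochrome c minus the flux at 0.1 mM
  malate, $F_P = J(\mathrm{1Oct}[c]) - J(\mathrm{+M.1})$, which removes
  anaplerotic and endogenous contributions (`faoCapacity()`).
- **Outer-membrane integrity.** Stimulation by exogenous cytochrome c,
  $(J_{[c]} - J)/J_{[c]}$, indicates cytochrome c loss through a damaged
  outer membrane (`cytcControlEfficiency()`). The damage flag defaults to
  0.15; the literature reports efficiencies but no diagnostic cutoff, so
  the threshold is an explicit, configurable choice.
- **Chemical background of the CIV assay.** Ascorbate/TMPD autoxidation is
  linear in oxygen above 50 µM; `calibrateChemicalBackground()` fits
  $J_{chb}(C) = a_{chb} + b_{chb} C$ by ordinary least squares over points
  at $C \ge 50$ µM (points below are excluded and counted), and
  `civActivity()` subtracts either an oxygen-matched azide rate (default
  tolerance 5 µM — "closely matched" quantified as a design choice) or the
  fitted line at the assay's oxygen level.
- **Non-steady states.** When respiration declines between a state's own
  mark ($Z_i$, e.g. $P_1$) and the rate just before the next titration
  ($Y_{i+1}$, e.g. $P_2$), ratios formed with the earlier rate are
  inflated; $P_1/E > 1$ is theoretically impossible and is flagged.
  `stepAnalysis()` classifies the relative drift $d = (Z_i - Y_{i+1})/Z_i$
  with a default steady tolerance of 5% (the phenomenon is documented in
  the source material without a numeric threshold; 5% is of the order of
  the technical repeatability of mark rates). `ecorr()` rescales the ET
  capacity, $E_{corr} = (P_1/P_2)\,E$, which restores
  $P_1/E_{corr} = P_2/E$ exactly. The correction is applied automatically
  only for the declining P-to-E transition; elsewhere it is opt-in.

## Derived quantities

Flux control ratios divide every (corrected) state rate by a common
reference — NS-pathway ET capacity in RP1 (step `5S`), combined FNSGp ET
capacity in RP2 (step `7U`) — making profiles independent of normalization
(`fluxControlRatios()`). Coupling control is summarized per sample as
$(P-L)/P$, the biochemical coupling efficiency $(E-L)/E$ (a linearization
of the respiratory control ratio $P/L$ to $[0,1]$, usable with mean ± SD),
and the excess-capacity index $(E-P)/E$. Because $P/L$ is unbounded,
group RCRs are reported as the inverse of the mean $L/P$
(`aggregateRatio()`); the naive mean of $P/L$ is also shown, labelled
statistically incorrect, and always exceeds the correct value by Jensen's
inequality. Additivity of convergent electron flow is
$A = (1-\alpha)/\beta$ with $\alpha, \beta$ the dominant and subdominant
single-pathway control ratios relative to the combined NS rate
(`additivityIndex()`); $A = 1$ at complete additivity ($NS = N + S$), 0
when the second pathway adds nothing. On an exact tie the S-pathway is
designated dominant — a deterministic tie-break consistent with S
dominating in most mitochondrial preparations.

Technical-repeat agreement between the two protocols uses the symmetric
(inverted) regression: OLS of $y$ on $x$ and of $x$ on $y$, the latter
re-expressed in $y$-on-$x$ form ($b_X = 1/\beta_X$,
$a_X = -\alpha_X/\beta_X$), averaged to $\bar b$ and $\bar a$
(`invertedRegression()`). Neither replicate is privileged, and on
collinear data both fits coincide. Group comparisons
(`clusterCompare()`) report two explicit heterolinearity criteria —
relative spread of group mean slopes above 20%, or disjoint seeded
bootstrap confidence intervals — because the published practice classifies
clusters visually; both criteria are reported so the decision is
auditable.

## The protocol state machines

`builtinProtocol()` ships RP1, RP2 and the blood-cell RP1 variant (no
octanoylcarnitine, which inhibits N- and NS-pathway respiration in PBMCs
and platelets) as YAML configs with one row per titration step: label,
titrant, pathway state, coupling state, role, and whether the step is a
stepwise uncoupler titration. Preparatory steps (`+Dig`, `+D`, `+M.1`) are
first-class so their rates remain available to corrections. The uncoupler
optimum is the maximum over that step's titration marks, ties broken
toward the lower concentration (less inhibition risk). The RP1 step `4G`
is reported as `N_E` with the annotation `{PGM}`; both names are in
circulation and the table carries the annotation so outputs are
self-describing. Comparable states across protocols are paired by class:
identical (routine, ren), harmonized (SGp$_E$, rox, CIV), and the
possibly-comparable OXPHOS pair (`2c` vs `3P`), which is comparable only
under zero additivity of the F-pathway.

## The synthetic-run generator

`simulateRun()` integrates the chamber oxygen balance by explicit Euler at
the sampling interval (default 2 s); state fluxes are piecewise constant
(or linearly drifting when a non-steady state is requested), so
higher-order integration would add nothing measurable. Air saturation
defaults to 180 µM, approximately the respiration-medium value at 37 °C.
Reoxygenations open the chamber when oxygen falls below 50 µM and approach
the target exponentially (15 s time constant); the Complex IV step starts
reoxygenated, emulating the open-chamber redox-equilibration phase of that
assay. Titrations leave a symmetric triangular spike (3 µM, 10 s) on the
recorded concentration — enough to exercise the exclusion logic, with no
claim to a physical spike model. Measurement noise is additive Gaussian on
the concentration. After the azide step, the chemical background is
re-measured in long closed segments at a ladder of oxygen levels (the
chamber's gas phase can be driven below air saturation, so levels below
the reoxygenation threshold are reachable; the ETS is fully inhibited
there). One root seed drives all randomness; a fixed seed reproduces a run
bit for bit.

The default fluxes emulate a permeabilized-cell run (2·10⁶ cells in a 2-mL
chamber): routine 30, leak 17, OXPHOS 73, N-pathway ET 93, NS ET 163, rox
3 pmol s⁻¹ mL⁻¹, Complex IV 220, autoxidation 8 + 0.1·C. These were
chosen once as typical magnitudes; the implied corrected L/P of 0.20 and
NS-additivity of 0.4 lie inside the ranges published for permeabilized
cells and tissues. `simulateCohort()` draws one lognormal scale per sample
(unit mean, given CV) and applies it to all mitochondrial fluxes: scaling
preserves every within-sample ratio exactly while reproducing the dominant
real source of between-sample spread (amount of material in the chamber);
the chemical background, an instrument property, is not scaled.

What the generator does *not* emulate: electrode drift and calibration
error, uncoupler dose–response shapes (doses are given as fractions of the
true ET capacity), substrate competition, oxygen diffusion gradients, or
autocorrelated sensor noise. Passing recovery tests therefore demonstrates
the correctness of the analysis chain under the stated trace
phenomenology, not robustness to every artifact of real instruments.

## Numerical choices and problem sizes

Slope estimation uses prefix-sum least squares per closed segment
(numerically adequate at these magnitudes; times are centered per
segment). Recovery checks in the test suite use full protocol runs of 300
s per state: noiseless runs reproduce every corrected coupling-state rate
to better than 0.1%; with 0.5 µM concentration noise, 200 seeded
replicates bound the across-replicate mean error of every corrected rate
by 2%. The chemical-background ladder uses seven levels of 1200 s, which
puts the single-run standard error of the fitted intercept and slope near
1% — comfortably inside the 5% recovery check. Cohort checks use n = 6
samples at 15% between-sample CV. These sizes are the package's validation
conditions; all are plain `simulationSpec()` arguments.

## Known limitations

- Rates are read from analyst-style marks; no automatic plateau detection
  is attempted (mark placement is the adaptation point for real exports).
- The inverted regression is the two-fit average by construction; formal
  errors-in-variables estimators (Deming, major-axis) are deliberately out
  of scope.
- Proprietary binary instrument files are not read; the canonical trace
  dialect is delimited text with a configurable column mapping.
- The P/O (ADP/O₂) ratio cannot be derived from these protocols and is
  not computed.
- Oxygen-solubility calibration of the raw sensor signal is assumed done
  upstream; traces enter in µM.
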