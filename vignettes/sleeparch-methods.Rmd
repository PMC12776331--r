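---
title: "sleeparch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sleeparch: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeparch)
```

This vignette is the package's own account of its methods: what each stage
computes, which assumptions it makes, why the defaults are what they are,
and what a passing test does and does not establish.

## The hypnogram and its conventions

The central object is the hypnogram: one arousal-state label per fixed
scoring epoch (10 s by default), with Wake (`W`), NREM (`N`) and REM (`R`)
as the only admissible states. Time is kept on the zeitgeber clock (ZT,
hours since lights-on), with a 12:12 light:dark cycle by default; all
windows are half-open `[start, end)`, epoch indexing is 0-based, and each
epoch belongs to the phase of its onset.

**REM rescoring.** Automated scorers commonly produce two REM artifacts:
isolated single REM epochs (below the two-epoch minimum for a REM bout) and
REM directly after Wake (sleep-onset REM, which healthy rodents do not
show). `apply_scoring_rules()` removes both: whole REM runs whose first
epoch follows Wake become Wake, then singleton REM epochs take the
preceding state, iterated to a fixpoint. We apply the Wake rule to the
*entire* contiguous REM run, not just its first epoch, because the artifact
being removed is the whole sleep-onset REM period; the alternative
(rescoring one epoch at a time) converges to the same fixpoint but can
leave intermediate states ambiguous. A recording that *begins* with REM has
no previous state to consult; we conservatively rescore the leading run to
Wake and warn, since a sleep-onset REM period cannot be ruled out.

**Bouts.** A bout is a maximal run of two or more same-state epochs.
Singleton runs are not bouts but still count toward time-in-state — the
two families of metrics are deliberately decoupled. Bouts spanning the
light/dark boundary are assigned to the phase of their onset epoch and are
not split; this makes light-phase and dark-phase bout counts sum exactly to
the 24-h counts, which the summary tables rely on. Duration histograms use
half-open bins `[lo, hi)` (a 60-s bout falls in the 60–100-s bin); the
conventional printed bin labels (`<60`, `60-100`, …) do not state a
boundary convention, so we fixed one and test it.

## State-conditioned spectral analysis

Each epoch's one-sided power spectrum is computed by FFT after applying a
periodic Hann window and zero-padding to `nfft` points. Scaling is
energy-consistent: the bin powers sum to the windowed signal's time-domain
energy (Parseval), so scaling the signal by $c$ scales every power by
$c^2$ and leaves every band ratio unchanged. The defaults — 500 samples/s
and an 8192-point FFT on the 5000-sample 10-s epoch — give a bin width of
$500/8192 = 0.0610$ Hz. This grid places the conventionally printed
boundary frequencies (4.88, 6.35, 7.08 Hz at two decimals) on bin centers.
Both `fs` and `nfft` are configurable.

Band edges are δ 0.5–4, θ 6–9, α 9–12, β 12–30 and low γ 30–60 Hz, with
half-open membership `[lo, hi)` so that the touching θ/α edge at 9 Hz is
never double-counted. The 4–6 Hz interval is deliberately unassigned, and
no high-γ band is computed because no standard edges exist for it; both
gaps can be covered by passing explicit `c(lo, hi)` bands.

**Transition-epoch exclusion.** State spectra exclude the first two epochs
of *every bout* of the state, not merely the first two state epochs of the
recording: transitions recur at every state change, and the exclusion is
meant to remove the spectrally mixed entry into each bout. Bouts of two or
fewer epochs therefore contribute nothing, and the included-epoch count
satisfies the identity $\sum_{\text{bouts}} \max(0, L - 2)$, which is
asserted against an enumeration oracle in the tests.

**Slow-wave activity.** The SWA rebound analysis normalizes hourly NREM
δ power on the deprivation day to the per-animal mean NREM δ power of the
baseline day's light phase. The normalization window is a package choice
(it is rarely stated in print); it is the window with the most NREM sleep
and hence the most stable per-animal baseline, and it is configurable.

## Perturbation protocols

The sleep-deprivation scorer takes explicit baseline-day and
deprivation-day hypnograms rather than inferring days from a longer
recording, compares hourly state minutes, cumulative NREM over the
recovery window (ZT6–11 by default), and dark-phase REM (the delayed REM
rebound). It warns if more than 5% of the deprivation window was scored as
sleep, since that indicates a failed deprivation rather than an analysis
problem.

MSLT latency is onset-anchored: measured from nap start to the *first*
epoch of the first qualifying (≥ 2-epoch) bout of the target state, not to
the second epoch that validates the bout — the onset convention of the
sleep field. A nap without a qualifying bout is censored at the nap
duration, never recorded as a pseudo-latency. The five 20-min naps default
to hourly onsets starting at ZT2 (20-min nap, 40-min enforced wake); the
inter-nap structure of the murine MSLT varies across labs, so the scorer
validates only non-overlap and operates on whatever hypnogram it is given.

## Group statistics

`twoway_anova()` computes Type III sums of squares via sum-to-zero
contrasts and single-term deletion from the full model. Type III is the
convention of the commercial statistics packages used in this field and is
the defensible choice for the unbalanced group sizes that mortality
produces in aged cohorts (e.g. 8/6/9/8); on balanced data it coincides
with sequential sums of squares, which the tests exploit via a closed-form
cell-mean oracle.

`repeated_anova()` is a complete-case split-plot ANOVA: between-subject
effects are tested against the subject stratum, within-subject effects
against the subject-by-within stratum. It stands in for the REML
mixed-effects ANOVA that commercial packages fit to incomplete repeated
measures: the two coincide exactly when data are complete, and rather than
approximate REML we drop incomplete subjects with an explicit warning.
This divergence is documented, not hidden; likelihood-based mixed models
are out of scope.

Fisher's LSD uses the parent ANOVA's pooled error mean square and error
degrees of freedom, with unadjusted two-sided p-values — LSD is by
construction an unadjusted procedure, which is why it is only run after a
significant omnibus F.

Per-bin spectral comparisons use pooled-variance unpaired t-tests by
default (Welch available via a flag) and correct across the family of bins
with the Holm–Šídák step-down procedure: p-values are sorted ascending and
compared at step $i$ of $m$ against $1-(1-\alpha)^{1/(m-i+1)}$, stopping
at the first failure; adjusted p-values are the running maximum of
$1-(1-p_{(i)})^{m-i+1}$. The correction family defaults to every bin in
the analyzed range (0.5–60 Hz) — the conservative reading when the plotted
range is narrower — and is configurable via `family_range`. Contiguous
rejected bins are reported as frequency intervals, which is how such
results are conventionally printed.

## The synthetic cohort generator

The generator exists so that every pipeline estimate can be checked
against a known truth. It is a semi-Markov alternating renewal process: on
entering a state, a bout length (≥ 2 epochs) is drawn from a
state-by-phase distribution (shifted geometric by default, discretized
lognormal optional), then the next state is drawn from exit-transition
probabilities. Wake never exits directly to REM and no bout is shorter
than two epochs, so generated hypnograms are fixpoints of
`apply_scoring_rules()` by construction — an invariant the tests assert.
The long-run fraction of time in state $i$ has the closed form
$\pi_i \mathbb{E}[L_i] / \sum_j \pi_j \mathbb{E}[L_j]$ with $\pi$ the
stationary distribution of the embedded chain, exposed as
`stationary_state_fractions()` and used as the renewal-theory oracle.

Defaults describe a nocturnal mouse: mean bout lengths (epochs) of 9/24
for Wake in light/dark, 12/9 for NREM and 7/6 for REM, REM entered from
NREM with probability 0.35 (light) or 0.25 (dark). These give ≈55% Wake
over 24 h with sleep concentrated in the light phase and REM ≈7–9%,
typical published values for aged C57BL/6 mice; they were chosen once, on
that basis, and are not fitted to any dataset. The "mutant" preset mirrors
the qualitative amyloid knock-in phenotype — dark-phase wake bouts ×2,
REM entries ×0.6 (fewer REM bouts), REM θ power ×0.7, and a further REM
entry deficit (×0.8) in females. These are presets for power and recovery
studies, not estimates.

EEG epochs are sums of unit-variance band-limited Gaussian noise
components weighted per state (NREM δ-dominant, REM θ-peaked, Wake
broadband), synthesized in the frequency domain, so expected band powers
are proportional to squared weights and band-power ratios have the
analytic expectation $(w_a/w_b)^2$. Epoch boundaries are not continuous;
since every analysis in the package is strictly per-epoch, the
discontinuity is invisible to it — but spectra of re-windowed or
overlapping segments would see it, which is a stated limitation. Activity
is Poisson per minute with state-by-phase rates; temperature is a cosinor
(mesor 36.5 °C, amplitude 0.7 °C, acrophase ZT18) plus state offsets and
AR(1) noise — values within the range reported for telemetered aged mice.

**What a green test establishes.** The generator reproduces the
*statistical structure* the analysis assumes: alternating states with
phase-dependent bout lengths, state-dependent band composition, diurnal
activity and temperature rhythms. It does not reproduce homeostatic
dynamics (no Process-S), estrus cycling, EEG artifacts, scorer noise, or
within-animal day-to-day drift. Parameter-recovery tests therefore
establish that the pipeline is a correct estimator under its stated model,
not that the model captures every feature of real telemetry data.

## Numerical and interface choices

- Percentages and minutes come from integer epoch counts; conservation
  (states summing to 100%, phases summing to 24-h totals) is exact up to
  one floating division and tested at $10^{-9}$.
- Missing values (no bouts, no included epochs, zero-denominator ratios)
  are `NA`, never 0, in both return values and CSV output.
- A degenerate ANOVA (zero residual mean square) reports `NA` F-statistics
  with a `degenerate` attribute instead of fabricating infinite values.
- Per-animal seeds in `simulate_cohort()` are derived from the master seed
  by a fixed affine rule, so any animal can be regenerated independently.
- Hypnograms travel as headered CSV (`epoch_index, zt_seconds, state`);
  configuration as YAML or JSON with unknown keys rejected. EDF containers
  are not read in this implementation — recordings exported from telemetry
  systems should be converted to the CSV dialect; this is the main
  interface limitation.

## Known limitations

- The repeated-measures ANOVA is complete-case, not REML; with missing
  within-subject cells its F-statistics will differ from mixed-model
  output (the df bookkeeping makes the difference visible rather than
  silent).
- The per-bin correction family, the SWA normalization window, and the
  MSLT nap spacing are all conventions with no single published standard;
  each is configurable and the default is stated above.
- The generator's EEG is stationary within epochs and independent across
  them; spectral estimates of long-range temporal structure (e.g. slow
  oscillation infra-structure) cannot be validated against it.
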