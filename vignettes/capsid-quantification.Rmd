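---
title: "Capsid quantification from RP-UPLC virion-protein chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsid quantification from RP-UPLC virion-protein chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CapsidQuant)
```

## The measurement model

Enterovirus capsids are icosahedral assemblies of 60 protomers. In an empty
procapsid each protomer is (VP0, VP1, VP3); on RNA encapsidation VP0 is
cleaved into VP2 + VP4, so a full virion's protomer is (VP1, VP2, VP3,
VP4). Two consequences carry the entire analysis:

1. **Total response conservation.** The cleavage rearranges residues but
   does not remove them, so the summed protein content per capsid — and the
   summed fluorescence response, which for tryptophan-dominated FLR
   detection is proportional to tryptophan content — is identical for empty
   and full particles. Total VP peak area is therefore proportional to
   total capsid count with a proportionality constant that can be
   calibrated against *any* standard of known concentration, even a
   standard that is itself a mixture of empty and full capsids.

2. **Compositional exclusivity.** VP0 appears only in empty capsids, VP2
   and VP4 only in full ones, and mole-for-mole: each uncleaved VP0 in an
   empty capsid corresponds to exactly one (VP2 + VP4) pair in a full one.
   With tryptophan conservation, `trp(VP0) = trp(VP2) + trp(VP4)`, the raw
   FLR area ratio `VP0/(VP2+VP4)` equals the molar empty:full particle
   ratio without any response-factor correction. A correction hook exists
   in `emptyFullRatio()` but defaults to the identity.

Quantification is then two lines of arithmetic: capsid number per injection
is `(total area − intercept)/slope` from an ordinary least-squares standard
curve (free intercept, unweighted — the calibration model is stated with an
intercept, and no weighting scheme is part of the method), and
concentration is that number divided by `Vinj/dilution`.

The empty *fraction* reported by `emptyFraction()` is `r/(1+r)`. This is an
interpretation of the measured ratio — it equates the area ratio with the
particle-number ratio — and is flagged as model-based in the documentation
rather than presented as a directly measured quantity. It is exactly
inverse to `f -> f/(1-f)`, which the tests verify.

For spiked mixtures, the theoretical empty fraction of a blend is weighted
by capsid count, `sum(v C f)/sum(v C)`, not by volume; only this weighting
balances the particle bookkeeping, which the tests confirm by enumerating
discrete particles.

## What the synthetic generator emulates

`simulateChromatogram()` builds a trace as
`linear drift + white Gaussian noise + sum of Gaussian peaks`, one peak per
VP at its reference retention time, with ground-truth area

```
area(v) = injected_capsids × 60 × occupancy(v) × trp(v) × responsePerTrp
```

where occupancy is the empty fraction for VP0, its complement for VP2 and
VP4, and one for VP1 and VP3. The generator exposes these closed-form areas
as ground truth, which is what makes peak detection and integration
testable to tight tolerances.

Choices, and why:

- **Pure Gaussian peaks.** The real assay's peaks are symmetric and
  baseline-resolved (the critical VP2/VP0 pair resolves at several times
  the regulatory Rs > 2 threshold), and Gaussians admit exact area oracles
  (`A·σ·√2π`). Exponentially modified peak shapes were considered and
  rejected as default: tailing would exercise the integrator differently
  but would forfeit the closed form that anchors the test suite.
- **Tryptophan-only response.** FLR detection at 280/352 nm is dominated by
  tryptophan; tyrosine contributes weakly and is ignored. This is a
  documented simplification: it makes VP4 (which has no tryptophan)
  entirely dark in simulation, whereas the real channel shows a <1% VP4
  peak from minor contributions.
- **Synthetic tryptophan counts.** The VP sequences are not public, so the
  per-VP counts (VP0 10, VP1 9, VP2 10, VP3 8, VP4 0) are fixture values
  chosen once to be realistic for proteins of 7–37 kDa while satisfying
  the conservation constraint `trp(VP0) = trp(VP2) + trp(VP4)` that the
  ratio method relies on. `defaultVPTable()` rejects any override that
  breaks the constraint. Tests that need a visibly eluting VP4 use a
  variant table (VP4 = 1, VP0 = 11) that still satisfies it.
- **Defaults.** Sampling 600 points/min over an 11.5-min run (the method's
  gradient duration, carried as metadata); peak σ 0.02 min (≈0.047 min
  FWHM, matching well-resolved UPLC protein peaks); reference retention
  times 4.335/5.669/7.079/7.527/8.775 min in the observed elution order
  VP4 < VP1 < VP2 < VP0 < VP3; `responsePerTrp = 1e-6` area units, which
  puts a 3.7e12 capsids/mL sample at the ~7e7 total-area scale of real
  reports. Noise is additive white Gaussian (`noiseSd`), drift linear, and
  `areaCV` adds multiplicative per-peak amplitude noise representing
  injection-to-injection variability; ground truth always records the
  pre-noise closed form.

What the generator does **not** emulate: retention-time drift between runs,
peak tailing, co-eluting matrix/host-cell-protein peaks, detector
saturation, and any physical link between gradient program and retention.
Passing tests therefore demonstrate the correctness of the computational
chain under the stated stoichiometric model, not robustness to every
real-chromatography pathology.

## Numerical choices in peak processing

- **Noise estimate**: `mad(diff(signal))/√2`, insensitive to peaks and slow
  drift; the prominence threshold is 10× this estimate by default, with an
  absolute floor of 1e-9 of the signal range so noiseless traces work.
- **Bounds**: descent from the apex to the first return within a noise
  floor of the local minimum, extended by 60% of the descent to cover the
  tail (≈4–10σ total), capped at the inter-peak valley when a neighbour
  interrupts. Integration is trapezoidal under a drop-line baseline whose
  endpoints are 5-point medians, so single noise excursions do not tilt
  the baseline; negative integrals are clipped to zero with a warning.
- **Apex**: parabolic interpolation over the three points around the
  discrete maximum; **width**: interpolated full width at half height above
  the drop-line baseline.
- **Resolution**: the half-height formula `Rs = 1.18Δt/(w½,1+w½,2)`. The
  processing software used for the original instrument data does not state
  its formula; the half-height variant is the European Pharmacopoeia
  convention and is exact for Gaussians. Reported instrument Rs values are
  therefore treated as instrument facts, not recomputable targets.
- **Assignment ties**: when two VPs claim one peak, smaller |Δrt| wins,
  then larger area; collisions are messaged, and unmatched VPs are
  reported absent rather than erroring (VP0 absent is the expected result
  for purified full capsids).
- **%RSD** uses the n−1 sample standard deviation throughout — the choice
  is validated by reproducing the printed precision statistics of the
  worked datasets exactly (e.g. retention-time %RSD 0.48 and ratio %RSD
  3.2).

## Mass identification

Deconvolution is a transparent charge-ladder scorer rather than a
maximum-entropy reconstruction: each candidate mass M on a 0.5-Da grid is
scored by the summed interpolated intensity at `(M + z·1.00728)/z` across
the charge range, inside the acquired m/z window. Two safeguards address
the classic failure modes:

- the raw sum is weighted by the longest *consecutive* run of charges
  carrying signal (a real envelope is consecutive in z; a 2M harmonic
  matches only every other charge);
- components are extracted greedily, stripping each accepted component's
  predicted peaks before re-scoring, so an M/2 sub-harmonic — which matches
  the parent's peaks exactly — cannot survive its parent's extraction.

Over 50 seeded random masses in 7–40 kDa the median recovery error is
under 0.05 Da with no spurious components, comfortably inside the 1-Da
documentation claim.

Adduct assignment is an exhaustive lexicographic argmin over
(|residual|, adduct count) across all candidates × adduct multisets (≤1
myristoyl at +210.36 Da, ≤3 sodium at +21.98 Da), tolerance ±5 Da — chosen
because correctly assigned intact masses in this mass range sit within
~3 Da of their calculated values, while the smallest adduct step (one Na,
21.98 Da) is far larger, so the search cannot alias. All masses are
averages, not monoisotopic: at 30 kDa isotopes are unresolved on a Q-TOF
and the calculated values are sequence averages.

## Problem sizes and determinism

Every stochastic test fixes its seed, and the simulation entry points take
a `seed` so that identical inputs give bit-identical traces. The suite uses
traces of ~6,900 points, six-level calibration series, 50-spectrum
deconvolution sweeps and 20-replicate ordering checks; these sizes were
chosen as the smallest that exercise each claim meaningfully, and the whole
suite runs in under a minute.

## Known limitations

- The empty-fraction conversion `r/(1+r)` assumes the area ratio equals
  the particle ratio exactly; real samples with partially filled or
  aberrant particles violate the two-species model.
- The simplified VP0/VP2 ratio overstates the full-capsid denominator by
  the missing VP4 share (<1% on FLR), a negligible but systematic bias.
- Calibration assumes the standard and sample share the same per-capsid
  response; a serotype or formulation change requires recalibration.
- The deconvoluter assumes profile-mode spectra with roughly symmetric
  charge envelopes; centroided sticks should be broadened before use.
- Peak integration is not a curve-fitting deconvolution: co-eluting peaks
  closer than ~3σ are flagged by the generator but not separated by the
  integrator (the real assay's peaks are baseline-resolved).
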