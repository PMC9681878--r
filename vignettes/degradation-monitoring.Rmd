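---
title: "Methods: untargeted cannabinoid identification and CBD degradation monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted cannabinoid identification and CBD degradation monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannastab)
```

## The problem

Cannabidiol (CBD) dissolved in an e-liquid matrix degrades during storage.
The degradation products — cannabielsoin (CBE) and its stereoisomer,
mono- and di-hydroxylated CBD, the quinone HU-331 and related species —
are pharmacologically uncharacterised, so monitoring them matters more
than monitoring the loss of CBD itself, which changes only slightly over a
month. `cannastab` implements the full analysis path for this kind of
study on untargeted UHPLC–TIMS–TOF data: a feature (one detected species)
carries four measured dimensions — m/z, retention time, collisional cross
section (CCS) from ion mobility, and intensity — plus signal-to-noise and
optionally a linked MS² spectrum. The pipeline identifies features against
a reference library, classifies the remainder by diagnostic fragments,
removes in-source artifacts, and quantifies storage trends.

Because instrument data cannot ship with the package, a seeded generator
(`generate_day1()`, `generate_stability_study()`) emulates the study
design and returns the planted truth alongside the data, so every stage of
the pipeline is testable end to end.

## Exact-mass arithmetic

All isotope masses are pinned in-source (`C` 12 exactly, `H`
1.00782503207, `O` 15.9949146196, electron 0.00054858 Da, and so on), so
every theoretical value is reproducible without external lookups. The
adduct ion m/z is

```
ion_mz = (monoisotopic_mass + adduct_mass_delta - charge * electron_mass) / |charge|
```

with the electron-mass correction included; at the 4th decimal place it
matters for matching at ≤ 5 ppm. Deuterium is treated as its own element
so the D3-labelled internal standard's m/z (318.2507 for protonated
C21H27D3O2) is computed from composition, never hard-coded:

```{r}
ion_mz("C21H30O2", "[M+H]+")    # protonated CBD
ion_mz("C21H27D3O2", "[M+H]+")  # deuterated internal standard
```

Mass error is reported as `(observed - theoretical) / theoretical * 1e6`
ppm. Formula enumeration (`enumerate_formulas()`) is exhaustive within the
element bounds (default C 0–40, H 0–80, O 0–10, N/S off, RDBE 0–25):
carbon and oxygen are looped and the hydrogen count is solved from the
residual mass, so no candidate inside the bounds can be missed. The window
arithmetic carries a one-part-in-10⁹ guard so a candidate exactly on the
ppm boundary is never lost to floating-point rounding; the test suite
verifies exact set equality against an independent vectorised brute-force
oracle on random masses.

Isotope envelopes are simulated by per-element convolution with
exponentiation by squaring, binning peaks within 0.01 Da (the M+1
isotopologues of ¹³C, ²H and ¹⁷O merge into one peak at the
probability-weighted mean mass) and pruning below 10⁻⁴ of the base peak.
For C21H30O2 this gives an M+1 relative abundance of 0.2313 — slightly
above the 21 × 1.07 % ≈ 0.225 carbon-only estimate, because the ²H and
¹⁷O contributions are included. The convolution conserves total
probability to 10⁻⁹, which the tests assert.

## Five-criterion identification

A feature is matched against a library entry on five criteria with these
defaults:

| criterion | default threshold | rationale |
|---|---|---|
| exact mass | ≤ 5 ppm | routine TOF mass accuracy; hard gate |
| retention time | ≤ 0.2 min | run-to-run RT stability of the method |
| CCS | ≤ 2 % | TIMS reproducibility across days |
| isotope pattern | similarity ≥ 0.8 | tolerant of intensity noise on M+1 |
| MS² | cosine ≥ 0.7 | standard spectral-match floor |

The mass criterion is a hard exclusion: nothing outside 5 ppm is
considered at all. A feature is **validated** only when all five criteria
pass, and **putative** when the mass criterion plus at least one other
passes. Absent evidence — no measured CCS, no observed M+1, no MS²
spectrum — is a *failed* criterion, not a skipped one, so a feature can
never be validated by missing data. Candidates are ranked by number of
criteria passed, then |Δppm|, then |ΔRT|.

The isotope score is an abundance-weighted Jaccard (Σ min / Σ max over
matched peaks), which penalises both missing and extra peaks and is
symmetric. In the pipeline the observed envelope (a feature plus its M+1
companion features) is on the *ion* m/z scale while theory is computed
from the *neutral* formula, so `match_feature_shape()` aligns both
envelopes at their base peaks and scores shape only — absolute mass is
already the first criterion and should not be scored twice.

CCS deviation is `|measured - reference| / reference * 100`, with the
reference in the denominator: the comparison is deliberately asymmetric,
as the reference value is the calibrated anchor.

## Classifying the unknowns

Features without a validated match go through fixed-order rules:

1. **In-source artifacts first.** Electrospray in-source fragmentation
   produces MS1 peaks (typically `[M−H₂O+H]⁺`) that mimic real compounds.
   A child–parent pair is linked when the m/z difference matches a neutral
   loss within 5 ppm *and* the two features co-elute within 0.05 min —
   chromatographic co-elution is what separates an artifact from a genuine
   isobaric compound at another RT. Linked children are labelled
   `in-source-artifact` and never given a chemical class; a child with
   several co-eluting parents is reported ambiguous rather than resolved.
2. **Composition-only quinone rule.** An ion composition equal to
   HU-331's (CBD + O − 2H) at an RT far (> 0.5 min) from the HU-331
   reference entry is `HU-331-like`.
3. **Core by diagnostic fragment.** The olivetol ion m/z 193.1228 marks a
   CBD-type core; the 205.1224 + 135.0448 pair marks a CBE-type core; the
   homologated 207.1379 ion marks the CBDH family. The rules are checked
   most-specific first (CBE, then CBDH, then CBD) because CBDH-family
   spectra also contain the olivetol ion and would otherwise be swallowed
   by the CBD rule. The per-fragment tolerance is
   `max(0.005 Da, 10 ppm)`, wide enough to absorb the spread in quoted
   diagnostic masses (135.0442 vs 135.0448).
4. **Oxidation level by mass delta.** The feature's m/z minus the core
   parent's m/z selects +O (hydroxy), +2O (dihydroxy) or 0 (isomer). A
   hydroxylation label is only emitted when the implied formula is among
   the feature's own formula candidates at 5 ppm, and requires elution at
   least 0.3 min *before* the parent (more polar compounds elute earlier
   on a reversed-phase column) for high confidence; later elution drops
   confidence to low rather than discarding the call.

The two CBE stereoisomers have identical spectra at MS² level; they
separate only in pseudo-MS³ on the in-source water-loss ion, via the
intensity ratio of m/z 245.1540 to 231.1378
(`distinguish_cbe_stereoisomer()`, threshold 2). **Which direction of the
ratio is which stereoisomer is an instrument-calibrated convention, not a
derivable fact**, so the orientation is an explicit argument rather than a
constant — this is a deliberately open parameter.

## Degradation trends

Each sample is normalised to its deuterated internal standard
(`normalize_to_is()`; exactly one feature must match the IS m/z within
5 ppm and RT within 0.1 min — zero or several matches is an error, not a
guess). A feature is quantifiable when S/N ≥ 10 (the limit of
quantification; the boundary is inclusive). Per (compound, condition,
day), the trend table reports the mean and sd over quantifiable
replicates, and counts — never imputes — below-LOQ replicates. Isomeric
peaks of the same classified compound (e.g. the several OH-CBE peaks) are
summed per sample, mirroring how multi-peak degradants are reported.

Per compound × condition, the slope comes from ordinary least squares on
day, and the monotonicity verdict from a Mann–Kendall test implemented
internally: for n ≤ 10 without ties the p-value uses the *exact* null
distribution of the S statistic (computed by the classical
inversion-count recursion and cached), otherwise the tie-corrected normal
approximation with continuity correction. With 5 sampling days the exact
test is both feasible and preferable — the normal approximation is poor
at n = 5. Note a structural property: a degradant absent on day 1
contributes only 4 time points, whose smallest exact two-sided p-value is
2/4! ≈ 0.083, so it can never reach an α = 0.05 verdict; the slope
estimate is unaffected.

Source attribution uses marker sets: CBDV, CBDP, CBDH, 6a-OH-CBD and
7-OH-CBD mark plant-derived CBD; the CBDH isomer marks synthetic CBD;
CBDB, OH-CBE, HU-331 and HU-331-like occur in both and are never used as
discriminators.

## The packaged library

`default_library()` holds 39 entries: the 35 standards of the optimised
separation panel, the three later additions CBDH, CBDM and Δ9-THCH, and
the deuterated internal standard D3-Δ9-THC. The IS takes the 39th slot
because the pipeline needs its composition in the library anyway (its m/z
is computed, not hard-coded), and because 7-OH-CBD — the other candidate
for that slot — is already one of the 35 panel compounds, so listing it
twice would create a duplicate. Entry m/z values are always computed from
formula and adduct at load time. Retention times and CCS values that come
from the study's identification tables are pinned; everything else is a
synthetic placeholder and carries `provenance = "synthetic ..."` so users
and tests can tell the two apart. The same applies to MS² spectra: only
the diagnostic fragments are published, so non-diagnostic spectra are
generic placeholders.

## The generator and what it does (not) model

`generate_stability_study()` emits the full design — 4 storage conditions
× days 1, 8, 15, 22, 29 × 5 replicates — with:

- linear-with-floor kinetics
  `intensity(t) = max(0, base + slope(condition) × (t − 1))`, with default
  slopes encoding the study's qualitative orderings (CBE-type products
  grow fastest under stress and light, barely at 4 °C; HU-331 accumulates
  most refrigerated in the dark and photodegrades under light; OH-CBE
  peaks in the dark at ambient temperature);
- Gaussian m/z noise (sd 0.5 ppm), RT jitter (sd 0.02 min), CCS noise
  (sd 0.2 %), and mean-one lognormal intensity noise (CV 10 %), so
  intensity noise is multiplicative and unbiased;
- S/N = intensity / noise-floor (200), so slowly formed degradants start
  below the LOQ and cross it mid-study, exercising the gating logic;
- M+1 companion features at the convolved isotope abundance, and planted
  in-source water-loss children (at 0.2 × parent intensity, exactly
  co-eluting) for the di-hydroxylated and OH-CBE species.

Limitations, deliberately accepted: kinetics are linear rather than
first-order (over 29 days with small fractional CBD loss the two are
indistinguishable at the planted noise level); chromatographic peak
shapes, saturation and ion suppression are not modelled; replicate noise
is i.i.d. with no batch structure; only the water loss is planted as an
in-source channel. The defaults *are* the study conditions for the test
suite — they were fixed before the acceptance outcomes were inspected and
are not tuned.

## Problem sizes and runtime

A full single-source stability study is ~4000 features across 100
samples; generation takes about a second, annotation a few hundred
milliseconds per sample, and the complete test suite — including 40
seeded stability studies for ordering and parameter-recovery checks —
runs in ~2 minutes on one CPU. Formula enumeration over the default
bounds is a few milliseconds per mass; the exact Mann–Kendall null for
n ≤ 10 is cached after first use.
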