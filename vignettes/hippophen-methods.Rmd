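---
title: "Methods: models, estimators and design choices in hippophen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in hippophen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippophen)
```

`hippophen` implements the four bespoke quantitative pipelines used to
phenotype mouse models of altered hippocampal neurogenesis: Morris water
maze (MWM) swim-strategy classification with strategy-block segmentation,
multi-taper spectral analysis of paired local field potentials (LFPs),
neurite morphometry on traced reconstructions, and developmental-milestone
maturity scoring. This vignette documents the underlying models, the
parameters that matter, the numerical conventions, and the choices made
where the published protocols leave the design open. Every pipeline can be
exercised end to end on seeded synthetic data with attached ground truth.

## Swim-strategy classification

### Geometry and features

Trials live in pool-centered Cartesian coordinates (cm, y up) inside a
170-cm pool with a 12-cm escape platform. Analysis zones are: an 8-cm-wide
*outer ring* at the wall (thigmotaxis zone, boundary at radius 77 cm for
the default pool), the complementary *inner area*, a 30-cm *focal zone*
around the platform, a *central disc* of the same diameter at the pool
center, the four *quadrants*, and the *platform corridor* — the angular
sector of half-angle 20° centered on the release-point-to-platform line.
The corridor width is not part of the published rule set; 20° follows the
scheme this family of classifiers descends from and is a tunable
threshold.

`zone_fractions()` attributes each path step's length to the zone
containing its **start point**; boundary points belong to the inner /
left-closed zone, so attribution is deterministic and
`frac_outer_ring + frac_inner_area = 1` and `sum(frac_per_quadrant) = 1`
hold exactly. Trials sampled coarser than 0.2 s are resampled at 0.1 s by
linear interpolation first. Two derived scalars summarize path structure:

* *heading efficiency* — net displacement toward the platform divided by
  path length; 1 for a perfectly straight approach;
* *circularity* — |net angular progression| / total angular progression
  around the pool center (samples within 5 cm of the center are skipped
  because their bearing is ill-defined); 1 for sustained one-directional
  circling, about 0 for a random walk.

### The rule cascade

The published strategy definitions give distance-fraction cutoffs
(thigmotaxis > 70% in the outer ring, inner-area strategies > 80% inside
it, directed search > 60% and direct swim > 80% in the corridor) but no
arbitration order, and the printed scanning / random-swim definitions are
partially garbled. `classify_trial()` therefore applies a deterministic
cascade from most to least specific — DSw, FS, DS, Tt, Ch, Sc, RS, else
Unclassified — with every rule parameterised in
`strategy_thresholds()`:

| label | rule (defaults) |
|---|---|
| DSw (direct swim) | corridor fraction > 0.80 **and** heading efficiency ≥ 0.70 |
| FS (focal search) | focal-zone fraction > 0.50 |
| DS (directed search) | corridor fraction > 0.60 **and** heading efficiency ≥ 0.30 |
| Tt (thigmotaxis) | outer-ring fraction > 0.70 |
| Ch (chaining) | circularity > 0.70 and mean radius within 25% of the platform's orbit radius |
| Sc (scanning) | inner fraction > 0.80, no quadrant > 0.50, circularity ≤ 0.70, central-disc fraction ≥ 0.12 |
| RS (random swim) | inner fraction > 0.80 (balanced-but-unstructured remainder) |

Three of these parameters deserve justification because they are not in
the published text:

* **Efficiency floors.** Seen from a release point on the wall, the ±20°
  corridor sector covers roughly a fifth of the pool area, including the
  pool middle, so undirected inner-area swims routinely accumulate > 60%
  of their distance "in the corridor". Directed search and direct swim
  are *directed*: they make net progress toward the platform. The cascade
  therefore demands heading efficiency of at least 0.30 (DS) and 0.70
  (DSw); the latter also separates a straight swim from a
  corridor-confined zigzag.
* **Scanning's central coverage.** The recoverable content of the garbled
  scanning definition is: inner-area swimming, balanced across quadrants,
  non-circular, with genuine sampling of the central region. "Genuine" is
  operationalised as ≥ 0.12 of swim distance inside the 30-cm central
  disc — about four times the chance level, since the disc is
  (15/85)² ≈ 3.1% of the pool area. Random swims hover at chance.
* **Random-swim balance clause.** The printed "not below 50% for none of
  the quadrants" double negative is interpreted as a balance condition
  (no quadrant above 50%) and attached to scanning; random swim is the
  unstructured remainder of the inner-area rule, which keeps the pair
  exhaustive.

Chaining is excluded from both strategy blocks because the block
definitions name only six strategies.

### Blocks

Block 1 comprises the non-hippocampal-dependent strategies (Tt, RS, Sc),
block 2 the hippocampal-dependent ones (DS, FS, DSw). `assign_blocks()`
establishes a block at the first run of ≥ 3 consecutive same-block trials
(`min_block_run`), dated from the run's first trial. The published rule
states only establishment; persistence is resolved as: an established
block holds until the *other* block is established by the same rule, so
relapses shorter than the run length do not reset it. Block-less trials
(Ch, Unclassified) interrupt runs but inherit the current block in the
timeline. The implementation is verified against an exhaustive
run-scanning oracle over every label sequence of length ≤ 8.

### Zone occupancy

`reversal_quadrant_times()` (time in the new vs old platform quadrant
after reversal) and `zone_occupancy()` (open-field center,
elevated-plus-maze arms, average velocity) share the same step-start
attribution and deterministic boundary conventions; quadrant boundaries
are left-closed in angle.

## Multi-taper LFP spectra and coherence

### Estimator

Recordings (protocol: 1000 Hz for 100 s per channel) are cut into 1-s
demeaned, non-overlapping segments — no further detrending or notch
filtering, since acquisition-side band-pass filtering is assumed — and
expanded on DPSS (Slepian) tapers with time-bandwidth 3 and 5 tapers, the
defaults of the MATLAB toolbox ecosystem this analysis style comes from.
The tapers are computed from the standard symmetric tridiagonal
eigenproblem (no R package on the system provides them) and validated by
orthonormality and spectral-concentration tests.

PSD: per segment and taper, power is the squared modulus of the FFT of
the tapered segment; averaging runs over tapers then segments, and the
one-sided per-bin spectrum is reported as `10 log10(power)` on the
1-Hz grid (1-s segments, no zero padding), restricted to 1–90 Hz.
The linear-scale one-sided spectrum sums to the signal variance
(Parseval), which fixes the scaling unambiguously; near-silent bins are
floored at 1e-20 before the log, with a warning, rather than returning
−Inf. Band means are formed on the linear scale and converted to dB.
Absolute PSD level depends on referencing and amplifier gain, which are
not modelled; coherence is invariant to both.

Coherence: cross- and auto-spectra are averaged over tapers **and**
segments before forming `|Sab|² / (Saa Sbb)` (the `average = "pooled"`
default). This gives roughly `n_tapers × n_segments` degrees of freedom
and a null bias of about their inverse (≈ 0.002 at 5 × 100). The literal
alternative — a magnitude-squared coherence per segment, then averaged —
is available as `average = "per_segment"` but carries a positive bias of
about `1/n_tapers` (0.2 at 5 tapers) under independence, large enough to
swamp genuine weak coupling; it exists for comparability, not for
inference.

Frequency bands are delta 1–4, theta 4–12, beta 12–20, low gamma 20–40
and high gamma 40–90 Hz, half-open `[lo, hi)` with the final band closed
at 90 Hz, so each shared edge belongs to exactly one band.

### Resolution bias at band edges

The 5-taper, time-bandwidth-3 estimator smooths spectra over ±3 Hz. At a
frequency where only a fraction ρ of the smoothing window overlaps a
coherent band, the estimate converges to `(ρ γ/(1+ργ))·(…)` rather than
the in-band value — for the symmetric SNR-1 model, `(ρ/(1+ρ))²` instead
of 0.25, i.e. 0.11 at a band edge where ρ = 0.5. Consequently the *mean*
over a band whose edges coincide with the source band's edges sits
noticeably below the closed-form plateau (for an 8-Hz band, the two edge
bins on each side are degraded), while bins well inside the band converge
to the closed form. The test suite therefore checks closed-form recovery
at interior bins, and users comparing narrow-band means against
theoretical coherences should expect this edge shading; it is a property
of the estimator's bandwidth, not an implementation artifact.

### The synthetic LFP model

`gen_lfp_pair()` draws `x = s + n1`, `y = α s + n2` with `s` band-limited
Gaussian noise (frequency-domain shaping: coefficients outside the source
band zeroed, half-open band convention matching the analysis bands) and
independent white noise per channel, scaled so the in-band per-Hz
source/noise ratios equal `snr_a`, `snr_b`. The magnitude-squared
coherence is then exactly
`snr_a/(1+snr_a) · snr_b/(1+snr_b)` in band and zero outside, attached as
ground truth. The model reproduces the coherence structure of coupled
recordings but none of the nonstationarity, 1/f background, line noise or
volume conduction of real LFPs — passing recovery tests validates the
estimator, not robustness to those artifacts.

## Neurite morphometry

Reconstructions use SWC semantics (whitespace-delimited text, one root,
`#` comments, unknown structure codes accepted). Dendritic length is the
sum of parent-child segment lengths, excluding soma-internal segments by
default. Sholl analysis counts segment crossings of spheres at 20-µm
radius increments centered on the soma node (for planar tracings this
reduces to the classical circles); where a published analysis centers on
the soma centroid instead, results can differ for multi-node somas — here
the root/soma node is the center, taken as given. Crossings are solved
analytically from the segment-sphere quadratic, so a chord dipping into a
sphere and out again counts twice; a node exactly on a sphere counts with
its outward-going segment only; tangencies do not count. These tie rules
make the profile exact and rotation/translation-invariant, verified
against a dense-sampling oracle (points every 0.01 µm, sign changes of
`d − r`).

Laminar-reach classification of immature (DCX-positive) cells takes the
layer boundaries (granule-cell layer → inner molecular layer →
medial/outer molecular layer) as per-cell radial distances read from the
image; a cell is *long* only if its maximal radial reach strictly exceeds
the IML/M-OML boundary, *short* otherwise, and *unclassifiable* if it
never leaves the granule-cell layer. Cell density is count divided by
region area (cells/mm²), with colocalisation decisions upstream.

## Developmental milestones

Daily scores over P1–P21 are binary (0/1) or graded (0–3; eye opening
0–2). The maturity day is the final day of the first run of the required
number of consecutive criterion days; the protocol text does not say
whether the first or last day of the run is registered, so the convention
is configurable (`registered = "final"` default, documented). The
per-test defaults — which tests carry the 3-consecutive-day rule — are
inferred from the protocol descriptions and shipped in
`default_milestone_rules()`, all overridable. Group summaries report the
median maturity day over animals that reached criterion (even group
sizes: mean of the middle pair), with never-reaching animals counted
separately rather than imputed. The Mann-Whitney U statistic is computed
from ranks with ties counted as half, reported as
`min(U, n1 n2 − U)`; p-values are left to `stats::wilcox.test`.

`gen_milestone_table()` draws one set of base maturity days and applies
the group shift to the second group (matched construction), so noise-free
group median differences recover the shift exactly; with score noise the
attached ground truth is only approximate, which is why recovery tests
run at `noise = 0`.

## Swim-path generators

Each generator produces the geometric signature of one strategy well
inside the classification thresholds, at 0.1-s steps and a nominal
18 cm/s swim speed (a realistic mouse swim speed): wall-following in the
outer ring (Tt), a reflected persistent random walk over the inner area
(RS), quadrant-balanced waypoint visits routed through the pool center
(Sc), constant-radius circling at the platform's orbit (Ch), a ±70°
zigzag toward the platform (DS, path ≈ 1.6× direct, efficiency ≈ 0.6),
an approach plus confined wander in the focal zone (FS), and a
near-straight release-to-platform swim (DSw). Release points are drawn
from the four compass positions. The generators emulate zone geometry,
not mouse locomotor dynamics: real trajectories show variable speed,
wall-biased turning and tracking noise that these paths lack, so
classifier recovery rates on synthetic paths bound idealised, not field,
performance.

All generators are pure functions of their parameters and an explicit
seed, run on a private RNG stream, and restore the caller's stream.

## Numerical conventions and test scale

All randomised tests fix seeds. Degenerate inputs fail loudly: stationary
trials, all-zero signals, zero-power segments, zero region areas and
day-gapped milestone series are errors, not silent NA propagation.
Protocol-scale checks use 1000 Hz × 100 s recordings (100 segments),
200 generated trials per strategy, all 9840 block-label sequences of
length ≤ 8, 100 random reconstructions against the dense Sholl oracle and
500 random sample pairs for the U statistic; these sizes keep the full
suite under two minutes on one core while leaving Monte-Carlo margins
well clear of the asserted tolerances.

## Known limitations

* Strategy thresholds beyond the published cutoffs (corridor half-angle,
  efficiency floors, scanning central coverage, chaining tolerance) are
  package choices; alternative settings may be needed to match other
  laboratories' classifiers.
* Band means adjacent to sharp spectral edges are shaded by the
  estimator's ±3 Hz bandwidth (see above).
* PSD absolute level is arbitrary-gain; only within-setup comparisons
  are meaningful.
* Sholl centering uses the soma node, not a reconstructed centroid.
* Milestone ground truth under score noise is approximate by design.
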