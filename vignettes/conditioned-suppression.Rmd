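---
title: "Methods: conditioned-suppression scoring, tinnitus inference and percent-area immunoreactivity"
author: "tinnscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditioned-suppression scoring, tinnitus inference and percent-area immunoreactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinnscreen)
```

# The behavioral assay and its statistic

In the conditioned-suppression paradigm a rat lever-presses for food under
ambient broad-band noise (BBN, 60 dB SPL). Pressing during 1-min
*speaker-off* periods is punished, so whatever the animal experiences
during speaker-off — silence, or its tinnitus — acquires inhibitory
control over pressing. Ten 1-min probe periods are embedded in each
60-min daily session (two of them always speaker-off, the rest tones or
BBN at 30–90 dB SPL); probes resembling the speaker-off percept suppress
pressing.

Behavior is scored by the running suppression ratio
$R = B/(A+B)$, where $A$ is the press count of the preceding 1-min epoch
and $B$ of the current one. $R$ is insensitive to slow motivational
drift (satiation) but sensitive to stimulus-locked rate changes, which is
precisely what makes it the right index for 1-min probes.

Numerical conventions adopted here, applied everywhere downstream:

- **Epochs** are half-open intervals $[60k, 60(k+1))$ seconds; a press at
  exactly 60.0 s belongs to minute 1.
- **$A + B = 0$** leaves $R$ undefined. It is carried as `NA` and
  excluded from every mean; any imputation (0, 0.5, 1) would bias the
  statistic in a different direction and none is defensible.
- **Minute 0** has no preceding segment and is always undefined.
- **QC boundaries are inclusive**: a session with exactly 200 presses, or
  a mean background $R$ of exactly 0.4, passes ("minimum of" / "at
  least").
- **"Background" for QC** means background-BBN minutes excluding probe
  minutes *and* the minute immediately following a probe, whose $A$ count
  is contaminated by the probe response. This is the conservative reading
  of averaging "during background"; it removes ten or fewer minutes per
  session and makes the criterion a pure measure of baseline behavior.

# The generative session model

The simulator exists to give every estimator in the package a known
ground truth: a latent severity parameter that a real experiment cannot
observe, but that simulated inference must recover.

Each animal carries a latent tinnitus severity $\tau \in [0,1]$ (0 for
all unexposed animals), a tinnitus pitch (default 20 kHz, the diagnostic
frequency after high-frequency octave-band exposure), a background press
rate $\lambda_{bg}$ and a trained suppression depth $c_{off} \in [0,1]$.
Per-minute press counts are Poisson with rate

$$\lambda = \lambda_{bg}\,(1 - c_{off}\, S),$$

where $S$ is the perceived similarity of the minute's stimulus to the
punished (speaker-off) percept, and press times are uniform within the
minute. $S$ mixes two channels by severity:

$$S = (1-\tau)\, S_{sil}(L) + \tau\, S_{tin}(f, L),$$

- $S_{sil}(L) = \mathrm{logit}^{-1}((L_{50}^{sil} - L)/s_{sil})$ —
  a quiet stimulus resembles silence, a loud one does not. Defaults
  $L_{50}^{sil} = 40$ dB SPL, $s_{sil} = 5$ dB/logit.
- $S_{tin}(f, L) = \max\{\phi,\; e^{-\Delta^2/2\sigma^2}\,
  \mathrm{logit}^{-1}((L_{50}^{tin} - L)/s_{tin})\}$ with $\Delta$ the
  distance in octaves from the tinnitus pitch — a Gaussian pitch kernel
  ($\sigma = 0.5$ octave) times a level admission window (the percept is
  faint; defaults $L_{50}^{tin} = 80$ dB, $s_{tin} = 10$ dB/logit).
  Broad-band noise receives only the kernel floor $\phi = 0.05$.
- Speaker-off has $S = 1$ identically: by construction, whatever is
  experienced then is the punished percept.

Two deliberate structural properties follow. First, because the tinnitus
window is shallower and right-shifted than the silence channel
($ (L_{50}^{tin}-L)/s_{tin} \ge (L_{50}^{sil}-L)/s_{sil}$ for all
$L \ge 0$), at the tinnitus pitch $S$ is non-decreasing in $\tau$ at
every testing level, so greater severity never *increases* the expected
probe press rate — the monotonicity that makes severity recoverable from
mean 20 kHz $R$. Second, BBN probes are nearly severity-blind (floor
only), reproducing the qualitative pattern that BBN discrimination
functions do not separate exposed from unexposed animals while 20 kHz
functions shift down.

Cohort defaults mirror the canonical design: 24 exposed + 16 unexposed
animals, 10 sessions each. Severity for exposed animals is drawn from a
Beta(2, 1) (most exposed animals develop some tinnitus, with a broad
spread — consistent with roughly two-thirds showing prominent evidence);
$\lambda_{bg}$ is log-normal with median 15 presses/min and log-SD 0.5,
so the press-count QC criterion has non-trivial action across animals;
$c_{off} = 0.85$ reflects deep but imperfect trained suppression. The
assay protocol never states base rates or suppression depth; these
are configuration choices about the simulator, not claims about any real
animal. Probe schedules place whole non-adjacent 1-min probes uniformly
among interior minutes via the standard non-adjacent-subset bijection, so
every admissible placement is equally likely and every probe is preceded
by a background minute (a clean $A$).

What the generator does *not* emulate: acquisition and extinction of the
suppression response (only steady-state discrimination), within-session
drift, inter-press refractoriness or bout structure, and any auditory
periphery (no ABR, no threshold shift). Passing tests therefore validate
the estimators under a stationary Poisson world, not the full richness of
operant behavior; conclusions about real data rest on the statistic, QC
and inference machinery, not on the rate model.

# Inference

Discrimination functions give every animal equal weight: per-animal mean
$R$ by stimulus and level first, then the group mean and SEM across
animals; the speaker-off point is carried with level `NA` and ordered
first. Animals' means in turn weight all their QC-passing probe minutes
equally (the protocol does not fix how many sessions feed a mean; the
package uses all passing sessions).

The subgroup rule ranks exposed animals ascending by mean 20 kHz probe
$R$: the lowest 16 of 24 are "prominent tinnitus" (then split 8/8 at
random, seeded, into antagonist/no-drug arms); the remaining 8 are "weak
tinnitus". Ties are broken by animal id, so classification is a pure
function of the data and the seed; permuting input order cannot change
membership.

Group comparison is a classical two-way mixed (split-plot) ANOVA — group
between subjects, presentation level within, fitted by sums of squares
via `stats::aov` with an `Error(animal)` stratum — not a modern
mixed-effects likelihood. That matches the F/df reporting style of the
assay's literature. Speaker-off rows are excluded before fitting, no
sphericity correction is applied (none is reported in this literature),
and that fact is recorded on the output. Unbalanced *empty* cells are
refused with their names rather than silently dropped. The test suite
checks the implementation against an independent textbook
sums-of-squares oracle on all balanced designs up to 3 groups × 4
levels × 5 subjects (tolerance 1e-10).

IHC group contrasts use uncorrected independent two-sample t-tests
(equal variance, two-sided) — deliberately no multiple-testing machinery,
matching the analysis convention the package reproduces. The degenerate
all-constant case returns $t = 0, p = 1$ for equal means.

# Percent-area immunoreactivity

Micrographs are single-channel rasters (3-channel input is converted by
Rec. 709 luminance) with a boolean area-of-interest (AOI) mask and a
pixel-area calibration. The original workflow thresholded each image
visually; the package keeps the *per-image adaptation* but makes it
reproducible: the threshold is computed per micrograph from AOI pixels
only, by exact Otsu — between-class variance maximized over every split
between distinct observed intensities, midpoint threshold — with
percentile and fixed-value overrides, and the value used is logged for
audit. Midpoint thresholds on the empirical values make the stained mask
exactly equivariant under positive affine intensity rescaling (brightness
and gain changes), which is the property that justifies automating a
"visually adjusted" step. Staining is dark-on-bright, so the mask is
$I < t$.

Particle analysis labels 8-connected components (corner-touching pixels
connect — the common particle-tool default; the labeler is validated
against a brute-force flood fill), intersects them with the AOI, and
excludes components touching the raster border (section edges,
border-hugging blemishes) and components contributing fewer than 4 px
(configurable) inside the AOI. Percent area is
$100 \times \text{stained px} / \text{AOI px}$ — invariant to pixel-area
calibration, while absolute stained area scales with it. Percent area,
not particle count, is the primary measure: overlapping somata make
counts unreliable in densely stained regions, whereas area fraction is an
unbiased density proxy. Both are reported.

The synthetic micrograph generator produces bright backgrounds
(mean 0.8) with Gaussian pixel noise (SD 0.03), dark non-overlapping
disk somata (radius 3–6 px, contrast 0.55) and optional border-hugging
blemish disks, and records the exact stained fraction by pixel-counting
the noiseless particle mask within the AOI. The default raster is
200 × 200 px with an 8-px AOI inset: at the default group fractions
(8% exposed vs 4% unexposed) an AOI then holds ~38 vs ~19 particles,
putting per-animal counting variability (CV ≈ 16–23%) in the realistic
range for low-magnification DAB sections, which carry dozens of stained
somata per region. Per-animal particle counts in the cohort generator
are Poisson around the target density, so group contrasts face genuine
between-animal variance. It does not emulate uneven illumination,
out-of-focus blur, partial staining gradients within somata, or genuinely
overlapping cells — so recovery within ±1 percentage point on these
images bounds segmentation error only under well-separated staining.

# Relative diffusion from molecular weights

For the dye-vs-drug diffusion argument the package scales diffusion
coefficients as $D \propto MW^{-e}$ with $e = 1/3$ by default
(Stokes–Einstein: $D \propto 1/r$ and $r \propto MW^{1/3}$ for compact
molecules), pooling a cocktail as the mean of member coefficients. With
the printed molecular weights (dye 374; cocktail mean 201) this gives
$D_{dye}/D_{cocktail} = (201/374)^{1/3} \approx 0.813$. The source
literature quotes 85% for this comparison without stating its equation or
per-compound weights; $e = 1/2$ gives ≈ 0.73, so no simple power law
reproduces 85% exactly from the mean weight alone. The package documents
the discrepancy, exposes the exponent, and asserts only its own
convention (ratio < 1 whenever the reference is heavier; invariance under
common rescaling of all weights).

# Problem sizes and runtime choices

The validation suite sizes its simulations to what the properties need
rather than to the full study: Monte-Carlo rate checks use ~10,000
simulated minutes (3-standard-error bands); severity recovery uses the
canonical 24 exposed animals × 10 sessions; ANOVA power uses 200
replicates of 8-vs-8 cohorts with 4 tone-only sessions per animal;
IHC power uses 200 replicates of the 4-vs-3 design at one micrograph per
animal. Oracle-equivalence checks run 1,000 random sessions (running-$R$
vs direct formula, exact), 1,000 random rasters up to 12 × 12
(labeling vs flood fill, exact) and randomized balanced ANOVA designs
(1e-10). All stochastic tests run under fixed seeds; every simulation
API takes an explicit seed and is byte-reproducible.

# Known limitations

- The similarity kernel is a minimal stand-in for perception: logistic
  in level, Gaussian in log-frequency, a single pitch. Multi-peaked or
  noise-like tinnitus percepts are not represented.
- The Poisson press model has no serial dependence; real operant streams
  are bursty. QC and $R$ are rank-based enough that this mainly affects
  dispersion, not bias, but power numbers transfer only approximately.
- The mixed ANOVA assumes sphericity (uncorrected), as does the
  convention it reproduces.
- Percent-area recovery degrades when somata genuinely overlap or
  illumination varies across the AOI; the generator deliberately avoids
  both, and the ±1-point recovery bound holds only in that regime.
- The diffusion estimate is an order-of-magnitude argument, not a
  transport model: no tortuosity, charge, or tissue binding.
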