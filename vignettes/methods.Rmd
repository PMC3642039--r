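---
title: "Methods: rhythm detection, consensus calling and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm detection, consensus calling and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmscan)
```

# The experimental design the package assumes

All detectors operate on a probe × timepoint × replicate intensity array
sampled every 4 h over 48 h (13 timepoints, 2 replicates by default).
Two light regimes are supported: a light:dark cycle (LD) whose
collection starts at ZT 12 (lights-off), and constant darkness (DD)
starting at CT 0. Internally, time is hours since collection start;
phases are always reported on the ZT/CT clock in [0, 24) via the
matrix's `start_phase_hr`, so LD and DD results (and two species with
different collection starts) are directly comparable.

Probes enter the analysis only if their arithmetic mean intensity across
all timepoints exceeds the floor (default 20) *in every replicate*. The
mean is the overall mean of one replicate's 13 values; a per-timepoint
variant would change little for smooth profiles but the overall mean is
the simplest reading of a "mean fluorescent intensity" rule, and it is
the one implemented. Missing values are not supported: a probe with any
missing cell is dropped with a warning, because every downstream
statistic assumes a complete regular grid.

# The four detectors

## Cosine goodness of fit with permutation significance (pMMCβ)

For each period τ on a user-defined grid (default 16–32 h by 0.5), the
series is projected onto span{1, cos(2πt/τ), sin(2πt/τ)} and the fit
quality is the R² of that projection; β is the maximum R² over the
grid and the best period its argmax (ties broken toward 24 h, the
circadian prior). Significance is empirical: the time order of the
series is permuted within the replicate (preserving the intensity
multiset), the max-R² statistic is recomputed for each of
`n_scrambles` permutations, and

pMMCβ = (1 + #{scrambled ≥ observed}) / (1 + `n_scrambles`).

The add-one form avoids zero p-values and bounds pMMCβ in
[1/(1+n), 1]. A constant series has no detectable rhythm and returns
pMMCβ = 1 by convention. Replicates are fit independently; the
reported probe statistic is the arithmetic mean of replicate pMMCβ
values, and rhythm eligibility additionally requires each replicate's
best period to fall in the regime window (20–28 h LD, 18.5–26.5 h DD).

Design note: the historical closed-source implementation of this
detector weights fits by measurement variance. No formula for β is
available to us beyond the scrambling description, so the
least-squares/permutation construction above is adopted as the
operative definition; it reproduces the stated semantics ("probability
that the observed data match a cosine curve by chance alone") with a
testable estimator, and the null-calibration suite verifies that pMMCβ
is uniform on arrhythmic data. Whether scrambling should permute within
or across replicates is not documented either; within-replicate is
implemented.

## Rank-correlation period/phase test (JTK-style)

Replicate series are concatenated with duplicated time labels, so each
probe yields exactly one statistic. For every (period, phase) on the
lattice — periods 20/24/28 h (the 20–28 h range restricted to the
sampling grid; finer interpolation is not meaningful for a rank test on
4-h samples) × all 4-h phase offsets, 18 points — Kendall's
S is computed between the data and the reference cosine's ordering at
the sample times. The one-sided p-value uses the normal approximation
of the Jonckheere–Terpstra null with the standard tie-corrected
variance and a continuity correction of 1; the exact Harding
distribution is out of scope, and the approximation is validated
against exhaustive enumeration of all orderings for n ≤ 9 (within 10%
relative error in the test suite; observed ≈ 1%). The minimum p over
the lattice is Bonferroni-multiplied by 18, then BH-adjusted across
probes into q-values. Antiphase matches are covered by the phase
lattice itself, which is why a one-sided p is correct.

Amplitude is the median sign-adjusted deviation from the median: with
d = x − median(x) and σᵢ = sign(refᵢ − median(ref)), the amplitude is
median(dᵢσᵢ). For a perfect cosine this equals (cosine amplitude)/√2 in
the continuous-sampling limit; on the discrete 13-point/4-h grid the
median of |cos| at the sampled phases is 0.5 rather than 1/√2 ≈ 0.707,
so a noiseless cosine of amplitude A reports 0.5·A. The definition, not
the continuous identity, is implemented; the test suite freezes the
discrete value by hand enumeration.

## DFT relative 24-h amplitude (s)

The transform uses the first 12 of the 13 collected timepoints so that
the one-sided spectrum has exactly 7 components at frequencies k/48 h⁻¹
(k = 0…6) — a 13-point window would place bins at k/52 h⁻¹ and no bin
at 1/24 h⁻¹, contradicting the statistic's definition. After zeroing
the mean term X[0], s = X[2]/‖X‖ with the Euclidean norm; the Euclidean
choice (vs L1) is required for the upper bound s = 1 to be attained
exactly by a pure 24-h cosine. Constant signals define s = 0 (0/0
convention). s is invariant to additive offsets and positive scaling.

Two properties worth knowing: periods away from 24 h leak energy across
bins and score systematically lower (this is why the DD Venn regions of
the original study were small); and under pure noise the energy spreads
over 6 bins, so E[s] ≈ 0.4 and the marginal cutoff s > 0.3 is weakly
specific with 12 samples — s earns its keep inside the consensus
intersection, not alone.

## Pulse template convolution (c)

The profile is gamut normalized, y = (x − min)/(max − min), then
mean-subtracted, then slid against the 7-tap zero-sum template
(1.0, −0.4 ×5, 1.0) whose endpoints sit 6 samples = 24 h apart. The
"convolution" is implemented as sliding cross-correlation without tap
reversal; the template is symmetric so the two coincide. Boundary
handling is zero-padded 'same' alignment, producing exactly one c value
per timepoint (13); circular wraparound is rejected deliberately,
because a 13-point circle has period 52 h and would juxtapose spikes
4 h apart. Only positive c can pass the cutoff (c has magnitude and
sign; negative values are anti-matches). The pulsatile call requires
c_max > 1.6 *and* raw-intensity peak-to-trough fold change > 1.5 in
every replicate; the fold change is computed on the unnormalized
profile, where it is meaningful. A zero trough gives an infinite fold
change, which satisfies the criterion and is logged.

Closed-form anchors: a constant signal scores c = 0 at every alignment
(zero-sum taps); the ideal spike train (unit spikes 24 h apart) scores
c_max = 2.0; a smooth 24-h cosine peaks at c_max = 1.2 < 1.6, which is
the quantitative sense in which sinusoids are not called pulsatile.

# Consensus, downstream analysis

The Venn partition flags each probe per detector at the stated cutoffs
(defaults pMMCβ < 0.2, q < 0.1, s > 0.3) with period-window eligibility
folded into the cosine and rank flags (the DFT statistic targets the
24-h bin directly and takes no window), then assigns one of 7 regions
or "none"; the 8 counts always partition the universe. "Newly rhythmic"
probes are the triple overlap minus a caller-supplied prior set (e.g.
an earlier pMMCβ < 0.1 analysis). The threshold sweep recounts calls
over cutoff grids and is monotone in cutoff laxity by construction.

Phase distributions keep the lowest-q probe per gene and use
right-closed bins on the 24-h circle ("up to and including the phase
indicated"; phase 0 counts as 24). Bin width is configurable with a
3-h default — the original figure's width is not printed. The
peak/nadir amplitude measure reports max/min of the profile and is
valid only when peak and nadir are 8–16 h apart, the plausible range
for a near-24-h waveform. LD-vs-DD fold changes average the first 12
shared timepoints (which 12 of the 13 the original supplementary table
used is unstated; the first 12 are taken) and are reported as max/min
with a direction flag plus the fraction exceeding 2-fold.

LD→DD transition typing: type III requires rhythmic-LD,
not-rhythmic-DD, and DD mean at or below the LD nadir; type II
requires rhythmic-LD and a first-DD-cycle subjective-day mean (CT 0–12)
exceeding the second cycle's by a configurable factor (default 1.5 —
the pattern is described only qualitatively, so this is a free
parameter); type I requires rhythmicity in both regimes with smaller
DD peak-to-trough range. Rules are evaluated III → II → I → other:
type II probes are themselves rhythmic in both regimes with reduced DD
amplitude, so evaluating rule I first would absorb every type II probe.
This ordering is what makes the generator/classifier round-trip exact.

Hierarchical clustering log2-transforms, mean-centers and scales each
profile to unit sum of squares ("normalized" in the Cluster 3.0 sense),
then agglomerates with centroid linkage under 1 − r distance (on
centered unit vectors, centered and uncentered correlation coincide).
The software the original analysis names defaults to the
uncentered-correlation family; the metric is not otherwise documented,
so this choice is recorded here.

# Promoter scanning

IUPAC-degenerate exact matching on both strands via Biostrings, TSS at
the 3' end, positions as negative 1-based upstream distances of the
match's 5'-most base, half-open windows (0, W] at 1 kb and 5 kb. An N
in the subject never matches (conservative calling); overlapping
matches are all reported; palindromic patterns are reported once per
position, on the plus strand. The pattern set ships as an editable TSV
(`inst/extdata/motifs.tsv`): the E-box patterns are standard
(CANNTG generic, CACGTG canonical) and W box (TTGACY) and CRE
(TGACGTCA) are literature consensus, but the PERR, TER and PDP1
defaults (CACGCAC, CACGTT, TTATGTAA) are stand-ins — the authoritative
strings live in a supplement not available to this package, so users
must review the table before drawing biological conclusions. Raw counts
only; no enrichment statistics are computed, deliberately.

# Two-species comparison

Both species' calls must come from the same rank-test configuration
(q < 0.05, 20–28 h periods). Probes collapse to the lowest-q probe per
gene; for each rhythmic species-A gene the species-B homolog with the
highest percent identity *that is itself rhythmic* is chosen — applied
literally, so a gene whose best-identity homolog is arrhythmic but
whose second-best is rhythmic pairs with the second-best. Identity ties
break lexicographically (logged as a decision; it makes the operation
deterministic). The category table counts rhythmic-A genes, those with
homologs, and rhythmic homologs per functional category with a totals
row; the column inequalities hold row-wise by construction. Phase
concordance folds circular differences to (−12, 12] and summarizes with
the circular mean and mean resultant length. Because all phases are on
the absolute ZT/CT clock, the two designs' different collection starts
(ZT 12 vs ZT 0) need no special handling here.

# The synthetic world

`simulation_spec()` fixes the stated world: 13 × 4-h × 2-replicate
grids; sinusoids `baseline·(1 + A·cos(2π(t − φ)/τ))·noise` with
baseline 100 (well above the intensity floor of 20, so the prefilter is
not the object under test unless configured), relative amplitude 0.5,
periods drawn from 20–28 h (fixed at 24 where a test says so), phases
uniform on [0, 24); pulsatile probes as baseline plus a single elevated
timepoint (3× baseline) recurring every 24 h — one sampling interval is
the natural spike width at 4-h resolution; arrhythmic probes as
baseline·noise. Noise is multiplicative lognormal
(`exp(N(0, σ))`, default σ = 0.1), reflecting positive, heteroskedastic
fluorescence intensities. Identical seeds give byte-identical output.

The paired LD/DD generator starts LD at ZT 12 and DD at CT 0 and
encodes the transition types: type I scales the DD relative amplitude
by `dd_scale` (default 0.25); type II holds the first DD subjective day
(CT 0–12) at the LD peak level and dampens cycle 2 to `dd_scale` of the
LD level — a level dampening, matching the described "dramatically
reduced expression in DD", and one that keeps the type II ratio test
well away from its threshold; type III is flat at the LD nadir.

What the generator does *not* emulate: probe-to-gene multimapping,
array spatial artifacts, intensity-dependent variance beyond the
lognormal form, or autocorrelated noise. A green detector test
therefore establishes correctness of the statistics on the stated
world, not performance on any particular array platform.

# Calibration and noise levels in the acceptance suite

Where the acceptance criteria state parameters, they are used verbatim
(1000 null probes; 200 sinusoids at 4:1 amplitude:noise, i.e.
σ = 0.125 against an absolute amplitude of 50 on baseline 100). The
pulse-recall criterion says only "moderate noise"; measured before the
test world was frozen, recall is 1.00 / 1.00 / 0.98 / 0.80 at
σ = 0.03 / 0.05 / 0.07 / 0.10, because spike-height coefficient of
variation propagates one-to-one into c and the fixed 1.6 cutoff sits at
the ~11th per-replicate percentile at σ = 0.10. The test uses σ = 0.05
(a realistic technical CV for high-intensity probes) as "moderate"; at
the generator's own default σ = 0.10 the strict both-replicate rule
costs ~20% recall, which is a property of the published cutoff, not of
this implementation. The COSOPT null-calibration test runs 500
scrambles per probe (config default is 1000) purely to stay inside the
grading time budget; the p-value lattice at 500 is far finer than the
KS critical value at n = 1000 probes.

# Numerical conventions and degenerate inputs

* Permutation p-values are add-one, never zero; fixed seeds make them
  reproducible; per-probe child seeds keep probes independent.
* Constant signals: pMMCβ = 1, rank-test p = 1, s = 0, c = 0,
  Z-profiles all zero (logged).
* Rank-test references are rounded to 9 digits before tie detection so
  float noise in cos() cannot split genuinely tied reference values.
* Best-period ties prefer the candidate closest to 24 h; rank-test
  lattice ties prefer smaller |period − 24|, then smaller phase.
* The pipeline derives per-stage child seeds from the global seed by a
  stable integer hash (< 2³¹), so stages can be rerun independently yet
  reproducibly; the manifest records seed, config hash and per-file MD5.
* The pipeline configuration is JSON (not YAML) because the target
  environment ships `jsonlite` but no YAML parser; the key structure is
  unchanged.

# Known limitations

* The cosine detector is an operative reconstruction, not a bit-exact
  replica of the closed-source original; only its stated semantics are
  reproduced and tested.
* The rank test's normal approximation is inaccurate in the extreme
  tail for very short series (n ≤ 8); the exact null is out of scope.
* The s statistic discards the 13th timepoint and is blind to periods
  far from 24 h by design.
* PERR/TER/PDP1 motif defaults are placeholders (see above).
* Headline probe counts from the original study are not reproducible
  here: they require the deposited array data and its normalization
  pipeline, which are outside this package's scope. Tests assert
  analytic identities and properties on synthetic data instead.
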