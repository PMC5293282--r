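---
title: "Quantifying replisome positioning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replisome positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

replitrack quantifies where the DNA-replication machinery sits inside
rod-shaped bacteria.  A fluorescently tagged replisome component (the
beta-clamp DnaN is the canonical choice, being present at high copy number
at active forks) forms diffraction-limited foci.  Because the two sister
forks of one replication round are usually closer than the diffraction
limit, a single focus normally contains a *pair* of replisomes; transiently
the pair fissions into two dim foci that later fuse.  The package measures,
over large automatically selected populations, how often fork pairs are
co-localized versus resolved, where foci sit along the cell's long axis as
a function of cell length, and how re-initiation before division produces
focus pairs near the quarter-cell positions.  Every stage can be exercised
against a synthetic-data generator whose ground truth is exported, so the
whole chain is testable without external data.

## The analysis chain

### Cell tracking and growth

Cell identity is taken from label-mask stacks (one integer label per cell
per frame, stable across frames; a division retires the parent label and
issues two new ones).  Per frame, cell length is the Feret extent of the
label along its principal axis.  Growth is fit per cell by unweighted least
squares in linear length space,

$$L(t) = L_0 \, e^{t/t_0}, \qquad t_D = t_0 \ln 2,$$

with $L_0$ and $t_0$ free.  Fitting in linear (not log) space matches a
least-squares fit of the length-vs-time curve itself.  Cells are retained
only if (i) their track shows no segmentation errors (no
vanish-and-reappear labels, no length jumps above 20% per frame — the 20%
operationalizes a criterion the source analyses leave qualitative),
(ii) $t_D$ lies between 1.5 and 4.5 h, and (iii) birth length lies between
1 and 4 µm.  Criterion (ii) is skipped for snapshots, where growth cannot
be measured, and the observed length stands in for birth length in (iii).

### Focus detection and scoring

Per frame: a 1-pixel-radius Gaussian blur; a watershed partition of the
smoothed frame into regions around each intensity maximum (equivalently,
basins of the inverted image); regions outside the cell masks are
discarded; each remaining region seeds one candidate at its brightest
pixel.  A 2-D Gaussian

$$G(\mathbf{x}) = I_g \exp\!\left(-\frac{|\mathbf{x}-\mathbf{x}_0|^2}{2b^2}\right) + I_0$$

is least-squares fitted over the 29-pixel disk of radius 3 around the seed
(on the raw frame, so the fitted width $b$ estimates the true PSF width);
the fitted $\mathbf{x}_0$ is used for all localization.  Intensity is then
measured on the smoothed frame over the disk re-centered at
$\mathbf{x}_0$:

$$I_b = A \min_{\text{disk}} I, \qquad
  I_a = \sum_{\text{disk}} I - I_b, \qquad
  \sigma = \frac{I_a}{\delta I \sqrt{A}},$$

with $A = 29$ the disk pixel count and $\delta I$ the standard deviation
of raw intensity over the entire cell mask — $\delta I\sqrt{A}$ is the
expected standard deviation of the integrated intensity if per-pixel noise
were uncorrelated.  Foci with $\sigma \ge 4$ are retained; lower scores
occur randomly through the cell and are intensity fluctuations.

Three measurement-image choices deserve explanation:

* **Disk sums on the smoothed frame.**  The min-pixel background estimate
  is only usable on a smoothed frame: on raw shot noise the minimum of 29
  independent pixels sits ~2 noise s.d. below the mean, which inflates
  $I_a$ of *empty* disks to $\sigma \approx 10$ and makes the threshold
  meaningless.  Smoothing correlates the disk, the minimum tracks the
  local background, and empty disks score ~1.5–2.5 while true foci score
  6–12 — reproducing the intended behavior of the cutoff.
* **$\delta I$ on the raw frame.**  The noise scale must stay on the raw
  scale, otherwise it shrinks together with the numerator and the
  discrimination vanishes.
* **Disks fully inside the mask.**  A disk crossing the cell boundary
  takes its minimum from outside the cell, inflating $I_a$ roughly
  tenfold; such candidates are rejected.  Foci of interest (midcell and
  quarter-cell positions) are always interior.

The Gaussian fit may move the center at most half a disk radius from the
seed: it refines to sub-pixel precision but cannot relocate onto a
neighboring fluctuation before re-scoring.  Candidates whose provisional
score at the seed pixel is below 0.6× the threshold skip the fit entirely
(economy only — the retention decision always uses the fitted-center
disk, and the margin is far wider than any fit-induced score change).

### Pair separations, the mixture, and factory counting

Within every cell-frame all $\binom{n}{2}$ unique focus pairs are formed;
the relative separation is the difference of relative long-axis positions.
Over a population these separations fall into two roughly Gaussian
sub-populations: resolved sister forks near 0.2 cell lengths and
quarter-cell focus pairs near 0.45.  A two-component Gaussian mixture
(means, variances, mixing fractions free) is fitted by EM: deterministic
quantile-based initialization (component means at the 25th/75th
percentiles), convergence when the log-likelihood changes by less than
1e-8, at most 2000 iterations, and deterministically jittered restarts if
a component collapses (s.d. below 1e-5).  No random numbers are used, so
classification is reproducible bit-for-bit.

Pairs with posterior probability of the low component above 0.5 are
candidate resolved-sister pairs (exactly 0.5 goes to the high population —
conservative toward factory counting).  Within a cell-frame candidates are
accepted greedily in decreasing posterior, each focus joining at most one
accepted pair.  Counting then follows the identity

$$n_\text{coloc} = n_\text{foci} - 2\,n_\text{resolved},$$

i.e. a single focus is one co-localized fork pair, an accepted resolved
pair contributes its two foci as one pair of separated sisters, and the
co-localized fraction pools $\sum n_\text{coloc} / \sum (n_\text{coloc} +
n_\text{resolved})$ over all cell lengths.

## The synthetic-data generator

The generator emulates the study conditions so that parameter recovery is
meaningful: slow exponential growth ($t_0 = 260 \pm 25$ min, i.e. $t_D
\approx 3$ h), birth lengths near 1.8 µm, division at a lognormal length
threshold of 3.6 µm with 1% septum-position noise, one replication round
per division cycle (C period $110 \pm 15$ min), a D-type gap ($50 \pm 15$
min; 85 min for the *B. subtilis* preset) between termination and the next
initiation, and pre-division re-initiation in 45% of cycles.  The
re-initiation timing is drawn as a Bernoulli per cycle — the study reports
the frequency, not a mechanism, and the Bernoulli realizes that frequency
exactly; the D-period draw supplies the gap scale.

Each active fork pair is one emitter cluster: home position at midcell
(0.5) or, for re-initiated rounds still inside the mother, at $0.5 \pm
0.225$.  The offset of 0.225 rather than 0.25 encodes the *observed* mean
separation of quarter-positioned focus pairs (0.45 cell lengths); homes at
exact quarters would put that mode at 0.50.  Confined motion is a
mean-reverting AR(1) walk (s.d. 0.025 cell lengths, autocorrelation 0.7
per frame).  The co-localized/resolved state follows a two-state Markov
chain whose stationary resolved probability is `p_resolved` (0.18 for the
*E. coli* preset, 0.21 for *B. subtilis*) and whose episode persistence is
0.4 per frame (mean episode ~10 min, "transient" fission-fusion; the dwell-time
distribution is otherwise unconstrained by observation).  Resolved
separations are drawn from N(0.2, 0.05²) cell lengths, truncated above at
0.32 (below the 0.33 bound) and below at 0.26 µm relative to the current
cell length: *resolved* is an operational state — a pair below the
diffraction limit renders as one focus and is co-localized by definition —
so sub-limit separations are not generated as "resolved".

Rendering: each emitter is an isotropic 2-D Gaussian (PSF σ = 110 nm) at
its sub-pixel position; a co-localized pair carries the full focus
amplitude (800 photons peak), each resolved sister half.  The diffuse base
is flat across the field (200 photons) — cell outlines live in the masks,
not the fluorescence — plus a slow cytoplasmic texture (s.d. 90 photons,
correlation length 6 px) that dominates $\delta I$ of focus-free cells,
and per-pixel Poisson noise.  Masks are stadium-shaped rods of width
1.1 µm.  For the *B. subtilis* preset, divisions are silent in the mask
with probability 0.35: the septum is invisible, the label spans the
sibling chain, and lengths inflate exactly as chaining inflates them in
real segmentations.

### Optical sampling: why 65 nm pixels

The score has a structural ceiling: a focus contributes to its own cell's
$\delta I$, and both $I_a$ and that contribution scale linearly with
amplitude, so for an isolated focus
$\sigma \lesssim c \, \sigma_\text{PSF,px} \sqrt{n_\text{mask}} / \sqrt{A}$
regardless of brightness.  At 160 nm/px the PSF is 0.7 px wide and a cell
mask holds only 100–200 px, which caps half-amplitude sister foci near
σ ≈ 3 — the σ ≥ 4 rule would reject essentially every resolved sister.
The renderer therefore samples at 65 nm/px (PSF σ = 1.69 px, 400–900 px
per mask), lifting the sister ceiling above 6 while the 3-px scoring disk
still covers the PSF.  The base level (200) and texture amplitude (90)
were calibrated by Monte Carlo against two pre-registered design targets —
pure-noise retained-focus rate below 2% per cell-frame, and reliable
retention of half-amplitude sisters — before the population analyses were
run.

### What the generator does *not* emulate

No photobleaching, no phase-contrast physics (masks are emitted directly,
so segmentation quality is an assumption, not a result), no chromosome
mechanics (fork motion is phenomenological, not driven by replicated DNA),
no 3-D PSF or defocus, and no cell crowding or contact.  Passing recovery
tests therefore validates the *analysis* under the stated imaging model;
it cannot certify behavior on data whose noise or morphology deviates from
that model.

## Numerical choices and degenerate inputs

* Growth fits start from the log-linear regression solution;
  non-convergence, $t_0 \le 0$, or $t_0 > 5000$ min (flat curves) flag the
  cell for exclusion.
* Focus fits bound $b \in [0.5, 5]$ px and $I_g \ge 0$; unbounded fits
  diverge on plateaus.  Failed fits drop the candidate.
* Flat cells ($\delta I = 0$) give score 0 and are rejected; flat frames
  yield no watershed candidates.
* Watershed merge tolerance is 1e-4 intensity units, so every smoothed
  maximum seeds a region; ties in greedy pair acceptance break by
  separation, then focus indices — all deterministic.
* Drift correction maximizes integer-pixel cross-correlation (FFT) of
  consecutive mask silhouettes within a ±10 px window; a peak at the
  window border is clamped with a warning.
* Pixel coordinates are 1-based pixel centers (R convention); relative
  long-axis positions are clamped to [0, 1] with 0.5 = midcell, and a
  cell's pole identity is anchored by inheriting the parent's axis
  orientation.

## Problem sizes

The shipped analyses use 15–200 founder lineages at 300 min (61 frames,
5-min interval) for time-lapse runs and 400–2000 independent cells for
snapshot runs; the package's validation suite runs 45–60 founders per
condition (≥ 200 complete cell cycles, thousands of retained foci), sizes
at which the recovered fractions have standard errors well inside the
recovery tolerances.  All randomness flows from a single integer seed per
run; reruns are byte-identical.

## Known limitations

* The mixture is one-dimensional (separation only), although separation
  and length are jointly informative; the low-population mean inherits a
  small upward shift from the high-population tail, accepted as-is.
* The high-separation population mixes quarter-pair, quarter-vs-sister
  and cross-cell-half pairs; its variance is wide and only its mean is
  interpreted.
* Near-threshold foci (σ just below 4) are discarded, so dim sisters in
  the smallest cells are slightly under-counted; the recovered
  co-localized fraction carries a corresponding upward bias of roughly one
  percentage point under the default conditions.
* Chained masks analyze a sibling pair as one long cell: within-chain
  factory pairs enter the high-separation population and sister
  separations halve in relative units.  This reproduces a known artifact
  of chaining organisms rather than correcting it.
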