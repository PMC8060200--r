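---
title: "Trial-frequency decomposition and cluster-based permutation testing of reaction-time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-frequency decomposition and cluster-based permutation testing of reaction-time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children and adults performing a long trial-based task do not respond with
a constant latency: reaction times (RTs) fluctuate from trial to trial.
This intra-individual variability (IIV) is classically summarized by the
standard deviation of a subject's RTs (RT\_SD). But RT\_SD is a single
number: a subject who is mildly noisy on every trial, one who is quiet
except for a few dramatic lapse episodes, and one whose performance
drifts slowly across the session can all produce *the same* RT\_SD while
behaving in qualitatively different ways. In attention research this
distinction matters — elevated IIV in attention-deficit presentations is
hypothesized to arise from *intermittent* performance breakdowns rather
than uniformly noisier responding.

`tftperm` makes the temporal structure of IIV visible and testable. It
treats the ordered sequence of RTs (one value per trial) as a signal and
decomposes it with complex Morlet (Gabor) wavelets into a
**trial × frequency power map**: power as a function of *which trial* and
of *cycles per trial* (0.05 cycles/trial = one full fluctuation every 20
trials). Two groups of such maps are then compared with a two-step
nonparametric cluster-based permutation test that controls the
family-wise error over the whole map.

## The decomposition

For a series of `T` trials the kernel at center frequency $f_G$
(cycles/trial) is

$$G(\Delta t) = \frac{1}{\sqrt{2\pi}\,\sigma_G}
  \exp\!\left(-\frac{\Delta t^2}{2\sigma_G^2} + i\,2\pi f_G \Delta t\right),
  \qquad \sigma_G = \frac{0.5}{f_G},$$

where $\Delta t$ is the trial offset from the kernel center and
$\sigma_G$ (in trials) sets the Gaussian envelope; the nominal kernel
support ("window") is $4\sigma_G$ trials. Frequencies are discretized in
steps of $1/T$ (for a 300-trial session, $1/300 \approx 0.0033$
cycles/trial) up to a configurable `f_max`, by default the Nyquist limit
of 0.5 cycles/trial. The power at trial $t$ and frequency $f_G$ is the
squared modulus of the convolution coefficient
$\left|\sum_j x(t + \Delta t_j)\,\overline{G(\Delta t_j)}\right|^2$.

Numerical choices a user should know about:

* **Mean-centering.** The series is centered on the subject's mean RT
  before convolution. Without centering the DC offset (an RT level of
  ~1200 ms against fluctuations of ~250 ms) dominates every low
  frequency and the map shows the mean, not the variability.
  Consequently the maps are invariant under constant RT shifts.
* **Discrete kernel length.** $4\sigma_G$ is generally not an integer;
  the kernel is realized with the nearest odd number of taps at or above
  $4\sigma_G$, so it is symmetric about an integer center and the
  mapping from coefficient to trial is unambiguous.
* **Edge handling.** The centered series is zero-padded outside its
  support, which preserves the full `T × F` map; every bin whose kernel
  support overhangs an edge is flagged in a cone-of-influence (COI)
  mask. Statistics include COI bins by default (`exclude_coi = FALSE`)
  because the full map is what is displayed and at low frequencies the
  COI covers a large share of the session; the switch lets users audit
  sensitivity to edge contamination.
* **Normalization.** Power carries the $1/(\sqrt{2\pi}\sigma_G)$
  amplitude prefactor and no further per-frequency energy
  normalization. Under this convention white noise has power
  proportional to $f_G$ across frequencies; comparisons between groups
  are unaffected because both groups share the convention bin by bin.
* **Implementation.** The convolution runs per frequency via FFT
  cross-correlation with padding past `T + n_taps`, so it is exactly the
  zero-padded direct sum; the test suite checks agreement with a naive
  per-bin inner-product evaluation to 1e-9 relative error.

## Response classification and the RT series

The time-estimation task asks for a 1200 ms interval estimate. Presses
within 200 ms of the target, i.e. in `[1000, 1400]` ms, are **correct**;
`[400, 1000)` ms is **early**; `(1400, 2000]` ms is **late**; anything
before 400 ms, after 2000 ms, or no press at all is **missed**. The
task definition leaves open whether the boundary values
themselves count as correct; the package closes the correct window on
both ends and half-opens the neighbors, which makes the four classes an
exact partition of the axis (verified by a 1 ms sweep in the tests).

`mean_rt` and `sd_rt` (RT\_SD) are computed over all non-missed
responses by default — whether the reference descriptive statistics
included early/late responses is not documented, so the subset is a
documented argument (`subset = "correct"` restricts to correct
responses).

The wavelet needs a finite value at every trial, but missed trials have
none. `build_rt_series()` fills them by linear interpolation between the
nearest valid neighbors (edge gaps: nearest-value extension) and returns
a validity mask marking imputed positions. Interpolation is the
minimal-assumption gap filler that preserves series length and adds no
spectral content of its own; sessions with fewer than two valid trials
are rejected.

## The two-step cluster-based permutation test

Step 1 computes a t statistic at every (trial, frequency) bin between
the two sets of maps — an unequal-variance (Welch) two-sample t for
independent groups, chosen because realistic group sizes differ, or a
paired t on per-pair differences — and a two-sided permutation p-value
from `n_shuffle` relabelings (group-label shuffles for independent
designs; independent per-pair sign flips, the exchangeability unit of a
paired design). The estimator is the add-one form
$p = (1 + \#\{|t_\pi| \ge |t_{obs}|\})/(1 + n_\text{shuffle})$, bounded
below by $1/(n_\text{shuffle}+1)$ so p-values are never zero. Bins with
$p < \alpha_\text{bin}$ (default 0.001) are marked.

Step 2 forms clusters of contiguous marked bins (4-connectivity by
default — orthogonal neighbors in the grid — with 8 configurable;
positive and negative t values cluster separately) and scores each by
its **mass**, the sum of its t values. Each *shuffled* map is
thresholded and clustered in exactly the same way, and the maximum
|mass| per shuffled map forms the Monte Carlo reference distribution; a
cluster is significant when its add-one p against that max-mass
distribution is below $\alpha_\text{cluster}$ (default 0.05). The
max-statistic construction is what controls the family-wise error over
all bins. The summary statistic `trials_covered_fraction` reports the
fraction of the session's trials intersected by at least one significant
cluster.

Design points where the procedure was genuinely open:

* **Cluster statistic.** Contiguity-based cluster inference needs a
  scalar per cluster; mass (sum of t) is used rather than extent (bin
  count) because it rewards both strong and large effects and is the
  common default in the field. The choice is internal to the package
  and applied consistently to observed and shuffled maps.
* **Bin-level reference.** The bin null is per bin, not pooled across
  bins (bins differ in scale across frequencies under the chosen
  normalization, so pooling would mix distributions). Observed and
  shuffled maps are thresholded against the same pooled
  leave-one-out rank among all `n_shuffle + 1` maps; for the observed
  map this reproduces the add-one estimator exactly, and the symmetry
  between observed and shuffled maps is what makes the step-2 reference
  distribution exchangeable.
* **Sidedness.** Two-sided throughout, with sign-separated clusters:
  group differences in variability structure have no a priori
  direction.
* **Exhaustive designs.** When the design admits no more relabelings
  than `n_shuffle` (all `choose(n, n_a)` label assignments, or all
  `2^{n_\text{pairs}}` sign patterns), the test enumerates them and the
  p-values are exact. For equal group sizes each unordered partition is
  enumerated once (its mirror image has the identical |t|), which keeps
  tie counting exact in floating point.
* **Degenerate bins.** A bin where all subjects share one value has
  t = 0 and p = 1. A zero-variance bin whose group means still differ
  gets a large finite sentinel t so that comparisons and masses stay
  well defined; continuous data never reaches this branch.

## The synthetic-data generator

The generator exists so the full pipeline is testable without clinical
data. It emulates 300-trial time-estimation sessions (three blocks of
100 in the task design; block structure is metadata only) at the
behavioral operating points of the reference cohorts:

* **Controls** (`control_params()`): tonic Gaussian jitter only — mean
  1171 ms, tonic SD 247 ms, 0.5% absent presses. Realized cohort-mean
  RT\_SD on accepted responses ≈ 243 ms.
* **Patient-like groups** (`add_params()`, `adhd_params()`): the same
  tonic machinery plus intermittent **anticipatory burst epochs**.
  Within an epoch the response distribution drops by `burst_shift`
  (~700–760 ms, i.e. premature presses around 600–650 ms) with its own
  spread; outside epochs behavior is control-like with a slightly slower
  baseline. The ADD-like preset uses 4 epochs of 26 trials, the
  ADHD-like preset 3 of 31, placed uniformly one per equal segment of
  the session so lapses are spread out and never overlap.

Why anticipatory rather than purely "noisier" bursts: RT\_SD is computed
on accepted responses inside the 400–2000 ms window. A symmetric
within-epoch SD multiplier pushes draws out of the window, where they
become misses, and the within-window SD saturates near ~280 ms no matter
how strong the burst — while the reference patient profile pairs an
RT\_SD of ~380–404 ms with only ~10 missed and ~90–100 *early* responses
out of 300. That combination forces a second response mode inside the
window below the target, which is also the natural behavioral reading
of an attentional lapse in a time-estimation task: the estimate
collapses and the press comes far too early. With the anticipatory
parameterization the calibrated presets realize cohort means of
~1142/402 ms (ADD-like) and ~1150/382 ms (ADHD-like) against the
247 ms control level, with realistic miss counts. Calibration was done
once, against the reference group means, with a ±10% acceptance band
reflecting sampling variability at cohort sizes of tens of subjects.
The multiplicative mechanism (`burst_mult`) remains available and is
what the power simulations use (a 2× tonic-SD burst with no shift).

`generate_profile()` serves a different purpose: it produces the four
SD-*matched* archetypes — uniform jitter, sparse strong bursts, dense
mild bursts, slow drift — whose deviations are rescaled so the sample SD
equals the target *exactly*. This makes the central claim sharply
testable: four series with identical RT\_SD are reliably separated by
burst-localized trial-marginal power and low-frequency concentration of
their maps (the suite requires separation in at least 95 of 100 fixed
seeds; the occasional failure is the dense-burst archetype, whose eight
mild epochs can blur into the uniform baseline).

What the generator does *not* emulate: feedback-driven learning across
blocks, RT autocorrelation outside burst epochs (tonic draws are
i.i.d.), skewed single-trial RT distributions, and any fitting of the
generative model to real patient data. Passing tests therefore
demonstrate that the *pipeline* recovers structure it is designed for,
not that real AD(H)D data has exactly this structure.

## The paired tonic-shift model

`apply_tonic_shift()` shifts every present response by a constant,
modeling a purely tonic change in performance such as a medication
effect on overall response speed. Because the decomposition centers each
series, a tonic shift changes accuracy counts (responses move relative
to the classification windows) while leaving every power map bit-for-bit
unchanged as long as no response crosses the 400/2000 ms acceptance
bounds — the dissociation between *improved accuracy* and an *unchanged
fluctuation profile*. The acceptance suite verifies both halves of the
dissociation on a simulated overshooting session.

## Simulation scale and reproducibility

Full-scale analyses default to `n_shuffle = 5000` with
`alpha_bin = 0.001` and `alpha_cluster = 0.05`. The package's
simulation-based checks run at a reduced scale chosen to keep the whole
suite fast on a single CPU while leaving the statistical questions
intact: null-calibration uses 200 replicate cohorts of 10 + 10 subjects
at `T = 100` with 500 shuffles, and burst-detection power uses 50
replicates of 20 + 20 subjects at `T = 300`. At 500 shuffles the finest
attainable permutation p is 1/501, so these runs threshold bins at
`alpha_bin = 0.01` — the two-step structure is unchanged, and
cluster-level family-wise error control does not depend on the bin
threshold. Every stochastic component (profiles, sessions, cohorts,
shuffles) is driven by explicit integer seeds, with per-subject seeds
derived deterministically from a master seed, so identical inputs and
seeds reproduce results bit for bit.

## Known limitations

* Imputed (missed) trials contribute interpolated values to the
  decomposition; the validity mask is available but the permutation
  statistics do not down-weight imputed bins.
* Bins inside the cone of influence are edge-contaminated; they are
  included by default for display fidelity and can be excluded for
  inference.
* The per-frequency power scale follows the amplitude-prefactor
  convention above; absolute power values are not comparable across
  packages using different Morlet normalizations, though group
  contrasts are.
* Only two-group (or paired two-condition) comparisons are supported;
  multi-group designs are run pairwise.

## A minimal session

```{r, eval = FALSE}
library(tftperm)

# simulate a control and a patient-like cohort
coh <- simulate_cohort(cohort_spec(control_params(), add_params(), 20, 20),
                       seed = 1)
maps_a <- lapply(coh$a, decompose)
maps_b <- lapply(coh$b, decompose)

res <- cluster_permutation_test(maps_a, maps_b, n_shuffle = 1000,
                                alpha_bin = 0.005, seed = 1)
res
report(res)
```
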