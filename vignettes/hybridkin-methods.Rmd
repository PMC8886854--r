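---
title: "Models and methods behind hybridkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridkin)
```

# The system

*Escherichia coli* RNase H removes the RNA strand of RNA:DNA hybrids — RNA
primers of Okazaki fragments, R-loop hybrids — and does so in two distinct
modes depending on the structure flanking the hybrid.  At a junction with a
3' ssDNA overhang (3'OJ) the enzyme anchors tightly and degrades the RNA
processively 5'→3' within a single binding event, so the degradation time is
independent of enzyme concentration.  On blunt-ended hybrids or hybrids with
a 5' overhang it acts as a sequence-nonspecific, distributive
endoribonuclease: each binding event contributes a single cleavage, the
enzyme leaves with the product, and the reaction stalls until another enzyme
binds — so the degradation time grows as 1/concentration through the
rebinding waits.

hybridkin implements the single-molecule FRET (smFRET) analysis by which
these claims are established — trajectory idealization, dwell-time
statistics, transition density plots (TDPs), the dwell-time
dissociation-constant estimator, degradation-time and pause measurement and
the processive-vs-distributive classification — together with a
continuous-time Markov (CTMC) simulator that generates the corresponding
synthetic experiments, so that every stage of the pipeline can be validated
against known ground truth without any external data.

# The kinetic model and its calibration

## State space

A substrate molecule is either unbound or bound at one of its junction
sites $j$ (chimeric junction CJ, nick junctions 3'NJ/5'NJ, overhang
junctions 3'OJ/5'OJ, blunt end BE, or the hybrid inner region).  The CTMC
rates are:

* binding to site $j$: $k_{on,j} \cdot C$ (per second, $C$ in nM),
* dissociation from site $j$: $k_{off,j}$,
* bound-state inter-site hop ("diffusion"): $k_{diff}$,
* catalysis: processive stepping at $k_{step}$ (1 nt per step, 5'→3') with
  an anchored-complex release rate $k_{release}$, or a distributive cut at
  $k_{cut}$ that removes the engaged 4-nt segment and releases the enzyme
  with the product.

Substrates with fewer than four consecutive ribonucleotides are inert
(enzyme engagement needs a minimal hybrid footprint), which is also why the
degradation-product mimics in the library bind only weakly and are never
cleaved.

## The dwell-time Kd and the calibration equations

Throughout the package the dissociation constant is the dwell-time
estimator as used in the single-molecule literature this package targets:

$$K_d = \frac{\bar\tau_{unbound}}{\bar\tau_{bound}\cdot C}.$$

Note this quantity is *concentration dependent*: under exponential kinetics
its analytic value is $k_{off}/(k_{on} C^2)$, not $k_{off}/k_{on}$.  The
package applies the estimator exactly as defined and every `kd_estimate`
records the concentration it was computed at; the library likewise records
the calibration concentration of every preset (0.2 nM for the binding
assays, 10 nM for the 5'ORDH dwell preset).

Each library entry stores per-site $K_d$ targets.  `get_preset()` inverts
the estimator: with a chosen bound dwell $\tau_b$, the mean unbound waiting
time to the site must be $\tau_u = K_d \tau_b C$, giving
$k_{on} = 1/(\tau_u C)$ and $k_{off} = 1/\tau_b$.  Calibration closure —
that the estimator applied to the analytic dwells returns the target to
within $10^{-9}$ relative error — is asserted for every preset.

## Choosing the free bound dwell

One parameter per site is not fixed by the $K_d$ target.  The 5'ORDH entry
pins it with measured values (bound 0.23 s, unbound 6.56 s at 10 nM).  For
all other presets the package chooses

$$\tau_{b,j} = \max\!\left(2,\ \frac{4\,\Delta t}{K_{d,j}\, C}\right)
\quad\text{seconds},$$

so each dwell class averages at least four camera frames
($\Delta t$ = 0.5 s for binding assays), and then scales *all* bound dwells
by a common factor so the aggregate unbound waiting time
$1/\sum_j k_{on,j} C$ averages at least 40 frames.  The common scaling
preserves every $K_d$ target and all on-rate ratios.  The 40-frame figure
keeps the mass of sub-frame unbound gaps near 1%: gaps shorter than one
frame are invisible to any uncorrected idealization, and their rate is what
limits event-counting accuracy (see *Known limitations*).

For the dual-overhang substrate the two sites must additionally satisfy the
observed binding-event ratio 35:11, which fixes the on-rate ratio; the two
bound dwells are then solved jointly from the 2×2 system so that both sites
still meet their $K_d$ targets (the event ratio and the $K_d$ ratio are not
mutually consistent under equal bound dwells, so per-site dwells are the
only faithful resolution).

The hop rate of the 3' overhang substrate is calibrated so that 8% of
binding episodes contain at least one inter-site hop before release:
$\sum_i \pi_i\, k_{diff}/(k_{diff}+k_{off,i}) = 0.08$ with $\pi_i$ the
binding-site mix; solved numerically.

## Cleavage parameters

*Processive* mode steps at $k_{step} = 10$ nt/s (a 25-nt RNA ramps in about
2.5 s, the few-second range of the observed degradation plateaus) and the
anchored translocating complex releases at $k_{release} = 0.001$ s$^{-1}$.
The near-zero release encodes the defining experimental observation for
this substrate class: single-turnover reactions go to completion with no
loss of the enzyme signal.  A larger release rate is not merely "more
noise": every mid-ramp drop-off inserts a rebinding wait proportional to
$1/C$, which a sufficiently powered concentration-series analysis will
detect as spurious distributive character.

*Distributive* mode performs one cut per binding event: after binding, the
engage-and-cleave step at $k_{cut} = 100$ s$^{-1}$ competes with
dissociation at $k_{off}$, and the cut releases both the 4-nt engaged
segment and the enzyme.  One-cut-per-bind is the standard definition of
distributive action, and the fast $k_{cut}$ (cleavage chemistry fast once
engaged; binding-limited kinetics) is required by the observed near
equality of pause and dissociation times: if unproductive rebinding were
common, detected pauses would be concatenations of several rebinding waits
and would exceed the mean unbound dwell by far more than the ~1 s
censoring offset.

## Rendering

A state path is rendered into frames of interval $\Delta t$ by exact
occupancy-weighted averaging of the piecewise-constant true FRET level:
enzyme-labelled binding assays map bound states to their site anchors
(E = 0.38/0.48/0.77 classes; unbound baseline 0.05, representing spectral
bleed-through rather than true zero), substrate-labelled degradation maps
the remaining-RNA fraction linearly onto an E ramp (0.2 → 0.7; linearity is
the minimal monotone choice and a config hook), and enzyme-tracking mode
decreases E linearly from the anchor as nucleotides are consumed.
Intensities are $I_A = E\,T$, $I_D = (1-E)\,T$ plus background; the
channel noise is $\mathcal N(0, \sigma/\sqrt 2)$ per channel with
$\sigma$ = `noise_sigma` = 8% of the total intensity by default, i.e.
`noise_sigma` is the standard deviation of the summed intensity.  This
split-noise reading is what makes two states at E = 0.05/0.77 separable at
≥ 99% frame accuracy under the default noise, which is the regime the
thresholds below assume.  Donor photobleaching (off by default) truncates
both channels to background.

# Idealization

`compute_fret()` forms the proximity ratio
$E = (I_A - bg_A)/((I_A-bg_A)+(I_D-bg_D))$, clipped to $[0,1]$, with the
background taken from a persistent post-bleach tail when one exists.  No
gamma or crosstalk correction is applied (the assays report
proximity-ratio FRET).

`idealize()` provides two interchangeable methods returning identical
structure — the assays' "idealized guideline":

* **threshold**: fixed cut-points (defaults 0.15 / 0.25 / 0.43 / 0.62 /
  0.90, i.e. an unbound class below 0.15 and three junction-class windows
  centred between the anchors) partition frames into states;
* **hmm**: a Gaussian-emission hidden Markov model fitted by EM from a
  k-means initialisation, with the state path by Viterbi.

Both paths then pass through a shared dwell-sequence cleanup that deals
with the two artifact classes of frame-integrated data:

1. **Noise flicker.** Adjacent dwells whose mean levels differ by less than
   $4.5\sigma$ (two-sample z-statistic, robust noise estimate from the
   median absolute frame-to-frame difference) are merged.  The 4.5
   threshold controls the multiple-comparison burden of ~10³ frames per
   trace: at 3σ a 250-frame dwell is split by chance about once per two
   dwells.  A short unbound run is never absorbed into a longer bound
   dwell, so resolved dissociation gaps survive; conversely a short
   excursion statistically indistinguishable from the baseline is absorbed
   into it.
2. **Camera blur.** A state change mid-frame renders one frame at an
   intermediate level.  Single-frame runs lying strictly between their
   neighbours' levels are merged into the closer neighbour; runs of at most
   two frames lying *below* two bound neighbours are relabelled unbound
   when their level implies majority-unbound occupancy (below the midpoint
   between the lower neighbour and the baseline) — a sub-frame
   dissociation-rebinding gap — and a boundary frame of a bound-to-bound
   junction that sits more than 3σ below both dwell levels is likewise
   relabelled (a gap masked by Viterbi or binning).  The majority rule is
   deliberate: frames are attributed to the state they spent most time in,
   and no missed-event (blur) correction beyond that is attempted.

`extract_dwells()` tiles the valid region exactly; the first and last dwell
of every trace are censored and excluded from dwell statistics (their true
duration is unknown).

# Binding statistics

`assign_sites()` labels bound dwells by the FRET window containing their
state level; consecutive bound dwells without an intervening unbound dwell
form one binding episode, and a site-to-site label change inside an episode
is a diffusion (hop) event.  `build_tdp()` is the 2-D histogram of
(E before, E after) over all idealized transitions (bin width 0.02;
transitions smaller than one bin cannot leave the diagonal and are
dropped).  `binding_frequencies()` implements the event-percentage
definition: (events in region) × 100 / (events in all areas), counting both
binding and dissociation directions.

`estimate_kd()` applies the dwell-time estimator with per-site partitioning
of the unbound time: $\bar\tau_{u,site}$ is the total unbound observation
time divided by the number of episodes *starting* at the site (which
reproduces $1/(k_{on,site}C)$ analytically under multi-site competition),
and $\bar\tau_{b,site}$ is the total uncensored bound time at the site
divided by the number of dissociations from that site into the unbound
state.  The release-count denominator matters on hopping substrates: a
naive per-dwell mean estimates $1/(k_{off}+k_{diff})$ — 12% short for the
3' overhang site — whereas time-per-release is unbiased for $1/k_{off}$.
Replicate structure for standard errors follows the
repeated-experiment convention: molecules are grouped into at least three
seeded batches and the s.e.m. ($\sigma/\sqrt n$, sample sd) is taken over
per-batch estimates.

# Degradation analysis

`measure_degradation_time()` measures the FRET ramp between 10% and 90% of
the anchor range on a median-filtered (window 3) series.  The period *ends*
at the first persistent (3-frame) crossing of the high threshold and
*starts* at the final departure from the start plateau before that point.
Anchoring the start to the last low frame is deliberate: at low enzyme
concentration a molecule waits on the start plateau for a time proportional
to $1/C$, and a first-crossing rule occasionally fires inside that plateau
on noise, leaking concentration-dependent waiting time into the measured
duration and biasing the classification toward "distributive".

`detect_pauses()` marks maximal intervals of at least 1 s inside the
degradation period where the slope of the boxcar-smoothed (0.5 s),
median-filtered series stays below max(0.005 FRET/s, 3σ of the propagated
slope noise); the noise-adaptive floor keeps flat segments from being
broken by per-frame slope noise, which at these noise levels dwarfs a fixed
0.005 FRET/s criterion.  Pause runs clipped by the period boundaries are
censored and excluded.  With exponential rebinding (mean 6.56 s at 10 nM)
and the 1 s minimum, memorylessness predicts a detected-pause mean of
about 1 + 6.56 ≈ 7.6 s, matching the observed near-equality of pause and
dissociation times — the model's key internal consistency check.

`classify_mode()` fits $t(C) = t_0 + a/C$ — the minimal mechanistic form: a
distributive enzyme pays one rebinding wait ($\propto 1/C$) per
dissociation — by least squares with a 1000-replicate case-resampling
bootstrap stratified by concentration.  The verdict is distributive iff the
lower 95% bound of $a$ exceeds zero.  `completeness_fraction()` counts
molecules whose final FRET lies within ±0.06 of the degraded anchor
(single-turnover processive reactions complete; distributive ones cannot,
having exactly one cut and no rebinding).

# Problem sizes and numerical choices

The validation experiments use fixed seeds and the following scales, chosen
so that every stochastic comparison has at least several hundred events
behind it: binding assays 40–70 molecules × 1500–7200 s at 500-ms frames
(≥ 500–3000 binding events), the dual-overhang competition 3 × 60
molecules, dwell/pause statistics 120–200 molecules at 100-ms frames,
diffusion analysis ≥ 1000 episodes, and the classification property 20
replicate experiments of 3 concentrations (1/10/100 nM) × 20 molecules per
preset.  All simulations are exact (competing exponentials); rendering
integrates the true FRET path exactly over each frame; identical seeds give
bit-identical traces.  Degenerate inputs (zero duration, dark traces,
constant series, empty transition lists) return well-defined empty results
rather than errors wherever the quantity is defined.

# What the generator does and does not emulate

The simulator reproduces exponential bound/unbound dwells at
junction-specific rates, site-specific FRET levels, rare bound-state
inter-site diffusion, processive monotone ramps versus distributive
staircases with concentration-dependent pauses, frame integration at
100/500 ms, Gaussian intensity noise and donor-bleach truncation.  It does
not model spatial diffusion of free enzyme, acceptor photophysics
(blinking, direct excitation), multi-enzyme co-occupancy, baseline drift,
or sequence-dependent cleavage preferences; nucleotide sequences are not
modelled at all because no analysed quantity depends on base identity.
Passing tests therefore demonstrate correctness of the estimators under the
stated kinetic model, not robustness to every pathology of real traces.

# Known limitations

* **Sub-frame events.**  Bound dwells of 0.23 s sampled at 100 ms leave
  ~35% of binding events shorter than a frame.  Such events cannot be
  detected by any idealization without blur correction (which is
  deliberately not applied: the analyses report raw averages), and every
  missed bind merges two unbound dwells.  The pipeline's mean unbound dwell
  on the 5' overhang substrate is consequently biased upward by roughly a
  quarter — an intrinsic property of the measurement at these conditions,
  not of the estimator.
* **Fused gaps.**  Dissociation-rebinding gaps shorter than about half a
  frame fuse two episodes; when the episodes sit at different sites the
  junction is indistinguishable from a genuine hop.  At the study
  conditions this inflates the measured hop-episode fraction by roughly one
  percentage point above the simulated 8% and caps hop-detection precision
  near 0.9.
* **Threshold sensitivity on staircases.**  Distributive degradation
  produces quantized FRET staircases; moving the ramp thresholds from
  10/90% to 15/85% of the range can move a threshold across a staircase
  plateau and change the measured duration by a whole rebinding wait, so
  degradation times on distributive substrates are more
  threshold-sensitive than smooth processive ramps.
* The printed-form dwell-time $K_d$ is concentration dependent (see above);
  estimates are only comparable at a common concentration.
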