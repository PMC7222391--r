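---
title: "Methods: PLI networks, spanning trees and the 2x2 emotion design"
author: "eegmst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI networks, spanning trees and the 2x2 emotion design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmst)
```

## The analysis in one paragraph

Emotional EEG is studied here as a weighted functional network: the 32
scalp electrodes of the standard montage are nodes, and the edge weight
between two electrodes is the phase lag index (PLI) of their band-limited
signals. Because conventional graph analysis of such networks depends on
an arbitrary edge threshold, the analysis backbone is instead the
spanning tree that maximises total PLI — the strongest loop-free
subnetwork, unique up to ties and containing exactly 31 edges for 32
nodes. The shape of that tree (line-like versus star-like) summarises
network reorganisation, and a small set of tree statistics quantifies it.
Trials are grouped by self-reported arousal and valence into four emotion
conditions, and condition differences are tested with a 2 (arousal) x 2
(valence) within-subject ANOVA followed by paired contrasts with
false-discovery-rate correction.

## Phase lag index

For two channels with instantaneous phases $\phi_i(t)$, $\phi_j(t)$,

$$\mathrm{PLI}_{ij} = \left| \left\langle \operatorname{sign}
  \Delta\phi_{ij}(t) \right\rangle_t \right|,
  \qquad \Delta\phi_{ij} \in (-\pi, \pi],$$

the asymmetry of the phase-difference distribution around zero. A
consistent lead or lag gives values near 1; both independent signals and
zero-lag (volume-conducted) mixtures give values near 0, which is the
reason PLI is used rather than coherence or the phase-locking value.
Differences of exactly $0$ or $\pi$ contribute sign 0 — the standard
convention, which makes the statistic blind to pure zero-lag coupling *by
construction*.

Phases come from the analytic signal (FFT-based Hilbert transform) of the
band-pass filtered trial. Filtering uses a linear-phase Hamming-window
FIR applied forward and backward (zero net phase); the transition width
is one quarter of the band width, and the realised design is logged on
the filtered object. The forward-backward pass is evaluated in the
frequency domain with odd-reflection padding of one filter length per
end, which is numerically equivalent to conventional `filtfilt` away from
the edges and lets all 32 channels be filtered in one FFT. Residual edge
effects are handled by trimming `edge_trim = 0.5` s from each end before
PLI; a PLI estimate is refused below 512 usable samples, so the shortest
admissible trial at 128 Hz is 5 s.

The five analysis bands are fixed: theta 4–7, alpha 7–13, beta1 13–20,
beta2 20–30, gamma 31–45 Hz, within the 4–45 Hz range of the preprocessed
input.

## From ratings to conditions

Valence and arousal are rated 1–9. Ratings in $[1, 4]$ are low, in
$[6, 9]$ high, and the open middle band $(4, 6)$ is unclassifiable; both
axes must classify for a trial to enter one of HAHV, HALV, LAHV, LALV.
The interval endpoints are closed: ratings can be continuous, and a
boundary value of exactly 4 or 6 is classified rather than dropped. Any
subject lacking at least one trial in any of the four conditions is
excluded (with a logged reason), since the within-subject design needs
all four cells — the same rule that removed one subject from the original
DEAP-based analysis. For DEAP-shaped input the first 32 array rows (the
EEG channels) are kept and the first 3 s of each 63-s trial — the
pre-stimulus baseline — are discarded rather than subtracted; the PLI of
the 60-s viewing window is the analysis target, and baseline subtraction
would alter phases without a defensible model of what to subtract.

## Trees and their metrics

The maximum-PLI spanning tree is built with Kruskal's algorithm: edges
ranked from highest to lowest PLI, each accepted iff it joins two
components. Equal-weight edges are taken in lexicographic node-index
order, making the tree deterministic even for degenerate inputs. With
$N$ nodes and $M = N-1$ edges, leaves $L$ (degree-1 nodes) and node
degrees $k_i$:

| metric | definition |
|---|---|
| MPLI | mean of all $\binom{N}{2}$ pairwise PLI values |
| degree\_max | $\max_i k_i / M$ |
| BC\_max | $\max_i \mathrm{BC}_i$, $\mathrm{BC}_i$ = fraction of shortest paths through $i$, normalised by $(n-1)(n-2)$ ordered pairs |
| leaf fraction | $L / M$ |
| diameter | $\max_{i,j} d(i,j) / M$ |
| eccentricity | $\tfrac1N \sum_i \max_j d(i,j) / M$ |
| tree hierarchy | $L / (2 M \cdot \mathrm{BC\_max})$ |

In a tree every path is unique, so betweenness reduces to counting the
endpoint pairs separated by removing a node; the package computes it by
that subtree decomposition and cross-checks against a general-purpose
graph library in its tests.

**Distance convention.** The definitions above need $d(i,j)$, the
shortest path length. Counting hops cannot reproduce the magnitudes
reported for 32-channel emotional EEG — a 32-node tree's smallest
possible hop diameter is $2/31 \approx 0.065$, already above the full
range of published diameters (0.048–0.056) — so the default convention
takes each edge's length as $1 - \mathrm{PLI}$ (strong edges are short)
and normalises by $M$. Hop counting remains available via
`distance = "hop"`, is used for the closed-form fixtures (a star's hop
diameter is exactly $2/31$; an 8-node line takes 7 steps end to end), and
every metric is tagged with the convention that produced it. The
reconstruction is flagged because the published analysis does not state
its normalisation.

**Aggregation level.** The published analysis computes statistics per
subject and condition but does not state whether trial PLI matrices were
averaged before tree construction or trees were built per trial with
metrics averaged after. Both paths are implemented
(`aggregation = "matrix-average"` / `"trial-metric-average"`); matrix
averaging is the default because it estimates each subject-condition
connectome from all available data before the highly nonlinear tree
step. The two agree exactly for single-trial conditions, which the tests
assert.

**Group aggregation.** Per condition and band, subject trees are overlaid
into an overlap graph whose integer edge weights count how many subjects'
trees contain the edge; the maximum-weight spanning tree of that graph
(same Kruskal, same tie-break) is the condition's average tree. Hub
tables list its nodes with degree $\ge 3$ (degree $\ge 4$ flagged as the
stronger tier), ranked by degree then name.

## Statistics

Each metric in each band is analysed with a two-factor fully
within-subject ANOVA (arousal x valence, both two-level). Effects are
tested against their own subject-by-effect error strata; with two levels
per factor sphericity is trivially satisfied, so no correction is needed
or applied. Effect size is partial eta squared,
$SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$, the scale on which
the published effect sizes (e.g. 0.614) are interpretable. Degrees of
freedom are always reported explicitly as (df_effect, df_error) — the
published "F(29,1)" ordering is ambiguous — and are taken from the data
rather than forced to any particular subject count. A noiseless additive
shift drives the error stratum to zero; that degenerate case is reported
as $F = \infty$, $p = 0$, $\eta_p^2 = 1$ rather than an error.

The four follow-up contrasts are fixed: HAHV−LAHV, HALV−LALV (arousal
within valence) and HAHV−HALV, LAHV−LALV (valence within arousal), tested
with two-sided paired t-tests. "FDR correction" is implemented as
Benjamini–Hochberg step-up adjustment; the family is the four contrasts
of one metric within one band (matching how the published contrast table
is organised), with pooling across metrics available as a config switch.

## The synthetic generator

No generative model is published for the DEAP recordings; the simulator
is therefore package-side validation machinery, built so that every
downstream stage has planted ground truth — it must not be read as a
physiological model of the data.

Each channel carries independent narrowband Gaussian noise in the target
band, synthesised in the frequency domain (which yields the analytic
signal for free). For a coupled pair $(i,j)$ with strength $s$ and lag
$\theta$, channel $j$ receives $s$ times a phase-shifted copy of channel
$i$'s carrier mixed with its own noise at weight $1-s$, so the mixing
weight maps monotonically onto expected PLI without integrating an
oscillator ODE. The shift is $\theta$ plus slowly wandering
wrapped-Gaussian jitter with SD $(1-s)\,\pi/2$ (a 1-Hz lowpass process),
keeping PLI strictly inside $(0,1)$ for intermediate strengths. Lags are
drawn from $\pm[\pi/6, 5\pi/6]$, bounded away from $0$ and $\pi$ where
PLI is blind. A zero-lag narrowband common source added to all channels
(`common_source_gain`) emulates volume conduction; white noise
(`noise_sd`, default 0.5 relative to unit-SD carriers) completes the
trial. The generator stores the wrapped phase-difference series of the
noise-free composites (`truth_dphi`), an estimation-path-independent
bookkeeping that tests compare downstream PLI against.

**Planted topology.** The default ground truth superimposes a line
backbone through all channels (constant coupling, default 0.45) and a
star overlay from a hub to every non-adjacent channel whose coupling
carries the condition effects. As the star coupling crosses the line
coupling, the strongest backbone of the network moves continuously from
line-like to star-like — exactly the axis the tree metrics are designed
to detect, so planted effects are visible in tree shape and not only in
mean connectivity.

**Condition model.** Star coupling =
`baseline + arousal_effect*[high arousal] + valence_effect*[low valence]
+ interaction_effect*[both]`, with a per-subject Gaussian intercept
(SD 0.05) on the baseline. High arousal and *low* valence raise coupling,
matching the direction of the published findings (most star-like trees
under high-arousal/low-valence); the signs are configurable. Defaults:
baseline 0.30, arousal 0.20, valence 0.10, interaction 0.05; 32 subjects,
10 trials per condition, 60-s trials at 128 Hz, mirroring the dimensions
of the DEAP design. Deterministic per-seed generation covers signals,
lags, intercepts and ratings (high ratings ~ U(6,9), low ~ U(1,4), so
classification round-trips).

What the generator does **not** emulate: 1/f background spectra, EOG and
movement artifacts, electrode geometry and realistic volume-conduction
mixing matrices, non-stationarity across a 60-s video. Passing tests
therefore demonstrate that the *estimation chain* is correct and
calibrated, not that DEAP physiology is reproduced.

**Noise floor of a PLI estimate.** After narrowband filtering,
consecutive samples are correlated over roughly $1/B$ seconds for band
width $B$, so the variance of the sign average is governed not by the raw
sample count but by the effective number of independent narrowband
samples, $n_\mathrm{eff} \approx T \cdot B$. Null (zero-lag or
uncoupled) pairs are therefore expected near $\sqrt{2/(\pi
n_\mathrm{eff})}$, and the package's validation checks bound them by
$3/\sqrt{n_\mathrm{eff}}$. Treating the raw 128-Hz sample count as $n$
would understate PLI variability roughly threefold in the gamma band and
far more in theta.

## Validation problem sizes

The simulation-based checks use the smallest sizes that the PLI contract
admits, chosen once:

* **Null calibration** (`null_rejection_rate()`): 200 replicates of a
  20-subject study, one trial per condition, 5-s trials (640 samples;
  512 usable after trimming — the contract minimum), gamma band, all
  effects zero. The arousal ANOVA on MPLI should reject at ~5%.
* **Direction recovery** (`direction_recovery_rate()`): 50 replicates of
  a 12-subject study with a planted arousal effect of +0.3, checking the
  five-metric sign pattern (MPLI, degree_max, leaf fraction up; diameter,
  eccentricity down for high arousal).

## Numerical choices and edge cases

* Kruskal tie-break: lexicographic (i, j); all-tied matrices still
  return a deterministic tree.
* Tree hierarchy with $L = M$ (pure star): the formula applies directly
  and gives 0.5; it is undefined (NA) only for 2-node trees where
  BC_max = 0.
* Phase of a constant/zero channel is undefined: refused with an error
  rather than returning noise.
* Paired t with zero-variance differences: reported NA, not an error,
  so one degenerate contrast does not abort a batch.
* Benchmark tables: the published gamma-band cell means, SDs and
  contrast statistics are encoded in `published_gamma_benchmarks()`, and
  `compare_to_published()` scores a metric table against them in
  reference-SD units. Reproducing those numbers requires the original
  gated recordings, so the package asserts the machinery and the encoded
  values' internal consistency, never agreement from synthetic data.

## Known limitations

* The weighted-distance normalisation for diameter/eccentricity is a
  reconstruction (flagged in output metadata), since the published
  analysis does not state one.
* PLI discards lag magnitude and direction; the generator's planted lags
  are recoverable only as presence/absence of asymmetry.
* The average tree is computed from matrix-averaged subject trees; with
  trial-level aggregation the subject trees fed into the overlap are
  still the matrix-average ones.
* The simulator's condition effects act on one band only
  (`band_of_effect`); cross-band interactions are not modelled.
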