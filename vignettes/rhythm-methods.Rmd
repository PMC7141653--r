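---
title: "Quantifying rhythm in animal acoustic signal sequences"
author: "ioirhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rhythm in animal acoustic signal sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(ioirhythm)
```

## The problem

Many animals produce acoustic signals as sequences of discrete elements —
syllables in bat isolation calls, clicks in sperm whale echolocation
trains, notes in bird song. Whether such a sequence is *periodic* (carries
an underlying metronome-like, isochronous beat), what that beat's
frequency is, and how *well* the beat describes the sequence are questions
that recur across bioacoustics, biomusicology, studies of vocal learning
and species discrimination. The analysis primitive throughout is the
element **onset** time; everything else derives from the
**inter-onset interval** (IOI), the time from one element's onset to the
next (element duration plus the following gap).

ioirhythm implements five complementary analyses on onset sequences and a
rule cascade that recommends which of them fit a given dataset. No single
method suffices: each has a characteristic failure mode, and the package
is designed so they can be run side by side and cross-checked.

## The methods and their assumptions

### IOI statistics

The mean IOI of a sequence converts directly to an exact beat frequency,
$f = 1/\overline{\mathrm{IOI}}$ (Hz). Variability is summarized by the
coefficient of variation $\widehat{CV} = s/\bar{x}$ with the $(n-1)$
sample standard deviation, corrected for small samples as
$CV^{*} = \left(1 + \tfrac{1}{4n}\right)\widehat{CV}$. The plain
estimator underestimates spread for the short sequences typical of
vocalization data, which is why the corrected value is what the summaries
report. The $(n-1)$ denominator is a deliberate choice: the small-sample
correction factor presupposes the sample estimator.

Two CV levels carry different information. The CV of all IOIs pooled
(`cv_overall`) mixes within- and between-sequence variability; the mean
of per-sequence CVs (`cv_sequence_mean`) isolates the within-sequence
part. Their gap is the package's indicator of likely individual
differences: internally steady sequences at different tempi give a small
per-sequence CV but a large pooled CV.

### nPVI

The normalized Pairwise Variability Index compares *adjacent* IOIs only:

$$\mathrm{nPVI} = \frac{100}{m-1}\sum_{k=1}^{m-1}
  \left|\frac{\mathrm{IOI}_k - \mathrm{IOI}_{k+1}}
  {(\mathrm{IOI}_k + \mathrm{IOI}_{k+1})/2}\right|$$

It is exactly 0 for an isochronous sequence, scale invariant, and bounded
below 200. Because only neighbours are compared, a sequence that drifts
slowly in tempo can still score low; nPVI indicates local isochrony, not
global tempo stability. When sequences are pooled into an "overall" nPVI
the pair that straddles a sequence boundary is excluded — those two IOIs
are not adjacent in time. This choice is recorded in the summary object
(`overall_npvi_excludes_boundaries`).

### Spectral beat detection with an internal reference

Onsets are binarized into a 0/1 point process at time resolution `dt`
(default 5 ms, giving a 200 Hz sampling rate and an analyzable band of
0–100 Hz). The discrete Fourier transform with the $1/N$ convention makes
the zero-frequency amplitude equal the time-domain mean,
$P_0 = n_\mathrm{events}/N$, which upper-bounds every other amplitude of
a 0/1 signal and therefore serves as an internal reference. The best
beat is the magnitude peak over $(0, f_{max}]$, DC excluded, ties to the
lowest frequency. No window or zero-padding is applied — the signal is
already a finite point pattern, not a stationary waveform excerpt.

Goodness of fit comes in two flavours:

* $\mathrm{GOF} = |P_\mathrm{best}|/|P_0|$ — the share of the internal
  reference carried by the single best beat; interpretable but strongly
  length dependent.
* $\mathrm{nGOF} = |P_\mathrm{best}|/(L\,|P_0|)$ — additionally divided
  by the sampling length $L$, which removes most of the length
  dependence and makes values comparable across datasets.

`L` is the **number of samples** by default. A duration-in-seconds
convention is also available (`length_unit = "seconds"`); it makes nGOF
invariant to `dt` for the same physical signal but shifts the scale by
$1/dt$. We verified on synthetic datasets at realistic study conditions
that the samples convention reproduces the order of magnitude of nGOF
values reported in comparative work on bat calls and whale click trains,
and made it the default. Whichever convention is used, reported nGOF
values are only comparable when `dt` and the convention are stated — the
spectrum result carries both.

The practical limit of the spectral method is frequency resolution: the
bin spacing is $1/(N \cdot dt)$ Hz, so a 0.5 s sequence has 2 Hz bins. For
sequences under about one second the package attaches a warning and the
decision cascade routes them away from the FFT.

### Generate-and-test (GAT) beat search

Every candidate frequency on a grid (default 2–100 Hz in 0.01 Hz steps,
9801 candidates, generated from integer indices to avoid floating-step
drift) is scored by overlaying the onsets with a perfectly isochronous
grid anchored at the first onset and computing the root-mean-square
deviation of onsets from their nearest grid point. The RMSD is normalized
to the beat period:

$$\mathrm{FRMSD} = \mathrm{RMSD} \times f,$$

the average temporal deviation as a fraction of a full cycle. This
normalization is what makes the minimum select the *slowest* beat
coinciding with the onsets: near-exact fits at a fundamental and its
harmonics have equal RMSD in seconds, so multiplying by $f$ penalizes the
harmonics. (A divide-by-frequency variant is provided as
`convention = "rmsd_over_f"` for comparison with other implementations,
but only the cycle-fraction form has this property.)

Two numerical details matter:

* **Exact ties** (FRMSD equal at several frequencies, as on perfect
  data) resolve to the lowest frequency, selecting the fundamental.
* **Grid quantization** can defeat that rule: a fundamental like
  $10/3$ Hz falls between 0.01 Hz grid points and scores a small positive
  FRMSD, while its harmonic 10 Hz sits exactly on the grid and scores 0.
  `gat_search` therefore accepts subharmonics $f^{*}/k$ of the minimizer
  as ties when their FRMSD lies within the quantization floor
  $\mathrm{span}\cdot df/(2\sqrt{3})$ — the worst-case FRMSD a true but
  off-grid beat accumulates from frequency rounding alone — and returns
  the slowest accepted candidate. The step is switchable
  (`harmonic_rescue = FALSE` gives the raw argmin).

Phase is anchored at the first onset. This is the simplest reading of
"testing against computed isochronous sequences", and none of the
statistics depend on absolute time. The key *limitation* of GAT is
cumulative timing noise: when IOIs are independently noisy, onsets drift
from any fixed grid like a random walk, and the phase decorrelates after
roughly $(\mathrm{period}/2\sigma)^2$ intervals. For Gaussian IOIs with
mean 0.2 s and SD 0.05 s that is ~4 intervals: the FRMSD curve is then
almost flat and the fitted frequency close to arbitrary, even though the
sequence has a perfectly good *local* beat. GAT is therefore reliable for
tight, short-to-medium sequences (it recovers a 10 Hz beat from 15-element
combs with ±10% independent jitter in >90% of replicates) but not for
long sequences with accumulating noise — for those the IOI and spectral
methods are the right tools, which is exactly how the decision cascade
routes them.

### Recurrence matrices

$M_{ij} = |\mathrm{IOI}_i - \mathrm{IOI}_j|$ over all index pairs,
rendered white (zero) to black (maximum). Isochrony appears as a white
plot; blocks and alternating checkerboards reveal higher-order structure
such as repeated multi-syllable motifs. The color scale is per-plot by
default, matching the absolute-difference reading; a shared `zlim` can be
passed when comparing plots, since the same shade otherwise does not mean
the same difference across plots. The matrix is meant for visual
inspection — the package deliberately does not auto-detect heterochronous
patterns from it.

### Beat clustering

Per-sequence beat frequencies within an individual are clustered
agglomeratively with group-average (UPGMA) linkage on Euclidean
distances, cutting the tree at a dissimilarity threshold (default 0.05).
The share of sequences in the largest cluster summarizes how strongly an
individual "prefers" one beat. Applied to raw frequencies in Hz, 0.05 is
a tight criterion; because the alternative reading (5% after dividing by
the mean frequency) is equally defensible, `normalize = TRUE` exposes it,
and the choice is recorded in the result. Reporting the distance measure,
linkage and threshold alongside the shares is essential for
comparability, and `cluster_report` carries all three.

## The decision cascade

`decide_method` encodes the workflow a practitioner follows: (1) is the
dataset periodic — unimodal IOI distribution, modest per-sequence
variability? (2) is it isochronous — low mean nPVI, or moderate nPVI with
small per-sequence CVs? (3) which beat methods fit — a large
`cv_overall − cv_sequence_mean` gap flags likely individual differences
(per-sequence GAT preferred over the oversimplifying pooled IOI mean);
median sequence duration under the FFT-adequacy limit routes away from
the FFT; tempo-drifting sequences route away from GAT.

No numeric thresholds for these rules are established in the literature,
so the defaults are package choices, chosen to separate clearly periodic
from clearly aperiodic synthetic data, and every one is a config key
echoed in the output: `npvi_strict = 15`, `npvi_loose = 50`,
`cv_sequence_max = 0.3`, `cv_gap = 0.1`, `fft_min_duration_s = 1`,
`tempo_slope_max = 0.3`. Unimodality is assessed by counting smoothed
histogram modes — a descriptive stand-in for visual inspection, not a
formal dip test. "Unclear" verdicts are legal outputs; the rationale
lists every rule that fired.

```{r decision}
sb <- list(mean_ioi = 0.078, cv_overall = 0.29, cv_sequence_mean = 0.19,
           npvi_mean = 22.8, duration_per_sequence = rep(1.0, 50))
decide_method(sb)
```

## Synthetic data: what it emulates and what it does not

The generators produce the three canonical test beds for these methods:

* `gen_isochronous(ioi, n)` — perfect combs (IOIs such as 0.1, 0.3 or
  0.5 s); ground truth for beat recovery, nPVI = CV = FRMSD = 0.
* `gen_uniform()` — 10 sequences of 100 elements with IOIs uniform on
  (0, 1) s; the aperiodic control.
* `gen_gaussian(mean, sd)` — 10 sequences of 100 elements with IOIs from
  a normal distribution (means 1, 0.2, 0.1 s with SDs 0.5, 0.1, 0.05
  respectively are the standard settings), any non-positive draw redrawn
  until positive. The truncation lifts the realized mean slightly; for
  mean 0.2, SD 0.1 the truncated-normal mean is
  $0.2 + 0.1\,\phi(2)/\Phi(2) \approx 0.2055$ s.
* `gen_jittered_comb(base_ioi, jitter_frac, n)` — a comb with
  independent uniform multiplicative jitter per IOI; the fixture for
  goodness-of-fit validation. Across a jitter sweep 0 → 0.4 the median
  nGOF decreases and the median FRMSD increases monotonically, and the
  two are strongly negatively rank-correlated — the cross-method check
  that both goodness-of-fit scales measure the same departure from
  isochrony.
* `synth_study_dataset()` — fully synthetic stand-ins emulating three
  realistic recording situations (short monosyllabic bat isolation-call
  bouts, medium multisyllabic bat isolation calls, very long sperm whale
  click trains), with sequence counts, element-count distributions and
  IOI means/SDs matching published descriptive statistics for those
  signal types, plus a per-sequence log-normal tempo offset that creates
  a between-individual variance component.

All generators take a mandatory seed and restore the caller's RNG state,
so datasets are reproducible byte for byte and never perturb a
surrounding analysis.

What synthetic data does **not** capture: real label files carry
measurement error from amplitude-threshold onset detection; real
sequences mix element types with systematically different gaps (the
alternating block structure visible in recurrence plots of multisyllabic
calls); and real noise is rarely i.i.d. — tempo drift and serial
correlation are common. Passing tests on synthetic data therefore
demonstrate correctness of the computations and the expected qualitative
behaviour of the measures, not field-readiness of any particular
threshold.

## Numerical choices and degenerate inputs

* Onset-to-sample mapping uses nearest-bin rounding (halves the
  worst-case quantization error versus flooring); two onsets landing in
  one sample merge into a single event with a warning and a QC count.
* The binary sequence starts and ends with an event by construction
  (first onset shifted to sample 0, last sample is the last onset).
* Spectral ties break to the lowest frequency; an all-ones binary
  sequence has no nonzero-frequency peak and is flagged `no_beat`.
* Beat-category bins are half-open $[10k, 10(k+1))$ Hz with the top band
  edge closed; modal-bin ties break to the lower bin.
* Sequences need ≥ 2 onsets for any fit, ≥ 3 for a CV or nPVI, ≥ 4
  samples for a spectrum; failures inside `rhythm_analysis` are collected
  into a QC section rather than aborting the run.
* Label files are parsed leniently by default (out-of-order rows sorted
  with a warning) because hand-edited field labels are common;
  `strict = TRUE` turns violations into errors.

## Problem sizes

The test suite and the reproduction script run entirely on generated
data at moderate sizes — sequences of 10–250 elements, datasets of 10–60
sequences, 50 replicates per condition in the jitter sweep — matching the
scale of the vocalization datasets these methods were developed for.
Spectra are cross-checked against a direct-sum $O(N^2)$ transform on
sequences up to 512 samples, GAT against explicit grid enumeration up to
50 onsets, and clustering against a naive $O(n^3)$ agglomeration up to 20
points.

## Known limitations

* GAT fits a single frequency per sequence; tempo-changing sequences and
  long sequences with accumulating timing noise defeat it (see above).
* The spectral method needs sequences of roughly ≥ 1 s at the default
  5 ms resolution; faster signals require a finer `dt` *and*
  correspondingly longer sequences to keep the bin width useful.
* The IOI-mean beat ignores all sequence structure; it is exactly the
  oversimplification the decision cascade guards against when individual
  differences are likely.
* The decision thresholds are heuristics; they are printed with every
  recommendation so that analyses remain comparable, not because they
  are canonical.
* nGOF values are only comparable across studies when `dt` and the
  length convention are reported with them.

## A worked example

```{r example}
ds <- gen_gaussian(0.1, 0.012, n_sequences = 6, n_elements = 25, seed = 101)
report <- rhythm_analysis(ds)
report
```

```{r recurrence-plot}
plot(recurrence_matrix(ds$sequences[[1]]))
```
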