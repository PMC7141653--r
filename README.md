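# ioirhythm

Rhythm and periodicity analysis of animal acoustic signal sequences in R.

Many animal acoustic signals — bat isolation calls, sperm whale
echolocation click trains, bird song — are sequences of discrete elements
whose timing may carry a metronome-like (isochronous) beat. `ioirhythm`
quantifies that temporal structure from element **onset times** alone. It
is aimed at bioacousticians and comparative researchers who need
reproducible, cross-comparable rhythm statistics rather than ad-hoc
per-study scripts.

## What it computes

All analyses start from inter-onset intervals (IOIs),
`IOI_k = t_{k+1} − t_k`:

* **IOI statistics** — mean-IOI beat frequency `f = 1/mean(IOI)` (Hz);
  coefficient of variation `CV = s/x̄` with the small-sample unbiased
  correction `CV* = (1 + 1/(4n))·CV`, at both the pooled and
  per-sequence level (their gap indicates likely individual differences).
* **nPVI** — normalized Pairwise Variability Index,
  `100/(m−1) · Σ |IOI_k − IOI_{k+1}| / ((IOI_k + IOI_{k+1})/2)`;
  exactly 0 for an isochronous sequence.
* **Spectral beat detection** — the onset sequence is binarized at 5 ms
  resolution into a 0/1 point process; the DFT peak over (0, 100] Hz is
  the best beat, and the zero-bin amplitude `P0 = n_events/N` serves as
  an internal reference for two goodness-of-fit values,
  `GOF = |P_best|/|P0|` and the length-normalized
  `nGOF = |P_best|/(L·|P0|)`.
* **Generate-and-test (GAT) beat search** — every candidate frequency in
  2–100 Hz (0.01 Hz steps) is scored by the RMS deviation of onsets from
  the nearest point of an anchored isochronous grid, normalized to the
  beat period (`FRMSD = RMSD·f`, a fraction of a cycle); the minimum
  selects the slowest beat that fits.
* **Recurrence matrices** — `M[i,j] = |IOI_i − IOI_j|`, rendered
  white-to-black to reveal higher-order structure.
* **Beat clustering** — UPGMA clustering of per-sequence beats within
  individuals with a dissimilarity cutoff; largest-cluster shares
  summarize individual beat "preferences".
* **Method recommendation** — a rule cascade (periodic? isochronous?
  which estimator suits the sequence lengths and variance structure?)
  that prints every threshold it used.

Synthetic generators (isochronous combs, uniform/Gaussian IOI datasets,
jittered combs, and stand-ins for three realistic recording situations)
make every analysis testable without external data.

## A worked example

```r
library(ioirhythm)

# six 25-element sequences with IOIs ~ N(0.1 s, 0.012 s): a 10 Hz beat
ds <- gen_gaussian(0.1, 0.012, n_sequences = 6, n_elements = 25, seed = 101)
rhythm_analysis(ds)
```

```
Rhythm analysis report for 'gaussian_m0.1_sd0.012'
IOI summary for 'gaussian_m0.1_sd0.012'
  144 IOIs in 6 sequences (0 skipped)
  mean IOI 0.0994 s, SD 0.0118 s, range 0.0722-0.126 s
  CV* overall 0.119, CV* sequence mean 0.121 (gap -0.00184)
  nPVI per sequence: 10.7-16.6, mean 13.7 (pooled 13.7)

Per-method beat summary:
  FFT: 6 sequences, beats 9.84-10.7 Hz; prominent category 10-20 Hz (83.3%)
  GAT: 6 sequences, beats 9.79-18.2 Hz; prominent category 10-20 Hz (66.7%)
  IOI: 6 sequences, beats 9.85-10.3 Hz; prominent category 10-20 Hz (66.7%)

Method recommendation
  periodic: yes | isochronous: yes | individual differences likely: FALSE
  recommended: IOI, FFT
  rationale:
   - periodic: unimodal IOI distribution with nPVI mean 13.7 <= 50 and mean per-sequence CV* 0.121 <= 0.6
   - isochronous: nPVI mean 13.7 <= strict threshold 15
   - CV* gap (overall - sequence mean) = -0.00184: individual differences not indicated (threshold 0.1)
   - median sequence duration 2.38 s meets the FFT-adequacy duration 1 s
   - IOI and FFT recommended: strong shared pattern, adequate sequence length
  thresholds: npvi_strict=15, npvi_loose=50, cv_sequence_max=0.3, cv_gap=0.1, fft_min_duration_s=1, tempo_slope_max=0.3, unimodal_bins=20
```

Reading the output: all three estimators agree on a beat near 10 Hz (the
generating 0.1 s IOI), the low nPVI mean (13.7) marks the sequences as
isochronous, and the near-zero gap between pooled and per-sequence CV*
says the six sequences share one tempo — so the simple IOI and spectral
estimators suffice and the heavier GAT search is unnecessary.

Single sequences work through the model-fitting interface:

```r
fit <- beat_fit(gen_jittered_comb(0.1, 0.08, 18, seed = 7), method = "gat")
fit
#> Beat fit (GAT method): 10.13 Hz
#>   goodness of fit: frmsd = 0.04807
#>   18 elements over 1.675 s
coef(fit); residuals(fit); plot(fit)
```

Label files and IOI tables are read with `read_label_file()` /
`read_ioi_table()` (tab-separated onset/offset rows; long-format CSV/TSV
with configurable column mapping). A thin command-line front end lives at
`inst/cli/ioirhythm.R` (`summarize`, `fft`, `gat`, `recurrence`,
`cluster`, `synth`, `run`).

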