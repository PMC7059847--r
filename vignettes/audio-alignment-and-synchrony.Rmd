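---
title: "Audio-based alignment of recordings and synchrony of expression time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audio-based alignment of recordings and synchrony of expression time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avsync)
library(ggplot2)
```

## The problem

Cameras that are not triggered by the experiment computer — head-mounted
action cameras above all — start recording at arbitrary times. Before any
frame-locked analysis, every recording must be aligned to the experiment
timeline. The practical trick is acoustic: a short, distinctive audio
segment (a "sync tune") is played at the start of the experiment, every
camera's microphone picks it up, and the recording is aligned by locating
that segment inside its audio track. The **offset** is the number of
seconds that must be trimmed from the start of a recording so that it lines
up with the reference; by this convention the reference occurs `offset`
seconds into the recording, and negative offsets (a recording that started
*after* the reference) are out of range — the roles must be swapped.

`avsync` implements that alignment, the agreement analysis used to validate
it against human raters, and the downstream statistics usually run on the
aligned recordings: event-locked comparisons of facial-expression evidence
and intersubject correlation (ISC) of expression time series.

## The alignment objective

Let $t_1,\dots,t_m$ be the reference samples and $s_1,\dots,s_n$ the
recording, both mono at a common rate $f$ (stereo is down-mixed; a rate
mismatch is resolved by resampling the lower-rate track up). For a
candidate lag of $k$ samples the sliding-correlation detector scores the
Pearson correlation

$$ r(k) \;=\; \mathrm{cor}\!\left(\, (t_1,\dots,t_m),\; (s_{k+1},\dots,s_{k+m}) \,\right), $$

and returns $\hat k = \arg\max_k r(k)$ over a grid of lags, ties broken to
the earliest lag so results are reproducible. The default grid spacing is
1 ms — the precision at which human raters do the same task by nudging
waveforms until the echo disappears — and the search covers the whole
feasible range unless restricted. Pearson scoring makes the detector
invariant to gain and DC differences between the two microphones, which
matters because the cameras record the room, not the line signal.

The FFT detector computes the same family of scores at *every* sample lag
at once: both signals are zero-meaned, the cross-products at all lags come
from one Fourier transform, and each lag is normalized by the energy of the
reference and of the window it faces, so that a perfect match scores 1 and
all scores lie in $[-1, 1]$. Internally the sliding-correlation search uses
the same transform plus running window sums, so both detectors cost
$O(n \log n)$ and a 1-minute recording at 8 kHz aligns in well under a
second.

Numerical edge cases are handled so that the argmax is always defined:
zero-variance windows (silence) score 0 with a warning rather than NaN, and
scores are clipped to $[-1,1]$ against floating-point overshoot.

### Two-stage search and its limits

`refine_offset()` re-searches ±2 coarse steps around a coarse optimum at a
finer spacing, and never returns a worse score than the coarse result. A
caveat worth stating plainly: a coarse-then-fine strategy assumes the
correlation peak is *wider than the coarse step*, i.e. that the reference
has energy at periods longer than the step. A tune made of 400–800 Hz notes
has a correlation peak only a couple of milliseconds wide, so a 10 ms
coarse grid can miss it entirely while period-aliased side lobes score
higher; with low-frequency content (tens of Hz) the coarse stage is
reliable. The same reasoning says a 1 ms grid search is only well-posed
when the true offset lies on (or effectively on) that grid; a sub-grid
truth should be chased with a sample-resolution search
(`step = 1/rate`, or `find_offset_xcorr()`), not with a coarser grid.

`shift_preview()` is the non-interactive stand-in for listening: it overlays
the reference with the shifted recording, and a residual offset error of
$d$ seconds shows up as an echo — a secondary autocorrelation peak at lag
$d$ — in the mixed audio.

## Audio plumbing

WAV (RIFF PCM) reading and writing supports 16/24-bit integer and 32-bit
float encodings. Integer samples are scaled by $2^{\text{bits}-1}$, so
full-scale positive 16-bit is $32767/32768$ — the slight asymmetry of the
integer range is kept rather than hidden. Resampling is done in the
frequency domain (spectrum truncation/zero-padding at the new length):
unlike FIR polyphase resamplers it introduces **no group delay**, which is
the property an alignment package actually needs; the price is a few
samples of wrap-around ringing at the ends of non-periodic signals.

Audio extraction from video containers and video trimming are a thin
contract over an external decoder binary (ffmpeg, found on the PATH or via
`options(avsync.decoder=)` / `AVSYNC_DECODER`). The seam is deliberately
narrow — build the argument list, run, read back — so the test suite can
substitute a fake decoder and the package can detect and report a missing
binary with an install hint. WAV trimming itself is pure R and
sample-exact; video cuts inherit the decoder's nearest-frame seeking.

## Agreement between automatic and manual offsets

The validation question is whether the detector agrees with careful human
alignment. `summarize_agreement()` consumes a wide table (one row per
recording, one column per rater, one automatic column) and reports, with
the difference always defined as automatic − manual:

* per recording: mean and SD of the differences across raters,
* per group label: pooled mean and SD over all differences in the group,
* overall: mean, SD, and a one-sample t-test of all differences against 0,
  with df = (number of differences) − 1.

SDs use the $n-1$ denominator and rounding happens only at print time. The
package ships a published 13-recording, 4-rater benchmark table
(`inst/extdata/manual_auto_offsets.csv`); on it the overall mean difference
is 0.001 s (SD 0.022) and the one-sample test gives t(51) = 0.46 — the 52
differences are treated as independent although raters share recordings, a
simplification the field makes and which we keep and label. (Note the
benchmark's own printed test quotes 50 degrees of freedom; with 52
differences the computed df is 51, and we report what we compute.)

## Expression analytics

Expression classifiers emit per-frame "evidence" values per channel (joy,
disgust, ...). The package keeps such series in long tibbles
(`subject_id`, `channel`, `time`, `value`).

* `downsample_series()` bin-averages to a lower rate: output sample $k$ is
  the mean over $[k/f_{out}, (k+1)/f_{out})$, trailing partial bins
  dropped. Analyses of slow affective signals conventionally run at 1 Hz.
* `epoch_means()` averages evidence inside each event window
  $[\text{onset}, \text{onset}+\text{duration})$; a `max` statistic is
  available behind a flag because window summaries are reported both ways.
* `two_sample_t()` / `two_sample_t_summary()` compare conditions with a
  pooled-variance t (df $n_1+n_2-2$); the summary route exists so published
  group summaries can be checked directly, and the two routes agree exactly
  on the same data. Welch's correction is behind a flag.
* `pairwise_isc()` computes Pearson correlations between all
  $n(n-1)/2$ subject pairs; the group summary (mean r, SD) is reported on
  the r scale, as is conventional.
* `isc_one_sample_test()` tests synchrony against zero on Fisher-z
  transformed correlations ($z = \operatorname{atanh} r$, clipped at
  $|r| = 1-10^{-7}$ with a warning), df = pairs − 1.
* `isc_condition_compare()` compares synchrony between two conditions on
  the z scale, either as a paired test matching pairs by label
  (df = pairs − 1) or as a pooled two-sample test (df $= n_1+n_2-2$; with
  10 pairs per condition that is df 18). Both are provided because group
  studies report this comparison both ways, and the two dfs differ; the
  output labels which was run.

Two-sided p-values are used throughout. A known limitation, inherited from
standard practice: the $n(n-1)/2$ pairwise values are not independent
(each subject appears in $n-1$ pairs), and the one-sample t-test ignores
this. Under the null of no shared signal the pairwise correlations are
uncorrelated, so the test size stays near nominal (measured ≈ 5% at
$\alpha = .05$ in the acceptance suite), but under strong synchrony the
effective degrees of freedom are fewer than pairs − 1.

## What the generators emulate

The synthetic fixtures define the conditions under which the package's
claims are tested.

* `make_sync_tune()` builds the reference: a sequence of equal-amplitude
  pure-sine notes (defaults: 2 s, notes at 440/554.37/659.25/783.99 Hz —
  an A-major-ish arpeggio of non-commensurate frequencies — at 8 kHz),
  5 ms cosine ramps, peak-normalized to exactly 0.9. Notes in sequence
  rather than summed keep the autocorrelation side lobes low, so the
  offset objective has one clear peak.
* `embed_tune()` drops the tune into Gaussian white noise at a known,
  sample-grid-snapped offset, with the SNR defined over the tune segment
  (where it matters for detection). Same seed, same bytes.
* `make_isc_group()` generates each subject as
  $\sqrt{\rho}\,\text{shared} + \sqrt{1-\rho}\,\text{private}_i$ with
  independent unit-variance Gaussian AR(1) components (coefficient 0.5 by
  default — real evidence traces are autocorrelated, not white), so the
  expected pairwise correlation is exactly the target $\rho$.
* `sim_event_table()` + `make_event_responses()` emulate an event-locked
  design: 10 trials per condition, 2 s stimuli, jittered 4/6/8 s intervals,
  boxcar responses plus Gaussian noise (default SD 1.5 in evidence units,
  chosen so condition effects of ~8 vs ~0.5 separate decisively, echoing
  published group means from such designs).

What the generators do **not** emulate, and hence what green tests do not
show: room reverberation, camera-microphone frequency response and
compression, clock drift between devices (explicitly out of scope),
non-Gaussian evidence distributions, or classifier dropouts when a face is
lost. The detectors' 100/100 recovery at SNR ≥ 0 dB on white-noise
fixtures is an upper bound on field performance, not a promise about any
particular camera.

## Problem sizes and seeds

The bundled analyses use the sizes the methods are designed around: 2 s
tunes in 60 s recordings at 8 kHz for the 100-fixture recovery study
(SNR drawn uniformly from 0–20 dB, true offsets on the millisecond grid);
groups of 5 subjects × 10,000 samples for ISC recovery at
$\rho \in \{0, .2, .4, .8\}$ and for the 200-replicate error-rate checks.
Every random draw flows from an explicit integer seed, fixtures are
bit-reproducible, and the CLI writes a JSON-lines log (tool version,
parameters, seeds) sufficient to replay any run.

## A short worked example

```{r example, fig.width = 6, fig.height = 3}
tune <- make_sync_tune(duration = 2, rate = 8000)
fx <- embed_tune(tune, total_duration = 60, true_offset = 7.916,
                 snr_db = 10, seed = 42)
res <- find_offset_sliding_corr(fx$target, fx$sample, step = 0.001)
glance(res)
autoplot(res)
```

```{r isc-example, fig.width = 5, fig.height = 4}
grp <- make_isc_group(n_subjects = 5, length = 10000, true_isc = 0.4, seed = 7)
isc <- isc_one_sample_test(pairwise_isc(grp$series))
glance(isc)
autoplot(isc)
```
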