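---
title: "Measuring and modelling fin whale 20 Hz song: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling fin whale 20 Hz song}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finsong)
```

## The problem

Male fin whales (*Balaenoptera physalus*) sing long, highly stereotyped
sequences of ~1 s downswept pulses centred near 20 Hz ("20 Hz notes").
The arrangement of inter-note intervals (INIs) — the time between the
center of one note and the center of the next — is regionally
distinctive and stable enough to serve as an acoustic marker of
subpopulation identity. In the New York Bight / Gulf of Maine pattern,
songs carry short INIs (~10 s) from fall into winter and long INIs
(~15 s) in spring, with variable transition periods in between; a year
in which long INIs persist through the fall instead is evidence of
either a behavioural shift or a second subpopulation moving through.

`finsong` implements the full measurement-and-analysis chain needed to
ask such questions of duty-cycled single-hydrophone recordings:

1. **songsynth** — a synthetic-deployment generator (waveforms plus
   ground-truth selection tables) so every downstream stage is testable
   without field recordings;
2. **audio / annotations** — WAV and Raven-style selection-table I/O,
   review-effort subsampling, daily song selection, singer attribution;
3. **note_measures** — spectrogram measurements per selection: inband
   power, peak/center frequency, 90% bandwidth, center time, SNR;
4. **ini_pipeline** — song construction, inclusion filters, INI
   computation and range filtering, song/period summaries;
5. **trend_models** — cyclic-spline gamma GAMMs for seasonal trends and
   model selection by AIC;
6. **pattern_class** — song and song-year pattern labels, transition
   and co-occurrence detection;
7. **workflow** — `run_pipeline()` orchestrates
   simulate → measure → analyze → report from one YAML config.

## Measurement conventions

All spectral measurements use a Hann window, 1024-point FFT and 90%
overlap at 2000 Hz sampling: a 1.953125 Hz × 0.051 s grid (reported as
1.95 Hz and 0.05 s at two decimals; the hop is `floor(0.1 * 1024) =
102` samples). Conventions mirror a Raven-style "robust" measurement
set:

* frequencies are reported on the bin grid `k * fs / nfft`;
* a frame belongs to a selection when its window-center time falls
  inside the selection;
* the PSD is scaled so total grid energy equals time-domain energy
  (Parseval, window- and overlap-gain corrected; tested to 1%);
* **inband power** is `10*log10` of the energy in the selection's
  time-frequency box, in dB re unit full-scale energy (relative, not
  calibrated to µPa — all downstream uses are ratios or comparisons);
* **peak frequency** is the bin maximising in-box energy (ties to the
  lower bin); **center frequency** is the first bin at which ascending
  cumulative energy reaches 50%; **90% bandwidth** is the span between
  the first bins reaching 5% and 95%. The discrete "first bin reaching
  the threshold" rule, with no interpolation, keeps every reported
  frequency bin-quantised — which is why reference medians such as
  19.53, 17.58, 27.34, 3.91 and 1.95 Hz are all multiples of
  1.953125 Hz.
* **center time** is the selection midpoint `(begin + end)/2`. An
  energy-median alternative was considered and rejected as the default
  because the midpoint is insensitive to SNR within the box, which is
  the reason center-to-center INIs are used in the first place.

One consequence of the Hann window worth stating: a pure on-bin
sinusoid spreads 1/4 of its amplitude into each adjacent bin, so its
discrete 90% bandwidth is two bins (3.91 Hz), not zero. A literal
single-bin spectrum does have zero bandwidth, and the tests
distinguish the two cases.

### SNR

For each note selection a noise window is auto-generated with the same
duration and frequency bounds, ending exactly 5 s before the note
begins. (The 5 s offset is the protocol; the equal duration is our
choice, making signal and noise energies commensurable.) With `S` the
linear inband power of the note box — signal plus noise — and `N` that
of the noise box,

$$\mathrm{SNR} = 10\log_{10}\!\frac{S - N}{N}\ \mathrm{dB},$$

so `S = 2N` gives 0 dB and `S = 11N` gives the 10 dB song-inclusion
boundary. When `S <= N` the SNR is undefined; the note is flagged and
excluded from SNR-dependent statistics rather than floored, since only
high-SNR material is retained downstream anyway. A noise window that
would start before the recording begins is likewise flagged. When the
noise window overlaps the previous note (possible when onset intervals
fall between 5 s and 5 s + two note durations), the measurement
proceeds as defined — the protocol is purely positional — but the row
is flagged `noise_overlap`.

## Song construction and filters

Singer identity is proxied by recording date: the review design keeps
at most one song recording per day, and days are farther apart than a
song sequence lasts. Songs must span at least 120 s (last note end
minus first note begin) and have mean SNR ≥ 10 dB; filters apply in
that order, and both boundaries are inclusive (a 9.9 dB song is out, a
10.0 dB song is in). Raw INIs are successive differences of note
center times; values below 4.5 s or above 30 s are removed with
machine-readable reasons (surfacing gaps, missed notes, multipath).
Song summaries (median, quartiles, IQR) and the pooled 75th-percentile
SNR threshold use linear-interpolation quantiles (R's default type 7).
Period means pool kept INIs over September–December ("short-INI
period") or March–May ("long-INI period") per song year, with the
s.e.m. computed as if INIs were independent; within-song
autocorrelation is the mixed model's job, not the summary's. Song
years run July 1 – June 30, aligned to the singing season.

"Clearest, most distinct song" — the daily selection rule — is
operationalised deterministically: most annotated notes, then highest
mean SNR, then earliest hour. Amplitude-based singer attribution keeps
the louder singer when every retained note is within ±3 dB of its
group median; any time-overlapping notes, or a note within 3 dB of
both singers' medians, excludes the whole song. The ±3 dB tolerance is
our threshold; the exclusion rule itself follows the field protocol.

## The synthetic-deployment generator

The generator writes what the analysis expects to read: 16-bit mono
PCM WAV at 2000 Hz in 30-min duty-cycle windows (30 min on per hour),
plus a tab-separated ground-truth selection table with `Singer`,
`SongID` and `TrueINI_s` columns.

* **Notes** are linear downsweeps with a Hann amplitude envelope. The
  frozen canonical note — 22.5 → 17.5 Hz over 0.9 s, amplitude 0.5 —
  sits inside the species-typical 23→18 Hz range and reproduces the
  reference spectral medians (peak 19.53 Hz, center 19.53 Hz, 90%
  bandwidth 3.91 Hz) under the measurement conventions above.
  Note duration and received levels are conventions, not published
  values, and are flagged as assumptions in the config.
* **Songs** draw onset intervals from a normal distribution around the
  month's mean (singlet patterning by default; a doublet offset is
  available), truncated to [4.5, 30] s, with every 10th interval
  replaced by a uniform 35–90 s surfacing gap — long enough that the
  INI range filter removes every gap by construction. Defaults give 31
  notes and 27 kept INIs per song (roughly 8 surfacing sequences),
  5–10 min of song per recording.
* **Deployments** assign song days per month — either preset counts
  (the per-month song counts of the reference study) or Bernoulli
  draws — and mix each song into power-law ("red") ambient noise with
  an exactly scaled RMS level (default −30 dB re full scale, −5
  dB/octave). Two presets fix the monthly INI means per song year:
  `"seasonal"` uses the song year's short-period mean in Sep–Dec and
  long-period mean in Mar–Jun, linearly interpolated with inflated
  jitter (1.5 s vs 0.3 s) through the Jan–Feb and Jul–Aug transitions;
  `"constant_long"` reproduces the song-year-four regime — long INIs
  year-round plus three short-INI intruder songs (one in October, two
  in November, mean 9.9 s). The constant-long Sep–Feb mean, 15.187 s,
  is solved so that the pooled September–December truth mean with
  equal kept-INI counts per song equals the reference 14.78 s cell.
* **Reproducibility**: one root seed; each day derives an independent
  child seed, so extending a date range never perturbs earlier days,
  and identical specs give bit-identical WAVs and truth tables.

What the generator does *not* emulate: propagation and multipath,
vessel noise and fish choruses, hydrophone response curves, clock
drift, or realistic received-level variation — synthetic SNRs
(~45–55 dB at the defaults) are far cleaner than field data, where the
75th-percentile SNR was near 32 dB. Passing tests therefore
demonstrate that the measurement and inference chain is correct, not
that it is robust to every field degradation; the SNR filter and
flagged-note machinery are exercised by dedicated low-SNR tests
instead.

## Trend models

Two candidate generalized additive mixed models for INI, both gamma
with log link and a per-singer random intercept:

* **m1**: `INI ~ s(month, cyclic, k ≤ 12) + s(song_year, k ≤ 5)` — one
  shared seasonal shape;
* **m2**: `INI ~ song_year + s(month, cyclic, k ≤ 12, by = song_year)`
  — a separate seasonal shape per song year, with the first observed
  song year as the reference level.

The month smooth is a cyclic cubic spline with period boundaries at
months 0.5 and 12.5, so predictions are continuous (value and slope)
from December into January; predicting at month 13 equals predicting
at month 1. Fits delegate to `mgcv::gam()` with the random intercepts
as `bs = "re"` smooths — the model family is exactly a GAMM, and a
single penalized-likelihood fit is more robust at simulation scale
than a nested lme representation. Smoothing parameters are estimated
by ML (not REML) so AICs are comparable across the two fixed-effect
structures; `select_model()` takes the AIC minimum with ties going to
the simpler model. With fewer than three distinct song years the m1
year spline degrades to a linear term. `R²` is reported as mgcv's
adjusted R², and the 95% bands are frequentist (link-scale normal
intervals back-transformed); both labels are stated in the output
because other conventions exist.

Spectral characteristics (center frequency, peak frequency, 90%
bandwidth of high-SNR notes — at or above the pooled 75th-percentile
SNR, on days with ≥ 10 such notes) are modelled the same way but with
identity link (the responses are far from zero, and the reference
analysis used an identity link), `k ≤ 10` for the month smooth
(late-spring months are typically absent), and a per-date random
intercept. Identity-link gamma predictions can go negative on
pathological data; the package warns rather than silently clipping.

Simulation tests verify the selection direction rather than any
coefficient value: data generated with a shared seasonal shape select
m1, and data with one aberrant constant-long year select m2 and flag
that year's coefficient, in ≥ 90% of 20 seeds at the test's sample
sizes (2 songs/month, 12 INIs/song). Absolute AIC or coefficient
values from the reference study are not reproducible without its
(undeposited) recordings and are not targets.

## Pattern classification

Songs are labelled SHORT when their median INI is strictly below
12.5 s — the midpoint of the ~10 s and ~15 s modes — else LONG; an
IQR above 2 s flags a variable (transition-type) song. A song year is
`SEASONAL_SHIFT` when Sep–Dec songs are predominantly SHORT and
Mar–Apr songs predominantly LONG; `CONSTANT_LONG` when ≥ 75% of
labelled songs are LONG including the fall months; symmetrically
`CONSTANT_SHORT`; otherwise, or with fewer than four labelled months,
`UNDETERMINED`. Co-occurrence — both labels in one month × song-year
cell with at least two songs — is the overlap signature. Transition
months are those whose song-median dispersion exceeds twice the
stable-month dispersion or whose monthly median lies more than 1 s
inside both modes. Every one of these constants (12.5 s, 75%, 2×, 1 s,
4 months) is a package convention exposed as an argument: the
reference analyses classified by inspection, and the run outputs carry
the thresholds in force so a reader can see exactly what produced a
label.

## Numerical choices and degenerate inputs

* Quantiles everywhere are linear-interpolation (type 7); documented
  and configurable where they matter (song summaries, SNR threshold).
* The spectrogram refuses recordings shorter than one window; empty
  box/grid intersections are errors, not NAs.
* Songs with fewer than two notes produce empty INI series; songs with
  no kept INIs are dropped from summary-level outputs.
* `compute_inis` sorts notes internally; nothing depends on input row
  order, and model fits are row-order invariant (tested to 1e-6).
* WAV samples are quantised `round(x * 32768)` clamped to the 16-bit
  rails, so write → read round trips are bit-exact.
* Period means for absent periods return an explicit "no data" row
  rather than an error, matching how effort gaps are reported.

## Problem sizes used in validation

The test suite and the acceptance script regenerate everything from
code. End-to-end recovery runs use the preset song counts — 16 songs
(song year 2, Sep–Dec), 13 songs (song year 1, Mar–May) and 39 songs
(song year 4, Sep–Dec, including the three intruders) — each song a
30-min, 2000 Hz recording with 31 notes, measured through the full
waveform → spectrogram → filter chain; the acceptance script averages
five independent deployment seeds per song year. Model-selection and
classifier properties use 20 seeds at truth level (no audio), where a
song year is a few hundred to a couple of thousand INIs. These sizes
give recovery standard errors near 0.01 s, an order of magnitude
tighter than the distinctions the analysis cares about (10 s vs 15 s).

## Known limitations

* Note *detection* is out of scope: selections come from annotations
  (or generator truth), never from the audio itself.
* Inband power is relative (dB re full scale), not calibrated; only
  ratios and comparisons are meaningful.
* The s.e.m. on period means understates uncertainty because INIs
  within a song are autocorrelated; use the GAMM layer for inference.
* The pattern thresholds are conventions; near-threshold songs
  (medians near 12.5 s) can flip labels under measurement noise larger
  than ~0.5 s, and the outputs flag the threshold used.
* Songs are recording-bound by design (one 30-min window); sequences
  spanning multiple duty cycles are not stitched.
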