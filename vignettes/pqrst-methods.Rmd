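---
title: "Methods: bilateral-filter PQRST delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral-filter PQRST delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pqrst)
```

## The model

A single-lead ECG beat is a narrow, tall QRS complex flanked by the low,
wide P- and T-waves. `pqrst` exploits exactly this contrast. Each sliding
window of the record is min–max normalized to $I \in [0,1]$ and passed
through a one-dimensional bilateral filter

$$B(x) = \frac{1}{W_p}\sum_{x_i \in \Omega} I(x_i)\,
  e^{-\frac{(x_i-x)^2}{2\sigma_{d,\Omega}^2}}\,
  e^{-\frac{(I(x_i)-I(x))^2}{2\sigma_{r,\Omega}^2}},$$

whose window $\Omega$ spans $2N+1 = 15$ samples at 360 Hz. The two standard
deviations adapt to the local population variance $\sigma^2(\Omega)$ of the
normalized signal:

$$\sigma_{d,\Omega} = \log_2\!\Big(\tfrac{\sigma^2(\Omega)}{\sigma^2_{max}}+1\Big)
  \sigma_{d,max} + \sigma_{min},$$

and analogously for $\sigma_{r,\Omega}$, with
$\sigma^2_{max} = 0.1310$, $\sigma_{d,max} = 10$, $\sigma_{r,max} = 1$,
$\sigma_{min} = 10^{-5}$. High-variance windows (QRS) are smoothed hard;
low-variance windows (baseline, P/T) pass through almost unchanged. $B$ is
therefore a *background predictor*: the ECG with its QRS suppressed. The
residual $D = I - B$ isolates the QRS, a moving sum over $2n+1$ samples
($n = 5$ at 360 Hz) enhances it to $E$, and maximal runs of $|E| >
\max|E|/2$ of length $L \ge 8$ are candidate-R intervals. Within a run the
R-peak is the argmax of $I$ if the run's excursion above the window mean
dominates ($\gamma = +1$), else the argmin ($\gamma = -1$, e.g. a PVC);
tied extrema (flat-topped R) resolve to the floor of their mean position.

Two notes where we depart from a literal transcription of the printed
method, both forced by internal consistency:

* **Magnitude thresholding.** The candidate rule is applied to $|E|$, not
  signed $E$. The polarity decision explicitly supports inverted R-waves,
  but an inverted R produces a *negative* residual lobe; thresholding
  signed $E$ at $\max E / 2$ would find only its small positive sidelobes.
  Using $|E|$ also makes detection exactly invariant under signal
  inversion, which we test.
* **Slope-predicate orientation.** With the backward difference
  $I'(t) = I(t) - I(t+1)$, the printed Q/S conditions describe a
  $\gamma$-oriented local *maximum*, yet Q and S are the notches *below*
  the R flanks — $\gamma$-oriented minima. We implement the minimum
  orientation ($\gamma\,\mathrm{sign}\,I'(x-1) > 0 \wedge
  \gamma\,\mathrm{sign}\,I'(x) < 0$); the onset/offset predicates keep the
  printed relaxed ($\le/\ge$, two-point confirmation) form, which is
  geometrically coherent for the shoulders.

## Fragmented R-waves

Additional R-peaks (fR-L, fR-R, fR-L2, fR-R2 patterns) are found by
scanning outward from R within $\alpha_f = \mathrm{round}(\tfrac12 F_s
\cdot 0.12\,\mathrm{s})$ samples of the most recently accepted peak. A
candidate must be a $\gamma$-oriented local maximum whose rebound sum of 10
successive point-pair differences exceeds $Th_f = 0.1$ on the normalized
scale. On the right side the printed sum telescopes to
$I(p)+I(p+1)-I(p+10)-I(p+11)$ — the drop over ten samples; the left-side
sum is implemented as its mirror (the printed index pattern mixes samples
from both sides and cannot fire on a mirrored left notch), and both sums
are multiplied by $\gamma$ so fragmented *inverted* beats are treated
symmetrically. Acceptance extends the scan recursively, so several notches
are found in order.

## P/T delineation and the point filters

Q, Q-onset, S, S-offset are detected on the normalized signal $I$; the P-
and T-wave fiducials on the noise-suppressed background $B$. The search
geometry is fixed by typical interval durations: $\alpha_Q =
\mathrm{round}(F_s\,QRS/2) + \alpha_{QM}$, $\alpha_{QL} = \alpha_{SR} =
\mathrm{round}(F_s\,QRS)$, $\alpha_P = \mathrm{round}(F_s\,PR)$, $\alpha_T
= \mathrm{round}(F_s\,(QT - QRS))$ with $QRS = 0.12$ s, $PR = 0.2$ s, $QT
= 0.44$ s. All sample-valued constants stated at 360 Hz (the run length 8,
the enhance half-width 5, the wing lengths 10/20) are rescaled by
$\mathrm{round}(F_s k / 360)$, so 250 Hz records work unchanged.

A P- or T-peak of polarity $\omega$ is accepted at $x$ when at least a
fraction $\rho = 0.95$ of the $2(w - v)$ wing slopes match the apex
pattern: $\omega\,\mathrm{sign}\,B'(x-l) \le 0$ on the left and
$\omega\,\mathrm{sign}\,B'(x+r-1) \ge 0$ on the right, with wings
$l, r \in \{v+1, \dots, v + (w-v)\}$ and base wing $w = 10$ (P) or $20$
(T). The deformation width $v$ starts at 0 and grows (to 5 for P, 10 for
T) until something is accepted; it skips samples next to the apex so
plateaued or locally notched waves still fire, and the accepted $v$ seeds
the onset/offset scans. $\rho_P$ is printed once as 0.9 and once as 0.95;
we default to 0.95, matching $\rho_T$, and expose it in
`detector_config()`.

Three design choices here are ours:

* **`sign(0)` passes, with an admissibility guard.** Zero slopes satisfy
  both wing inequalities — the deformation mechanism needs this — but on a
  perfectly flat segment *every* point then fires and the scan would
  return the Q-onset shoulder as "P-peak" on any clean record. We
  therefore additionally require each wing side to contain at least one
  strictly-signed satisfying slope. On real, noisy ECG the guard is
  vacuous; on clean synthetic data it restores apex recovery.
* **Cluster refinement.** With $\rho < 1$ the scan's first acceptance
  lands 1–2 samples before the apex (its shoulder already passes 38/40
  wings). Within one contiguous run of accepting positions we return the
  position with the maximal wing count (earliest on ties). Separated
  acceptance clusters keep first-wins semantics.
* **Onset/offset wing signs.** The printed onset/offset conditions repeat
  the apex sign pattern, which cannot hold at the toe of a clean wave (the
  inner wing sits on the rising wall). We use the mirrored pattern —
  $\omega\,\mathrm{sign}\,B'(x-l) \ge 0$ (left), $\omega\,\mathrm{sign}\,
  B'(x+r-1) \le 0$ (right), all wings required ($\rho = 1$), wings 2/4 for
  onsets and 4/2 for offsets — under which the outward scan from the apex
  stops exactly at the toe.

When both polarities yield a complete (onset, peak, offset) triple, the
inverted candidate wins only if it is both wider and spans the larger
triangle area on $B$ (computed as the absolute shoelace area of its three
fiducials). Undetected P/T points are mapped: a missing P-peak collapses
all P fiducials onto the Q-onset, a missing T-peak onto the S-offset, a
missing onset onto the peak/S-offset and a missing offset onto the
Q-onset/T-peak, so every emitted beat carries all 11 fiducials and
satisfies the ordering invariant. At high heart rate, when the previous
T-offset reaches the Q-onset, the P search range is empty and the P-wave
is mapped rather than searched across the beat boundary.

## Sliding windows and seam stitching

Records are processed in windows of 2000 samples with step 1600 (at
360 Hz; both rescale with $F_s$), so consecutive windows overlap by 400
samples and all window statistics ($S_{min}$, $S_{max}$, $I_{mean}$,
$E_{max}$) are local, as a streaming implementation requires. Beats
reported by two windows are matched on their R-peak within 50 ms and
collapsed; a beat is *perfect* in a window when its R lies at least
$\mathrm{round}(0.44\,\mathrm{s}\cdot F_s)$ samples from both window
edges — the typical QT time, i.e. the farthest any fiducial extends from
its R — and perfect copies from the earliest window win. A margin of only
half the fragment range would protect the QRS scan but not the T-wave
search, and the stitcher would keep seam beats whose T fiducials were
truncated at the window edge; the QT-sized margin makes "perfect"
coincide with "all 11 fiducials had room". Stitching is idempotent, and
the stitched R set is stable (within one sample) across steps 1400, 1600
and 1800.

## HRV and interval trends

From the detected R-peaks: RR mean/SD (s), instantaneous heart rate
$60/RR$ mean/SD (bpm), NN50 (strict $|\Delta RR| > 50$ ms), pNN50
$= 100\,\mathrm{NN50}/(n-1)$, RMSSD (ms), the triangular index HTI
(intervals divided by the peak count of the RR histogram at 1/128 s bins)
and TINN (baseline of the least-squares triangle over that histogram,
ms). Frequency-domain powers integrate a Welch PSD (Hann window, segments
up to 120 s, 50% overlap) of the tachogram linearly resampled at 4 Hz and
demeaned, over VLF 0–0.04, LF 0.04–0.15, HF 0.15–0.40 Hz in ms²;
normalized units divide by total minus VLF. A `method = "direct"` variant
treats the interval series itself as uniformly sampled at the mean beat
rate, for the reading of tachogram processing that skips resampling. No
ectopic-interval filtering is applied by default. Per-beat trends are
plain fiducial arithmetic: ST = S-offset→T-onset, PR = P-onset→Q-onset,
QT = Q-onset→T-offset, in seconds; fully mapped P-waves legitimately
produce PR ≈ 0.

## The synthetic generator

`synthesize_record()` is the package's test substrate, not a realism
exercise. Each wave is a *truncated* Gaussian bump — shifted down by 1% of
its amplitude and clipped at zero — so the support is exactly finite, the
apex and the onset/offset toes are analytically known, and slopes vanish
identically outside the support. Defaults: P 0.15 mV at −0.170 s
(σ 0.015 s), Q −0.10 mV at −0.030 s (σ 0.008 s), R 1.0 mV (σ 0.016 s),
S −0.15 mV at +0.035 s (σ 0.008 s), T 0.30 mV at +0.250 s (σ 0.026 s),
RR 0.8 s: a textbook beat whose QRS lasts ≈ 0.10 s, PR ≈ 0.17 s and QT ≈
0.38 s. Fragment patterns plant narrow bumps (0.30 mV, σ 0.006 s) at
±0.036/±0.072 s so the planted notches are genuine local maxima of the
clean waveform; morphology flags cover inverted/absent P, inverted,
hyperacute, biphasic and plateau T, flat-topped R and negated QRS. White
Gaussian noise is added at a stated SNR, $10\log_{10}(P_{sig}/P_{noise})$
over the record, and sinusoidal baseline wander is optional. Everything is
bit-reproducible under a seed.

What passing on this substrate does *not* show: robustness to electrode
motion artifacts, muscle noise, rhythm pathology (AF, ectopy sequences) or
the full morphology spectrum of clinical databases. Those require
benchmark recordings, which the package deliberately does not bundle; the
CSV/JSON readers and the evaluation metrics (`match_annotations()` with
the 50 ms tolerance, `detection_metrics()`, `rmse_stats()` with
$RMSE = \sqrt{m^2 + s^2}$ and population SD) are the harness for running
them externally.

## Numerical choices and degenerate inputs

* All computation is double precision; the filter window truncates at
  record edges and renormalizes, so every output is a convex combination
  of window values and constant signals are exact fixed points.
* The variance mapping is open-ended above $\sigma^2_{max}$
  (`clamp_sigmas = FALSE` by default), as printed.
* Normalization defaults to min–max; the literal divide-by-maximum mode is
  available (`normalization = "literal"`) but does not map onto $[0,1]$
  for signals with negative baseline. Constant windows are degenerate and
  yield no beats.
* Scan ties resolve to the first index in scan direction; flat-top R ties
  to the floored mean of the tied extrema.
* Out-of-range wing points fail their condition (peaks, bounds); the
  relaxed Q-onset/S-offset look-ahead treats out-of-range confirmation
  points as satisfied so edge beats still resolve.
* Fragment rebound sums truncate at the window edge (partial sums against
  the same threshold).

## Problem sizes

The test suite and acceptance script run entirely on synthetic data:
50 clean 30-beat records (plus 8 at each of five SNR levels and a 120-beat
record for HRV) at 360 Hz, and filter-oracle comparisons on 100 random
signals of length ≤ 200. These sizes were chosen to exercise every code
path, including multi-window stitching, while keeping a full run in the
low minutes on one core.

## Worked example

```{r example}
rec <- synthesize_record(n_beats = 10, rr_jitter = 0.04, seed = 7)
det <- ecg_detect(rec$record, fs = rec$fs)
glance(det)
head(tidy(det)[, c("beat_id", "p_peak", "q_onset", "r_peak", "s_offset",
                   "t_peak", "gamma")])
hrv_time(rr_intervals(det))
```

```{r plot, fig.height = 3}
autoplot(det, xlim = c(1, 1200))
```
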