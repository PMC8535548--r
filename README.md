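# pqrst

Fiducial-point delineation of single-lead ECG: finds the eleven landmarks
of every heartbeat — P-onset, P, P-offset, Q-onset, Q, R, S, S-offset,
T-onset, T, T-offset — plus R-wave polarity and fragmented (notched)
R-peaks, and derives heart-rate-variability metrics and ST/PR/QT interval
trends from them. It is aimed at biomedical-signal researchers who need a
transparent, fully inspectable PQRST delineator and a ground-truth
synthetic substrate to validate detection pipelines against.

## Method

The detector rests on a variance-adaptive one-dimensional **bilateral
filter** used as a background predictor. Each sliding window (2000
samples, step 1600 at 360 Hz) is normalized to I ∈ [0, 1] and filtered
with

    B(x) = (1/Wp) Σ_{xi∈Ω} I(xi) · exp(−(xi−x)²/2σd²) · exp(−(I(xi)−I(x))²/2σr²)

where both standard deviations grow with the local window variance:
σ = log2(σ²(Ω)/σ²max + 1)·σmax + σmin (σ²max = 0.1310, σd,max = 10,
σr,max = 1). The narrow, high-variance QRS is smoothed away while P/T
waves and baseline pass through, so the residual D = I − B isolates the
QRS. A moving sum enhances D to E; runs of |E| > max|E|/2 with length
L ≥ 8 are candidate-R intervals, and the R-peak is the run's argmax (or
argmin for inverted beats, γ = −1). Q/S and their shoulders follow from
γ-oriented slope predicates on I; P/T peaks, onsets and offsets from
symmetric and asymmetric point filters on B, with a deformation-width
recursion for plateaued waves, a width-and-area rule for inverted waves,
and mapping of undetected points onto Q-onset/S-offset so every beat is
complete. Per-window beats are stitched across the 400-sample window
overlap with seam-beat references.

Evaluation uses the field's conventions: sensitivity Se = TP/(TP+FN),
positive prediction +P = TP/(TP+FP), detection error DER = (FP+FN)/(TP+FN)
at a 50 ms matching tolerance, and RMSE = √(m²+s²) for delineation errors.

See `vignettes/pqrst-methods.Rmd` for the full model, parameter table and
design rationale.

## Worked example

```r
library(pqrst)

rec <- synthesize_record(n_beats = 10, rr_jitter = 0.04, seed = 7)
det <- ecg_detect(rec$record, fs = rec$fs)
det
#> <ecg_detection> 10 beats over 2895 samples at 360 Hz (2 windows)
#>   inverted R: 0  fragmented: 0

head(tidy(det)[, c("beat_id", "p_peak", "q_onset", "r_peak", "s_offset",
                   "t_peak", "gamma")], 3)
#>   beat_id p_peak q_onset r_peak s_offset t_peak gamma
#> 1       1     30      71     91      113    181     1
#> 2       2    351     392    412      434    502     1
#> 3       3    622     663    683      705    773     1

hrv_time(rr_intervals(det))
#>   rr_mean rr_std hr_mean hr_std  nn50 pnn50 rmssd   hti  tinn
#> 1   0.795 0.0440    75.7   3.95     2    25  57.6   4.5  23.4

m <- match_annotations(det$beats$r_peak, rec$truth$r_peak, fs = 360)
cbind(m, detection_metrics(m))
#>   total tp fn fp  se  pp der
#> 1    10 10  0  0 100 100   0
```

The beat table gives 1-based sample indices: beat 1 has its P apex at
sample 30, QRS onset at 71, R at 91 and T apex at 181, i.e. a PR interval
of (71−30)/360 ≈ 0.11 s and upright polarity (γ = +1). The HRV row says
the jittered RR series averages 0.795 s (75.7 bpm) with RMSSD 57.6 ms.
The matching row confirms all 10 planted beats were recovered within
50 ms with no false positives. `autoplot(det)` overlays the fiducials on
the trace, and `interval_trends(det)` returns per-beat ST/PR/QT durations.

A thin CLI wraps the same functions
(`inst/cli/pqrst detect|eval|hrv|synth`).

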