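---
title: "Delineating ECG fiducial points with sliding-window parabola regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating ECG fiducial points with sliding-window parabola regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgparafit)
```

## The method

A single-lead ECG is a quasi-periodic voltage trace whose clinically
meaningful landmarks are five wave apices per beat: P, Q, R, S and T.
This package locates them with one primitive applied twice at different
scales: a sliding-window least-squares fit of a vertex-centred parabola,

$$y'(j) = a\,(i-j)^2 + v, \qquad j \in [i-w,\; i+w],$$

scored by the quadratic-mean fit error
$\varepsilon(i) = \frac{1}{2w+1}\sum_j \big(y(j)-y'(j)\big)^2$.
Substituting $x = (i-j)^2$ makes the fit a simple linear regression, so
$a$ (the opening coefficient, mV/sample²) and $v$ (the vertex amplitude,
mV) have closed forms, and the whole profile over all centres reduces to
moving sums — the reason the method is cheap enough for embedded use.

Three properties of the pair $(a, \varepsilon)$ carry all the
information the detectors use:

* at a wave apex the trace is locally parabolic, so $\varepsilon$ has a
  local minimum there;
* line-like stretches also yield small $\varepsilon$, but with
  $|a| \approx 0$ — the magnitude of $a$ separates waves from the
  isoelectric line;
* the model has no linear term, so with $x \ge 0$ an upward peak fits
  with $a < 0$ and a downward peak with $a > 0$: the sign separates
  maxima from minima. Printed threshold conditions on $a$ are therefore
  interpreted as magnitude conditions, with the sign used as the
  polarity filter — a literal $a > 5\times10^{-4}$ would reject every
  upward R peak.

## Pipeline and parameters

`delineate_ecg()` chains the stages; each is exported separately.

**Preprocessing.** A Butterworth low-pass (order 10, cut-off 100 Hz, the
upper edge of the diagnostic ECG band) removes broadband and EMG noise.
Filtering is zero-phase (forward–backward) by default: a causal pass
would delay every apex by the group delay, which is fatal when detections
are scored against references at a 10 ms tolerance. The trace is
reflect-padded by ten nominal filter lengths so the order-10 startup
transient (which decays over roughly a hundred samples) never reaches
the retained segment. Baseline wander is then removed by subtracting an
order-8 polynomial fitted to the whole record by least squares. The
polynomial is built on a normalised index $u = i/(N-1)$: a raw-index
Vandermonde basis at order 8 over $10^4$ samples is numerically
singular. Order 8 tracks roughly two wander cycles per record; slower
drifts vanish, faster wander (several cycles in a 20 s strip) is beyond
its reach and partially survives.

**Window sizes.** The R window half-width is `round(0.030 * fs)` samples
(the approximate width of the R apex inside a 70–100 ms QRS), the
narrow P/Q/S/T half-width `round(0.012 * fs)` (sized to the 20–30 ms Q
wave). Rounding is half-away-from-zero with a floor of one sample,
which reproduces the published 500 Hz sizes ($w=15$, length 31;
$w=6$, length 13) and stays defined at any rate. Because $a$ is in
mV/sample², its thresholds are rate- and gain-dependent: the defaults
hold for mV-scaled signals at 500 Hz and scale as $(fs/500)^2$
elsewhere.

**R detection.** Candidates are strict local minima of $\varepsilon$
(the centre of an $\varepsilon[i-2] > \varepsilon[i-1] < \varepsilon[i]$
triplet; plateaus of equal values report their leftmost centre) with
$|a| > 5\times10^{-4}$ and $a < 0$. Candidates closer than a 200 ms
refractory (a 300 bpm ceiling, absent from the printed method but
needed against notched R waves) collapse to the steepest parabola.

**Isoelectric level.** The mean of the trace over centres that are both
flat ($|a| < 10^{-4}$) and well fitted ($\varepsilon < 0.01$ mV²).
The printed flatness condition appears with the inequality reversed; the
accompanying text ("make minimum this value to fit our parabola at a
straight line") is unambiguous, so flatness is implemented as a maximum
on $|a|$. Two caveats are worth knowing. First, the parabola has no
slope term, so a slanted line of slope $m$ passes the error gate
whenever $m^2 \cdot w(w+1)/3 < 0.01$ — every physiologic wave shoulder
qualifies. Those shoulders pull the estimate upward by a few hundredths
of a mV on typical morphologies (the package's tests bound the bias at
0.05 mV). Second, if no centre qualifies (a pathological, never-flat
trace) the signal median is returned with a warning.

**Segmentation.** Beats are fixed windows centred on each interior
detected R: half-width `round(mean RR / 2)`, length `2*half + 1`, which
reproduces the published pair (192, 385) from the published mean spacing
384.28 samples. The first and last R serve as the reference frame and
are not segmented, so $k$ detections yield $k-2$ beats. (The source
description also speaks of extracting as many beats as detections in its
worked example; the explicit minus-two rule is implemented and the
discrepancy left at that.) Windows that overrun the record — possible
with irregular rhythm — are zero-padded and flagged.

**P/Q/S/T delineation.** Within each beat the narrow window yields
candidates of either polarity (magnitude floor $|a| > 10^{-4}$, the same
flatness threshold, so line-like centres never become candidates).
Amplitude margins around the isoelectric level then discard
insignificant ripples: maxima must exceed `iso + upper_margin`, minima
fall below `iso - lower_margin` (0.08 mV each by default). The margins
are data-dependent by construction — they should sit slightly below the
smallest wave expected in the data — and are the method's documented
weak point: a shallow Q whose rendered apex lands inside the margin is
reported absent, never mislabelled. Same-polarity candidates closer
than 40 ms keep the one farther from the isoelectric level; the
de-duplication is per polarity because the Q–R and S–R apex gaps
(~30 ms) are physiologically shorter than any sensible refractory.
Labelling is relative to R: Q is the nearest minimum before R, S the
nearest after, P the largest maximum before Q, T the largest after S,
with candidates restricted to 300 ms before / 400 ms after R (generous
clinical PR and R-to-T bounds). Without that restriction a beat window
that overlaps its neighbour — routine under R-R jitter — would label the
neighbour's R as its T.

**Sensitivity.** A detection matches a reference of the same label when
their temporal distance is at most the tolerance (10 ms by default;
boundary inclusive). Matching is greedy nearest-first with each
detection consuming at most one reference; pooled point-level counts are
the primary report (they reproduce the published Q arithmetic,
175 missed of 7020 → 97.5%), with a per-record variant behind
`level = "record"`. Labels with no reference points are reported
undefined rather than zero.

## The synthetic generator

`generate_ecg()` renders each beat as five Gaussians on a constant
baseline — amplitude, apex offset from R, and width per wave — at R
times spaced `rr_mean` apart with truncated-Gaussian jitter, plus
optional sinusoidal wander, sinusoidal powerline interference, white
noise, and band-limited EMG-like noise. A sum of Gaussians was chosen
over a dynamical-system ECG model because it gives closed-form control
of every amplitude and width, which the margin-failure tests need.
Ground-truth annotations are recomputed as exact extrema of the rendered
noiseless component, so overlap between neighbouring waves (the R
upslope partially filling the Q dip, for instance) is reflected in the
truth rather than biasing the score. Two seeds drive two independent
streams: `seed` for the noise terms, `rr_seed` for beat placement, so
changing only the noise seed re-draws noise over a bit-identical
noiseless trace.

The default morphology is a textbook lead-I beat: P(−160 ms, +0.15 mV,
σ 25 ms), Q(−30 ms, −0.10 mV, σ 8 ms), R(0, +1.0 mV, σ 12 ms),
S(+30 ms, −0.15 mV, σ 10 ms), T(+250 ms, +0.30 mV, σ 45 ms).
`random_template()` draws morphologies uniformly from physiologic
ranges; two of its bounds encode method-level constraints worth stating.
Positive-wave amplitude floors (P ≥ 0.15 mV) keep the smallest wave
clearly above the 0.08 mV margin plus the upward isoelectric bias —
the same calibration a user must perform on real data when choosing
margins. And the P offset stays within 180 ms of R because an apex at
exactly the 200 ms R refractory distance can, when steep enough to pass
the R curvature threshold, survive refractory collapse as a false R;
130–180 ms is also the textbook peak-to-peak range.

What the generator does **not** emulate: pathological morphologies
(ectopy, bundle-branch blocks, atrial fibrillation), respiratory
modulation, electrode motion artefacts, and the amplitude
non-stationarity of real recordings. Passing the synthetic suites
therefore demonstrates correctness of the mechanism under the model's
assumptions, not clinical-grade performance; on real data the margins
and curvature thresholds must be re-tuned to the lead, gain and rate.

## Numerical choices and degenerate inputs

* The vectorised profile uses moving sums and agrees with the per-window
  closed form to well below 1e−12; the per-window path computes
  $\varepsilon$ directly from residuals, avoiding the cancellation of
  the sum-of-squares identity.
* Ties in the error signal (plateaus) break leftmost; all local-minimum
  inequalities are strict.
* The detected apex is the fitted vertex position (the error minimum),
  which can sit a sample or two off the raw sample extremum when the
  window straddles an asymmetric neighbour (measured worst case: two
  samples on clean synthetic beats) — comfortably inside the 10 ms
  tolerance.
* Degenerate inputs error early with messages naming the precondition:
  windows outside the signal, `w = 0`, cut-offs at or above Nyquist,
  polynomial order ≥ N−1, fewer than 2 (mean R-R) or 3 (segmentation)
  R peaks, non-uniform time columns (>1% spacing deviation).
* Fewer than three detected R peaks make delineation impossible; the
  pipeline then returns the R annotations it has and a `NULL` beat
  matrix rather than failing.

## Test problem sizes

The suites run on synthetic records of 8–25 beats at 500 Hz (roughly
6–20 s), and the end-to-end recovery suite uses 50 random morphologies
of 20 beats each — small enough to run in seconds, long enough that
every stage (including the order-8 baseline fit, whose fidelity depends
on record length) operates in its intended regime. The baseline-wander
property is asserted on ~10 s records, where an order-8 polynomial can
represent the two cycles of 0.2 Hz drift it is asked to remove.

## Known limitations

* Peak detection only: wave onsets/offsets (PR, QT intervals) are out of
  scope, as is any rhythm classification.
* Thresholds are specified in mV/sample² at 500 Hz; other gains and
  rates require rescaling (documented above), and the published values
  were tuned by inspection on one database.
* The isoelectric estimate is a single global constant per record; it
  cannot follow residual post-correction drift, which is the root of the
  shallow-Q failure mode the package reproduces.
* The WFDB reader supports format 16 single- and multi-channel records
  (the ECG-ID encoding); other WFDB signal formats are rejected with a
  clear error.
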