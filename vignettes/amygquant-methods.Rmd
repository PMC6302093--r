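---
title: "AmygQuant: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AmygQuant: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

AmygQuant re-implements, as a tested pipeline, the quantitative workflow
of an amygdala anxiety-circuit study: open-field behavioral geometry,
position- and event-linked beta-band LFP analysis, miniature-PSC
detection and passive-membrane estimation from voltage-clamp sweeps,
rule-based cFos and perisomatic-puncta quantification, and a factorial
statistical layer. Because no public recordings exist for this kind of
study, every analysis is driven by a synthetic cohort generator that
plants known effects; this vignette documents the models behind both the
generators and the estimators, the parameters that matter, and the
choices made where the design was genuinely open.

## The synthetic cohort

**Trajectories.** Mouse open-field paths are modeled as a correlated
random walk: a two-dimensional Ornstein–Uhlenbeck velocity process
(correlation time 0.5 s, stationary per-axis SD 6.4 cm/s, giving a mean
speed near 8 cm/s, typical of mice in a novel arena) integrated at 20 Hz
— a common video-tracking rate — and reflected at the walls of the 50 cm
square arena. Center avoidance (thigmotaxis) is planted as a radial
outward acceleration of 20 cm/s² per unit of the `centerAvoidance`
knob. With the knob at zero the reflected walk occupies the arena almost
uniformly, so time in the 37.5 cm center square approaches its area
fraction (0.5625); at the wild-type setting (0.3) the simulated animals
spend roughly 20–25% of the session in the center, and at the
high-anxiety setting (1.2) almost none, matching the qualitative range
seen in real open-field data. No published trajectory model exists for
this study; the OU walk is the simplest process that produces
thigmotaxis with realistic kinematics.

**SAP episodes.** Stretch-attend postures are drawn as a Poisson process
at the planted per-minute rate. Start times are anchored at samples
lying in a 4 cm band just outside the center-zone boundary — SAPs are
risk-assessment postures shown at the periphery–center transition — and
durations are uniform on 1–3 s, a plausible window consistent with the
wavelet snapshots such studies show; the source material states no
durations. The episodes are returned as ground-truth intervals.

**LFP.** The signal is a sum of (i) Gaussian background with a 1/f^1.5
amplitude spectrum, (ii) a theta (8 Hz) oscillation with slow amplitude
jitter, and (iii) a beta (24 Hz) oscillation whose instantaneous
amplitude carries all planted structure:
A(t) = A0 (1 + g_d (1 − d(t)/d_max)) · g_SAP(t), with d(t) the distance
from the arena center and g_SAP active inside SAP intervals. The base
beta amplitude (30 µV) is set about ten-fold above the in-band 1/f
background power (noise SD 15 µV over the full band), so band-power
estimates track the planted envelope rather than background
fluctuations — the generator's job is to make planted effects the
dominant in-band signal, which is what the recovery tests require.
Real LFPs differ in ways the generator does not emulate: broadband
transients, volume-conducted EMG, non-sinusoidal oscillations and
electrode drift. Passing recovery tests therefore demonstrates
correctness of the estimators, not robustness to every artifact of real
recordings.

**Voltage-clamp records.** Each sweep is the numerically integrated step
response of the series-resistance/parallel-RC clamp circuit (10 mV,
20 ms test step at the sweep start), plus a Poisson train of inward
miniature PSCs — biexponential kernel, rise 0.5 ms, decay 15 ms, gamma
amplitudes with mean 50 pA and CV 0.3 — plus leak and Gaussian noise.
The step interval is half-open: the onset sample holds the pre-step
current, so the sampled peak lies strictly below ΔV/Rs, as in a real
digitizer. Current-clamp sweeps come from an adaptive exponential
integrate-and-fire membrane (EL −70, VT −50, ΔT 2, reset −58 mV,
a = 2 nS, b = 30 pA, τw = 100 ms) with a stylized +30 mV spike sample;
only counts, thresholds and first-spike amplitudes are analyzed, so no
detailed conductance model is needed.

**Images.** cFos fields plant soft-edged nuclear disks whose peak
intensities are drawn deliberately above or below three times the flat
background, making the positive count unambiguous. Puncta fields plant
a dark soma with a traced 96-vertex perimeter polygon and Gaussian
puncta at known signed distances from the perimeter (in-annulus
puncta within ±0.8 µm, distractors deep inside the soma and ≥3.5 µm
outside), separated enough never to merge under connected-component
labeling. Annulus membership at any expansion is therefore known
geometry, not an estimate.

## Spectral analysis

Raw LFP is band-limited to 0.7–400 Hz and downsampled to 1 kHz. Both
FIR stages (anti-alias low-pass before decimation; high-pass at the
output rate, default 6 s kernel) are Blackman windowed-sinc designs
applied with zero phase: the implementation multiplies by |H(f)|² in a
single FFT pass with reflection padding, which is algebraically the
forward–backward application of the same kernel. Signals shorter than
three kernel lengths are rejected rather than filtered badly.

Power spectra use the multitaper method with time-bandwidth 3 and 5
Slepian tapers, the conventional setting for 1 s windows. The DPSS
tapers are computed from the standard symmetric tridiagonal eigenproblem
and cached per window length; the unit test pins them to
`scipy.signal.windows.dpss` to eight decimals. PSDs are one-sided in
µV²/Hz so that the integral over frequency equals the signal variance
(checked to 10% on white noise); band power is the PSD summed across the
band times the bin width. Sliding windows follow the conventional
band-specific settings (theta 4–12 Hz, 1 s/0.8 s overlap; beta
18–30 Hz, 1 s/0.5 s; gamma 0.15 s/0.1 s). The gamma band bounds are not
fixed by the convention this package follows; 40–100 Hz is used and
flagged as a package default. The same TW = 3, K = 5 setting is reused
for every window length, which for the 0.15 s gamma window implies a
40 Hz analysis bandwidth — acceptable because gamma power is only
reported, never tested, here.

The Morlet transform uses 40 logarithmically spaced center frequencies
over 1–120 Hz (log spacing is standard for a two-decade span; the
convention source is silent), wavelets 10 cycles long with Gaussian
envelope SD = n_cycles/(2πf), truncated at ±5 SD.

## Position- and event-linked beta

Each sliding-window power value is assigned the trajectory sample
nearest its center time. Distance from the arena center is binned at
3 cm; bin means are normalized by the mean power over all windows beyond
18 cm ("periphery"), so the periphery aggregate is 1 by construction.
Bins backed by fewer than 3 windows are flagged under-sampled and
excluded along with empty bins: a mean of one or two stochastic power
estimates is not a usable bin value. The distance trend is ordinary
least squares of normalized power on bin-center distance, pooled across
the subjects of a group (matching per-genotype correlation analysis),
with per-subject slopes reported alongside; the sign convention is
power-versus-distance, so beta elevated toward the center appears as a
negative slope. Speed control uses 5 cm/s bins without normalization.

SAP-triggered beta averages the per-time-point summed beta series inside
each episode, then across episodes. The per-time-point series is the
1 s beta window evaluated on a 50 ms hop so that 1–3 s episodes contain
dozens of estimates; in the cohort pipeline the fine hop is evaluated
only across episode spans, with the ordinary 0.5 s hop supplying the
out-of-episode baseline, which changes nothing statistically and keeps
the computation linear in the number of episodes. A planted amplitude
doubling appears as a power ratio near 4; in-band 1/f background
dilutes it slightly below 4 (the acceptance band is ±15%).

## Patch-clamp analytics

**QC.** Cells pass only with initial access resistance ≤ 13 MΩ, ≤ 20%
drift, and leak ≤ 200 pA.

**Detection.** The sliding template is
e(t) = (1 − e^(−t/τ_rise)) e^(−t/τ_decay) (defaults 0.5/15 ms for
inhibitory minis, 45 ms long; an sEPSC-style variant would use 0.2/3 ms).
At every lag the template is optimally scaled and offset by least
squares — running sums and one FFT cross-correlation make this O(n log
n) — and the detection criterion is the scale divided by its standard
error, i.e. the regression t-statistic; the offset term makes the
criterion exactly invariant to constant baselines. Events are strict
local maxima of the criterion above threshold (default 4). Two
acceptance rules suppress duplicates on an event's tail: a later peak
counts only if the criterion re-armed below half the threshold in
between, or if it is ≥2.5-fold more prominent than the intervening
valley (a genuinely overlapping event re-elevates the criterion
many-fold; noise wiggles on a decaying tail do not). Because a second
event inside the template window inflates the regression SE and can
mask the first, detection runs a second pass: detected events are
subtracted as scaled full-length kernels (full length, so no truncation
step is left behind) and the residual is re-scanned at a conservative
3× threshold. The t-criterion has an irreducible false-alarm floor of
roughly one to two near-threshold crossings per minute in white noise
at threshold 4; planted events score an order of magnitude higher.
The capacitive-step span (onset to step end plus 5·τ2, capped at
5×20 ms) is masked before detection.

**Kinetics.** Amplitude is peak minus the 2 ms pre-event baseline; rise
time is the interpolated 20–80% interval; decay is a least-squares
single-exponential from the peak to 90% recovery, flagged unfit when the
next event intrudes.

**Passive properties.** Averaged step transients (the pipeline averages
30 consecutive sweeps, which suppresses mini contamination of the
steady state) are fitted with I(t) = A1 e^(−t/τ1) + A2 e^(−t/τ2) + A∞
by multi-start Levenberg–Marquardt on log-τ parameters, τ1 < τ2
enforced. The circuit algebra inverts the step response of the
series-Rs / parallel-Rm-Cm circuit: the extrapolated peak I0 =
A1 + A2 + A∞ gives Rs = ΔV/I0; the steady state gives Rs + Rm = ΔV/A∞;
and the amplitude-weighted time constant (A1τ1 + A2τ2)/(A1 + A2)
equals Cm·RsRm/(Rs+Rm). This algebra was frozen only after recovering
50 random circuits (Rs 5–20 MΩ, Rm 100–800 MΩ, Cm 15–45 pF) from
noiseless simulated responses to within 5% each (in practice ~10⁻⁵%).
When minis contaminate the averaged transient the fitted A∞ absorbs a
small inward offset and Rm is biased upward; heavily contaminated fits
are caught by the non-physical-value guards and reported as NA.

**AP metrics.** Spikes are upward crossings of a 20 mV/ms dV/dt
criterion (the phase-plane threshold read-out; the exact criterion value
is configurable since conventions differ) inside the 500 ms step.
Thresholds are reported after subtracting the 7.9 mV liquid junction
potential; first-AP amplitude is peak minus threshold.

## Image quantification

cFos counting binarizes at exactly 3× the supplied background (in
application mode the background defaults to the histogram mode) and
counts connected components with areas in 20–300 µm², a plausible
nuclear range left configurable because the convention source is
silent. Colocalization greedily matches centroid pairs within a radius,
nearest first, each spot used once. Perisomatic puncta are connected
components (area gate 0.05–3 µm²) whose centroids fall within the
annulus obtained by offsetting the traced perimeter by the expansion
(1.4 µm postsynaptic, 2.0 µm presynaptic) in both directions —
"expanded in each direction" is read as a symmetric band because puncta
straddle the traced perimeter; an outward-only mode is available.
Density is count divided by perimeter length, the puncta-density unit
used in such studies ("particles per area divided by perimeter" in the
original rule conflates units; count/perimeter matches the reported
figures). Annulus membership uses exact signed point-to-polygon
distance, so for a circle of radius r the rasterized band area matches
4πrd to within 2% at 0.1 µm pixels.

## Statistics

Grubbs screening iterates the two-sided single-outlier test at α = 0.05
(critical value from the t distribution), removing at most one value
per pass and never shrinking a group below 3. The factorial layer fits
value ~ A*B with sum-to-zero contrasts and partial (Type-III-style)
sums of squares so balanced designs reproduce the textbook
decomposition exactly (asserted against a brute-force projection
oracle) and unbalanced cohorts behave like common ANOVA software.
Post-hoc comparisons are Tukey studentized-range tests across the four
cells; an unpaired-t option exists because histology conventions
sometimes quote pairwise t-tests ("paired" in that convention is read
as a misnomer — the groups are different animals — so both unpaired
options are exposed and nothing is guessed). Distribution comparisons
use the asymptotic two-sample Kolmogorov–Smirnov test on per-cell
means.

## The end-to-end cohort check

The pipeline's integration test simulates ten cohorts of 4 groups × 5
subjects with 5-minute sessions — LFP synthesized at 2 kHz (the
preprocessing minimum), tracking at 20 Hz, 30 × 0.5 s voltage-clamp
sweeps per cell at 10 kHz; these are desk-scale problem sizes, chosen
once. The planted pattern mirrors the biology: the high-anxiety group
has elevated center avoidance and positive beta gains; the
elevated-inhibition group has a higher mini rate; the double group has
avoidance and beta gains normalized back to control values. The
recovered pattern is judged with the package's own statistical layer —
Tukey comparisons across the four cells for the between-group claims
(center time reduced, SAP beta elevated, mini frequency elevated, and
the double group non-significant versus control) and a one-sided
signed-rank test of per-subject slopes for the within-group
beta-distance gradient. Per-pair Welch tests were deliberately not used
for the "indistinguishable" claims: with near-zero within-group
variance they flag trivial seed-level clustering, whereas the pooled
Tukey contrast is scaled by the between-genotype variability, which is
both statistically appropriate and what such studies report. The
pattern reproduces in ≥9 of 10 seeded cohorts.

## Known limitations

The generators are statistical look-alikes, not biophysical
simulations: no network dynamics behind the LFP, no dendritic filtering
of minis, no imaging point-spread/deconvolution model. Passive-property
estimates from mini-contaminated records carry an upward Rm bias (see
above). The mini detector's timing jitters by a few milliseconds for
small events in noise, so stochastic benchmarks score matches within
±5 ms (±1 ms for clean events). Gamma-band bounds and several area
gates are package defaults, clearly marked, not conventions inherited
from the study design.
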