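---
title: "Quantifying T9SS rotation, gliding, and belt transport with gearbelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying T9SS rotation, gliding, and belt transport with gearbelt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gearbelt)
```

## The model

gearbelt treats the gliding machinery of Bacteroidetes as a *tri-component
gearset*: proton-driven stator units spin an outer-membrane ring, the ring
propels a closed cell-surface conveyor belt, and the belt's surface adhesin
(SprB) converts belt motion into cell gliding. The package quantifies the
three assays that observe this chain — tethered-cell rotation, single-cell
gliding, and TIRF tracking of the belt adhesin — and provides a stochastic
simulator of the chain itself that doubles as the ground-truth generator
for every test.

### Motor ensemble

Each of the `n_motors` T9SS units (observed range: 8–12 per cell) is an
independent two-state continuous-time Markov chain over rotation
directions $\{+1\ (\mathrm{CCW}), -1\ (\mathrm{CW})\}$. Dwell in the
dominant direction is $\mathrm{Exp}(\tau_d)$ with
$\tau_d = $ `mean_dwell_dominant_s`; dwell in the minority direction is
$\mathrm{Exp}(\tau_m)$ with $\tau_m = \tau_d (1-b)/b$, so the stationary
probability of the dominant direction is exactly the bias $b$. A bias of
0.85–0.95 reproduces the observed directional split of motor populations
(≈ 90% of wild-type units CCW at any instant, 5–15% rotating opposite:
one dissenter among 8–12 units is 8.3–12.5%, `opposite_fraction()`).

### Belt and cell kinematics

While all motors agree with the consensus present at the last engagement,
the belt is engaged and the cell translates at `run_speed_um_s` along its
heading. Any motor flip slips the belt (`engagement_rule = "all"`,
encoding "rotating in unison"; a majority-threshold alternative is exposed
as a config option but is not the default). During a slip the cell is
stationary for an $\mathrm{Exp}(\texttt{slip\_mean\_s})$ re-engagement
delay; optional translational diffusion during slips defaults to 0 to keep
ground truth crisp. At re-engagement the heading is reversed by $\pi$ with
probability `reversal_prob`, otherwise redrawn from a von Mises
distribution around the previous heading with concentration `turn_kappa`
(0 = uniform). The defaults `reversal_prob = 0.5`, `turn_kappa = 0`
produce both the back-and-forth motion and the sudden random turns seen in
gliding trajectories.

The emergent run length is $\tau_d/(2 b\, n)$ (ensemble flip rate
$n(b/\tau_d + (1-b)/\tau_m) = 2 b n/\tau_d$), which the test suite checks
against a Kolmogorov–Smirnov comparison with the exponential law in the
$b \to 1$ limit.

### Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_motors` | 10 | – | middle of the observed 8–12 range |
| `bias` | 0.9 | – | observed 85–95% rotational bias |
| `mean_dwell_dominant_s` | 180 | s | gives runs of ≈ 10 s (long runs, quick turns); unconstrained by direct measurement |
| `run_speed_um_s` | 2 | µm/s | wild-type gliding speed |
| `slip_mean_s` | 1 | s | "within seconds" re-engagement |
| `turn_kappa`, `reversal_prob` | 0, 0.5 | – | uniform new headings plus frequent reversals |
| gear ratio | 1.5 | µm/rev | derived: 2 µm/s ÷ 1.3 Hz (`belt_um_per_rev()`); speed is a direct parameter, the ratio is documentation |

The dominant dwell deserves a note: no experiment in this system measures
single-motor switching times. We fix it once so that the *emergent* run
length (≈ 10 s at the defaults) matches the qualitative description of
long runs interrupted by brief turning events and the ≈ 27 µm wild-type
farthest-displacement scale over a 60 s observation; it is deliberately
not revisited per experiment. Where an acceptance experiment prescribes a
different value (the motor census uses 10 s) that value is passed
explicitly.

## Synthetic imaging

The renderer emulates, at analysis fidelity, what the assays image:

* **Tethered cells** — a dark rod (2D capsule with a one-pixel soft edge)
  on a bright background rotating rigidly about a fixed tether point;
  Gaussian pixel noise (sd 0.05 of the dynamic range by default). Phase
  contrast halos are *not* modeled: the analysis thresholds globally, so a
  halo would not change centroids at this fidelity.
* **Gliding cells** — the same rod translated along an input track,
  oriented along its instantaneous velocity.
* **Belt spots** — a 2D Gaussian spot (σ = 0.15 µm) moving at constant
  speed along the stadium-shaped midline perimeter of an elongated capsule
  (two straight edges plus two semicircular pole caps,
  $P = 2(L-W) + \pi W$), wrapping at the path end, with Poisson photon
  noise (2000 photons/spot/frame over a 10 photon/px background). An
  oscillation mode bounces the spot inside a 1 µm segment, emulating the
  short back-and-forth trajectories of a disrupted belt.

Default calibration is 0.1 µm/px and 15 fps (the recording rate of the
motility videos); a ~5 µm cell spans ~50 px. The actual microscope pixel
sizes are not published, so these are plausible values, not reproductions.
The coordinate convention has y increasing upward
(`y_um = (rows − row + 0.5) · pixel_size`), making CCW in the mathematical
sense equal CCW in a conventionally displayed image; the absolute
chirality of the published videos cannot be fixed from text, but all
signed comparisons in the package are internally consistent, and the
mirror-image test asserts exact sign equivariance.

What a green test does *not* establish: robustness to focus drift,
photobleaching, cell crowding, halo artifacts, stage drift, or
segmentation of dividing cells — none of which the generator emulates.

## Analysis pipeline choices

* **Rotation.** Per frame: global Otsu threshold (dark object), largest
  4-connected component, darkness-weighted centroid. The rotation center
  is a Kasa circle fit to the centroid cloud rather than the time-mean
  centroid: for recordings covering a non-integer number of revolutions
  the time-mean centroid is offset and biases the recovered frequency
  (measured +4.5% at 0.3 Hz over 5 s; < 0.5% with the circle fit). A
  static cell defines no rotation center at all, so a known center (e.g.
  a generator's tether point) can be supplied. Angles are unwrapped by
  mapping successive differences into $(-\pi, \pi]$ (exact $\pi$ resolves
  toward $+\pi$); frequency is the *net* unwrapped excursion over duration
  — robust to centroid jitter and aligned with the full-revolution filter,
  which uses net excursion (not total variation) precisely to exclude
  Brownian dithering. Up to 10% of frames may fail segmentation and are
  linearly interpolated; more is an error. Population summaries report the
  dominant-direction subpopulation's mean unsigned speed; the published
  "mean speed" is read this way (the alternative — signed mean over the
  whole distribution — would mix the two directions).
* **Gliding.** Greedy ascending-distance nearest-neighbor linking with a
  `max_jump_um` gate and gap tolerance; ties break by track age, then by
  detection coordinates, making the result invariant to detection order.
  Greedy is adequate in the sparse-scene regime (steps ≪ separations) and
  is checked against a brute-force optimal-assignment oracle there; on
  dense adversarial scenes greedy and optimal genuinely differ. Speeds:
  positions are smoothed with a 5-frame centered moving average and the
  displacement is evaluated at the window timescale (endpoints share no
  raw samples). This puts the stationary-track noise floor at ~0.12 µm/s
  for 0.05 µm localization noise at 15 fps, and recovers the published
  speed grid {0.4, 0.64, 0.88, 0.89, 2.0} µm/s within a few percent.
  Consecutive-frame differencing of the smoothed positions would have a
  0.27 µm/s floor — dominating the slowest strain — which is why the
  window-timescale form is used. Farthest displacement is referenced to
  the first sample; per-strain averages are per-track values averaged
  across tracks. Detection gaps are excluded from speed averages, never
  imputed.
* **Turns.** Headings come from smoothed velocities *on moving frames
  only*, so a slip pause does not mask the heading change across it; a
  turn is a > π/2 change between the mean headings of the preceding and
  following 5-frame windows, a reversal a turn within π ± π/6. Two
  reversals closer than the window cancel and are intrinsically
  unresolvable at the sampling rate.
* **Spots.** Difference-of-Gaussians band-pass (σ and 3σ), peaks above
  median + 5×MAD, plus an integrated-mass criterion (≥ threshold ×
  4πσ²_px, the mass of a just-detectable PSF-sized object) that rejects
  single correlated-noise spikes; subpixel positions by intensity-weighted
  centroid in a (4σ+1) px window. At defaults this gives 100% recall, zero
  false positives, and ~6 nm localization on the synthetic videos. Shape
  classification: *looped* requires a revisit within 0.5 µm after at least
  half the estimated cell perimeter of path **and** genuine transverse
  extent of the connecting path (> 0.25 µm) — without the latter a 1D
  oscillation retracing itself would count as a loop; *oscillatory*
  requires ≥ 3 direction reversals along the dominant PCA axis with
  confinement ratio < 0.2; otherwise *extended*. The oscillation
  thresholds are declared defaults, not biological claims.

## Statistics layer

The Mann–Whitney test enumerates all $\binom{n_1+n_2}{n_1}$ label
assignments when $n_1+n_2 \le 14$ (≤ 3432 assignments, covering the ≥ 6
spots-per-strain comparisons exactly, ties handled by midranks); beyond
that it uses the normal approximation with tie and continuity corrections.
Two-tailed p doubles the smaller tail and caps at 1 — tie-heavy exact
two-tailed definitions vary across implementations, so this choice is
documented rather than assumed. The KDE uses the Silverman factor
$1.06\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$ with a grid
spanning the data ± 4 bandwidths (trapezoidal integral 1 ± 1%). The spin
angle is the closed-form optimal in-plane rotation
$\mathrm{atan2}(\sum \hat a\cdot(u_i\times v_i), \sum u_i\cdot v_i)$ after
centering and projecting both point sets onto the plane ⊥ axis; it
recovers the ±36° steering step of the published protocol to < 0.1° and is
antisymmetric by construction. Work integration is the raw rectangle rule
$\sum_i F_i\,\Delta\theta_i$; engine-specific restraint bookkeeping is out
of scope.

## The motor census question

One acceptance experiment asks what fraction of 1000 simulated motors at
bias 0.9 is "classified CCW" over a 30 s observation with a 10 s dominant
dwell. Classifying each motor by its net rotation over the window answers
a different question than the published 90%/10% split: the time-averaged
direction of a chain with a ~1.1 s minority dwell is CCW with probability
≈ 1 over 30 s, so that classifier converges to ~100%, not 90%. The 90%
figure is a *census* — the fraction of units rotating CCW at an instant,
i.e. the stationary distribution. `run_motor_census()` therefore reports
the percentage of motor-time spent CCW (expectation exactly the bias),
which is the quantity the assay's population statistics estimate. The
discrepancy between the two readings is itself a property of the model
worth knowing: per-unit ergodic averages hide the minority population that
the instantaneous census reveals.

## Numerical choices and degenerate inputs

Seeds: every simulation takes one seed; per-motor streams are split by
index and pipeline stages derive seeds from the global seed by a
stage-name hash (`derive_seed()`), all below $2^{31}$. Angle-difference
wrapping resolves exact $\pi$ toward $+\pi$. Otsu operates on the native
integer histogram; component ties break toward the lower row index. The
bias = 1 limit is absorbing (no switching, zero slips, straight run at
exactly `run_speed_um_s × duration_s`). Zero-spread KDE samples,
empty Mann–Whitney samples, near-zero spin axes, and all-on-axis point
sets raise typed parameter errors. Tracks shorter than the smoothing
window fall back to raw differencing with a warning; populations with no
record passing the full-revolution filter return an explicit empty
sentinel.

## Known limitations

* The gearset does not model torque, proton flux, gear-ratio dynamics, or
  ring conformational states; the motor-to-belt coupling is a direct speed
  parameter with a documented derived constant (1.5 µm/rev).
* A single belt per cell is assumed; multiple belt loops per cell have
  been observed but are not modeled.
* The wild-type gliding-speed recovery lands ≈ 10% below the run speed by
  construction: simulated cells pause during belt slips (engaged fraction
  ≈ 0.91 at the defaults) and the speed estimator honestly averages over
  pauses, as the real measurement does.
* The slip-duration distribution and re-engagement geometry are
  parameterized, not asserted — the underlying biology is only constrained
  to "within seconds".
* Greedy linking is not globally optimal in dense scenes; the brute-force
  oracle bounds its behaviour only in the sparse regime it is designed
  for.
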