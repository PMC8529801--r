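---
title: "Right-heart 4D flow analysis: models, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Right-heart 4D flow analysis: models, assumptions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flow4d)
```

# What the package computes

`flow4d` analyses time-resolved three-directional phase-contrast MRI
(4D flow CMR) velocity fields with a focus on right-heart hemodynamics:

1. **Gating**: assessment and repair of ECG trigger logs compromised by
   missed R-wave triggers, respiratory gating at a target efficiency,
   and retrospective binning of acquired projections into cardiac
   phases.
2. **Background phase correction**: removal of the slowly varying
   eddy-current phase offset by fitting a 3rd-order polynomial to the
   velocity of stationary tissue.
3. **Great-vessel flow**: through-plane velocity integration over a
   segmented vessel lumen, giving the flow curve Q(t), stroke volume
   (SV), cardiac output (CO = SV x HR), and body-surface-area-indexed
   values (SVi, CI).
4. **Ventricular metrics**: kinetic energy KE = 1/2 rho V sum(|v|^2)
   over a chamber mask (rho = 1060 kg/m^3, V the voxel volume), the
   energy efficiency eta = SV/KE, and the mask-mean vorticity magnitude
   from the discrete curl, with systolic and diastolic peak extraction.
5. **Flow visualization**: RK4 streamline and pathline tracing.
6. **Cohort statistics**: per-subject percent changes and age-adjusted
   two-group comparisons via OLS with a dummy-coded group variable.

Because clinical 4D flow data cannot be redistributed, every stage is
validated against synthetic phantoms with closed-form ground truth:
pulsatile tubes (plug and Poiseuille profiles), analytic vortices
(solid-body, Lamb-Oseen, Hill), polynomial background offsets, and
simulated trigger/respiration streams.

# Coordinate and unit conventions

All modules share one convention: the voxel grid is axis-aligned,
index (0,0,0) sits at the grid corner, and world coordinates in mm are
the 0-based index times the (isotropic) voxel size. Velocities are in
m/s, lengths in mm, times in ms. Two consequences worth noting:

* With velocity in m/s and areas in mm^2, the through-plane sum
  `sum(v) * spacing^2` is numerically in mL/s, so no unit juggling
  appears in the flow code.
* Polynomial background models are evaluated on coordinates normalized
  to [-1, 1] per axis. This keeps the 3rd-order design matrix well
  conditioned and is shared verbatim between the phantom's offset
  injection and the background fit, so a recovered coefficient is
  directly comparable to an injected one.

# The phantoms and what they do (and do not) emulate

`make_tube_phantom()` builds a straight tube along z with a plug or
parabolic profile scaled by a per-phase waveform. Each voxel holds the
**partial-volume average** of the analytic profile over an 8x8
subvoxel lattice, as an imaging voxel would; this makes the discrete
flow integral match the closed form (Q = v pi R^2 for plug, half that
for Poiseuille) to a fraction of a percent, rather than inheriting the
lattice-counting error of a binarized disk. A bright static-tissue
shell surrounds the tube and dim "air" fills the rest, so
stationary-tissue detection has realistic material classes to work
with.

`make_vortex_phantom()` provides solid-body rotation (curl exactly
2 Omega everywhere, and exactly representable by trilinear
interpolation since the field is linear), the Lamb-Oseen vortex
(smooth, with analytic vorticity Gamma/(pi rc^2) exp(-r^2/rc^2)), and
Hill's spherical vortex (interior solution only; the velocity outside
the sphere is zeroed, so comparisons for this mode use an eroded
mask). An optional `field_radius` truncates the in-plane support,
leaving genuine stationary surroundings for the preprocessing chain;
the default keeps the analytic field over the whole grid so that curl
stencils at mask voxels never touch a truncation edge.

The phantoms deliberately do **not** simulate MR physics: no k-space
sampling, no velocity aliasing, no anatomically realistic chamber
geometry, and velocity noise is i.i.d. Gaussian per component, voxel
and phase with no spatial correlation. Passing tests therefore
demonstrate correctness of the *analysis* under controlled conditions,
not robustness to every artifact of real acquisitions.

# Gating model

A projection's cardiac time is the time since the most recent
preceding trigger. A log is flagged as compromised when more than 5%
of projections have cardiac time exceeding the median RR interval
(lower median for even counts — deterministic and order-statistic
based). Repair interprets every interval longer than 1.5x the median
RR as k merged beats, k = round(interval / median RR), and inserts
k - 1 uniformly spaced triggers. Original triggers and projection
timestamps are never modified, and the repair is idempotent.

Two design points deserve explanation:

* **Forced splitting for heart-rate estimation.** The 5% rule decides
  whether re-binning is warranted, but the mean heart rate
  60000/mean(RR) is biased low by *any* missed beat: a log with 5% of
  beats dropped sits right at the detection boundary, and when it
  (correctly) escapes the global flag its HR is still ~2-5% low.
  Interval splitting is a no-op on clean logs — no interval exceeds
  1.5x the median — so `correct_triggers(log, force = TRUE)` applies
  it unconditionally, and heart-rate estimation uses that path. The
  detection rule itself is unchanged.
* **Respiratory gating as an order statistic.** Gating at efficiency e
  accepts the ceiling(eN) projections whose interpolated belt value is
  closest to end-expiration; the "adaptive threshold" is simply the
  corresponding order statistic. Ties at the threshold are all
  accepted (deterministic and order-independent). End-expiration
  polarity is a flag (default: expiration = waveform maximum), since
  belt sign conventions vary by vendor.

Projections before the first trigger have no cardiac time and are
rejected; projections after the last trigger are binned against the
median RR.

# Background correction

The model is a static (time-invariant) polynomial per velocity
component, fitted by QR least squares to the *time-averaged* velocity
of stationary-tissue voxels — eddy-current offsets are constant at
fixed gradient waveforms, so fitting the temporal mean maximizes SNR
without changing the estimand. Stationary tissue is detected by
thresholding time-averaged magnitude (default: at its 25th percentile)
and the temporal standard deviation of speed (default: adaptively at
its 10th percentile); both thresholds are exposed because the
interactive, semi-automatic equivalents in clinical tools have no
single canonical value. The fit is per component (standard practice;
nothing couples the components physically), requires at least as many
voxels as monomials (20 at order 3), and rejects rank-deficient
designs such as masks confined to a plane.

Validation: injected random cubic offsets are recovered to ~1e-15
relative error noiselessly; under Gaussian noise the coefficient RMSE
scales as 1/sqrt(n of fit voxels) (measured slope -0.50 across masks
of 10^3..10^5 voxels) and is unbiased over repeated noise draws.

# Flow quantification

Measurement planes are sampled on a square lattice (default spacing =
half a voxel) by trilinear interpolation — the same interpolant used
for streamline tracing — and the through-plane velocity is the
interpolated vector dotted with the plane normal. The lumen is, by
default, segmented once on the time-maximum |through-plane velocity|
map as the 4-connected component containing the plane center above 10%
of the plane maximum, then reused across phases (a static lumen;
per-phase contouring is available but clinical practice for great
vessels usually contours once). SV is the periodic trapezoidal
integral of Q(t) over one RR, including the wrap-around segment; for
the uniform phase grids produced here this reduces to mean(Q) x RR and
is spectrally accurate for band-limited waveforms.

Known bias: the 10% threshold excludes the partial-volume rim where
the smeared velocity falls below threshold, giving a systematic
underestimate of ~1-2.5% across radii 6-10 mm — well inside the 3%
validation band, and common to both groups in any comparison.

# Ventricular kinetic energy, efficiency, and vorticity

KE uses the voxel volume from the header (1.25 mm isotropic gives
1.953 mm^3); it can be pinned (e.g. to 1.95 mm^3) to replicate
published processing exactly. Both raw KE (joules) and
mask-volume-indexed KE (J/mL) are reported, because published tables
are ambiguous about which normalization "indexed by mask size" refers
to; eta = SV/KE is reported in mL/mJ at the systolic and diastolic KE
peaks.

Vorticity is the discrete curl: central differences in the grid
interior, one-sided at grid boundaries, spacing converted to meters so
the result is in 1/s. Central differences are *exact* on globally
linear fields, which the test suite exploits: random linear fields
give machine-precision agreement with the analytic curl, and
solid-body rotation gives mask-mean vorticity exactly 2 Omega. The
mask summary is the mean of per-voxel vorticity-vector *magnitudes*
(summing vectors first would cancel in symmetric vortices and could
not produce the strictly positive tens-per-second scale reported for
ventricles); the vector-resultant convention is available as an
option.

**Systole/diastole split.** The split is derived from the great-vessel
flow curve: systole is the contiguous run of phases around peak flow
that stays at or above 10% of the peak (threshold exposed), found by
walking cyclically backward and forward from the peak; diastole is the
remainder. The cyclic search makes the split independent of which
phase the reconstruction labels as 0 — a shifted flow curve yields
identically shifted windows — while reducing to the intuitive "from
cycle start to the post-peak threshold crossing" for curves whose
upstroke begins at phase 0. Peaks are window maxima of the per-phase
metric curves.

# Streamlines and pathlines

Streamlines integrate dx/ds = v/|v| (arclength parameterization, so
near-stagnant regions advance geometrically rather than stalling) with
classical RK4; pathlines integrate dx/dt = v(x, t) with linear
interpolation between cardiac phases, periodic wrap over the RR, and a
time step derived from the target spatial step and local speed, capped
at half a phase interval. Termination: grid exit, speed below a floor,
or a step cap.

On the trilinearly interpolated grid the velocity field is only C^0,
which caps the *observable* convergence order of any integrator near 3
regardless of scheme; the clean 4th-order behaviour of the integrator
is therefore demonstrated on smooth fields — the analytic Lamb-Oseen
profile (measured order 3.8-3.9) and solid-body rotation, whose
trilinear interpolant is the analytic field itself. On the gridded
Lamb-Oseen phantom, a circular orbit at the core radius drifts by
~0.007% per revolution at a step of core/100.

# Cohort statistics

Group comparisons fit y ~ 1 + age + group by QR least squares, with
the group dummy coded term = 0, preterm = 1 so the coefficient is the
adjusted preterm-minus-term difference, tested two-sided against
Student's t with n - 3 degrees of freedom. Exact fits (zero residual
variance) report se = 0, p = 0 and a degenerate-fit flag. Exercise
response is summarized as per-subject percent change — the mean of
per-subject changes, which differs from the percent change of group
means whenever baselines and changes correlate. p-values are
deliberately uncorrected for multiple comparisons (flagged in the
output metadata), favouring sensitivity in an exploratory setting.
Type-I error of the group test is calibrated: on null simulations at
n = 52 the empirical rejection rate at alpha = 0.05 stays inside the
binomial 95% band.

# The end-to-end synthetic cohort

`run_synthetic_cohort()` generates a two-group (term/preterm),
two-condition (rest/exercise) cohort of 13 subjects per group and runs
every subject-condition through the complete chain: trigger simulation
with missed beats (2% at rest, 10% during exercise) -> gating repair
and HR recovery -> respiratory gating and binning -> offset-corrupted
pulsatile tube -> stationary-mask/fit/subtract -> plane extraction,
lumen segmentation, flow, SV, BSA indexing -> offset-corrupted
ventricle vortex -> KE/eta/vorticity with peaks -> age-adjusted group
tables.

Cohort-level defaults follow the published study population: ages
span adolescence to young adulthood (13-30 y, age-matched across
groups), and the rest/exercise heart-rate and stroke-volume-index
distributions use the reported group means and SDs (e.g. rest HR
73 +/- 13 vs 79 +/- 14 bpm; rest SVi 40 +/- 5 mL/m^2). The *injected
group effects* are a design choice: a -8 mL/m^2 exercise SVi deficit
and a +16 s^-1 diastolic vorticity excess on within-group SDs of ~4
and ~8 respectively (standardized effect ~2). Published
between-group differences are smaller (standardized ~0.7) and would
not be reliably detectable at 13 subjects per group; the pipeline
check asks whether the chain *recovers what was injected* with
p < 0.05, so the effects are sized by a power calculation (>99% power
at alpha = 0.05, n = 13/group) rather than tuned to any observed
outcome. Per-subject problem sizes (32 x 32 x 16 tube grids,
24 x 24 x 24 vortex grids, 15 phases, 45 s trigger streams) keep a
full 52-scan cohort comfortably within a few tens of seconds while
leaving every stage non-trivially exercised.

# Numerical choices and degenerate inputs

* Lower median for RR intervals: deterministic under ties.
* Respiratory-gate ties at the threshold: all accepted.
* Flat flow curves: systole/diastole split refuses rather than
  guessing; flow curves that never cross the 10% threshold fall back
  to the cyclic minimum as the diastolic anchor.
* Empty stationary masks raise a threshold error naming both knobs;
  rank-deficient background designs raise a conditioning error.
* Zero-velocity streamline seeds return a single-point polyline.
* Exact-fit regressions are flagged rather than dividing by zero.
* All randomness flows through explicit seeds; trigger simulation is
  bit-reproducible given a seed.

# Limitations

Masks are inputs (or phantom-provided); there is no automatic chamber
segmentation. No venc unwrapping, Maxwell-term or
gradient-nonlinearity correction is attempted. The gating repair
models the documented failure mode — missed triggers lengthening
apparent RR — not arbitrary trigger corruption, and does not rescale
cardiac times within split intervals (a single re-assessment pass is
available via `reassess = TRUE`). The phantoms' noise model is white;
correlated noise, motion and segmentation error in real data will
widen all error bands.
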