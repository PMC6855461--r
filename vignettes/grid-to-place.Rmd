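---
title: "From grid cells to a place cell: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From grid cells to a place cell: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gridplace` simulates the feed-forward transformation from medial
entorhinal cortex (MEC) grid cells to a hippocampal CA1 place cell: a pool
of oscillatory-interference (OI) grid cells with diverse spacing,
orientation, and lattice phase drives a reduced multicompartment
Hodgkin-Huxley pyramidal cell through distal excitatory synapses, and the
resulting spatial firing, excitatory ramp inputs (ERIs), and theta phase
precession are quantified. This vignette explains each model stage, its
assumptions, the parameters that matter, and the design choices made where
the published description left the design open.

## Synthetic foraging trajectories

All stages consume a rodent trajectory in a 1 m x 1 m arena.
`generate_trajectory()` produces a correlated random walk: speed follows
an Ornstein-Uhlenbeck process (mean 0.2 m/s, stationary SD 0.1 m/s,
relaxation time 1 s, clipped at zero) and heading accumulates
wrapped-normal increments (SD 0.3 rad per 20-ms step); wall collisions
reflect the heading specularly so the speed statistics are unaffected by
the boundary. These defaults were chosen once so that a 10-minute session
covers at least 90% of the 3-cm occupancy bins, matching open-field
foraging data. The generator emulates the coverage and speed statistics of
real foraging; it does not reproduce home-base behavior, wall-following
(thigmotaxis), or the inhomogeneous occupancy of real sessions, so results
on real position files (see `read_position_file()`) can differ in dwell
statistics at the arena border.

## The oscillatory-interference grid cell

Each cell holds six velocity-controlled oscillators (VCOs) with preferred
directions spaced 60 degrees apart from a base direction
$\phi_{pref} \in [0, 60)$. VCO $i$ runs at

$$f_{VCO,i}(t) = f_\theta + \beta\, s(t)\cos(\phi_{pref,i} - \phi(t)),$$

with $f_\theta = 10$ Hz and gain $\beta \in [1, 3.5]$ Hz/(m/s). Because a
time-varying frequency makes the printed closed-form cosine argument
ill-defined, phases are path-integrated,
$\theta_i(t{+}dt) = \theta_i(t) + 2\pi f_{VCO,i}(t)\,dt$, and the
interference signal is

$$g(t) = n_{VCO}\cos\theta_\theta(t) + \sum_i \cos(\theta_\theta(t) + \theta_i(t)),$$

which reduces to the sum-of-cosines form at constant velocity. The spatial
consequence is a triangular lattice of constructive-interference vertices
with spacing $2/(\sqrt{3}\beta)$ meters — 57.7 cm at $\beta = 2$ — rotated
by $\phi_{pref}$.

A spike is emitted at every 1-ms oscillator step with
$g(t) \ge g_{thres} = n_{VCO} = 6$, subject to an absolute refractory
period. The refractory default equals the oscillator step (1 ms), i.e.
one spike per supra-threshold sample: with the supra-threshold duty cycle
of roughly a third of each theta cycle at a field center, this yields the
conventional model's characteristic peak map rate of ~300 Hz. A 3-ms
refractory is available via `grid_cell_params()` but caps the smoothed
peak rate near 70 Hz, far below that signature.

### The in vivo-like variant

The conventional model's rate is unphysiologically high and flat across a
field. `simulate_grid_cell(mode = "invivo_like")` therefore (1) builds the
un-thinned rate map on the same trajectory, (2) takes its local maxima
above 20% of the peak as firing-field centers, and (3) retains each spike
with probability

$$p(d) = p_{peak}\exp(-d^2 / 2\sigma^2),$$

where $d$ is the distance from the animal's position to the nearest field
center. The printed Gaussian density form exceeds one near $d = 0$, so it
is implemented as this acceptance profile. $\sigma$ defaults to one-third
of the measured field radius of the un-thinned map (~4-6 cm at
$\beta = 2$). The acceptance at a field center, $p_{peak} = 0.15$, was
calibrated once so the thinned peak map rate lands in the 20-30 Hz range
of in vivo grid cells; it is the counterpart, under per-millisecond spike
emission, of the same calibration rule that motivates lower values under
sparser emission schemes.

### The pool and selection randomness

`build_pool()` lays a 100 x 100 lattice over $\beta \in [1, 3.5]$ (closed)
and $\phi_{pref} \in [0, 60)$ (half-open): 10,000 cells.
`sample_cells()` draws without replacement and reports the randomness of a
selection as the Shannon entropy (base 2) of the empirical distribution
over selected parameter pairs relative to its maximum $\log_2 n$; distinct
draws give exactly 100%.

Cells selected for a network experiment additionally receive a uniform
spatial *lattice offset* (grid phase), implemented as initial VCO phases
$2\pi\beta(\hat u_i \cdot \Delta)$. Without it, every lattice shares a
vertex at the trajectory origin — all 250 selected cells would pile onto a
single artificial hotspot and the place field could never relocate across
selections. Grid phase is one of the diversity dimensions of real MEC
populations. The single-cell default keeps all phases zero (a vertex at
the origin), which is the configuration under which $g(0) = 2 n_{VCO}$.

## The Hodgkin-Huxley place cell

`build_cell()` discretizes a soma (20 x 20 um) plus a uniform apical
equivalent cylinder into 155 compartments (31 in the scaled profile),
with axial resistivity 150 Ohm cm and 1 uF/cm^2. The cylinder diameter
defaults to 50 um so that the reduced cell's total membrane area
(~1e5 um^2) — and with it the input conductance (R_in ~ 30-60 MOhm) —
approximates a full reconstructed CA1 pyramidal cell. A literal thin
neurite (2 um) of the same length has ~20x less membrane, an input
resistance over a gigaohm, and is driven into sustained depolarization by
250 synapses of 200 pS; no discrete place field can form on it. The thin
geometry remains available (`cable_d`) and is used in the test suite to
demonstrate dendritic attenuation.

Six membrane currents follow the conductance-based membrane equation:
leak (12.5 uS/cm^2, -65 mV), transient Na (9.4 mS/cm^2, +50 mV; gates
$m^3 h s$ with $s$ a slow, partial inactivation), delayed-rectifier K
(1.05 mS/cm^2, -90 mV; single gate $n$), M-type K (45 uS/cm^2), A-type K
(1.04 mS/cm^2; activation x inactivation), and h-current (5 uS/cm^2,
-30 mV). The gating kinetics are a sigmoidal CA1-style parameterization
compiled into the integrator (`src/hh_core.cpp`); the governing
constraints, found the hard way, are that (a) the Na window
($m^3_\infty h_\infty$ overlap) must stay well below the total
subthreshold K+leak conductance at every voltage, or the cell latches in
a depolarized state after its first spike, and (b) with a *first-power*
delayed rectifier, $n_\infty$ must be steep and depolarized
(half-activation -15 mV, slope 7) so it repolarizes spikes without
shunting the subthreshold range. The resulting cell rests near -68 mV,
has a ~-45 mV dynamic threshold, overshooting spikes (+15 to +25 mV), and
fires tonically from ~0.7 nA without depolarization block.

Voltage is advanced by backward Euler with a tridiagonal solve over the
cable; gates by exponential Euler; default step 0.025 ms (0.1 ms in the
scaled profile — halving the step changes spike counts on fixed input by
at most one). Spikes are upward 0-mV crossings with a 2-ms dead time.
Somatic voltage is recorded at 1 kHz. Integration aborts with an error if
|Vm| exceeds 200 mV.

### Synapses and somatic drive

Each selected grid cell projects through one single-exponential synapse
(`EPSG(t) = w e^{-t/\tau}`, w = 200 pS, tau = 30 ms, reversal 0 mV)
placed either at the compartment nearest 315.95 um path distance
(`single`) or uniformly over 300-400 um (`distributed`). The somatic
drive (`theta_drive()`) comprises: a theta-frequency (10 Hz) inhibitory
conductance `g_inh * max(sin(2 pi f t), 0)` with reversal -70 mV (the
sinusoidally gated conductance is rectified to remain non-negative; the
signed alternative was tested and entrains spike timing so strongly that
phase precession disappears); a constant step current; and Gaussian white
current noise specified as an intensity in nA sqrt(ms) so the voltage
noise (~1-2 mV with the default 0.2) is independent of the integration
step.

The step current implements the requirement that the place cell sustain a
minimum mean rate of 2.5 Hz. `run_transformation()` calibrates it by
bisection *with the first input set attached*, i.e. on the session mean of
the driven cell. Calibrating the isolated cell instead puts the operating
point so high that the mean synaptic drive lifts background firing to
7-10 Hz and the "field" balloons to ~60% of the arena; session-mean
calibration leaves the background near 1-2 Hz and yields compact fields
(~300-700 cm^2, peak 10-18 Hz), which is the regime in which the
viability census is meaningful.

## Spatial analysis

Rate maps divide spike counts by dwell time in 3-cm bins and smooth with
a 5 x 5 boxcar whose window truncates at edges and excludes unvisited
bins. Firing fields are 4-connected components of bins at or above 20% of
the map peak; components under 15 bins are discarded, and a field is
viable when its area lies between the configurable lower bound (default
240 cm^2, with the 15-bin rule also enforced; the published account
equates 15 bins with 240 cm^2 although 15 x 9 cm^2 = 135 cm^2 — both
thresholds are exposed rather than reconciled) and 60% of the arena.

The autocorrelogram evaluates, at every lag, the Pearson correlation of
the map with its shifted copy over the overlap region (lags with under 20
overlapping bins are undefined); the raw unnormalized lag sum is
available for cross-checking against the literal double-sum definition.
Autocorrelogram peaks are 3 x 3 local maxima with correlation at least
0.1, merged within 2 bins, and restricted to lags whose overlap region is
at least 20% of the map (extreme-lag correlations are unstable). Grid
spacing is the mean distance from the center to the up-to-six nearest
peaks (circle through the outermost peak as fallback when fewer). The
grid score rotates the autocorrelogram in 6-degree steps and reports
`min(corr 60, corr 120) - max(corr 30, corr 90, corr 150)` over an
annulus (inner radius half the nearest-peak distance, outer the outermost
peak + 2 bins), with the rotated copy bilinearly interpolated. This
conventional estimator carries a small negative interpolation bias (the
90-degree rotation is lattice-exact while the others are smoothed); a
symmetric polar-sampling variant without that bias was tried and scores
~0.2 higher than the published scale, so the conventional form is kept.

## ERIs and phase precession

The phase analysis is a two-stage protocol. The network simulations run
with step current and noise only; the theta conductance enters when the
extracted ERI is *replayed* through the cell. This mirrors the
experimental logic — the ramp is characterized first, then superimposed
with the oscillation — and is also a practical necessity here: OI grid
spikes are rigidly locked to the shared theta clock (opposite-direction
VCO pairs make the interference envelope real-valued, so bursts sit at a
fixed phase), and a place cell driven by those bursts inherits their
phase rather than precessing.

**Passes.** `extract_passes()` takes maximal contiguous trajectory
segments inside the field (dilated by one bin), requiring at least 0.5 s,
at least 3 place-cell spikes, and at most 5 s — longer segments are
in-field meanders, not single traversals, and carry no monotone
position-drive relationship.

**ERI measurement.** The despiked envelope of the spiking trace is nearly
flat: in-field firing clamps the cap-and-median filter at the cap level,
and spike after-potentials mask the underlying ramp. The experiment
therefore measures the ERI on a sodium-blocked twin simulation — same
synapses, same noise realization, Na conductance zeroed — whose
subthreshold voltage is the in-silico analogue of the pharmacologically
isolated ramp. `extract_eri()` itself retains the general
cap-at-(-50 mV)-and-median-filter (40 ms) contract for spiking traces.

**Classification.** A smoothing spline with factor p = 0.9 is fitted as a
penalized cubic spline, with the roughness penalty evaluated on time
measured in theta periods (0.1 s); this resolves the ramp while
discarding the theta-band wiggle (in raw seconds the same factor gives a
near-linear fit whose maximum sits at a segment end). The relative peak
position classifies the ramp: R_peak < 0.35 left-skewed (L), > 0.65
right-skewed (R), otherwise symmetric (S), boundaries inclusive to S.

**Replay.** `eri_replay()` injects the smoothed ramp as somatic current —
depolarization times a conversion gain of 0.15 uS per mV, capped at
1.2 nA (the driving-force saturation of the conductance input it stands
for) — together with the calibrated step current, noise, and the theta
conductance at 0.02 uS, strong enough to gate spike timing within each
cycle. A 1-s lead-in at baseline precedes the ramp and spikes in the
first theta cycle after onset are discarded as settling transients. The
gain and theta amplitude were fixed once on a development set of 90
passes and reproduce the network's in-field rates (~10 Hz).

**Slope.** Spike phases follow the peak-to-peak linear interpolation rule
against the injected oscillation's (exactly periodic) peaks.
`circular_linear_fit()` maximizes the mean resultant length of
`phase - rho * distance` over a slope grid with local refinement, ties
toward zero; per pass the search is bounded by one full cycle across the
pass (|rho| <= 360/path length) — steeper optima are aliased wrap fits.
Distance is measured from field entry.

Rising ramps advance spikes to earlier phases as the inhibition-escape
point moves forward each cycle, so R-ERIs yield negative slopes and
L-ERIs positive ones; the scaled experiment reproduces the R-negative /
L-positive / S-near-zero ordering with mean rho(R) around -2 to -5
deg/cm.

## Scaled experiment profile

The full study conditions are 600-s sessions, 250 cells per set, 100
repeats, 155 compartments at 0.025 ms. The documented desk-scale profile
(`experiment_config(scaled = TRUE)`) uses 150-s sessions, 15 repeats, a
31-compartment cable, and 0.1-ms integration; one scaled
`run_transformation()` takes roughly 8 minutes on one CPU. The
acceptance script and the test suite run this profile. All repeats share
one foraging session, as in the source protocol.

## Known limitations

- **Count sweep, upper end.** With the step current fixed at the
  250-cell calibration, 50-cell inputs evoke no field (as in the source
  experiments), but at 500 cells the reduced cell's fields saturate
  around 53% of the arena — below the 60% viability cut — because its
  firing rate does not saturate as sharply as a full morphology. The
  excess-excitation trend (rising peak rate and area) reproduces; the
  strict viability drop at 500 does not.
- **Place-field relocation on a fixed session.** All cells share one
  theta clock, so on a short shared session the trajectory sampled at
  the common burst times imprints a spatial pattern that can pin the
  place field regardless of the selected cells. The effect averages out
  with session length. (Giving each cell its own theta phase removes
  the pinning but destroys the theta-burst structure of the aggregate
  input and with it the pass statistics; per-repeat sessions
  de-correlate the census but push the class shares S-modal — so the
  shared clock and shared session of the source protocol are retained.)
- **Census variance.** Because the 15 desk-scale repeats share one
  session and the field location is partially pinned, the pooled ERI
  census resamples correlated traversals: class shares and per-class
  slope means vary substantially between session seeds (R share roughly
  40-75%, mean rho(L) roughly +1 to +4 deg/cm across development
  seeds).
- **ERI class shares.** The R/S/L split depends on pass geometry through
  a random-walk trajectory; R is modal (~40%) but the S share runs a few
  points above the published 27%.
- Passing the synthetic-trajectory tests shows the pipeline behaves
  correctly under idealized foraging statistics; real sessions with
  inhomogeneous occupancy may shift field-detection and pass statistics.
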