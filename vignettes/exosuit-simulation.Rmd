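---
title: "Neuro-mechanical exosuit control: model, generator and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuro-mechanical exosuit control: model, generator and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exolift)
```

# Overview

`exolift` simulates, end to end, a back-support exosuit whose assistive
cable force is commanded by a neuro-mechanical model-based controller
(NMBC): an EMG-driven musculoskeletal model estimates the *active*
component of the L5/S1 flexion-extension moment in real time, and the
controller commands a fraction of that moment through the suit's cables.
A trunk-inclination-based controller (TIBC) serves as the load-agnostic
kinematic baseline. Because no public dataset accompanies this problem,
the package includes a first-class synthetic-trial generator that plays
the role of the study cohort; every other module is exercised against it.

The pipeline is:

1. **Geometry** (`build_reference_geometry()`, `fit_surrogate()`) — a
   reduced 8-MTU trunk model with spline surrogates of MTU length and
   moment arm versus L5/S1 flexion angle.
2. **EMG processing** (`envelope()`, `normalize_mvc()`, `map_channels()`,
   `excitation_to_activation()`) — the causal envelope chain and the
   nonlinear EMG-to-activation shaping.
3. **MTU dynamics** (`fiber_kinematics()`, `force_curves()`,
   `mtu_force()`) — stiff-tendon Hill-type muscles with an explicit
   active/passive split.
4. **Lumbar loads** (`emg_driven_moments()`, `compression_force()`,
   `top_down_id()`) — moments, compression, and the quasi-static
   inverse-dynamics reference.
5. **Calibration** (`calibrate()`) — bounded adaptive simulated annealing
   matching model moments to the reference on one repetition per weight.
6. **Controllers** (`nmbc_desired_force()`, `tibc_desired_force()`,
   `actuator_track()`) and **metrics** (`work_loop_area()`,
   `cumulative_compression()`, ...).
7. **Orchestration** (`run_experiment()`).

# The musculoskeletal model

## Geometry surrogates

Each musculo-tendon unit (MTU) is described by an analytic ground truth
$L(\theta) = L_0 - r_0\theta - r_1\theta^2/2$ and
$r(\theta) = r_0 + r_1\theta$, which satisfy the tendon-excursion identity
$r = -\,dL/d\theta$ exactly. Moment arms are extension-positive
(extensors $r_0 > 0$, the rectus abdominis flexor $r_0 < 0$). Cubic
interpolating splines (FMM end conditions, which reproduce cubic
polynomials exactly) are fitted on a 50-point grid over the working
domain $[-0.2, 1.3]$ rad and evaluated at run time; evaluation outside
the fitted domain is a hard error because spline tails carry no
information. The domain bounds are a package choice: the lumbar share of
a deep stoop lift stays well inside them.

The full 3D wrapping geometry of a musculoskeletal model is out of
scope; the 8 bilateral MTUs mirror the muscles a surface-EMG montage can
actually measure (iliocostalis, longissimus thoracis pars lumborum and
pars thoracis, rectus abdominis). All constants live in
`inst/extdata/default_geometry.json`.

## Hill-type MTU dynamics

The tendon is rigid (slack length `l_ts`), so the fibre takes up all MTU
length change; with the constant-thickness pennation rule the fibre
state has the closed form
$l_f = \sqrt{(L - l_{ts})^2 + (l_{opt}\sin\phi_{opt})^2}$. Force is

$$F = \underbrace{F_{max}\, a\, f_L(\tilde l) f_V(\tilde v)\cos\phi}_{active}
  + \underbrace{\max\{F_{max}(f_P(\tilde l) + \beta \tilde v)\cos\phi,\,0\}}_{passive}$$

with a Gaussian active force-length curve (width $\gamma = 0.45$), an
exponential passive curve normalized to reach $F_{max}$ at strain
$\epsilon_0 = 0.6$ (shape $k_{pe} = 4$), and a Hill force-velocity curve
($f_V(0)=1$, $f_V(-1)=0$, curvature 0.25) whose eccentric branch
saturates at 1.4 with a matched slope at zero velocity. The linear
damper ($\beta = 0.1$) sits in parallel with the passive element and is
therefore counted in the *passive* component — the NMBC must track only
the active part. These specific curve shapes are package choices from
the standard Hill-type family; only the model family, not the equations,
is fixed by the problem. Tendon slack lengths in the default parameter
set place each fibre at optimal length at the neutral angle, a
convenient and analytically checkable normalization.

## EMG processing

The envelope chain is the real-time one: second-order Butterworth
band-pass 30-300 Hz, full-wave rectification, second-order Butterworth
low-pass at 3 Hz, all causal (forward-only). Phase lag is deliberately
part of the modelled behaviour; zero-phase `filtfilt` would misrepresent
an on-line controller. Filter states start at zero, so the first 0.5 s
of every trial is flagged as settling and excluded from statistics.
Envelopes are divided by MVC values and clipped at 1 (with a logged clip
count), then shaped into activations by
$a = (e^{Au}-1)/(e^A-1)$, $A \in (-3, 0]$, the usual exponential account
of the nonlinear EMG-force relationship. The default $A = -1.5$ sits
mid-range; calibration can move it per muscle group.

## Loads

Moments are the moment-arm-weighted sums of MTU forces, split into
total/active/passive. Compression is a transparent surrogate: each MTU
contributes a fixed axial fraction $c_i$ (0.95 extensors, 0.90 flexors)
of its force, plus the trunk-axial gravity component of the
superincumbent mass and of the box while held. A full 3D joint-reaction
analysis is not reproducible without the original full-body model; this
surrogate preserves the property that matters for the controller
comparison — muscle force dominates compression. Shear is not computed.

The reference moment for calibration is quasi-static top-down inverse
dynamics: $M_{ID} = m_{ub} g d_{ub}\sin\theta + s_{box} m_{box} g
(L_t\sin\theta + d_{reach})$. Box inertia is neglected and segment
inertia is off by default — the protocol is metronome-paced at 30 bpm,
slow enough that gravity dominates; an optional $\ddot\theta$ term
exists for faster movements.

# Calibration

Simulated annealing (bounded, Corana-style adaptive steps, geometric
cooling at 0.85, seeded) minimizes the summed squared error between
EMG-driven and reference moments over one repetition per weight
condition. The parameter vector holds a maximum-isometric-force scale
and a shape factor per muscle group (bilateral pairs share), plus global
tendon-slack and optimal-fibre-length scales — 10 dimensions for the
default muscle set. Bounds ($F_{max}$ scale 0.5-2.5, $l_{ts}$ scale
±5%, $l_{opt}$ scale ±2.5%) are physiological-plausibility choices
exposed in `calibration_config()`. The schedule (5 cycles per step
adjustment, 4 adjustments per level) spends the default 20,000-evaluation
budget over roughly 100 temperature levels, which cools the acceptance
probability to numerical zero; the best-ever point is returned and the
run is bit-reproducible for a fixed seed.

**Identifiability.** A single moment signal cannot separate collinear
extensor contributions: the minimum-norm activation distribution used by
the generator makes the per-group moment regressors nearly proportional,
and the shape factors can trade off against strength scales while
changing the fitted moments by well under 0.1% of peak. Parameter
recovery is therefore meaningful for the *pooled* extensor strength
scale (recovered within a few percent on noise-free data), not for
individual group splits. This is a property of EMG-driven calibration in
general, not of the optimizer.

# Controllers

NMBC: $F = \mathrm{clamp}(SR \cdot \mathrm{LPF}_{10\,Hz}(M_{active})(t-\tau)/d_{cable},\,0,\,2\times445\,N)$
with support ratio $SR = 0.2$, cable moment arm $d_{cable} = 0.08$ m and
electromechanical delay $\tau = 80$ ms, implemented as an
integer-sample shift as a real-time ring buffer would. The steady-state
gain is $SR/d_{cable} = 2.5$ N per N m. The per-cable ceiling of 445 N
reflects a 45.35 kg load-cell rating; the two cables split the command
equally (symmetric lifting only).

TIBC: $F = \mathrm{clamp}(k\max(\theta, 0), 0, 2\times445\,N)$, with
$k = SR\, M_{static}(30^\circ, 5\,kg)/(d_{cable}\cdot 30^\circ\pi/180)$
so that at the tuning pose TIBC matches the NMBC steady force for the
same static moment ($k \approx 364$ N/rad at the default
anthropometry). The clamp at upright is a package choice; assistance in
hyperextension would mean pushing the wearer forward.

A first-order lag plant with optional seeded Gaussian noise
(`actuator_track()`) stands in for the cable actuation so that desired
versus measured tracking errors exist to be measured; it is a plant
model of this package, not a reconstruction of any hardware.

# The synthetic cohort

`generate_kinematics()` builds metronome-paced cycles: four 2 s
minimum-jerk phases (bend, lift to upright, bend to place, return),
peak trunk inclination 75°, lumbar share $\lambda = 0.5$ of trunk
inclination, a box resting at table height (46.5 cm) that is carried
between the grab and place events, and a bounded (≤2°) seeded smooth
jitter that vanishes at the endpoints and near upright. Peak
inclination and the lumbar share are declared package choices — typical
of deep stoop lifting — since they follow from no printed protocol
value.

`generate_cohort()` samples anthropometry from the target cohort
statistics (mass 67 ± 9 kg, height 1.73 ± 0.07 m, truncated at ±2 SD)
and ground-truth parameter scales uniformly over the central half of the
calibration bounds; the full bound range would produce subjects whose
extensors saturate (or are implausibly strong) in the 15 kg condition.

`distribute_activations()` inverts the moment summation: flexors sit at
a 2% co-activation baseline, and the active extensor moment remaining
after passive and flexor contributions is shared in closed form with
minimum-norm weights $w_i = r_i F_{max,i} f_{L,i} f_{V,i}\cos\phi_i$.
The force-velocity factor is included in the weights — it is known from
kinematics alone under the stiff tendon, and omitting it would leave
~25% round-trip error at mid-phase velocities, defeating the
self-consistency the generator exists to provide.

`synthesize_raw_emg()` uses a constant-amplitude random-FM carrier
(instantaneous frequency wandering inside the flat middle of the
passband) instead of broadband noise: the rectified mean of such a
carrier is deterministic, so the 3 Hz envelope of the synthesized signal
tracks the target excitation to within the causal filter lag rather than
carrying ~12% stochastic ripple. A 2% MVC additive floor keeps silent
channels realistic; the floor carrier occupies a disjoint frequency band
so its beat against the signal carrier stays far above the envelope
cutoff. The round trip (activations → raw EMG → envelopes →
activations) recovers slowly varying activations within ±0.05; it
*cannot* hold that tolerance across the instantaneous load-transfer
steps at box pickup and drop, where the 3 Hz envelope (group delay
~75 ms) necessarily lags. This is the same lag a physical real-time
pipeline exhibits.

Assisted trials are fixed points: the controller's measured force
becomes an exosuit moment $M_{exo} = F d_{cable}$, the human target drops
to $M_{required} - c\,M_{exo}$ (compliance $c = 1$: full quasi-static
offloading), and activations/EMG are regenerated until $M_{exo}$ changes
by ≤0.5 N m everywhere. The contraction factor is about
$SR\,c/(1+SR\,c)$, so convergence takes 3-5 iterations; the carrier
realization is frozen across iterations to keep the map deterministic.
Kinematics are identical across NOEXO/NMBC/TIBC for a given subject,
weight and repetition, isolating controller effects by construction.

## What the generator does *not* emulate

Real participants change technique under assistance, lean on the
device, co-activate, fatigue, and vary their pacing; the generator's
humans offload exactly proportionally and move identically in all
conditions. Passing tests therefore demonstrate the internal
consistency of the pipeline and the *mechanistic* behaviour of the
controllers, not human outcomes. One concrete consequence: under
proportional offloading the NMBC loop is self-limiting (its moment
reduction is bounded by $SR/(1+SR) \approx 16.7\%$), while the
inclination baseline keeps pushing at full gain through the no-box
bending phases. Integrated over a cycle the prescribed TIBC tuning then
delivers *more* total assistance than NMBC, and the cumulative
compression reduction ordering between the two controllers reverses
relative to a human cohort, where reported NMBC reductions exceed the
proportional-offloading bound itself — evidence of behavioral
adaptation that this generator deliberately excludes. NMBC still shows
its signature properties here: load-adaptive forces without load
information, assistance at erect stance while holding the box, and a
positive work loop.

# Metrics

Work loops are signed shoelace integrals of mass-normalized cable force
over trunk inclination around the closed cycle, positive when raising
forces exceed bending forces at the same angle; any memoryless law
(TIBC with zero actuator lag) scores exactly zero. Phase windows are
fixed fractions of the time-normalized cycle — lowering 1-25% and
60-75%, lifting 25-40% and 75-100%, erect stance 40-60% — which is
sound here because the metronome makes time fractions and movement
phases coincide. Cumulative compression is the trapezoidal integral of
compression force over 1, 5 or 10 concatenated cycles in kN s.
Reductions are computed per subject against the matched-weight NOEXO
condition and then pooled.

A note on magnitudes: the literal time-integral of a multi-body-weight
compression force over ten 8 s cycles is of order 150-250 kN s
(e.g. 4 BW x 67 kg x 9.81 x 80 s ≈ 210 kN s). Reported cumulative
loads in the exosuit literature are sometimes an order of magnitude
smaller than their own mean compression values imply, suggesting an
undocumented normalization; this package implements the literal
definition and reports percent reductions, which are invariant to any
such scaling.

# Numerical choices and problem sizes

* Angles are radians internally; degrees appear only at I/O boundaries.
* Filters: all Butterworth designs are cached; filtering is causal with
  zero initial state.
* Fibre velocity: central differences smoothed by a causal 6 Hz
  low-pass; one-sided differences at the ends.
* The assisted fixed point errors out (reporting its residual) rather
  than silently returning a non-converged trial.
* Default test and demonstration runs execute the model at 100 Hz — at
  that rate trials carry true excitations (a 30-300 Hz band-pass needs
  more than 600 Hz of sampling), while the full raw-EMG path is
  exercised at 1 kHz. The packaged experiment sizes (10 subjects x 10
  repetitions at 100 Hz for the headline quantities; 2 x 2 for the
  reduced CI preset) were chosen so a complete run is comfortable on a
  laptop core.
* Simulated annealing restarts each temperature level from the best-ever
  point; out-of-bounds candidates are resampled uniformly inside the
  violated bound, and a candidate outside the bounds passed to the
  objective scores the largest finite double.

# Known limitations

* One degree of freedom: no 3D wrapping, shear, or per-vertebra loads.
* The compression projection coefficients are declared surrogates, not
  estimates from joint-reaction analysis.
* Per-group strength splits are weakly identifiable (see Calibration).
* The envelope round trip degrades at instantaneous load transfers.
* TIBC's behaviour at cycle start/end depends on a clamping choice the
  underlying problem leaves open.
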