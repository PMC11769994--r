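---
title: "A planar neuromusculoskeletal walking model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A planar neuromusculoskeletal walking model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plangait)
```

This vignette documents the model behind `plangait`, the assumptions and
parameter choices it makes, and what its synthetic data can and cannot
stand in for. It is the package's methods reference; the README shows the
quick tour.

## The model

### Skeleton

The body is a sagittal-plane chain of seven rigid segments: a combined
head-arms-trunk segment (HAT) and, per side, thigh, shank and foot. Nine
generalized coordinates describe it: the hip-point translation (x forward,
y up), the HAT orientation, and one rotational degree of freedom at each
hip, knee and ankle. Joint angles are defined distal-minus-proximal, so
hip flexion, knee extension and ankle dorsiflexion are positive. A
frequently quoted description of this model family gives the floating
base four degrees of freedom (three translations plus one rotation), which
cannot be exercised in a strictly planar mechanism; the effective planar
count implemented here is 9, and the third translation is deliberately
absent.

Segment lengths are proportional to body height and masses, CoM offsets
and moments of inertia to body mass, via the classic gait-analysis
proportion table shipped as a plain-text fixture
(`inst/extdata/segment_proportions.tsv`). The default body is 1.74 m and
72.80 kg. The equations of motion are assembled exactly (d'Alembert /
Jacobian form) in compiled code; correctness is established in the test
suite by machine-precision ballistic energy conservation, a
finite-difference Lagrangian residual, and a closed-form compound-pendulum
limit enforced through an exact pin-force construction.

Passive joint moments use the double-exponential joint-limit form with
linear damping common in this literature. The coefficients are
configuration, not measurements: they produce < 1 N m in the physiological
mid-range and steep restoring moments beyond it. The knee hyperextension
branch is deliberately stiff (the knee locks mechanically just past
straight); with a soft branch the unoptimized model "walks" by vaulting on
a hyperextended knee, which is not a gait worth optimizing around.

### Ground contact

Each foot carries a heel and a toe contact point. The vertical force is a
damped quadratic spring in the penetration depth, clipped at zero so
withdrawal never produces adhesion; the shear force is Coulomb friction
smoothed with a tanh in the sliding velocity. Defaults (stiffness
2.5e6 N/m^2, damping 2 s/m, friction coefficient 0.9, smoothing 0.1 m/s)
put quiet-standing penetration below 1 cm. The smoothing scale trades
stick fidelity against numerical stiffness; 0.1 m/s keeps the
fixed-step integration well behaved at the cost of a small stance-phase
creep.

### Muscles

Eighteen Hill-type muscle-tendon units actuate the model: iliopsoas,
glutei, hamstrings, rectus femoris, vasti, biceps femoris short head,
gastrocnemius, soleus and tibialis anterior per leg. Paths are 2-3 point
polylines in segment frames (`inst/extdata/muscle_table.tsv`); the
coordinates are nominal planar approximations chosen to reproduce
textbook moment-arm magnitudes and signs, not a digitized specimen. The
iliopsoas has a pelvic-brim via point: a straight line from origin to
insertion loses most of its flexion moment arm once the hip flexes, which
makes swing initiation impossible.

Maximum isometric force is specific tension (60 N/cm^2) times PCSA. PCSA
values are tabulated for the 1.83 m / 91 kg reference specimen of the
anatomical literature and scaled to the model body by
`(mass / 91) / (height / 1.83)` - muscle volume scales with body mass and
fiber length with stature; this scaling rule is a package decision, since
the source describing the reference data does not state one. Maximum
shortening velocity is 12 optimal fiber lengths per second for every
muscle. Activation follows the standard first-order two-time-constant
law (55 ms activation, 65 ms deactivation), switching at `u = a` for
continuity.

The four muscle curves are: an exponential-toe tendon reaching maximum
isometric force at 4% strain (linear beyond the toe); a Gaussian active
force-length of width 0.35 optimal lengths; an exponential passive
force-length engaging above optimal length and reaching 1 at 60% strain;
and a Hill hyperbola (shape factor a/F0 = 0.25) with a smooth eccentric
branch that plateaus at 1.5 and matches the concentric slope at zero
velocity. Contraction dynamics invert the force-velocity curve in closed
form so that the fiber force `(a fl_act fv + fl_pas) fmax cos(pennation)`
balances the tendon force; inversions outside the curve's range are
clamped to [-vmax, 1.5 vmax] and counted in the trial record. Pennation
is constant (no pennation-angle dynamics). CE lengths initialize at the
isometric equilibrium for the initial activation (0.05).

### Aging variants

Three parameter transforms represent the muscle-property changes between
roughly ages 30 and 70: deactivation time +20% (dT), maximum isometric
force -30% (dF), maximum shortening velocity -20% (dV). The OA (older
adult) variant applies all three; YA is the identity. Nothing else
changes, so any gait difference between variants is attributable to those
three numbers.

### Metabolic energy

Per-muscle metabolic power follows the Umberger-style decomposition:
activation/maintenance heat `(128 fFT + 25) A^0.6` W/kg with `A = u` when
`u > a`, else `(u + a)/2`; shortening/lengthening heat proportional to
normalized CE velocity (coefficients 100/vmax_ST and 153/vmax_FT, slow-twitch
maximum velocity taken as vmax/2.5); and the positive (concentric) CE work
rate. Fiber-type mix defaults to 50/50 (a fixture, since no mix is
published for this configuration). The heat sum is clamped at zero;
eccentric work enters only through lengthening heat. Basal metabolism is
excluded: with fixed trial duration it shifts every candidate gait
equally. Muscle mass is PCSA x optimal fiber length x 1059.7 kg/m^3.

The objective's energy term is the trapezoidal time integral of summed
muscle power divided by body mass and by the net forward CoM travel
(J kg^-1 m^-1).

## Control and optimization

Stimulation is open loop: each right-leg muscle gets one square burst per
1.12 s stride (onset, offset, amplitude), with a 0.01 baseline floor;
bursts may wrap across the cycle boundary, which late-stance-to-swing
muscles need. Left-leg muscles replay the right profile delayed by half a
stride. That yields 27 decision variables, normalized to the unit cube.

The objective is
`omega1 * RMSang + omega2 * WBEmeter` with both weights 1.0: RMSang sums,
over the four steps (a step runs between successive right/left foot
contacts, so its boundaries are heel strikes of alternating sides), the
RMS deviation of the seven segment angles at each step's toe-off from
the target toe-off posture (`sqrt(sum(dtheta^2)/7)` per step, radians,
summed over steps - the summation convention is stated explicitly
because a per-step mean is the plausible alternative); the target
describes a right toe-off and is mirrored for left toe-offs. A step
without a toe-off - the gait fell first, or never alternated -
contributes a fixed worst-case term of 1 rad, which is what makes
one-sided hopping gaits unattractive to the optimizer. RMSang is kept
in radians; the choice matters because it sets the balance against the
energy term and is therefore part of the configuration.

Trials that fall (HAT CoM below 70% of standing height), diverge, or fail
to travel at least 0.1 m are penalized: 18 x (unlived fraction of the
trial) + 8 x mean squared trunk deviation + 2 x mean joint-angle deviation
from the gait template + a displacement shortfall term. The shaping terms
exist to give the optimizer a gradient through the (vast) non-walking
region of the search space; they are all identically zero for a completed
walk with normal travel, so the objective of interest is untouched at the
solutions that matter.

The optimizer is a standard CMA-ES (rank-mu update, cumulative step-size
adaptation, population `4 + floor(3 ln 27) = 13`), box constraints by
clamping, seeded and fully deterministic. It starts from a hand-tuned
physiologically timed warm-start profile. Optimizing gait from scratch in
a 27-dimensional open-loop space typically needs tens of thousands of
evaluations; the warm start plus shaping brings usable solutions into the
few-thousand range that a desk machine handles. Variant fits may
optionally warm-start from a previously optimized young-adult solution
(`x0` argument), which is also how the packaged experiment keeps its
runtime modest.

## Analysis

Toe-off and heel-strike events are threshold crossings of the vertical
GRF at 0.05% of body weight, linearly interpolated between samples;
contact or flight phases shorter than 50 ms are treated as chatter during
event assembly (the raw detector keeps them if asked). Steps are
delimited by successive heel strikes of either side.

The margin of stability is evaluated at the left toe-off of the second
step: `MoS = BoS - XCoM`, with the right toe as the base-of-support
boundary and `XCoM = P_CoM + V_CoM sqrt(l/g)` the extrapolated CoM using
the right-ankle-to-CoM distance as pendulum length. Typeset statements
of the XCoM formula are easily garbled by formatting, so to be explicit:
the implemented form is the standard extrapolated center of mass
(the CoM position advanced by its velocity times the inverted-pendulum
time constant `sqrt(l/g)`). If no
left toe-off falls inside step 2 the second left toe-off overall is used.
Step length is the right-left toe distance at that instant; the walking
velocity statistic averages forward CoM velocity over steps two and
three.

Validation correlates simulated hip/knee/ankle angle curves (heel-strike
to heel-strike, resampled to 101 points) against reference group means at
zero lag; the overall score is the unweighted mean over the three joints.
Zero lag is a deliberate choice - allowing lag optimization would inflate
agreement.

## Synthetic reference data

The package generates every input that would otherwise come from
experiments: a gait template (5-harmonic Fourier series fitted to
textbook-shaped keypoint curves) for a "30s" and a "70s" group, the
target toe-off posture (template evaluated at the 60% toe-off phase and
converted to segment angles), reference mean +/- SD curves (template plus
smooth correlated Fourier noise across simulated subjects, 10 per group
by default), and the initial condition (template posture at right heel
strike, forward velocity 1.3 m/s, trunk leaned slightly forward). The 70s
template has a reduced range of motion and, most prominently, a blunted
ankle push-off excursion - the best-documented kinematic signatures of
older-adult gait.

These stand-ins are deterministic functions of their seed and are clearly
labeled synthetic. Consequences worth stating plainly: cross-correlations
of simulated gait against these curves validate internal consistency, not
agreement with any real cohort; and the target posture is not the
(unpublished) experimental posture, so absolute outcome values (margin of
stability, step length, velocity) can differ from values obtained with
the real references even when the model and method are faithful.
Between-variant orderings are far more transferable than absolute values,
which is why the package's acceptance surface checks orderings.

## Numerical choices

* Fixed-step RK4 at dt = 1 ms, states: 9 q + 9 qdot + 18 activations + 18
  CE lengths. Activations are clamped to [0, 1] and CE lengths to
  [0.25, 1.85] optimal lengths after each step (the clamps are inactive in
  healthy simulations).
* Muscle moment arms are central finite differences of path length with
  step 1e-5 rad (exact for these piecewise-linear paths to well below the
  integration error).
* Determinism: simulations are bitwise reproducible; the optimizer and
  all synthetic-data generators use a small self-contained
  Park-Miller/Box-Muller RNG so results are pure functions of their seed
  and never touch R's global RNG state.
* Impact sensitivity: with a stiff nonsmooth contact model, individual
  trajectories depend sensitively on the step size after the first
  heel strike (halving dt from 5e-4 to 2.5e-4 s perturbs a 0.5 s
  trajectory as much as halving from 1e-3 to 5e-4 does). This is a
  property of the mechanical model, not of the integrator, whose order is
  verified in the smooth regime (flight-phase dt-halving agrees to 1e-6;
  ballistic energy is conserved to machine precision). Aggregate gait
  outcomes should accordingly be read as representative of the attractor,
  not as trajectories converged pointwise in dt.
* The fall-penalty constants (18 per unlived trial fraction, 8 per unit
  mean-square trunk deviation, 2 per radian of template deviation, 5 per
  meter of displacement shortfall below the 2 m a four-step walk covers) were balanced so that a nearly complete
  alternating walk scores better than a degenerate non-alternating gait
  that merely survives; no completed-walk objective includes the
  fall terms.

## Problem sizes in the packaged experiment

The packaged experiment and acceptance analysis refine each variant from
the shipped reference profile: 900 objective evaluations x 2 optimizer
seeds per variant (best-of) in the acceptance script, 520 x 2 in the test
suite's end-to-end block; `run_experiment()` defaults to 3 seeds. These
sizes are the package's own desk-scale defaults; larger budgets (tens of
thousands of evaluations, many restarts) sharpen the optima but do not
change the method. At desk scale the between-variant outcome differences
are of the same order as optimizer-seed variability, so individual
orderings of closely spaced variants can flip between runs; the
between-run spread of the margin of stability is several centimeters.
The unit and property tests run in seconds; the five-variant analysis is
the long pole and is sized to minutes.

## Known limitations

* Sagittal plane only; no arm swing, no trunk articulation, no
  mediolateral stability (the margin of stability here is anteroposterior
  only).
* Open-loop square-pulse control: one burst per muscle per stride, no
  reflexes or sensory feedback; gait robustness to perturbations is out
  of scope.
* Muscle paths are straight polylines without wrapping surfaces; moment
  arms are approximate away from mid-range postures.
* The metabolic model's coefficients follow the cited family but the
  exact published variant is not reproducible from the available
  description; energy values are comparable within this package, less so
  across implementations.
* Step timing is fixed (0.56 s per step) and the left leg is an exact
  half-cycle mirror of the right; cadence variation and asymmetry are
  excluded by construction.
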