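---
title: "Predictive simulation of prosthetic and stiff-knee gait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive simulation of prosthetic and stiff-knee gait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

predgait predicts periodic walking by optimal control: it finds joint and
muscle trajectories that minimize a physiological effort criterion subject
to the dynamics of a planar musculoskeletal model, without tracking any
measured motion. The package targets a clinical question: how does gait
reorganize after a knee disarticulation treated with a variable-damping
microprocessor-controlled prosthetic knee (MPK), and what does an imposed
stiff-knee-gait (SKG) restriction do to either a prosthetic or an
unimpaired gait? This vignette explains the model, the two optimal-control
problems, the statistics used to compare gait curves, the synthetic-data
generator, and every numerically consequential choice.

## The musculoskeletal model

The default model is a sagittal-plane chain with nine degrees of freedom:
pelvis translation (x, y), pelvis/HAT tilt, and hip, knee and ankle pin
joints on each leg. Segment masses, lengths, centres of mass and inertias
are scaled from Winter-style reference proportions by body mass and height
(`build_reference_model(mass, height)`). Nine Hill-type muscles per leg
cover the functional groups that drive sagittal gait: iliopsoas, gluteus
maximus, biarticular hamstrings, rectus femoris, vasti, short biceps
femoris, gastrocnemius, soleus and tibialis anterior. Muscle paths are
polynomials of the spanned joint angles (degree 1 by default, i.e.
constant moment arms representative of planar gait models); moment arms
are the exact negative derivative of the length polynomial, so path length
and moment arms can never disagree.

Sign conventions: hip flexion, knee flexion, and ankle dorsiflexion are
positive; radians internally, degrees in every file and report.

Every pin joint carries a passive moment

M(q, q') = k1 exp(-k2 (q - q_lower)) - k1 exp(k2 (q - q_upper)) - b q' - k_lin q

an exponential joint-limit pair plus linear damping and an optional linear
spring. This one form serves four roles: physiological joint limits, the
MPK hyperextension stop and flexion limit, the elastic
energy-storage-and-return (ESR) prosthetic ankle (through `k_lin`, default
300 N m/rad), and the SKG conditions, which simply lower the knee
flexion limit `q_upper` (137.5 degrees in the reference setting; 14.9, 30
or 35 degrees in the restricted conditions; the orthosis condition uses 20
degrees and adds the orthosis mass to the thigh and shank).

Foot-ground contact is Hunt-Crossley: two spheres per foot (heel, toe)
with normal force k delta^(3/2) (1 + 3/2 c ddelta/dt), smoothly clamped at
zero so separation can never pull, and smoothed Coulomb + viscous
friction. Stiffness (3e5 N m^-1.5), dissipation (1 s/m) and friction are
calibratable per subject; they were chosen once so that roughly one body
weight corresponds to ~1.7 cm penetration, which keeps the contact
curvature tractable for the optimizer. Penetration is smoothed with a
1 mm softplus.

### Clinical variants

* `apply_amputation()` converts the healthy model: the IL knee becomes the
  MPK degree of freedom, prosthetic shank/foot segments default to 60% of
  the intact masses (exact component masses are unpublished, so this is an
  explicit, config-overridable assumption), the ESR ankle replaces the
  muscle-driven ankle, and only muscles spanning the IL hip are retained.
  Biarticular hip muscles lose their distal attachment in a knee
  disarticulation, so their geometry is truncated to the hip terms; hence
  no IL muscle spans the knee or ankle.
* `mirror_to_hypothetical_healthy()` mirrors the sound side onto the
  amputated side and rescales to the heavier intact-body mass — a
  "what if this person were unimpaired" model.
* The MPK damper is T_MPK = a_MPK D_MPK q', with D_MPK = 1 N m s/rad in
  the optimal (REF) setting and 0.75 when deactivated (DACT); a_MPK
  follows a first-order lag (tau = 30 ms) on the MPK excitation, which is
  a control of the optimization.

## Muscle-tendon dynamics

Muscles use a Hill model with compliant tendon in implicit form. States
are activation a and normalized tendon force f~; their time derivatives
are controls. The tendon force-length curve is exponential with 4.9%
strain at maximal isometric force and is inverted in closed form, so fiber
length follows explicitly from (l_MT, f~) and the fiber velocity from
(v_MT, df~/dt). The equilibrium residual

(a f_L(l~) f_V(v~) + f_P(l~)) cos(alpha) - f~ = 0

is an algebraic path constraint at every collocation node. The curves are
smooth closed forms: Gaussian active force-length (width 0.2), exponential
passive force-length, and a logistic force-velocity with eccentric plateau
1.4. Activation dynamics use distinct activation/deactivation time
constants (15/60 ms) blended smoothly around e = a. The metabolic model is
a smoothed Bhargava-style sum of activation and maintenance heat (scaled
by muscle mass derived from F_max and optimal fiber length), shortening
heat, and positive fiber work, with softplus smoothing; it is always
nonnegative and strictly increasing in activation.

## The two optimal-control problems

Both problems are transcribed by third-order Radau collocation (the state
is a cubic polynomial per mesh interval; dynamics are enforced at the
Radau nodes, which include the interval end, so state continuity is
automatic) and solved by a built-in SQP method (below).

**Parameter estimation.** Along prescribed hip kinematics, reproduce a
joint-moment trajectory with the IL hip muscles while minimizing

integral( W_E1 a^2 + W_E2 L_opt + W_E3 Re^2 + W_E4 (a'^2 + f~'^2) ) dt

where Re is a heavily penalized reserve actuator that keeps moment
matching feasible. Maximal isometric force, optimal fiber length and
tendon slack length are personalized as multipliers bounded to [0.5, 2]
of the generic values, started at 1. Because nothing in this objective
penalizes strength, the force multipliers of active muscles drift toward
the upper bound at the true optimum — a structural property of the
objective, not a solver artifact; the tests therefore assert bound
compliance, directional movement toward a known truth, and that the
personalized fit strictly beats the generic one, rather than exact truth
recovery.

**Gait prediction.** Find periodic state/control trajectories and a free
cycle time T minimizing

integral( W_P1 a^2 + W_P2 Edot^2 + W_P3 q''^2 + W_P4 (a'^2 + f~'^2)
          + W_P5 e_MPK^2 ) / Dist dt

subject to collocated skeletal dynamics (implicit inverse-dynamics
residual with contact), Hill equilibrium, activation dynamics, periodicity
of every state except the pelvis forward position, and
Dist = speed x T with the imposed average speed (1.48 m/s by default, the
fastest speed observed across conditions, so speed effects are excluded
from comparisons). The MPK excitation term exists only for the amputee
variant. Because the mesh step is T/n, the 1/Dist normalization makes the
discretized objective independent of T except through the physics.
Default weights (2000, 0.01, 1, 1, 100) were set once so the terms have
comparable magnitude on the nominal guess with q'' in rad/s^2; all are
configuration-exposed.

### Initial guess, bounds, scaling

The default guess evaluates smooth periodic gait templates (the same ones
the synthetic-data generator uses), with the two legs half a cycle apart.
Three adjustments matter: the pelvis height is placed so that the lowest
contact sphere penetrates ~5 mm (so the guess starts in contact, not in
flight or buried); for prosthetic variants the IL stance knee is seeded
near extension (passive knees give little stance support); under an SKG
condition the knee guess is saturated smoothly below the imposed limit
(otherwise the exponential passive moment overflows at the guess).
Accelerations are seeded from forward dynamics along the guess
trajectory, which zeroes the hard nonlinear constraint rows at the start
and leaves the initial mismatch in the nearly linear collocation rows. A
prior solution or a time-series file can be supplied instead; different
guesses may converge to different local optima, which the result records
(the solver is deterministic: same configuration, same result).

Variables and constraint rows are scaled to order one (e.g. forces by
body weight, collocation rows by typical state rates). Muscle states are
bounded to [1e-4, 1] (activations) and [0, 3] (normalized forces).

### The NLP solver

No interior-point library is available to R here, so the package ships
its own sparse solvers. The default is SQP: Newton-type steps on the KKT
system with a positive diagonal objective-curvature model plus Levenberg
damping, an l1-penalty merit with backtracking and a second-order
correction step, and bounds by freezing active variables. Because the
Hessian model is diagonal, the KKT step reduces to a sparse SPD Schur
complement solved by supernodal Cholesky; the free cycle time appears in
every collocation row and would densify that matrix, so it is split off
and handled by a rank-one Woodbury update. An augmented-Lagrangian solver
(`solve_nlp_al`) with the same problem interface is used for the smaller
estimation problem and kept as an alternative.

The prediction is solved by continuation: bounded residual joint
actuators are added to the skeletal rows, the problem is solved with the
bound shrinking over stages (100, 30, 10, 3, 1, 0.3, 0.1, 0 N m), and
the final stage — with the bound exactly zero — is the true problem. A
converged result means the final-stage constraint violation is below the
feasibility tolerance and no merit descent remains; an independent
post-hoc evaluation of all physical residuals at the reported solution is
stored in `$verification`.

Tolerances: the default feasibility tolerance is 1e-3 in scaled units.
At the default scaling this corresponds to skeletal residuals well below
1 N (or N m), Hill residuals below ~1e-3 of maximal isometric force, and
periodicity mismatches below ~1e-3 of a state's typical range; the
imposed-speed constraint is typically met to ~1e-6 m/s, orders below its
1e-4 m/s acceptance band. Tighter tolerances are configurable but at
desk-scale mesh sizes the bounded muscle states make the last decade of
scaled feasibility expensive.

### Problem sizes and runtime

The package defaults to 50 mesh intervals for prediction (about 12,000
variables and 10,000 constraints for the amputee model; roughly 5-7
minutes on one CPU) and 12-50 for estimation (seconds to a minute).
Richer meshes are configuration choices, trading runtime for sharper
resolution of the contact transients; the directional comparisons in the
test-suite use 20 intervals, which preserves the large SKG effects.

## Whole-curve statistics

`spm_paired_nonparametric()` implements one-dimensional statistical
parametric mapping for paired designs with a permutation null: the paired
t statistic is computed at each of the 101 cycle nodes, the null
distribution of the supremum of |t| is built from sign flips of the trial
differences (exhaustive up to 2^13; a seeded subsample of 10,000 beyond
that), and the critical threshold is its (1 - alpha) empirical quantile.
Inference is two-tailed on |t|; suprathreshold clusters are maximal
intervals above the threshold. With n = 7 trials the permutation
distribution has 128 atoms, so the achievable family-wise level is 6/128
(about 4.7%) at nominal alpha = 0.05 — the type-I simulation in the tests
accounts for this granularity. If all differences are zero at a node the
t value is defined as 0. Parametric random-field SPM is out of scope; the
interface reserves a method flag.

`dtw_score()` is dynamic time warping with a Sakoe-Chiba band of 5% of
the series length (the maximum temporal shift allowed), endpoints pinned,
local cost |x_i - y_j|, and the score defined as the total accumulated
cost — zero iff the warped curves coincide. Curves entering a comparison
are first normalized jointly by the maximum absolute value over the two
collections in that comparison (a per-comparison constant, recorded as an
attribute), mapping everything into [-1, 1]. `dtw_matrix()` scores many
muscles at once, assigns NaN to muscles that do not exist on one side
(e.g. the amputated side), and grouped muscles are formed as the
pointwise maximum of their components.

`peak_metrics()` refines the discrete maximum by a parabola through the
peak and its neighbours (ties broken toward the earlier sample; no
refinement at window edges). Gait cycles are segmented at upward
crossings of vertical GRF through 20 N and resampled to 101 points by
cubic splines.

## Synthetic data

`generate_trials()` emulates the structure of the study's recordings:
5 (amputee) or 7 (healthy) repeated trials per condition, each a set of
smooth periodic gait-cycle curves — double-peaked knee flexion with a
swing peak near 65 degrees, double-bump vertical GRF, burst-like EMG
envelopes. Trial-to-trial variability is multiplicative amplitude scaling
(SD 5%) plus a smooth monotone time warp (SD 1% of the cycle), which is
how repeated gait trials actually vary; additive white noise is used only
for EMG envelopes, since white noise on kinematics is not physiological.
All curves are exactly periodic. A condition effect can be injected as a
smooth offset over a window; `inject_skg_effect()` saturates knee flexion
below a limit with a 1-degree soft minimum (a no-op when the limit
exceeds the peak, which also makes it idempotent) and adds the
contralateral early-stance knee-moment compensation.

`generate_estimation_dataset()` builds joint-moment data that are exactly
achievable by a model with known perturbed parameters: smooth normalized
tendon-force curves are chosen (above the passive floor along the
motion), the implied activations are recovered in closed form from the
Hill equilibrium, and the moment is the sum of moment arm x force. The
generating truth ships with every dataset.

What passing tests on these data do and do not show: they verify the
statistical machinery (exact permutation behaviour, DTW properties,
detection power), the estimator's mechanics, and the optimal-control
pipeline end to end; they cannot validate the model against real
prosthetic gait, soft-tissue artifact, marker noise, or EMG crosstalk,
none of which the generator emulates.

## Known limitations

* The planar reduction omits frontal/transverse mechanics (hip
  ab-/adduction compensations are invisible), and constant moment arms
  are a first-order geometry.
* The predicted gait is one local optimum; different initial guesses can
  yield different costs. The multistart helper is simply to rerun with a
  different guess and compare recorded objectives.
* Passive-moment coefficients, prosthetic masses and contact parameters
  are defaults standing in for unpublished subject-specific calibrations;
  all are exposed in the configuration.
* The estimation objective cannot identify absolute muscle strength (see
  above); it identifies the redundancy resolution and the fit.
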