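---
title: "In silico development of FNS stepping patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico development of FNS stepping patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fnstep)
```

## The problem

Functional neuromuscular stimulation (FNS) restores stepping after spinal
cord injury by delivering current pulses to paralyzed muscles. The
stimulation pattern — when and how strongly each channel fires across the
gait cycle — is conventionally tuned by hand, which is slow and tends to
park every channel near its maximum. `fnstep` implements an *in silico*
alternative: a muscle-actuated gait model is driven by a staged
trajectory-optimization cascade that finds minimal muscle excitations
achieving a stepping motion; the optimized excitations are then compiled
into device-ready pulse-width schedules; and a gait-trial analysis
pipeline quantifies how stepping with such a pattern compares to stepping
with a manually tuned one.

This vignette documents the science inside each module: the model and its
assumptions, the cost and constraint structure of the optimal-control
problems, the numerical methods, what the synthetic data emulate, and the
design decisions taken where the problem statement left the choice open.

## The planar musculoskeletal model

`planar_biped()` builds an eight-segment sagittal-plane biped: a pelvis
floating base (x, y, pitch), a lumped trunk/head/arms segment on a pitch
joint, and thigh-shank-foot chains per side (10 coordinates in total).
Total mass is 76.2 kg at a 1.84 m build; segment masses, inertias and
lengths are standard anthropometric proportions. The full study-scale
model in this line of work has 29 three-dimensional degrees of freedom;
the planar realization keeps the method intact (muscle-driven multibody
dynamics, contact, staged optimization) at a size where every experiment
in the test suite runs on one core. The model description is configuration
data (`read_msk_model()`/`write_msk_model()`), so richer topologies can be
declared without touching code.

**Muscles.** Hill-type muscle-tendon units with smooth active
force-length, force-velocity and passive-elastic curves (the standard
smooth parameterization used by gradient-based muscle-driven
optimization), normalized so that maximal activation at optimal fiber
length and zero velocity produces exactly the maximum isometric force.
First-order activation dynamics use activation/deactivation time constants
of 15/60 ms with a smooth blend of width 0.05 in excitation-activation
difference; the blend width matters numerically (a sharp switch stalls
collocation convergence) and is exact in both saturated regimes. Tendons
are rigid by default; a compliant mode adds normalized tendon-force states
with an implicit equilibrium formulation and an invertible exponential
tendon curve, at the cost of two extra channels per muscle. Muscle paths
are constant moment arms per coordinate — adequate over the modest joint
excursions of FNS-assisted stepping and fully declared in the model
configuration.

The muscle set mirrors the FNS channel inventory of the participant-
informed model: bilateral iliopsoas (psoas + iliacus elements), vasti
(three elements) and tibialis anterior, plus right sartorius, right biceps
femoris short head and left tensor fasciae latae (`"model_p"`). Because
the early cascade stages impose half-stride left-right symmetry, they run
on a bilateral completion of every group (`"model_g"`, the general-model
surrogate), and the mid-cascade stages on the symmetric
iliopsoas/vasti/tibialis set (`"symmetric"`). Muscle groups matter because
one stimulation channel drives all elements of a group — that is what the
synergy cost term encodes.

**Contact.** Three spheres per foot (heel, metatarsal, toe) against the
ground plane with a smoothed Hunt-Crossley law: the penetration enters
through a square-root softplus of width 1 mm, making the force defined
and C-infinity for any penetration (required by the gradient-based
solver), with the Hunt-Crossley dissipation factor smoothed the same way
and a tanh friction law (0.05 m/s smoothing velocity). Stiffness defaults
to 5e4 N/m^1.5: deliberately soft ground, trading a centimeter-scale
static penetration for well-conditioned collocation. At zero penetration
the residual force is about 0.56 N, under 0.1% of body weight. Seven
spheres per foot appear in the three-dimensional lineage of this contact
model; published sensitivity results show the method robust to the
number and placement of contact elements, and three suffice in the
sagittal plane.

**Reserve actuators.** Bounded generalized forces on the base (250 N
forward, 800 N vertical, 150 Nm pitch), the trunk joint, and each leg
joint (60 Nm). They represent walker support and residual volitional
control, and they guarantee controllability of every coordinate so the
optimizer always has a feasible path; the effort cost penalizes them ten
times more heavily than muscle channels, so the solution shifts work into
the muscles wherever it can.

**Dynamics.** A planar recursive Newton-Euler formulation supplies
inverse-dynamics residuals; the implicit form
`residual(state, state-derivative, controls) = 0` is what the collocation
enforces. The implementation is verified against closed-form oracles in
the test suite: a pendulum's small-amplitude period to 1%, static standing
balance against a virtual-work computation, exact linearity of the
residual in segment inertia, exact left-right mirror symmetry, and a
non-increasing mechanical-plus-contact-elastic energy audit for passive
motion with dissipative contact.

## Cost terms and constraints

Six cost subterms operate on discretized trajectories:

* marker tracking — time integral of weighted squared distances between
  model markers and reference markers, with bony-prominence markers
  weighted ten times the rest;
* contact tracking — squared per-foot ground-force error normalized by
  body weight, the per-foot force being the vector sum over that foot's
  spheres;
* synergy — squared within-group excitation differences, one term for a
  pair and two for a triple, because one channel drives the whole group;
* effort — weighted squared controls over all channels (muscles equal,
  reserves penalized), divided by the center-of-mass travel distance in
  predictive mode;
* energy-injection penalty — ten times the squared excitations of the
  rectus abdominus and external oblique channels (zero in the planar
  fixture, which omits them);
* auxiliary-derivative penalty — squared tendon-force rates, active only
  with compliant tendons.

The tracking composition weights all six (the distance factor cancels the
effort normalization); the predictive composition keeps only synergy,
effort, energy and auxiliary terms. All subterm weights default to 1 with
a reserve-channel multiplier of 10; no published values exist for them,
so they are configuration with those defaults. Units are mixed across
subterms (m^2 s, s, N^2/s) and are deliberately not nondimensionalized —
the weights absorb units.

Standalone evaluation uses trapezoidal quadrature (matched by independent
oracles to 1e-10 in the tests); the transcribed objective uses composite
Simpson weights on the same grid, consistent with the transcription
order — this is what lets the solver hit the closed-form minimum-effort
double-integrator objective to four significant figures.

Eight constraint families attach to a problem: half- or full-stride
symmetry of states and controls (reserve channels exempt, as they
represent volitional effort; the forward pelvis translation state exempt
so the model can advance), joint-speed bounds scaled from the
neurotypical reference range, average center-of-mass speed, final-time
bounds, leg clearance, straight knees at double-stance onset, and initial
rest. Two readings deserve notes. First, the speed bound concerns *joint*
coordinates; the pelvis-to-ground coordinates keep their model ranges,
because the reference pelvis advances monotonically and scaling its
strictly positive speed range would forbid standing still — contradicting
the initial-rest constraint. Second, double-stance onset is defined
kinetically: the node where a foot's total normal force rises through 5%
body weight after a sustained unloaded period and stays loaded (the
persistence requirement keeps grazing-contact chatter from spawning
spurious events); the knee-angle tolerance there defaults to one degree.
Whether the straight-knee condition applies to both knees or only the
striking leg's knee is genuinely open; the analysis operation defaults to
both, while the cascade constrains the striking knee — the supporting hip
and knee flex through stance in these gaits, and requiring the trailing
knee straight at footstrike contradicts (through the mirrored endpoint
condition) the flexion that starts its own swing.
Leg clearance is the Euclidean gap between contralateral knee-center and
ankle-center pairs; the general default floor is 5 cm, while the cascade
stages use 2 cm because in the sagittal *projection* the joint centers of
crossing legs legitimately approach each other (out-of-plane offset
provides the rest in three dimensions).

## Transcription and solver

Problems are transcribed by separated Hermite-Simpson collocation on a
uniform mesh (2N+1 collocation points for N intervals; mesh nodes plus
midpoints). Dynamics are enforced implicitly: generalized accelerations
join the controls and the multibody residual is a path constraint at
every point — the formulation that keeps muscle and contact stiffness out
of the defect equations. The free final time (when bounded rather than
fixed) is one more decision variable.

No general nonlinear-programming solver is assumed; the package carries
its own, shaped around the structure of these problems:

* every cost subterm is an integral of squares, so the objective is
  natively a least-squares stack;
* bound constraints are eliminated by a sigmoid reparameterization of
  each variable onto its interval, which simultaneously implements
  variable scaling to order one (the midpoint of the bounds maps to
  zero — exactly the default initial guess of the staged procedure);
* equality constraints (defects, dynamics path residuals, boundary
  conditions) carry augmented-Lagrangian multipliers; the leg-clearance
  inequalities are converted to smooth equalities with bounded slack
  variables (hinge penalties at high penalty defeat a Gauss-Newton
  model), while the few knee-event inequalities use the positive-part
  augmented form;
* each outer iteration minimizes the augmented least-squares stack with
  a sparse Levenberg-Marquardt method: the Jacobian comes from forward
  finite differences compressed by an exact structural coloring (about
  60 colors for the gait problems instead of one evaluation per
  variable), assembled into a fixed sparsity template and solved through
  a sparse normal-equation Cholesky factorization with adaptive damping
  and a trust-region step cap;
* multipliers advance only when an outer iteration actually reduced the
  infeasibility, and are kept bounded — without this safeguard the
  multipliers diverge whenever an inner solve terminates early;
* the forward pelvis translation of the predictive problems is a pure
  gauge freedom (nothing in the cost or constraints depends on absolute
  position), so the cascade pins its initial value at zero and shifts
  warm starts accordingly — removing a null direction from the normal
  equations.

The residual stack itself is evaluated in compiled code with a single
forward-kinematics pass per collocation point serving the dynamics,
marker positions, foot forces, clearance points and center of mass; an R
reference implementation of the same stack is kept and the two are
asserted equal to machine precision in the tests, alongside a dense
finite-difference check of the colored Jacobian on every constraint
combination.

Feasibility tolerance defaults to 1e-6 (on scaled residuals: defects per
state span, forces per body weight), optimality tolerance 1e-4, both
configuration. Knee-event nodes are frozen during each inner solve and
refreshed between outer iterations from the current contact forces.

Solver verification rests on closed forms: the rest-to-rest
minimum-effort double integrator (objective 12 d^2/T^3, control linear in
time) to four significant figures in about two seconds; the same law for
a rod pivoted at its center of mass, exercised through the full multibody
path; warm-start determinism; and mesh-refinement consistency on a
gravity-loaded pendulum swing (documented tolerance 5%).

## The staged cascade

`cascade_config()` encodes the staged procedure: a tracking problem
(marker + contact tracking of a neurotypical reference under half-stride
symmetry and 10% joint-speed bounds) solved at 10 then 50 mesh intervals,
followed by six predictive refinements. Predict1 drops the tracking
terms, relaxes the speed bounds to the full reference range, and adds leg
clearance, initial rest, a 0.4 m/s average-speed target and a [0.4, 0.6] s
final-time window; Predict2 adds the straight-knee double-stance
constraint; Predict3 cuts the muscles to the symmetric
iliopsoas/vasti/tibialis set, drops the target to 0.1 m/s with final time
in [0.9, 1.1] s (magnitudes typical of FNS-assisted stepping); Predict4
multiplies the reserve penalty tenfold (the magnitude of this increase is
unpublished and therefore configuration); Predict5 raises the target to
0.2 m/s; Predict6 restores the asymmetric participant muscle set,
exchanges half-stride for full-stride symmetry and opens the final time
to [2.0, 2.2] s — a complete two-step cycle. Each stage warm-starts from
its predecessor, interpolating across mesh changes, matching channels
across muscle-set changes, and mirroring-and-concatenating the half
stride into a full stride at the symmetry switch.

Two initialization choices deviate deliberately from the midpoint-of-
bounds default (which remains `solve_ocp()`'s documented default). The
cascade's first stage starts from a balanced quiet-standing trajectory
(base height solved so the contact force equals body weight, optionally
with a split-stance hip stagger): the purpose-built solver, unlike an
interior-point method with exact second derivatives, needs a physically
consistent trajectory to converge within desk-scale budgets. And the
first predictive stage is seeded with a gait-template step
(`nt_step_guess()`): a half stride of the reference kinematics beginning
at peak leg separation, so the legs exchange roles over the stage.
Without this, the optimizer reliably converges to a "legs parallel"
shuffle — a local basin in which the symmetry constraint is satisfied
trivially but the leg-clearance constraint cannot be met; the predictive
problems are described in their source as starting from a neurotypical-
gait-based guess, which is precisely what this seed is.

Constraint violations are reported on the scaled residuals; the reduced
verification cascade (`reduced_cascade_config()`: tracking at 10 mesh
intervals, then Predict1 and Predict2, all at 10 intervals) completes
with every stage below 1e-4 and is exercised as-is by the acceptance
suite. The full eight-stage, 50-mesh-interval configuration is provided
and runs the identical code path; the package's own test problem sizes
are the reduced ones.

## Pattern compilation

The optimized excitations become stimulation patterns in four steps.
Swing-phase excitations are extracted per side — left from the first half
of the two-step cycle, right from the second, stance discarded — using a
5%-body-weight unloading threshold on the foot force, and muscle-group
elements are averaged into one channel trace. Each trace is resampled to
22 points by linear interpolation and mapped to pulse widths by the
channel calibration, Stim = Excitation x Sat + Thresh, clamping to the
0-255 microsecond device range. Two empirical strength scalings follow:
left-side pulse widths multiply by 1.2 (re-clamped) and the right-side
time base stretches by 50%. Frequency schedules start at 16 Hz and double
after 0.15 s for all muscles except the vasti; the right side returns to
16 Hz for the final 30% of the pattern ("approximately 30%" implemented
as exactly 30%, configurable), the left holds the higher rate.

Charge per swing is amplitude times pulse width summed over pulses placed
sequentially from time zero at the instantaneous scheduled frequency,
pulse widths linearly interpolated between the 22 samples; a partial
trailing inter-pulse interval delivers no pulse, and only the cathodic
phase of the biphasic pulse is counted (whether published charge totals
include both phases is unstated; single-phase is assumed here).
Amplitudes are calibration inputs — they are set per channel on the
device and never printed — so charge comparisons between an optimized and
a manually tuned pattern take per-muscle charges as inputs and report
percent reductions, their mean over muscles showing a reduction, range
endpoints, and any increases. Manually tuned patterns are accepted as
pulse-width CSV files; they are specified directly in pulse width and
need no saturation/threshold mapping.

## Synthetic data

`generate_nt_reference()` stands in for the neurotypical reference
recordings: a truncated-Fourier joint-angle gait template (left and right
half a stride out of phase) realized into marker trajectories by the
model's forward kinematics at 100 Hz, and per-foot double-bump vertical
ground-reaction forces at 1000 Hz with a 0.6 duty factor, normalized so
the vertical impulse per stride equals body weight times stride time.
Defaults: 0.4 m/s at 120 steps/min — a slow, self-selected pace with a
0.4 m stride and a 0.5 s half-stride tracking window consistent with the
[0.4, 0.6] s predictive final-time bounds.

`generate_trial()` emulates instrumented stepping trials with exact
ground truth: per-side step time, step length and swing-to-stance ratio
(defaults at the magnitudes measured for FNS-assisted walker stepping:
roughly 17 s step times, 0.54 m step lengths, ratios near 0.14), heel and
toe markers that dwell through stance and advance through swing, walker
handle load-cell forces with a programmed swing-phase resultant peak, and
per-step detection features (medial-lateral walker velocity, toe travel)
with optional injected outliers placed at the third quartile plus three
interquartile ranges. Noise is additive Gaussian on marker positions
(default off; 2 mm typical) and handle forces (2 N typical) — magnitudes
of ordinary optical capture and load cells. All randomness flows from the
spec's single seed and global RNG state is restored afterwards.

What the generators do not emulate: soft-tissue artifact, marker
occlusion and relabeling, spasm-interrupted steps (represented only as a
manual exclusion list in the analysis), three-dimensional kinematics, and
the correlation structure of real walker loading. Passing recovery tests
on these data therefore demonstrate the correctness of the analysis
arithmetic, not robustness to every artifact of real recordings.

## Gait-trial analysis

The analysis pipeline mirrors the experimental post-processing: zero-lag
second-order Butterworth lowpass filtering at 6 Hz (forward-backward
passes with odd-reflection padding; squared magnitude response, so the
amplitude ratio at the cutoff is one half); step metrics from events
(step time footstrike-to-footstrike per side, swing toe-off-to-
footstrike, step length between the landing heel and the contralateral
heel at its latest footstrike — whether heel or toe markers define step
length is unstated in the source methods, and heel is chosen here);
Tukey-fence outlier rejection on medial-lateral walker velocity and
anterior toe travel with the conventional k = 1.5 (the basis is stated,
the multiplier is not), fences computed once so removal is
order-independent; stride normalization to a percent-cycle grid with
pointwise ensemble mean and sample standard deviation; upper-extremity
effort as the Euclidean norm of the summed left-plus-right handle force
vectors (the alternative norm-then-sum convention is a flag), peak and
time-average per gait cycle and per swing; gait speed estimated as
side-averaged mean step length over side-averaged mean step time; Welch's
unequal-variance t-test with Satterthwaite degrees of freedom and the
Wilcoxon rank-sum test for Likert-scale usability responses (median and
interquartile range per question). Normality checking is a report — the
supremum distance between the sample ECDF and a matched normal CDF — not
a gate, matching the visual confirmation used experimentally.

For synthetic trials the step events come from the generator; for marker
data an event rule based on foot-marker vertical minima would be needed
(the experimental pipeline used an accelerometer trigger and states no
kinematic rule), and events are accepted as input.

## Known limitations

The planar fixture cannot express hip hiking, circumduction, or
mediolateral walker loading; its muscle parameters are representative
rather than subject-derived. The purpose-built solver is robust on the
fixture's problem sizes but is not an interior-point method: very stiff
contact settings or poorly scaled custom models can slow it markedly, and
its feasibility reporting is on scaled residuals. Charge comparisons
depend on per-channel amplitudes that are calibration inputs. The
compliant-tendon mode is exercised by the unit tests but the shipped
cascade runs rigid tendons.
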