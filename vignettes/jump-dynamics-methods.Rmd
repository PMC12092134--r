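---
title: "Forward-dynamics simulation of bipedal vertical jumping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-dynamics simulation of bipedal vertical jumping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpsim)
```

# Scope and model class

`jumpsim` implements a desk-scale workflow for predictive simulation of
maximum-effort vertical jumping in bipeds: planar (sagittal-plane)
musculoskeletal models driven by Hill-type aggregated muscle actuators,
optimized by a genetic algorithm that searches activation patterns for
maximum centre-of-mass (CoM) height within a time limit, and analysed
with the standard force-plate jump performance metrics.  Two reference
taxa are shipped as fixtures -- an adult human (68.33 kg, 9 actuators)
and a helmeted guineafowl (1.38 kg, 11 actuators including a
tarsometatarsophalangeal, TMTP, joint) -- together with the three muscle
reconstruction schemes used to parameterize them and the sensitivity
variants of the avian model.

The planar restriction is a deliberate modelling decision, not a
shortcut: every joint in the models is a flexion-extension hinge, and
vertical jumping is well approximated as a sagittal-plane activity.
Bilateral symmetry is collapsed -- each left/right actuator pair becomes
one planar actuator with doubled PCSA, the paired long-bone sections are
pooled the same way (doubled area and second moment), and the foot
contacts of both feet are pooled.

# The musculoskeletal model

## Segments, joints, contacts

Segments are uniform solid primitives (cylinders and cuboids) with
density defaults of 1000 kg m^-3 for limb segments, 850 kg m^-3 for the
head/torso and 800 kg m^-3 for the neck (lowered for airways); mass,
centre of mass and the transverse moment of inertia follow from the
closed-form solid formulas.  Joints are hinges with *soft* limits: inside
the admissible range they are free, beyond it a spring-damper torque
pushes back, so the range can be marginally exceeded under load.

Ground contact points are unilateral spring-dampers
(`Fz = max(0, k * penetration - c * v_z)`), so the foot can be lifted
without resistance and the ground can never pull.  Horizontal ground
force is smoothed Coulomb friction, `-mu * Fz * tanh(v_x / 0.01 m/s)`.
Contact stiffness and damping are configuration values (defaults: human
60 kN/m and 2 kN s/m per pooled contact, guineafowl 4 kN/m and
80 N s/m); the originating studies do not publish their constants, so
ours are tuned only for quiet standing (a few millimetres of static
penetration) and stable integration.

## Muscle actuators

Limb musculature is aggregated into functional actuators ("hip
extensor", "knee flexor ankle extensor", ...).  An actuator is an ideal
cable routed through anchor points on the segments, optionally bending
around planar wrap circles centred at the joints.  A wrap engages only
when the straight segment between its neighbouring path points would
penetrate the circle and the wrap arc is shorter than a half turn;
tangent points, arc length and the resultant force on the wrapped
segment follow the frictionless-pulley solution, so a wrap circle of
radius `r` centred on a hinge produces a constant moment arm `r` while
engaged.  Muscle forces enter the dynamics as point forces at the path
points (exactly equivalent, by virtual work, to the moment-arm
formulation).

The contractile machinery is a Hill-type model with linear series (SE)
and parallel (PE) elastic elements:

* active fibre force `a * F_max * f_L(l) * f_V(v)` with
  `F_max = sigma_max * PCSA`;
* `f_L` a symmetric quadratic about the optimal fibre length, reaching
  zero at `(1 +/- fl_width) * L_opt` (default width 0.5);
* `f_V` the Hill hyperbola `(1 - v/vmax) * a_h / (a_h + v/vmax)` for
  shortening, with shape `a_h = a/F0 = 0.25` by default, clamped to zero
  at `vmax` and capped at 1 for lengthening (no eccentric force
  enhancement);
* SE: linear spring engaging beyond the tendon slack length, reaching
  `F_max` at 4% strain by default;
* PE: soft linear spring engaging past `L_opt` (default stiffness
  0.1 F_max per unit strain), small enough that a passive model can
  crouch under gravity.

`sigma_max` defaults to 0.3 N mm^-2, the conventional vertebrate maximum
isometric stress.  Activation is instantaneous (no excitation-activation
dynamics), deliberately reproducing the simplification of the modelling
tradition this package follows; the consequences (unrealistically fast
force onset) are discussed below.  With a compliant tendon the CE length
is a state variable: at each step the SE force is computed from
`l_SE = l_MTU - l_CE`, the required CE force from the series balance
`F_CE = F_SE - F_PE`, and the CE velocity from the inverted
force-velocity relation (with a shallow regularizing slope on the
eccentric side so the inversion is defined above the plateau).  Where
the slack length is zero the tendon is rigid and the fibre follows the
path directly.

## Fibre lengths, tendons, PCSA

Fibre (fascicle) length is estimated by the *range-of-motion* (RoM)
method: the excursion of the actuator's path length over the full
admissible range of every joint it crosses, found by grid search
(1 degree per joint by default).  PCSA is muscle volume divided by fibre
length, with muscle density 1056 kg m^-3.  Tendon slack length is the
path length at a *tendon reference posture* minus the fibre length,
floored at zero.

The tendon reference posture is fixed per model (human: the shallow
crouch; guineafowl: a mid-range crouch) rather than per starting
posture.  This keeps the muscle parameters identical across starting
postures -- the same animal tested in three positions -- and places each
fibre mid-way on its force-length curve in the middle of its working
range.  Resolving tendons at each starting posture instead would make
extensors strongest exactly where a jump starts and weakest where it
pushes, which is both anatomically wrong and lethal to countermovement
jumping.

## The three reconstruction schemes

* **Measured** (`model1`): per-actuator PCSAs from the shipped
  single-limb parameter tables (subject-specific MRI data for the human,
  literature dissection data scaled isometrically for the guineafowl).
* **Schematic** (`model2`): total limb muscle mass is 35% of body mass
  (both limbs), partitioned 40/30/20/10% across hip/knee/ankle/TMTP and
  65:35 between extension and flexion at each joint, each pool divided
  equally among the actuators acting there.  Under the default
  *sum-of-joint-shares* policy a biarticular actuator accumulates its
  share from every pool it belongs to, which conserves the per-limb pool
  exactly.  The human model has no TMTP joint; by default its 10% share
  is dropped (`missing_joint_policy = "renormalize"` is available).
  The published per-actuator values of this scheme are not exactly
  recoverable from the stated rules (independent recomputation under
  both plausible readings deviates by a few percent), so the policy here
  is explicit and configurable rather than tuned to reproduce a table;
  the shipped tables carry the published values verbatim.
* **Regression** (`model3`): PCSAs predicted from bone/attachment areas
  through user-supplied log-log regression coefficients
  (`predict_regression()`); the published hominoid/archosaur
  coefficients are external data, so the shipped tables again carry the
  published predicted values rather than re-deriving them.

Sensitivity variants of the guineafowl model: `fl_x2` doubles every
fibre length and halves every PCSA (volume conserved) and recomputes
tendons; `fl_half` tunes only the distal muscles by 0.5;
`optimized_tendons` frees the tendon slack lengths of the uniarticular
extensors within +/-10% as optimization genes; `deeper_crouch` starts
from a more flexed posture.

## Bone-stress constraint

Each long bone carries a midshaft section (area `A`, second moment `I`,
outer-fibre distance `c`).  During simulation the internal force and
moment at the section are evaluated by a force balance on everything
distal to the cut (descendant segments in full, the distal half of the
sectioned segment under a uniform split, external contact and muscle
point forces on that side), and peak compressive stress is the beam
formula `|F_axial|/A + |M| c / I`.  When any section exceeds its failure
stress (300 MPa by default) the simulation terminates with a flag.

During optimization a failure at or before the CoM apex discards the
solution (sentinel fitness below every attainable value): no jump may
achieve its height through skeletal failure.  A failure during the
subsequent fall terminates the simulation but keeps the fitness, because
landing is explicitly outside the objective -- maximum-height jumping is
optimized and analysed up to the apex only.  A blanket discard would
reject essentially every successful jump, since nothing rewards a
controlled landing.

# Geometry conventions and starting postures

World frame: x forward, z up, angles counter-clockwise.  Joint angles
are zero at the anatomical neutral; hip flexion is positive, knee
flexion negative (full extension 0), ankle dorsiflexion positive --
matching the printed experimental posture conventions.  The shipped
human starting postures are the measured ones: full extension (hip 10,
knee 0, ankle -5 degrees), shallow crouch (67, -58, 6) and deep crouch
(114, -95, 11).  The guineafowl's exact experimental angles are not
published; the shipped crouched posture (hip 150, knee -105, ankle 45,
TMTP -20) is a documented estimate built on the published convention
that the femur starts horizontal, and the deeper crouch variant (160,
-120, 60, -25) approximates the deepest countermovement depth.  Both are
plain configuration values.

The initial configuration places the contact-bearing segment level with
the ground and pre-compresses the contact springs by the static
penetration `m g / sum(k)`.  The starting posture fixes the whole-body
geometry, so the horizontal CoM offset relative to the feet is whatever
the printed angles imply; segment proportions were chosen so that all
shipped postures start statically balanced within the foot support
polygon.  No balance controller exists -- staying upright during the
push-off is part of what the optimizer must solve.

Muscle action signs are validated when the fixtures are built: every
extensor's path must lengthen with joint flexion at every tested working
posture.  Flexor moment arms are allowed to cross zero at the extreme
crouch poses (real flexor arms do collapse near full flexion); they are
sign-checked at mid-range and extended postures.

# Numerical methods

The equations of motion of the floating-base planar tree are assembled
by a recursive Newton-Euler pass (bias forces) plus unit-acceleration
columns (joint-space inertia matrix) and solved by dense Cholesky
factorization each step.  The default integrator is fixed-step
semi-implicit (symplectic) Euler -- stiff spring contacts want small
fixed steps, and the symplectic update keeps the conservative submodel's
energy error bounded (< 0.1% over 1 s at the default step).  A classical
RK4 integrator is available for validation runs.  Default steps: 0.1 ms
for the reference models, 1 ms for the toy optimization model (its
contacts and tendons are softened accordingly).

Two discretization facts matter when checking conservation laws.  The
velocity state of the symplectic update is staggered by half a step, so
take-off velocities should be read with a central difference (the
package's metric code does); and the CoM momentum of an *articulated*
discrete body drifts at first order in the step while the limbs swing,
so the impulse-momentum identity and the ballistic-apex identity are
verified at refined steps (2e-5 s and 1e-5 s), where they hold to
1 mm/s and 1e-6 m respectively.

Degenerate muscle states are handled explicitly: a slack series element
transmits no force; an inactive overloaded fibre lengthens at `vmax`; a
fibre whose required force exceeds the eccentric plateau lengthens along
a shallow regularizing slope; CE lengths are floored at 5% of optimum.

# The optimizer

The controller genome is invented plumbing (the underlying simulation
tradition does not publish its encoding): per actuator,
`n_phases` piecewise-constant phases (duration and level genes), left
and right sides implicitly symmetrized and in phase; optionally one
tendon-scale gene in [0.9, 1.1] per uniarticular extensor.  The GA uses
tournament selection (size 2), uniform crossover (rate 0.9), Gaussian
mutation clipped to the gene bounds with a geometrically annealed scale
(0.25 of the range decaying tenfold across the run), and elitism
(>= 1 elite, making best-of-generation fitness monotone).  Tendon genes
are initialized at 1.0 -- the anatomical estimate -- so the search space
with tendon genes is a strict superset of the fixed-tendon problem and
deviations must earn their keep; activation genes are initialized
uniformly at random.  Runs are fully seeded and reproducible, and
replicate seeds follow a documented arithmetic scheme
(`base + 7919*(limit-1) + 101*(replicate-1)`).

Fitness is the maximum CoM height reached within the time limit.  The
time limit matters: too short truncates flight, too long invites the
optimizer to "fill the time" with junk movement, so `time_limit_sweep()`
runs replicate optimizations over a grid of limits and flags the first
limit whose best height reaches the overall plateau.  The package's own
experiments use plateau-selected limits of 0.7 s from the deep crouch
and 1.1 s from full extension for the toy model.

# The toy optimization model

GA experiments need thousands of fitness evaluations, so they run on a
deliberately small 4-segment biped (trunk, fused thighs, shanks, feet;
six uniarticular actuators) built *by the package's own reconstruction
pipeline*: schematic mass partitioning for the muscle masses, RoM fibre
lengths from its own geometry, PCSA by the volume/length quotient, and
tendons from the shallow-crouch reference posture.  It is a first-class
tested model, not a mock: the physics invariants, the stress-discard
path and the optimization experiments all run on it.  Problem sizes for
the shipped experiments -- population 50, 200 generations, 10 seeds per
condition in the test suite (5 in the acceptance script), 4 activation
phases per actuator, 1 ms steps -- were chosen so a complete experiment
runs in minutes on one core.

Two robust qualitative results mirror the experimental phenomenology:
optimized from the deep crouch the model squat-jumps (monotonic
extension), while from full extension it discovers a countermovement --
it must, since a fully extended limb has no concentric distance left;
and freeing the uniarticular extensor tendons within +/-10% never
reduces the attainable height in the median.

# The synthetic trace generator

`synth_trace()` emulates force-plate recordings with known ground truth.
It builds a piecewise-smooth vertical ground-reaction-force profile --
quiet standing, optional unweighting dip (countermovement), a
raised-cosine push whose amplitude is solved in closed form to hit the
requested take-off velocity, a decline to zero at take-off, then
ballistic flight -- and integrates it into the CoM trace.  The returned
ground-truth metrics are computed directly from the constructed profile,
so the construction is the oracle against which `detect_phases()` and
`compute_metrics()` are tested.  Gaussian force noise is optional and
seeded.

What the generator does *not* emulate: marker kinematics, force-plate
drift and filtering artefacts, asymmetric left/right loading, and
landing. Passing recovery tests on these traces therefore demonstrates
the correctness of the phase/metric definitions and their noise
robustness at the 1%-of-body-weight level, not performance on raw
laboratory files.

# Metric definitions and conventions

Take-off is the first instant the vertical force stays below 0.5 N
(three consecutive samples; the hold debounces sensor noise and is
transparent on clean traces).  The jump start is the first sustained
+/-5% body-weight departure, whose sign also gives the provisional
strategy label.  The relative net vertical impulse (RNVI) is the
concentric-phase vertical GRF impulse net of body weight divided by body
mass, so by impulse-momentum it equals the CoM velocity change and
matches the take-off velocity -- a consistency the tests assert on every
simulated jump.  Countermovement classification uses a 5 mm descent
threshold below the starting CoM height (at-threshold classifies as
countermovement), separating genuine unweighting from numerical jitter.

# Known limitations

* Planar dynamics: no mediolateral balance, no arm swing, no trunk
  torsion.
* Instantaneous activation overestimates the achievable rate of force
  development, particularly for small, fast animals.
* Aggregated actuators with single wrap circles reproduce moment arms
  only to first order; the published elastic-work decompositions are
  therefore reproducible qualitatively, not quantitatively (the source
  engine's elastic-element constants are unpublished).
* Segment geometry is primitive-based; the shipped proportions are
  standard published values scaled to the reference body masses, not
  subject meshes.
* The printed reference parameter tables contain a handful of internal
  inconsistencies at the 0.01-1 mm^2 level (their totals do not always
  equal their column sums); the shipped fixtures carry the printed
  values verbatim and the tests document per-cell tolerances where the
  print disagrees with itself.

# Reproducing the analyses

```{r, eval = FALSE}
# a reference model and a simulated squat jump
toy <- make_toy_biped("deep_crouch")
ctl <- constant_controller(toy, c(`hip ext` = 1, `knee ext` = 1,
                                  `ankle ext` = 1))
tr <- simulate_jump(toy, ctl, duration = 0.8)
trajectory_metrics(tr)

# a small optimization
cfg <- ga_config(population = 50, generations = 200, seed = 1,
                 time_limit = 0.7, n_phases = 4, dt = 1e-3)
run <- run_ga(toy, cfg)
classify_strategy(genome_trajectory(toy, run$best_genome, run$spec))
```

The repository-level script `scripts/acceptance.R` recomputes every
headline quantity (worked examples, invariant measurements, recovery
errors, optimization outcomes) from scratch and writes them as JSON.
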