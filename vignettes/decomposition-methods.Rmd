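---
title: "Decomposing tibiofemoral contact loads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing tibiofemoral contact loads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeload)
```

## The question the package answers

The compressive load carried by the knee's medial and lateral condyles
during walking is not produced by body weight alone: muscles and ligaments
that cross the joint pull the femur and tibia together and can shift load
between the two compartments. `kneeload` attributes the axial
(longitudinal-tibia) contact load of the total, medial, and lateral
tibiofemoral compartments to three force categories — external
(intersegmental ground-reaction plus gravity resultant), muscle, and
ligament — frame by frame through the stance phase of gait, and compares
the resulting percent contributions between a healthy-like cohort and a
medial knee-osteoarthritis (KOA)-like cohort.

## Frames, signs, and the free body

All joint-level mechanics live in a right-knee tibial frame: x anterior,
y proximal (the tibial longitudinal axis), z medial, origin at the knee
joint centre. Left-limb recordings are mirrored into this convention at
ingestion so "medial" and "varus-positive" mean the same thing for every
trial. The frontal-plane moment axis is the anterior axis and is
adduction-positive: a positive moment loads the medial compartment.

Every force source handed to the decomposition is expressed as the load
delivered to the joint from the femoral side (a femur free body). The
external source is the net intersegmental knee load `-(GRF + segment
weights)` with its transported couple; a tensioned muscle or ligament
appears as the pull it exerts on the femoral side, directed along its
straight-line path toward its tibial attachment. This single convention
makes compression positive for every category: soft-tissue tension loads
the joint, and the external knee adduction moment (EKAM) appears directly
as the frontal component of the external couple. The user-facing primitive
`bundle_line_of_action()` reports the equal-and-opposite pull on the tibia
(the conventional way ligament lines are tabulated); `ligament_sources()`
flips it onto the femur free body when it builds decomposition sources.

## The two-point moment balance

The joint is a medial/lateral two-point contact: all axial load passes
through two contact points separated by the intercondylar width `w`
(defaulting to 0.029 x height, fixed per subject, as contact points are
identified once from standing radiography in the emulated protocol). For
each source `s` with axial component `A_s` (compressive-positive
projection on the tibial long axis) and frontal-plane moment `M_s` about
the **lateral** contact point,

* `C_med,s = M_s / w`
* `C_tot,s = A_s`
* `C_lat,s = A_s - M_s / w`

which is the unique additive split consistent with quasi-static force and
moment equilibrium of the two unknown compartment loads. Negative values
are meaningful: a source whose moment-balance share is below zero unloads
that compartment (the external category typically unloads the lateral
compartment under a positive EKAM). The test suite checks this per-source
formula against an independent monolithic solve of the two-equation
equilibrium system on a thousand random frames, and checks exact
superposition.

Only the load along the tibial longitudinal axis is decomposed; shear
contact components and contact-point migration are out of scope.

## The ligament model

Ten ligaments are modelled as 22 straight-line elastic bundles: ACL and
PCL (2 bundles each), MCL (5), LCL (3), MPFL and LPFL (3 each), and the
anterolateral, posteromedial, posterior oblique and popliteofibular
ligaments (1 each). Bundle force is the standard piecewise
nonlinear-elastic law with a quadratic toe region,

```
F(eps) = 0                        eps < 0
       = k * eps^2 / (4*eps_lim)  0 <= eps <= 2*eps_lim
       = k * (eps - eps_lim)      eps > 2*eps_lim
```

with the linear strain limit `eps_lim = 0.03`. The toe-region coefficient
`k/(4*eps_lim)` is the only choice that makes the two loaded branches meet
with continuous value and slope at `eps = 2*eps_lim`; the tests pin both
continuities to 1e-12 relative to `k`.

Slack lengths are calibrated from the full-extension reference pose: if a
bundle spans length `L_ref` there and its reference strain is `eps_r`,
then `L_0 = L_ref / (1 + eps_r)`, so the strain at full extension is
exactly `eps_r`. The shipped `k`, `eps_r` and attachment coordinates are
literature-plausible placeholder values on an idealized condyle-scaled
geometry (cruciates a few thousand newtons per unit strain and taut or
slack in extension as appropriate; collaterals 1600-2500 N per bundle;
`eps_r` within about -0.02 to +0.05). They are deliberately user-replaceable
through a JSON parameter file, and every numerical acceptance property is
independent of them. What the defaults are built to get right is the
frontal-plane structure: varus rotation monotonically loads the lateral
structures (LCL, popliteofibular, anterolateral) and slackens the MCL
group, which is what drives the healthy-versus-KOA contrast below.

The MPFL/LPFL route to the patella; the reduced model treats the patella
as co-moving with the tibial extensor path, so their tibiofemoral moments
are computed like any other bundle. Ligament wrapping, bone contact and
viscoelasticity are not modelled, and KOA knees share the healthy ligament
parameters (a stated limitation of the emulated protocol).

## Reduced quasi-static lower limb

The pipeline needs only knee-level quantities, so the full-body
musculoskeletal machinery is reduced to a foot + shank free body under
quasi-static (inertia-free) balance. Net knee force is `-(GRF + segment
weights)`; the net couple collects the GRF moment about the knee centre,
segment-weight moments and the force-plate free moment. EKAM is the
adduction-positive frontal component of that couple. Segment masses and
lengths come from standard proportional anthropometry (shank 4.65% and
foot 1.45% of body mass; shank length 24.6% of height), configurable per
subject. Because nothing is differentiated, no filtering is needed; the
1000 Hz GRF is aligned to the 100 Hz kinematic clock by averaging the
surrounding 10 ms window.

Muscle forces come from static optimization over a reduced seven-element
set (vasti, rectus femoris, medial/lateral hamstrings, medial/lateral
gastrocnemius, TFL/iliotibial band): minimize the cubic activation
criterion `sum((F_i/F_max,i)^3)` subject to the sagittal knee-moment
balance and force bounds. The cubic exponent is the ecosystem default for
recruitment criteria and is configurable. The problem is solved through
its dual: per-muscle forces follow in closed form from the KKT
stationarity conditions, with a monotone one-dimensional root search for
the single-constraint case (exact to machine precision; validated against
the two-muscle closed form `F1/F2 = (M1/M2)^(3/2)`) and a BFGS ascent of
the concave dual when a frontal constraint is added. Unreachable demands
are assigned to a residual actuator and reported, never silently absorbed.

Three design choices deserve explanation, because the design was genuinely
open:

* **Ligaments first.** Ligament forces are pose-determined passives; they
  are evaluated before recruitment and their sagittal moments are
  subtracted from the muscle demand. This keeps the recruitment problem
  convex and mirrors passive-element + optimization pipelines.
* **Two-joint gastrocnemius baseline.** In a knee-only model the
  gastrocnemius would be recruited only by the (small) late-stance knee
  moment, grossly underestimating its force: in reality it is sized by the
  ankle plantarflexion demand. The engine therefore gives the
  gastrocnemius pair a baseline force equal to a configurable share
  (default 35%) of the ankle plantarflexion moment over a 5 cm Achilles
  arm, entering recruitment as a lower bound. The quadriceps then
  co-contract to restore the sagittal balance, which is where the
  late-stance muscle loading of the joint comes from.
* **Unilateral contact.** Condyles push; they cannot pull. Under a strong
  adduction moment with little lateral soft-tissue force, the two-point
  algebra can drive the lateral "compressive" load negative — a liftoff
  state the algebra cannot represent. When the passive plus sagittally
  recruited solution would put a compartment in tension, recruitment is
  repeated with a second equality constraint holding that compartment at a
  marginal compressive load of 1% body weight. This plays the role of the
  non-pulling contact elements of full musculoskeletal pipelines, and it
  also keeps phase-integral percent denominators strictly positive.

The frontal moment is otherwise carried by the bicondylar contact itself —
that is precisely the premise of the two-point decomposition — so plain
frames recruit against the sagittal demand only.

## Synthetic cohorts: what they emulate and what they do not

No motion-capture data accompany the emulated protocol, so a seeded
generator stands in for the cohort. Its defaults are the study conditions:
20 subjects per group, both limbs, 10 stance trials per limb; kinematics
at 100 Hz, GRF at 1000 Hz; gait events at 16%/84% of stance (typical adult
double-support boundaries, configurable; event-based sub-phases are the
default whenever events exist). Anthropometry follows the emulated
demographic table (healthy 65.7 ± 4.6 kg, 1.58 ± 0.05 m; KOA 66.8 ± 8.7 kg,
1.56 ± 0.06 m). Self-selected speeds are not published for the cohorts, so
the presets use typical older-adult values chosen once: healthy
1.20 ± 0.10 m/s, KOA 0.90 ± 0.12 m/s.

Waveforms are standard adult stance templates. The vertical GRF is the
smooth two-peak curve `BW * (0.75/0.65) * (sin(pi*t) + 0.35*sin(3*pi*t))`
(peaks about 1.1 body weight, mid-stance valley exactly 0.75 BW before
noise, zero at both stance endpoints); Gaussian-bell templates were
rejected because they cannot vanish at the endpoints. The
anterior-posterior force is derived by prescribing the sagittal offset of
the GRF line of action from the knee — posterior in early stance
(quadriceps demand), anterior in late stance (gastrocnemius demand), with
amplitude scaling as the square root of walking speed — because a
quasi-static generator cannot simultaneously match measured AP-force
envelopes and measured knee moments; the knee moments are what the
decomposition consumes. The centre of pressure progresses heel to toe with
a medial offset (default 35 mm lever) that creates the EKAM; knee flexion
follows the usual early-stance bump plus pre-swing rise; the varus angle
is the subject baseline minus a small mid-stance dip. All noise is
low-pass-filtered Gaussian perturbation so the quasi-static assumption
stays valid.

The two groups differ **only** through interpretable parameters: the KOA
preset has a 1.4x EKAM lever multiplier, a +5 degree varus offset, 0.7x
quadriceps and gastrocnemius strength, and slower speed. No waveform or
parameter was tuned toward any published contribution percentage — the
group contrast in the outputs must emerge from these four mechanisms or
not at all. Mechanistically it does: varus loads the posterolateral
structures, which flips the ligament category's medial-compartment share
from positive (healthy) to negative (KOA) and makes ligaments the dominant
lateral-compartment contributor in KOA, while the larger EKAM deepens the
external category's negative lateral share.

What the generator does **not** emulate: marker-level kinematics and
soft-tissue artifact, true inter-trial correlation structure, asymmetry
between limbs, KOA-specific ligament degradation, EMG-consistent muscle
timing, and inertial (non-quasi-static) dynamics. Passing tests therefore
demonstrate correctness of the mechanics and statistics on data with the
assumed structure, not validity of any clinical magnitude: the percent
contributions this package prints for synthetic cohorts are
model-consistent illustrations, and only their qualitative sign structure
is asserted anywhere.

## Phase summaries and statistics

Per-frame category contributions are integrated over the whole stance and
the three sub-phases (first double support, single support, second double
support). The percent contribution of category `c` to compartment `X` over
phase `P` is the integral ratio `100 * int_P(C_X,c) / int_P(F_X)`, which
conserves a 100% three-category sum at every aggregation level and is
stable where per-frame ratios are not (the mean-of-ratios definition is
available as a config switch for comparison). Phase boundaries are
interpolated into the trapezoidal integrals so sub-phase integrals add
exactly to the whole-stance integral.

Subjects are the experimental unit: each subject's trials and limbs are
averaged before any group statistic (avoiding pseudo-replication; the SD
reported in tables is across subjects). Between-group contrasts use the
independent t-test when both groups pass Shapiro-Wilk normality at
alpha = 0.05 and the rank-sum (Mann-Whitney) test otherwise; the
signed-rank form is reserved for the paired within-group category
contrasts, which is the design it actually fits. p values are
Benjamini-Hochberg adjusted, one family per output table (per
compartment), and the suite checks the adjustment against a brute-force
step-up reference.

## Numerical choices and degenerate inputs

* Coincident attachments (< 1e-9 m) and frontal contact-point separations
  below 1e-6 m are hard errors, as are non-monotone time vectors,
  mis-ordered gait events, and constant samples handed to the normality
  test.
* A phase whose compartment load-time integral is below 1e-9 x peak x
  duration raises a degenerate-phase error rather than returning an
  unstable percent.
* The recruitment root search brackets the monotone dual and polishes with
  a safeguarded Illinois iteration to ~1e-11 relative; the two-constraint
  dual ascent reports its residual moments.
* Trial CSVs are written at full double precision (`%.17g`), making every
  writer/reader pair bit-exact on round trip; run outputs are
  deterministic functions of the configuration (including seeds), and the
  manifest records the configuration digest.
* Problem sizes used in the checks: 1000 random frames for the
  decomposition oracle, 300 parameter draws for the recruitment closed
  form, 1000 random p-vectors for the FDR reference, and the full
  20 + 20 x 2 x 10 cohort for the end-to-end run (about one minute of
  compute on one core).

## Known limitations

The reduced model omits patellofemoral mechanics, co-contraction beyond
the gastrocnemius-quadriceps coupling described above, EMG-driven
recruitment, shear contact loads, and contact-point migration. Ligament
and muscle attachment geometry is idealized rather than subject-specific.
The synthetic cohorts cannot validate clinical magnitudes; they exist so
that the pipeline's mechanics, bookkeeping and statistics are fully
testable in the absence of the original recordings.
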