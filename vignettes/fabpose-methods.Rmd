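---
title: "Methods: inverse posture estimation from cancellous bone fabric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse posture estimation from cancellous bone fabric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`fabpose` treats a standing-phase hindlimb as a quasi-static system: the
only acceleration is gravity, the ground reaction force (GRF) is vertical
and of magnitude one body weight (1 BW), and all internal forces are
resolved instant-by-instant with no inertial terms. These assumptions
restrict the method to mid-stance-like loading, which is also the loading
regime expected to dominate the remodelling stimulus of cancellous bone:
GRF magnitudes and joint reactions peak around mid-stance in striding
bipeds.

The central object is the *characteristic posture*: the single limb
configuration whose continuum-level principal stress trajectories best
align with the observed trabecular fabric. It is a time- and load-averaged
abstraction, not necessarily any instantaneous pose, but in validation it
should resemble the mid-stance posture.

The global frame is +x anterior, +y medial, +z dorsal, right limb, SI
units throughout. Six generalized coordinates are free: hip
flexion–extension (reported as elevation relative to the horizontal,
negative below), hip abduction–adduction and long-axis rotation (positive
= abduction / external rotation), and hinge flexion at the knee, ankle and
metatarsophalangeal (MTP) joints. Hip rotation composes FE, then AB-AD,
then LAR. The pelvis is fixed; the pes is a rectangular prism whose length
stands in for digit III.

### External loads

With the GRF vertical and 1 BW at the pes centroid (taken as the centre of
pressure, COP), static equilibrium requires a couple on the pes. Its
mediolateral component has magnitude `m·g·|COP_y − COM_y|` — the price of
allowing a non-zero step width while keeping the COP at the foot centre —
and its anteroposterior component `M_y` absorbs the millimetre-scale
residual between COP and COM in x. `build_external_loads()` constructs the
couple directly from the global-equilibrium condition; with the default
1 mm COP tolerance the `M_y` term stays small relative to BW times COM
height.

### Static optimization

Muscle redundancy is resolved by minimizing the sum of squared activations
subject to moment balance at each free degree of freedom, the classical
static-optimization polynomial criterion. An actuator's moment about a DOF
is `a · F_max · r`, with the tendon-excursion moment arm `r = −dL/dθ`
evaluated by central finite difference (half-width 0.25°) of the posed
polyline length; for a straight path this reduces to the geometric lever
arm, and it generalizes consistently to via-point paths. All 38 actuators
(34 muscles, 4 collateral ligaments modelled as linear reserve elements
without slack length or elasticity) share a default maximum force of 2 BW;
a sensitivity mode substitutes per-muscle maxima derived from muscle
architecture at a constant isometric stress of 3×10⁵ N/m², leaving every
other part of the solver untouched. Force–length–velocity properties are
deliberately ignored; forces act purely along the posed geometry.

The MTP joint, whose crossing musculature is heavily simplified, carries
an additional reserve actuator bounded at ±1000 Nm; it enters only the MTP
moment-balance row and carries a small objective weight (default 1e-6) so
it is recruited only where the modelled muscles cannot balance the joint.

The QP itself — minimize a positive diagonal quadratic subject to equality
constraints and box bounds — is solved by a primal active-set method
written for this package (`solve_box_eq_qp()`): a clamping phase finds a
bound-feasible point, then ratio-test steps and single-variable multiplier
releases converge to the unique optimum of the strictly convex program.
`pracma::quadprog` is used in the test suite as an independent oracle,
never as the solver. KKT residual tolerances are 1e-10; moment-balance
residuals above 1e-6 Nm raise an infeasibility error naming the violated
DOFs.

Joint reactions follow by distal-to-proximal Newton–Euler recursion over
the solved actuator tensions, gravity, and the pes loads, expressed in the
global frame. Two built-in consistency checks: the ball-and-socket hip
must carry no reaction moment, and the axial hinge moment at the MTP must
equal minus the reserve moment.

## Finite-element stage

Each posture feeds two linear-elastic solves: the femur, bookended by an
acetabular structure (restrained) and a proximal-crus structure (through
which the knee force enters), and the tibiotarsus + fibula, bookended by a
distal-femur structure (knee force) and a proximal-tarsometatarsus
structure (restrained). Intervening joint soft tissues are single
homogeneous volumes; materials are isotropic linear elastic (bone
17,000 MPa, ν 0.3, 2,060 kg/m³; cartilage 50 MPa, ν 0.45; knee composite
100 MPa, ν 0.3), config-overridable. Elements are 4-node
(constant-strain) tetrahedra; nodal stress is recovered by volume-weighted
averaging of adjacent element stresses, which the patch test verifies to
be exact for affine displacement fields.

Three implementation choices deserve emphasis:

* **Bonded contact by node sharing.** All entities of one simulation are
  meshed on a single cubic lattice (each cube split into six Kuhn
  tetrahedra, which conform across cell faces), so interfaces between
  bone, soft tissue and bookends share nodes exactly. Load transfer is
  seamless with no constraint machinery, and the bond is directly
  auditable (`mesh_audit()`). A lattice of spacing *h* automatically
  respects the isoparametric edge-length cap: the boundary surface is made
  of right triangles with legs *h*, whose mean edge length
  `L = sqrt(4A/(√3 n))` gives a cap `2L ≈ 2.15 h`, above the largest tet
  edge `√3 h`.
* **Bone-local solving.** Each assembly is meshed once in its bone's local
  frame with idealized, axis-aligned articular caps and slabs; posture
  enters through the load vectors, rotated into the bone frame. This is
  what lets one stiffness factorization (cached per session) serve the
  entire posture search, and it is also the natural frame for fabric
  comparison, since fabric is bone-bound. Stress tensors can be rotated to
  the global frame for export.
* **Remote attachments as statically equivalent loads.** The remote knee
  force and the segment-weight attachment are realized as the
  minimum-norm nodal load set whose resultant equals the applied force
  and whose moment about the remote point vanishes, rather than as
  multipoint kinematic constraint equations. The stated mechanical
  contract — the net force vector passes through the remote point — is
  preserved exactly; the local stiffening that constraint equations
  introduce is not reproduced, which matters only within the bookend
  buffer (Saint-Venant).

The ankle joint moment is *not* applied in the tibiotarsus simulation by
default: the restraint sits close to the distal tibiotarsus and would
distort the transmission of an applied moment, so that moment is carried
by the restraint instead. A flag (`apply_ankle_moment`) enables it for
exploration. Distal-tibiotarsus stresses should therefore be read with
caution.

With the bookend restrained, a consistent linear solve is exactly
balanced, so the pipeline solves with restraints and without body-load
correction; the inertia-relief operator (`inertia_relief()`) is provided
— and verified to cancel net force and moment to below 1e-9 relative —
for unbalanced or free-floating load cases.

## Trajectories and the alignment score

Principal stresses are the eigenvalues of the nodal (or element) stress
tensor, sorted σ₁ ≥ σ₂ ≥ σ₃, with axial eigenvectors under a
deterministic sign convention. Directions are *axial* data (v ≡ −v), so
regional means use the orientation tensor (1/N)Σ v vᵀ — its dominant
eigenvector is the proper sign-free mean; this is the package's
interpretation of a "mean direction of vectors" for principal-stress and
fabric data alike. Samples whose eigenvalues are nearly repeated
(|σᵢ−σⱼ| < 1e-6‖T‖) have no meaningful direction and are flagged and
excluded.

Two spherical regions are scored on the femur, following the standard
comparison: the femoral head (radius one-half of the sphere fitted to the
head, centred one region-radius beneath the contact centroid where the hip
force arrives — the "just under the surface" placement, with the offset
depth config-exposed) and the medial condyle (radius one-third of the
condyle sphere at the condyle centre). The angular deviation
`arccos|v_σ₃ · v_u₁|` is computed per region and combined as a weighted
mean with the head weighted twice the condyle, encoding the priority of
hip correspondence when ranking postures. Regional statistics are sampled
at element centroids (six per lattice cell), which keeps the small condyle
region populated well above the five-sample minimum at the default mesh
spacing.

`midshaft_loading_summary()` condenses diaphyseal loading into torsion
obliquity (angle of the most axis-parallel principal direction to the long
axis: 0° for axial load, 45° for pure torsion), torsion sense (helicity of
σ₁, sign-invariant under the axial ambiguity), and the neutral-surface
angle from the mediolateral axis (from a linear fit of axial stress over
the section).

## Synthetic data: what it emulates and what it does not

`generate_synthetic_limb()` builds an idealized bird-like right hindlimb
at chicken scale: body mass 1.56 kg, right-limb segment masses totalling
0.159 kg (thigh 0.080, shank 0.050, tarsometatarsus 0.020, pes 0.009 kg),
leaving 1.401 kg in the fixed pelvis segment, whose COM sits 0.068 m
anterior to and level with the hip. Bone lengths are femur 75 mm,
tibiotarsus 112 mm, tarsometatarsus 88 mm (275 mm total), pes prism 45 mm;
the femoral head is a 6 mm-radius sphere whose centre defines the hip
joint; condyles, cnemial crest, a slender distally-fused fibula and a
pelvis stub are simple implicit solids. Shape parameters (head offset,
condyle spacing, lengths, lattice spacing `mesh_h`, default 2 mm) are
config-exposed. The 38-actuator topology mirrors the standard avian
hindlimb set at reduced fidelity, with activity flags matching mid-stance
electromyography-based assignments; attachment end points are snapped to
bone surface nodes so the musculoskeletal and FE stages load the exact
same nodes. The default actuator geometry was tuned once so that the
mid-stance posture family is statically feasible with 2 BW actuators —
prominent patellar-trochlea and hypotarsus wraps give knee extensors and
ankle plantarflexors lever arms near 1 cm and 7 mm respectively, in the
physiological range for a chicken-sized limb.

What the synthetic layer does *not* emulate: species-accurate bone
geometry (so absolute stress magnitudes and the literature's printed
deviation angles are out of reach by design), trabecular microstructure,
anisotropic or poroelastic tissue behaviour, wrapping surfaces, patellar
and tarsal sesamoids, and any knee/ankle degrees of freedom beyond
flexion. Passing tests therefore demonstrate internal correctness and
recoverability of the inverse problem on an idealized limb — not
validation against real avian anatomy.

Fabric fields come from two generators. `fabric_from_posture()` runs the
forward pipeline at a known posture and samples σ₃ (σ₁ where tension
dominates, e.g. the anterior cnemial crest; within the scored compressive
regions always the region's own component, so the zero-noise field scores
exactly 0° at the generating posture — the pipeline's fixed point). Axial
noise rotates each axis about a random perpendicular by a folded-normal
angle, the natural noise model for axial data; a sd of 5° emulates
specimen-to-specimen fabric variation about an archetype.
`archetype_fabric()` instead blends prescribed per-region axes through the
orientation tensor with Gaussian distance weights, giving an analytic,
pipeline-independent target.

## The search

The published protocol was manual iteration under expert judgment;
`run_search()` formalizes it as deterministic coordinate descent over the
joint hierarchy — hip extension before knee — with a shrinking step
schedule (default 10°, 5°, 2.5°). The distal and frontal-plane angles are
not searched: at every proposal the MTP is reset to put the pes flat on
the ground, the ankle is solved (closed-form initialization on the
least-reclined branch, then secant refinement) so the COP lies under the
whole-body COM in x within 1 mm, and hip abduction is adjusted so the step
width reaches a target of 10 % of hip height, below the 15 % admissibility
limit. This mirrors how the three admissibility constraints partition the
joints in practice: the COP constraint governs knee/ankle/MTP, the
step-width constraint governs hip AB-AD and LAR. Only strict score
improvements of at least 0.5° are accepted ("similar" correspondence does
not count as progress), so the accepted-score sequence is monotone and
termination at the smallest step is well-defined; an evaluation cap
returns best-so-far with a warning. Every evaluated posture in the audit
trail is admissible; proposals whose repair stalls or whose statics are
infeasible are recorded and skipped — infeasibility at the extremes of the
posture domain (e.g. very extended postures that would need active ankle
dorsiflexors at mid-stance) is an honest model outcome, not an error.

`fit_posture()` wraps the search as a fitting function returning a classed
object with `print`, `summary`, `coef` and `plot` methods; the rest of the
package is deliberately a pipeline of plain functions, since the artifact
is a tool rather than a single estimator.

## Numerical choices and problem sizes

Default problem sizes were chosen to keep a full search interactive on one
CPU: the 2 mm lattice gives ≈11,000 tets (femur assembly) and ≈10,000
(tibiotarsus), one-time factorizations of a few seconds, and under a
second per posture evaluation thereafter; a three-seed recovery
experiment completes in about a minute. FE benchmarks in the tests use bars of 4–60 thousand
elements, where the constant-strain element reproduces the uniaxial
solution to well under 1 %, surface bending stress to ≈7 % (the
element's known stiffness in bending plus the half-element bias of nodal
averaging at surfaces), and torsion helices to within 2° of 45°.

Other defaults: QP reserve weight 1e-6; moment-arm finite-difference
half-width 0.25°; COP tolerance 1 mm; degenerate-eigenvalue threshold
1e-6 relative; muscle-force spread count 20 nodes. The degree-of-crouch
metric is pluggable; the default is `1 − hip_height / limb_length` with
limb length the fully extended hip-to-ground distance, which makes the
fully extended column score exactly 0. Known limitations are inherited
honestly from the modelling frame: no dynamic effects, a single load case,
linear isotropic tissues, and weak constraint of torsional loading in the
distal limb.
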