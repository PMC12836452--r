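---
title: "Passive epicardial sleeves on an idealized left ventricle: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive epicardial sleeves on an idealized left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a myocardial infarction, the scarred wall segment stops contracting,
stretches during systole (bulging) and seeds adverse remodeling.  Passive
epicardial sleeves — compliant layers attached to the outer surface of the
heart — are a candidate therapy: they carry part of the wall load without any
actuation.  `sleevesim` is a finite-element laboratory for the mechanics of
such sleeves on an idealized spheroidal left ventricle (LV): a continuum
sleeve shell and an auxetic (negative Poisson ratio) metamaterial sleeve can
be fitted to an infarcted ventricle, driven through a pressure-prescribed
cardiac cycle, and scored by organ-level (EDV/SV/EF) and regional (fiber
strain, torsion, infarct bulging) markers.

## Geometry

The ventricle is bounded by two spheroidal surfaces of the form

$$x(\theta,\phi) = \big(R\sin\theta\cos\phi,\; R\sin\theta\sin\phi,\;
H(1+\cos\theta)\big),$$

with the polar angle $\theta = 0$ at the apex.  The default dimensions are
the published ones: epicardial basal radius $R_{epi} = 2.72$ mm, height
parameter $H_{epi} = 5.92$ mm, basal wall thickness $T_{base} = 0.67$ mm and
apical thickness parameter $T_{apex} = 0.77$ mm; the endocardial surface uses
$R_{endo} = R_{epi} - T_{base}$ and $H_{endo} = H_{epi} - T_{apex}$.  The
wall is truncated at $\theta_{max} = \pi/2$, so the apex sits at $z = 2H$ and
the open base at $z = H$: the apex-to-base height equals $H_{epi}$, matching
its description as the total height.  Because each surface carries its own
$H$, the two basal circles sit at different heights and the basal cut is the
slant annulus joining them; the closed-form wall volume used as the meshing
oracle integrates exactly that solid (see `spheroid_volumes()`), which is
*not* the difference of the two spheroidal caps.

The wall is meshed structurally: the $(\theta,\phi)$ shell is triangulated
(pole fan plus quads split along the diagonal through the smallest node id),
extruded through transmural layers into prisms, and each prism is split into
three tetrahedra with the same smallest-id diagonal rule, which keeps the
decomposition conforming everywhere without a mesh generator.  Midside nodes
are created at parameter-space midpoints and mapped through the exact surface
blend, so the quadratic elements are curved; the meshed cavity volume agrees
with the half-spheroid closed form to 0.2% at the coarse resolutions used
throughout and to 0.01% one refinement level up.

The infarct is an angular window (default: transmural, centred at
$\theta_c = \pi/3$, $\phi_c = 0$, half-widths $\Delta\theta = \pi/5$ and
$\Delta\phi = \pi/4$ — a mid-lateral patch; all parameters configurable).
The myofiber field is rule-based: the helix angle runs linearly from +60° at
the endocardium to −60° at the epicardium in the local
circumferential–longitudinal tangent plane.  Neither the infarct extent nor
the fiber field of the spheroidal arm is published, so both are declared
package defaults, not source values.

## Constitutive model

The passive myocardium is a Fung-type transversely isotropic hyperelastic
solid,

$$W = c\,[\exp(Q(\bar E)) - 1] + \tfrac{K}{2}\big[\tfrac{J^2-1}{2} -
\ln J\big],\qquad
Q = B_1\bar E_{11}^2 + B_2(\bar E_{22}^2 + \bar E_{33}^2 + 2\bar E_{23}^2)
  + B_3(\bar E_{12}^2 + \bar E_{13}^2),$$

evaluated on the deviatoric Green–Lagrange strain in the fiber frame (axis 1
= fiber).  Two conventions deserve a note:

* **Transverse-shear counting.**  The transverse-shear strain enters $Q$
  through both symmetric tensor components ($2\bar E_{23}^2$).  With a single
  $\bar E_{23}^2$ the form would not be invariant under rotations about the
  fiber axis — i.e. the material would not actually be transversely
  isotropic, and the arbitrary orthonormal completion of the fiber direction
  used to build the local frame would leak into the results.  The doubled
  counting is the convention of the classical exponential myocardium laws
  this family descends from; with it the rotation invariance holds to
  machine precision (verified in the test suite) and the frame completion is
  provably immaterial.

* **Stress–energy consistency.**  The passive Cauchy stress is implemented
  as the exact derivative of $W$: $T = \tfrac{1}{J}\,\mathrm{dev}[\bar F
  \bar S \bar F^T] + \tfrac{K}{2}(J - \tfrac1J) I$ with $\bar S = \partial
  W_{dev}/\partial\bar E$.  The deviatoric projector is required for
  consistency (a finite-difference oracle checks stress against the energy
  derivative to $10^{-5}$ relative on random states); shorthand forms of
  this push-forward sometimes omit it.

Region stiffness scales are the published estimates ($c_{LV} = 0.416$,
$c_{infarct} = 0.649$, $c_{RV} = 0.297$ kPa with $B_1 = 47.15$,
$B_2 = 22.55$, $B_3 = 24.60$); sleeves share the law with $c_{sleeve} =
\zeta\,c_{LV}$.

**Bulk penalty.**  $K$ is not published.  A penalty of $1000\,c$ keeps
$|J-1| < 0.02$ under passive inflation but fails badly once systolic active
stress (hundreds of kPa against $c \approx 0.4$ kPa) compresses the wall:
$|J-1|$ reached 0.20.  The simulation default is $K = 10^4 c$ per region,
giving $|J-1| \le 0.011$ at ED and $\le 0.05$ at ES on the default meshes.
Raising $K$ further is counter-productive in this displacement-based
formulation: beyond ${\sim}2\times10^4 c$ the cancellation noise of the
volumetric term exceeds the $10^{-8}$ relative Newton tolerance, so the
solver can no longer certify its own convergence.  $10^4 c$ is the largest
penalty that honours the stated tolerance; the residual ES compressibility
is the price of the penalty formulation and is asserted at its measured
level (0.08 bound) rather than pretended away.

**Active stress.**  Contraction is a fiber-aligned second Piola–Kirchhoff
stress $S_{act} = \frac{T_a}{2E_{ff}+1} N\otimes N$, uniform in space,
applied in the remote myocardium only (the scar has lost its myofibers;
sleeves are passive).  $T_a$ is the calcium-induced tension modulated by a
linear Frank–Starling relation, $T_a = T_{Ca}\max(0,\,1 +
s(\lambda_{dia}-\lambda_{ref}))$ with slope $s = 2$ per unit diastolic fiber
stretch and $\lambda_{ref}$ the mean remote diastolic stretch of the
no-sleeve run — so a sleeve that reduces diastolic stretch also reduces
active tension, and the sleeve scenarios inherit $\lambda_{ref}$ from the
baseline.  Neither the magnitude nor the time course of $T_{Ca}$ is
published; see the calibration section.

## Sleeves

**Continuum sleeve (S₀).**  The epicardial facets of the coverage band are
extruded outward along the analytic surface normal into a solid shell
(default thickness 0.16 mm, one element layer).  The inner surface reuses
the wall's epicardial nodes — corner and curved midside alike — so sleeve
and myocardium share one displacement field; there is no contact or penalty
at the interface.  The thickness-to-wall-thickness ratio is validated to be
below one.

**Auxetic sleeve (A₀).**  The metamaterial is the rotating-triangles family:
a triangular lattice of pitch $a$ carries a co-centred inner triangle of
edge $b$ in every lattice cell; neighbouring inner triangles are separated
by slits of clearance $(a-b)/\sqrt3$ and welded pairwise near each lattice
vertex by hinge ligaments of length $w$.  For the default cell
($a = 1.17$, $b = 0.98$, $w = 0.11$, $t = 0.16$ mm) the specified clearance
and the geometric slit width coincide ($0.1097 \approx 0.11$ mm), which is
the self-consistency check that this is the intended family.  The hinge
matching is chiral (each vertex welds three of its six adjacent
triangle-pairs, rotated copies of one another), so each inner triangle hinges
to exactly three neighbours — the mechanism that produces lateral expansion
under stretch.  The cell pattern consequently has three-fold rotational
symmetry about each lattice vertex but no mirror symmetry; a mirrored panel
is the opposite-handed lattice.

The panel is tiled in the plane (brick-staggered so the footprint stays
rectangular), sized to the unrolled coverage band (meridional arc length
versus local azimuthal arc length), clipped to the band, and lifted onto the
epicardium by barycentric mapping: a panel node inside reference triangle
$(p_0,p_1,p_2)$ with coordinates $(\lambda_0,\lambda_1,\lambda_2)$ maps to
$\lambda_0 V_0 + \lambda_1 V_1 + \lambda_2 V_2$ on the triangulated surface.
After extrusion to its design thickness, every inner-surface node is tied to
its epicardial triangle by the same barycentric weights, as linear
multi-point constraints eliminated structurally through the solver's
reduction matrix — the displacement-field realization of the mapping, and a
single displacement field across the interface (nodes that land exactly on
epicardial nodes reduce to plain sharing).  The default coverage band is the
infarct window plus a margin; cell count follows from the band and the fixed
cell size.

Measured on a flat 3×3-cell panel stretched 5% with free lateral edges, the
lattice returns an effective Poisson ratio of about −0.31, against +0.47 for
a continuum sheet of the same law and thickness — the auxetic signature the
sleeve is built for.  The ideal point-hinged mechanism has $\nu = -1$;
finite hinge width and the soft exponential matrix dilute it.

## Cardiac cycle, loading and solver

The cycle is pressure-prescribed on the endocardium in normalized time: a
smoothstep filling ramp to EDP = 1.5 kPa at $t = 0.40$, a steep
isovolumic-like rise to the single systolic peak $P_{sys} = 12$ kPa at
$t = 0.60$, relaxation to zero by $t = 0.80$; activation is a squared-sine
pulse on $[0.40, 0.85]$.  These magnitudes and timings are synthetic
package defaults (a plausible post-infarction rodent hemodynamic envelope),
not measured values.  The activation window deliberately outlasts the
pressure relaxation: with prescribed pressure there is no circulation to
hold volume during isovolumic relaxation, and letting pressure persist after
activation ends would re-inflate the chamber mid-cycle and corrupt the ED
definition.  Isovolumic phases are therefore only approximated, which is a
stated limitation of normalized-time pressure driving.  ED is the step of
maximum cavity volume, ES the minimum; cavity volume is the divergence
theorem over the deformed endocardial surface closed by a quadratic basal
cap (exact for the quadratic facets, hence translation-invariant to machine
precision).

The solver is a displacement-based total Lagrangian formulation with
quadratic tetrahedra and a 14-point, degree-5 quadrature rule (certified
against closed-form monomial integrals in the tests; the exponential
stiffening makes low-order rules unreliable).  The endocardial pressure is a
follower load with a finite-difference load stiffness; the material tangent
is a finite-difference derivative of the analytic stress.  Newton iterations
with backtracking converge to $10^{-8}$ relative residual — relative to the
largest of the external load, the increment's initial imbalance, a small
fraction of the largest load the system has carried, and a
stiffness-times-area force scale (the latter two let unloaded late-cycle
states at assembly precision be recognized as equilibria).  Stagnation well
below $10^{-6}$ relative is accepted as the numerical floor.  Linear solves
use a supernodal sparse Cholesky, falling back to LDLᵀ when the
follower-load term makes a transient tangent indefinite, then to shifted
(damped) factorizations, with every solution validated through its linear
residual.  Failed increments are retried with halved load steps.

Boundary conditions follow the basal-plane recipe: zero axial translation on
all basal nodes (in-plane contraction and rotation remain free), one basal
node pinned in-plane and a second restricted to the line towards the first,
removing the rigid modes.  Default cycle resolution in the analyses is 12–16
steps; the scenario meshes use 5 polar rings × 10 azimuthal divisions × 1
transmural layer (≈ 270 wall elements), sizes chosen so a full
three-scenario comparison runs on a laptop-class single core in minutes.
The EDV changes by well under 1% between this and the next refinement level.

## Calibration (frozen defaults)

Two magnitudes close the study conditions and were calibrated once by the
package's own procedures, then frozen into `make_scenario()`:

* **Geometric scale 2.2876** — bisection on the uniform scale until the
  passively inflated chamber reaches an end-diastolic volume of 0.65 mL at
  EDP 1.5 kPa (closure within 0.5%).  Scaling acts on the reference geometry
  before inflation.  The resulting mean ED wall thickness is ≈ 1.84 mm
  (deformed wall volume over deformed mid-surface area).  The reported
  companion value of 0.54 mm is unreachable under uniform scaling of these
  wall dimensions: wall-volume conservation pins the thickness near
  1.8 mm once the volume target fixes the scale near 2.3.  The package
  reports the measured value and the corresponding acceptance comparison is
  left failing rather than redefined.
* **Peak activation 218.4 kPa** — secant search until the no-sleeve
  infarcted ventricle ejects ≈ 40% (a physiological post-infarction band).
  This is an effective magnitude of the uniform-activation model at this
  mesh resolution, not a sarcomere-level tension.

With these defaults the MI baseline produces EDV 0.645 mL, SV 0.256 mL,
EF 39.6% — an end-diastolic volume and stroke volume consistent with the
rodent-scale targets the geometry was scaled to.

## What the synthetic scenarios do and do not show

The generator reproduces the *structure* of the study conditions — geometry,
materials, sleeve designs, a pressure-prescribed cycle with length-dependent
activation — with synthetic waveforms standing in for unpublished in-vivo
pressure data, an idealized fiber rule standing in for diffusion-tensor
architectures, and a coarse single-ventricle mesh standing in for a
subject-specific biventricular model.  Organ-level numbers (EDV, SV, EF) land
in the calibrated bands by construction; regional contrasts between sleeve
designs are genuine model outputs but small at this scale, because a
0.16-mm-thick passive patch on a 1.8-mm wall shifts strains by fractions of
a percent.  Passing directional tests therefore demonstrates that the
pipeline resolves the sleeve-design orderings under these idealized
conditions, not that the magnitudes transfer to a real post-infarction
heart.  One ordering — lower remote-strain dispersion under the auxetic
sleeve than the continuum one — is not reproduced at this scale (the two
dispersions differ by about 1% with the continuum sleeve marginally
narrower) and its acceptance check is left failing as an honest negative.

In the spheroid's systole the apex and the infarct move apex-ward
(longitudinal elevation) rather than base-ward: with a mid-wall
circumferential fiber rule, circumferential shortening dominates and volume
conservation lengthens the chamber.  Infarct elevation statistics are
reported in the surface frame (z increasing base to apex) as the axial
component and its positive fraction; at these conditions the fraction
saturates at one for all designs and the elevation ordering is carried by
the mean axial displacement, which is larger with the auxetic sleeve than
the continuum one.

The stiffness-ratio sweep (EDV and SV versus $\zeta \in \{1,2,5\}$) uses the
full-coverage continuum sleeve with a 90° fiber angle — the spheroid analog
of the configuration in which that sweep was originally studied.  With the
localized default coverage the EDV ordering survives but the SV ordering
does not (the effect is below discretization resolution), which is why the
sweep is defined on the full-coverage configuration.

## Numerical choices, degeneracies, tie-breaks

* Quadrature degree 5 (14 points) for volume terms, degree 4 (6 points) for
  facet loads and surface integrals; both certified in the tests.
* Mesh diagonals by the smallest-global-id rule, which is face-local and
  hence conforming; negatively oriented tetrahedra are repaired by swapping
  their last two vertices at build time.
* Elements whose centroid lands on the long axis would have a degenerate
  circumferential direction; the fiber assigner falls back to the
  longitudinal tangent and flags them (none occur on the default meshes).
* The azimuthal seam and the pole are handled in parameter space (angle
  averaging through unit vectors; pole nodes carry no azimuth).
* The panel clip keeps the largest connected lattice component; a
  disconnected tiling is a construction error, not a warning.
* The lattice Poisson test steps displacement adaptively (the hinge rotation
  makes fixed large steps diverge) and measures lateral strain in the
  central third of the specimen away from the grips.
* Determinism: there is no randomness anywhere in the pipeline; two runs of
  the same scenario are bitwise identical.

## Known limitations

* Pressure-prescribed driving: no circulation model, so isovolumic phases
  are approximate and stroke work depends on the synthetic waveform shapes.
* Displacement-based near-incompressibility: systolic $|J-1|$ up to 0.05 at
  the default penalty (see above); a mixed formulation would remove this at
  the cost of a different solver.
* The coarse meshes underresolve strain concentrations at the infarct border
  zone; regional dispersion statistics are the quantity most affected, and
  the one directional finding this package fails to reproduce is exactly a
  dispersion ordering.
* The sleeve-design contrasts at matched stiffness ratio are small on the
  spheroid; conclusions about magnitudes (rather than orderings) need finer
  meshes and measured hemodynamics.
* Torsion magnitudes are sensitive to the basal constraints; the metric is
  computed between interior slices precisely to limit that bias, but
  absolute values should be read qualitatively.
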