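---
title: "Methods: garment pressure on rigid and soft legs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: garment pressure on rigid and soft legs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpress)
```

## The model

A medical compression textile (CT) is a tubular knit worn stretched on the
lower leg. `ctpress` models the worn steady state, not the donning motion:
once the tube sits at a measurement position, it is assumed to carry a
constant hoop tension and press on the limb normally through a frictionless
full contact. The chain has four links.

**Fabric constitutive law.** The knit is treated as linear elastic in the
course (circumferential) direction over its working stretch band. A strip
test gives the course modulus as `E = F_T / (b h ε)`
(`fabric_modulus_from_tension()`), averaged over the strain levels the
tester records; `ε` is taken as engineering strain of the clamped length,
the natural reading for clamp-to-clamp data. The wale modulus, shear
modulus and Poisson ratio are carried in `fabric_spec` because they
describe the orthotropic sheet, but the worn-tube mechanics below is
hoop-dominated, so only `E_F`, `h`, `R_F` and `v_F` (through the mismatch
factor) enter the solver.

**Wear strain and membrane tension.** A tube of relaxed radius `R_F` worn
on a girth `C` is stretched by `ε = (C − 2πR_F)/(2πR_F)`, floored at zero
for a slack garment (`wear_strain()`); the tension per unit length is
`T = E_F ε h` (`membrane_tension()`). Strains above 0.8 trigger a warning
because 15–80% is the working stretch band of these knits.

**Laplace's law.** A tensioned membrane on a curved surface exerts
`P = T κ`. The familiar shorthand "tension over girth" is dimensionally
loose; `laplace_pressure()` therefore takes a radius of curvature
(`C/2π` for circular sections, via `laplace_pressure_girth()`), and
`local_pressure_profile()` extends this to irregular sections using the
discrete local curvature, so flatter regions of a scanned contour receive
less pressure and concave artefacts cannot blow up (see *Numerical
choices*).

**Tissue foundation.** Soft tissue is homogeneous, isotropic,
incompressible (ν = 0.5 by default) neo-Hookean material; the constants
derive from the elastography modulus through the standard isotropic
relations `S = E/(2(1+ν))`, `B = E/(3(1−2ν))`, `C10 = S/2`, `D1 = B/2`
(`neo_hookean_params()`), with `D1 = Inf` flagged at exact
incompressibility. The contact response is summarized by the Hertz
mismatch factor `k = (1 − ν²)/(πE)` (`mismatch_factor()`).

## The Hertz contact chain and the ΔP identity

For one fabric–leg contact element under normal load `F` between surfaces
of radii `R` (limb) and `R_F` (fabric), Hertz theory gives the contact
radius `a = (3πF(k + k_F) R R_F / 4(R + R_F))^(1/3)` and peak pressure
`q = 3F/(2πa²)` (`contact_radius()`, `unit_pressure()`). The surface
displacement is implemented in the dimensionally consistent classical
form

> ω(r) = (k + k_F) · πq (a² − r²) / (4a),  so  ω(0) = (k + k_F) πqa/4,

which is the *total* approach of the two bodies; each body's own surface
moves in proportion to its own mismatch factor (pass the other factor as
zero to get one body's share). The interface pressure is defined as
`P = F/(2πa²)`, exactly one third of `q` — the convention this model
adopts throughout; the conventional mean `F/(πa²)` is available as
`mean_pressure()` but not used by the pipeline.

The rigid-vs-soft pressure-diversity ratio
`ΔP = (w_r/w_s) · (k_s + k_F)/(k_r + k_F)` (`pressure_ratio()`) is the
package's central comparison quantity. When both displacements come from
the Hertz expression at the same `q` and `a`, `w ∝ (k + k_F)` and the two
ratios cancel: **ΔP = 1 identically**, for any tissue stiffness in the
physiological 1400–3000 Pa band and any contact geometry. That algebraic
cancellation is the mechanical reason why garment pressure delivery is
insensitive to whether the limb underneath is a rigid mannequin or a soft
leg, and it is asserted to 1e-12 over 10⁴ random draws in the test suite.

## The equilibrium solver

The explicit-dynamics finite-element stage that a commercial solver would
perform is replaced by a quasi-static fixed point on the limb girth
(`solve_equilibrium()`):

1. `ε = wear_strain(C)`, `T = E_F ε h`, `P = T · 2π/C`;
2. indentation `w = k_leg · π a₀ / 4 · P` (Hertz foundation over a contact
   patch of radius `a₀`), or `w = P / k_W` for a Winkler bed of stiffness
   `k_W`;
3. `C ← C + damping · ((C₀ − 2πw) − C)`, until the relative girth
   residual falls below `tol`.

Two displacement quantities are reported. The *leg indentation* `w` uses
the leg-side mismatch factor only: in Hertz theory the total approach
`(k + k_F)πqa/4` splits between the bodies in proportion to their own
factors, and only the leg-side share moves the limb surface. This choice
makes the rigid limit exact — a printed-polymer leg at 3 GPa indents by
nanometres and the solved pressure equals the closed form
`P = 2π E_F h (1/C_F − 1/C₀)` to machine precision — and makes the
`E_s → ∞` soft solve converge to the rigid solution. The *total contact
approach* `w_contact = (k_leg + k_F)πa₀P/4` is carried alongside, because
it is what the ΔP chain consumes: feeding two solver runs' total
approaches at a matched reference pressure into `pressure_ratio()`
(`delta_p_from_results()`) reproduces ΔP = 1 to 1e-9.

The foundation itself is the package's own desk-scale coupling rule (the
source workflow leaves the per-element load unspecified), so the absolute
soft-leg indentation depends on the patch radius `a₀`; accordingly the
quantitative claims rest on ratios, limits and identities rather than on
absolute `w`. Two behaviours of this simple foundation are worth knowing.
First, pressure loss from tissue yield scales like `E_F h w / C²`, so it
is strongest at the distal (small-girth) positions: a profile that is
degressive on a rigid mannequin can flatten or locally invert on a very
soft leg. Second, the equilibrium pressure increases monotonically with
tissue stiffness and with wear strain (both proven by tests), so the
foundation solver — unlike the matched-delivery ΔP identity — does show a
small systematic stiffness effect; the statistical battery therefore
compares *measured* pressures under the matched-delivery design (below).

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `patch_radius` (a₀) | 0.02 | m | sensor/patch scale of pneumatic pressure probes |
| `tol` | 1e-8 | – | relative girth residual; far below meter resolution |
| `max_iter` | 200 | – | fixed point contracts (factor ≈ 0.2–0.6 damped); typically < 60 iterations |
| `damping` | 0.5 | – | unconditional convergence over the cohort parameter grid |
| `rigid_threshold` | 1e9 | Pa | moduli at/above take the exact rigid path |
| tissue ν | 0.5 | – | incompressible soft tissue |
| rigid-leg ν | 0.3 | – | printed-polymer value (only E is specified for the mannequin) |
| 1 mmHg | 133.322 | Pa | unit boundary; SI everywhere internally |

## Validation statistics

`dro()` implements the deviation ratio |measured − simulated|/measured ×
100. Normality uses `stats::shapiro.test` (appropriate for the n < 50
group sizes here and enforced as 3 ≤ n ≤ 50), correlation uses
`stats::cor.test`, and group comparisons use two-sided paired *t* tests
with Bonferroni adjustment by the number of comparisons actually run
(`paired_t_bonferroni()`); sidedness is two-sided throughout and α =
0.05. `stiffness_noise_experiment()` encodes the matched-delivery design:
every stiffness group reads the *same* true pressures through an
independent ±3 mmHg meter, so any detected group difference is a false
positive; with three pairwise comparisons the family-wise error stays
near 5%, and across 100 seeded cohorts ≥ 95% of runs report no
significant difference.

## The synthetic cohort

The generators (`cohort_spec()`, `generate_leg()`, `generate_fabric()`,
`simulate_swe()`, `simulate_picopress()`) emulate the study conditions:
three subjects, two compression classes (I and III), four positions,
tissue stiffness uniform on 1400–3000 Pa, and frustum-like legs with
ankle girths of 20–24 cm rising to 32–38 cm at the calf with a slight
taper above it. Section boundaries are Fourier-perturbed ellipses
(harmonics 2–5, relative amplitude = `irregularity`, default 0.1, aspect
ratio 0.78–0.95); every boundary is checked to be a simple polygon.
Fabric batches draw from the measured ranges of each class (course
modulus 0.33–0.38 MPa for class I, 0.33–0.76 MPa for class III,
thickness 0.62–0.69 mm, Poisson ratio 0.19–0.25, density
468.2–532.7 kg/m³).

Tube radii are sized by *graduated targeting*: per subject and class an
ankle pressure target is drawn inside the nominal class band (18.5–21
mmHg for class I, 34–42 mmHg for class III) and each more proximal
position targets 86–97% of its distal neighbour; the relaxed radius then
solves the closed-form rigid-limb pressure exactly, with the modulus draw
floored so the wear strain stays at or below 0.8. This makes generated
cohorts degressive by construction — which is a property of the sizing
ladder, mirroring how graduated stockings are actually dimensioned, not
of arbitrary independent draws.

Elastography noise is modelled at the modulus level: each site reports
`E_i = E_true (1 + cv·z_i)` (standard-normal `z`, truncated at 5% of
`E_true`) as the corresponding shear-wave velocity, so `noise_cv` is the
coefficient of variation of a single-site modulus estimate and the
8-site mean recovers `E_true` to about `cv/√8` (~3% mean absolute error
at cv = 0.1). Meter noise is uniform over ±3 mmHg — the instrument spec
states a precision, not a distribution, so the bounded-support choice is
the conservative reading; a Gaussian option (sd = precision/2) is
provided — followed by rounding to the 1 mmHg resolution and flooring at
zero. All generators are pure functions of (spec, seed): a single root
seed is fanned out by a stable string hash per entity, so adding a
subject never perturbs earlier subjects, and outputs are identical across
platforms using R's default generator.

What the generators deliberately do **not** emulate: scanner point-cloud
noise and surface reconstruction, bone/vein internal structure,
multi-layer (skin/fat/muscle) tissue, BMI-anthropometry correlations, and
any time dependence of fabric tension. Passing tests on this cohort
therefore demonstrate the correctness and internal consistency of the
mechanics and statistics, not the fidelity of any individual subject's
anatomy.

## Numerical choices

* **Curvature clipping.** Discrete local radii are clipped to
  [1e-4, 10] m; a collinear vertex triple returns the upper clip, so a
  locally flat scan segment yields a small finite Laplace pressure rather
  than zero or infinity.
* **Orientation and simplicity.** Cross-sections are stored
  counter-clockwise (reoriented on construction) and rejected if
  self-intersecting (vectorised all-pairs segment test).
* **Radial displacement.** The inward offset moves vertices along
  central-difference vertex normals; for circles this is exact
  (girth drops by 2πw up to the sampling sinc factor, < 1e-6 relative at
  ≥ 720 vertices) and for convex sections it matches the parallel-curve
  length L − 2πw to 1e-3. Displacements large enough to self-intersect
  are rejected.
* **Degenerate inputs.** Slack garments return a converged zero-pressure
  result with a warning; zero load gives a zero contact state; constant
  samples are rejected by the statistical tests.
* **Reference-table quirk.** In the bundled elastography reference data,
  subject S1's reported mean (0.002040 MPa) is not the mean of its two
  regional values (0.002060 MPa); `mean_swe_modulus()` implements the
  plain mean and the discrepancy is documented rather than special-cased.
  The S2 and S3 rows, which are arithmetically consistent, anchor the
  tests.

## Problem sizes

The shipped tests and the acceptance script use: 10⁴ random draws for the
ΔP identity, a 100-point seeded parameter grid for solver convergence,
100 seeded cohorts (n = 48 per stiffness group: 12 subject-position cases
× 4 meter repeats) for the statistical-recovery rate, 200 seeded
elastography sessions for modulus recovery, and cohorts of 3 subjects ×
2 classes × 4 positions for the end-to-end run. These sizes were chosen
so each claim is estimated with comfortable margin while the whole suite
runs in well under a minute.

## Known limitations

The fabric is linear elastic and time-independent (no stress relaxation
during wear); the tissue is a homogeneous incompressible half-space
summarized by one modulus, so regional stiffness differences enter only
through per-position solves; contact is frictionless and purely normal;
the indentation is treated as a uniform inward radial displacement when
mapped to circumference change; and the desk-scale foundation replaces,
but does not reproduce, a full finite-element contact solution — its
absolute indentations depend on the patch-radius parameter and should be
read comparatively.
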