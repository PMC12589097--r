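---
title: "Inelastic femur mechanics and fracture discrimination: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inelastic femur mechanics and fracture discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the constitutive
and structural model, the descriptor definitions, the synthetic-data
design, the statistical estimators, and the numerical choices that were
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Constitutive model

Bone is modelled as an isotropic elastic–perfectly-plastic solid with
compartment-specific parameters derived from volumetric density.

**Density chain.** Radiological density `ρ_QCT` (g/cm³; inputs in mg/cm³
are divided by 1000 on entry) is converted to ash density
`ρ_ash = 0.87 ρ_QCT + 0.079` and to apparent density via the ash/apparent
mass ratio, default 0.6 (physiological range 0.55–0.63; values outside it
warn). Both conversions are explicit named functions — `ash_density()`,
`apparent_density()` — because the two elasticity laws use *different*
density measures and units.

**Elasticity.** Trabecular `E = 0.003715 ρ_app^1.96` with `ρ_app` in
kg/m³; cortical `E = 10200 ρ_ash^2.01` with `ρ_ash` in g/cm³; E in MPa;
ν = 0.3. The two power laws meet discontinuously at the compartment
interface; the test suite documents (as an invariant over a density grid)
that the cortical law dominates once `ρ_ash ≥ 0.5` g/cm³. A unit-sanity
guard rejects trabecular densities below 10 kg/m³, which are almost
certainly g/cm³ values passed in the wrong unit.

**Yield.** Trabecular `σ_yc = 38.5 ρ_app^1.48`, `σ_yt = 22.6 ρ_app^1.26`
with `ρ_app` in g/cm³ — the Morgan-type coefficients produce physiological
MPa only in those units, so the trabecular *yield* laws deliberately use
g/cm³ while the trabecular *elasticity* law uses kg/m³. Cortical yields
are linear in E: `σ_yt = 0.33 + 0.0039 E` and, by default,
`σ_yc = −0.41 + 0.0062 E`. The leading sign of the cortical compressive
intercept is typographically ambiguous in the source material
(`−041 + 0.0062·E`); we keep the printed minus (the expression stays
positive for all physiological E) and expose the `+0.41` reading behind
`cortical_syc_positive_intercept = TRUE`. A configurable positivity floor
(default 0.01 MPa) guards the degenerate low-E corner.

## 2. Finite-element solver

**Kinematics and element.** Small strains (descriptor displacements are
1–3 mm on a ~100 mm organ) and eight-node hexahedra with B-bar (mean
dilatation) integration: deviatoric terms at the full 2×2×2 Gauss rule,
volumetric strain replaced by its element average, which passes the
distorted patch test to machine precision and avoids volumetric locking at
ν = 0.3. B-bar was chosen over one-point deviatoric under-integration
because the latter leaves zero-energy (hourglass) modes that would need ad
hoc stabilisation on the coarse phantom meshes used here.

**Plasticity.** J2 (von Mises) perfect plasticity with radial return. The
yield stress at each integration point is `σ_yc` when the trial mean
stress is compressive and `σ_yt` when tensile — the simplest model that
honours both printed yield laws. The hard sign switch makes the residual
discontinuous in the displacement, which defeats Newton's method, so the
selection is blended smoothly over a narrow trial-pressure band (1% of the
mean yield stress; a sigmoid in `p_trial`). The band is two orders of
magnitude smaller than the uniaxial mean stress at yield, so the
closed-form bar solutions are still met to 1e-6 relative; near pure shear
the effective yield approaches the average of the two branches, which we
consider physically reasonable. The algorithmic tangent omits the
band-derivative term (it is non-symmetric); a backtracking line search on
the residual norm restores global convergence at the cost of linear
convergence rates in increments where many points sit near the switch.

**Boundary conditions.** All constraints are encoded in a sparse
transformation `u = C q + d g`: the distal shaft cross-section fully
fixed; the greater-trochanter patch fixed only along the fall direction
(two tangential generalised dofs per node); the femoral-head surface nodes
rigidly coupled (translations only) to a reference point whose component
along the fall axis is the prescribed displacement `d`, with the two
transverse reference translations left free. The conjugate reaction is
simply `g·f_int`, and the reduced tangent `CᵀKC` stays symmetric. The fall
direction is built from adduction (tilt in the frontal x–z plane) and
internal rotation (about the shaft axis), both limited to the simulated
0–30° range; the suite verifies that rigidly rotating mesh and fall axis
together leaves the force–displacement curve unchanged to ~1e-7.

**Load stepping and failure.** Default increment 0.05 mm (tests and
phantom studies use 0.1–0.25 mm), Newton tolerance
‖residual‖ ≤ 1e-6·|reaction|, up to four increment halvings on
non-convergence. Failure is declared at the first increment whose reaction
falls below `drop_fraction` (default 0.999) of the running maximum — the
first true decrease. In this small-strain perfectly-plastic setting a
homogeneous structure only plateaus; the drop that does occur in the
phantoms comes from stress redistribution between the compressive and
tensile yield branches as bending progresses. If no drop occurs before
`max_displacement`, the run returns `failed = FALSE` with a warning and
descriptors refer to the cutoff point.

**Energies.** External work is accumulated by the trapezoid rule on the
reaction–displacement pairs; the plastic dissipation increment uses the
matching trapezoid `½(σ_n + σ_{n+1}) : Δε_p`, which makes the discrete
balance `W_ext = E_elastic + E_dissipated` an identity at converged states
(the suite checks closure to 1e-4 on every phantom run; observed ~1e-8).

## 3. Descriptor extraction

`F0` is the maximum reaction force, `D0` its displacement (first index on
ties). The curve truncated at `D0` is decomposed by a continuous
two-segment least-squares fit whose first segment is anchored at the
origin — anchoring is what makes `F1 = k1·D1` a single elastic
force/displacement pair. For a fixed breakpoint the two slopes solve a
2×2 normal system in closed form; the breakpoint minimising total SSE is
located on a grid (default 100 candidates between the 2nd and penultimate
samples) and refined by bracketed 1-D optimisation, which by construction
attains an SSE no worse than the exhaustive sample-breakpoint search the
tests compare against. Collinear data degrade gracefully to `k2 = k1`,
`D1 = D0`, hence `D2 = 0`.

Energies: `E_nl` is the trapezoidal integral of the loading curve,
`E_lin = ½F1·D1`, `D2 = D0 − D1` exactly, and `E_res` is *defined* by the
identity `E_nl − E_dis` (the unloading-curve integral is the cross-check,
not the definition). `D3` is the zero-force intercept of the unloading
branch by linear interpolation; without a simulated unload, the
elastic-slope fallback `D3 = D0 − F0/k1` is used, and the two paths agree
exactly when the true unloading is linear at slope `k1` (a tested
invariant).

## 4. Synthetic data

**What the generators emulate.** The study conditions are a retrospective
case–control design: 64 incident hip fractures and 64 controls, with
published group means ± SDs for four densitometric references and ten
mechanical descriptors. Those values ship as a typed fixture
(`inst/extdata/table3_descriptors.csv`) and parameterise every generator
default; sample sizes default to 64 + 64.

**Descriptor-level cohorts** draw each group from a multivariate normal
with those means/SDs. The source tables report no between-descriptor
correlations, so the joint structure is a modelling choice: a
block-structured default (force block 0.9; displacement 0.8; density 0.7;
energy 0.6; 0.6 between force and the other blocks, tapering to 0.3–0.5
elsewhere). Univariate results are insensitive to it; every
combination-descriptor AUROC is correlation-sensitive and should be read
qualitatively (the suite asserts only that a combination is at least as
good as its best component). Positivity is enforced by rejection
resampling of offending rows — simpler than truncation adjustment, with
negligible mean bias at the tables' coefficients of variation.

**Curve-level cohorts** draw per subject the quadruple
`(F0, D0, D1, D3)` — deliberately the same four quantities the extraction
recovers, so their group moments match the reference statistics by
construction — and derive the elastic force `F1 = F0·D1/(D0 − D3)`, i.e.
an elastic slope `k1 = F0/(D0 − D3)` such that linear unloading from the
peak lands exactly at `D3`. The loading curve is bilinear with a quadratic
C1 knee blend (half-width 0.1 mm by default; zero gives exact round-trip
recovery of the breakpoint). Correlations: `corr(D0, D1) = 0.866` is
pinned by the published SD of `D2 = D0 − D1`; `corr(D0, D3) = 0.9` and
`corr(D1, D3) = 0.7` keep the physical ordering `D3 < D0 − D1` almost
surely (~0.4% rejection); strength–displacement entries keep the generic
0.6. An earlier parametrisation that derived `D3` from drawn `(F0, F1,
D0, D1)` carried a Jensen-type ratio bias of ~0.5% into the `D3` mean;
drawing the extracted quantities directly removes it.

**Phantoms.** The graded beam is a prismatic hex mesh with a cortical
shell of fixed *physical* thickness (so refinement does not change the
geometry) and a trabecular core, its density field delivered as a
rectilinear image to exercise the trilinear-interpolation path. The
femur-like phantom sweeps elliptical cross-sections along a shaft that
bends ~55° toward the fall axis, with a narrowed neck and widened head,
densities per element (a curved sweep has no natural rectilinear
sampling). Defaults: cortical 850 mg/cm³, trabecular 150 mg/cm³, 5%
density CV — chosen once as representative of proximal-femur compartment
values; the default femur-like phantom fails (force drop) around 1.7 mm at
~3 kN, inside the published descriptor ranges. What phantoms do *not*
emulate: real inter-subject shape variation, the 2D→3D reconstruction
step, cortical thickness gradients, or anisotropy — so passing tests
demonstrate the mechanics and statistics of the pipeline, not clinical
validity on real femurs.

## 5. Discrimination statistics

Group differences use a Shapiro–Wilk gate at α = 0.05 per group (the gate
is stated in the source methodology, the specific normality test is our
choice): both normal → unpaired t-test, Welch variant by default;
otherwise Mann–Whitney U with tie correction (also the path for constant
groups). The U statistic itself is the rank-form pair count, tested
against explicit pair enumeration.

Logistic models are unpenalised with intercept, features standardised
inside each training fold; perfect separation is handled by capping
standardised coefficients at |β| ≤ 50 rather than penalising, to stay
faithful to plain logistic regression.

**Cross-validated AUROC — an estimator choice that matters.** The AUROC of
*pooled* leave-one-out probabilities is pessimistically biased for weak
predictors: leaving subject *i* out shifts the fold's fitted model against
*i*, and at chance-level signal this fold-shift dominates the ranking
(measured here: ~0.37–0.40 at the null for n = 128, against a true value
of 0.5 — a documented property of pooled CV-AUC estimation). A published
AUROC of ~0.5 for a weak descriptor is therefore *unreachable* by that
estimator. The package implements both estimators: `loocv_logistic()` +
`auroc()` for the pooled path (whose per-subject scores are also what the
DeLong comparison needs), and `lpocv_auroc()` — leave-pair-out
cross-validation, refitting on n−2 for every case–control pair — which is
nearly unbiased and is the estimator used for all reported cohort AUROCs
and for the acceptance pipeline. The C++ IRLS kernel makes the ~4100
refits per 64 + 64 cohort cost milliseconds.

The DeLong variance/covariance estimator uses midrank placement values;
the suite checks it against a stratified bootstrap (within 15% at
n = 200) and against an independent implementation (`pROC`).

## 6. Numerical choices and degenerate inputs

- Newton: tolerance 1e-6 relative to the reaction, 100 iterations,
  backtracking line search, four increment halvings; singular reduced
  tangents (limit states) fall back to a tiny-ridge solve.
- Yield-branch blend band: 1% of the mean yield stress (see §2).
- Bilinear fit: breakpoint grid of 100, `optimize()` refinement at 1e-10
  of the span; fewer than 4 points or collinear data → degenerate fit.
- Ties at `F0`: first index. Unloading `D3`: linear interpolation between
  the bracketing increments; an unloading branch that never reaches zero
  force is an error (no extrapolation).
- Seeds: every stochastic entry point takes an explicit seed; cohort
  tables and full-study report bundles are bit-identical under identical
  configuration (tested).

## 7. Known limitations

- **Element technology.** B-bar hex8 is over-stiff in bending. On the
  uniform bending beam the strength at fixed displacement moves ~7.5%
  between 4 and 8 elements across the section and ~2.6% between 8 and 12;
  the sequence contracts, but desk-scale budgets stop short of the <2%
  regime, so phantom strengths should be read as mesh-resolved only to a
  few percent. (The suite asserts the contraction on the affordable pair;
  the numbers above come from a longer offline sequence.)
- **No softening physics.** Perfect plasticity cannot represent true
  post-peak structural collapse; the detected force drop reflects
  tension/compression yield redistribution, not damage. No contact, no
  dynamics, no fatigue.
- **Statistical scope.** Univariate discrimination values are reproducible
  from group moments alone (binormal reasoning); combination AUROCs
  inherit the assumed correlation structure and are reported as
  correlation-sensitive. The cohorts are multivariate normal by
  construction; real descriptor distributions need not be.
- **Problem sizes.** Test-suite simulations use 160–512 element phantoms
  with 0.1–0.25 mm increments; the acceptance pipeline uses 500 cohort
  replicates (AUROC targets) and 5000-subject curve cohorts — sizes chosen
  to make the Monte-Carlo error small relative to the tolerances they are
  checked against.
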