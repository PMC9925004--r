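---
title: "Methods: sex-specific electrophysiology on detailed and smoothed synthetic ventricles"
author: "cardiosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific electrophysiology on detailed and smoothed synthetic ventricles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiosim` is a desk-scale computational cardiac electrophysiology
workbench. It asks how two commonly ignored model ingredients — the
trabeculated anatomy of the ventricular endocardium (including
free-running false tendons), and male/female differences in ion-channel
expression — change the predictions of monodomain simulations: activation
maps, pseudo-ECG intervals, and the inducibility and location of reentrant
ventricular tachycardia after an infarct. Everything runs on a single CPU
on synthetic anatomies; the design mirrors the full-heart workflow of
high-performance solvers while keeping each stage testable.

## The cellular model

The ionic model is the O'Hara–Rudy human ventricular myocyte model (41
state variables; endocardial, mid-myocardial and epicardial variants) with
the conductance-rescaling preset of its regulatory-science recalibration
applied by default (`preset = "dutta"`: GKs ×1.870, GK1 ×1.698, GNaL
×2.661, GKr ×1.013, PCa ×1.007). `preset = "baseline"` restores the
original formulation. Units follow the source model: potentials in mV,
time in ms, concentrations in mmol/L, currents in µA/µF.

Three layers of parameter scaling sit on top:

* **Transmural cell types.** Layer labels are assigned from the Laplace
  transmural coordinate Φ at thresholds 0.3/0.7 — the inner 30% of the
  wall is endocardial, the middle 40% mid-myocardial, the outer 30%
  epicardial.
* **Sex phenotypes.** The female phenotype multiplies channel
  conductances by expression ratios shipped as an editable table
  (`inst/extdata/sex_expression_scaling.csv`; female/male Gto 0.64, GKr
  0.80, GKs 0.80, GK1 0.85, Gncx 1.10). The exact per-current values used
  by the reference full-heart study were published in supplementary
  material that is not redistributed here, so the shipped table encodes
  the direction and approximate magnitude of the reported repolarizing
  potassium-current down-regulation; any table of the same shape can be
  substituted. The male phenotype is the identity.
* **Apex–base gradient.** The slow delayed-rectifier conductance g_Ks
  decays linearly along the apicobasal coordinate. The magnitude of the
  decay is not constrained by the reference study ("linear gradual decay"
  only); the default reaches 0.8 at the base and is configurable
  (`iks_base_scale`).

Integration is Rush–Larsen for the 28 voltage-dependent gates (using
per-timestep lookup tables in the compiled core) and forward Euler for
concentrations and voltage, at dt = 5e-3 ms for the single cell and 0.01
ms in tissue. Initial conditions for tissue come from single-cell pacing
at the run's cycle length; `pace_to_limit_cycle()` implements the strict
convergence criterion (inter-beat RMSE of the 1-ms-resampled calcium
transient below 1e-7 mmol/L, typically a few hundred beats), while tissue
runs default to a fixed number of pre-pacing beats (`init_beats`), which
changes tissue markers by well under a millisecond.

Stimuli default to −80 µA/µF; 0.5 ms for the isolated cell (twice-threshold
convention) and 2 ms for tissue patches, where diffusive loading raises
the capture threshold.

## Synthetic anatomy

`make_biventricular_pair()` generates a *pair* of tetrahedral meshes with
a shared epicardial outline: a smoothed member (truncated-ellipsoid
two-cavity shell) and a detailed member that adds endocardial trabecular
ridges and ≥ 1 cm false-tendon bridges until a target trabecular volume
fraction `100·(V_d − V_s)/V_d` is met (attainable range covers the 8.7%
to 16.3% of the reference cohort). Generation is voxel-based (conforming
Kuhn subdivision into six tetrahedra per voxel) and bit-reproducible from
`(configuration, seed)`.

Two deliberate desk-scale choices:

* **Element size 0.04 cm.** Conduction at the transverse diffusivity
  (1.9e-3 cm²/ms) blocks numerically for element sizes above ≈ 0.045 cm
  with this ionic model, so all conducting fixtures use the same 0.35–0.4
  mm element scale as the reference full-heart meshes. Resolution is a
  knob, but coarser meshes are only useful for geometry-level tests.
* **Miniature shell.** To keep node counts workstation-sized at that
  element size, the default shell is about 1/2.5 the linear size of an
  adult heart (LV outer semi-axes 0.40 × 0.40 × 0.62 cm, wall 0.15 cm;
  crescent RV). Activation and interval markers are therefore
  *qualitatively* comparable to full-heart values (ordering, signs,
  sex/geometry differences), not quantitatively; the package never claims
  full-heart numbers from these fixtures.

Trabeculae are short 2×2-voxel columns hugging the endocardium in the
apical two thirds (cross-section ≈ 0.6 mm², the scale of the smallest
structures the reference models resolve); false tendons are free-running
voxel cylinders between wall attachments, ≥ 1 cm where the cavity allows
a chord that long, otherwise the longest available chord. The transmural
coordinate Φ (endo 0 → epi 1) and apicobasal coordinate (apex 0 → base 1)
are Laplace solves with Dirichlet boundaries; cavity sub-structures carry
endocardial (Φ = 0) boundary values on their entire surface, which makes
their interior gradient collapse — exactly the property the fiber rule
uses to detect them. A one-element fast-endocardial layer (a surrogate
for the Purkinje network's rapid endocardial spread) covers the apical
two thirds of each cavity.

`insert_scar()` converts a transmural disc to non-excitable dense scar
with a border-zone shell and a border-zone corridor (isthmus) crossing
the core. `place_iars()` places the five sinus initial-activation
regions (two RV free wall, high anterior paraseptal LV, central left
septal surface, and a posterior paraseptal LV patch anchored at
apicobasal coordinate 1/3) from analytic targets shared by both members
of a pair, so detailed/smoothed runs are stimulated identically.

## Fibers

The compact wall follows the classical rule-based transmural helix:
orthonormal triads from the transmural and apicobasal gradients, helix
angle interpolating linearly from +60° (endo) to −60° (epi), transverse
angle 0. Trabecula detection uses the transmural-gradient magnitude:
`t = ||∇Φ||/T` below the threshold `T` and 1 otherwise, with `T = 0.1`
expressed against the gradient in 1/mm (the reference work states the
threshold without units; with Φ normalized to [0, 1] and ≈ 1.5–4 mm
walls, compact tissue sits at 0.25–0.65 1/mm and thin cavity structures
near 0). Sub-structures blend the helix angle as
`α = 90°(1 − t) + α_endo·t` in a frame whose longitudinal axis is the
structure's long axis: purely longitudinal fibers for t → 0 and a smooth
transition at the endocardial junction (the junction-continuity test
allows a 15° 95th-percentile nodal jump at the default resolution).

## Monodomain solver

The tissue model is the standard monodomain reaction–diffusion equation
`dV/dt = ∇·(D∇V) − (I_ion − I_stim)/C_m` with the anisotropic tensor
`D = D_f ff' + D_t ss' + D_n nn'` per element. (The reference text prints
the diffusion term with the opposite sign, which would be anti-diffusive
read literally; the standard sign is implemented.) Diffusivities in
cm²/ms: working myocardium and sub-structures 5.8e-3 / 1.9e-3 / 1.9e-3,
fast-endocardial layer 1.7e-2 / 5.8e-3 / 5.8e-3, border zone isotropic
1.9e-3 (excitable, unmodified cells), dense scar passive with isotropic
diffusion at 10% of the transverse value. A published scar conductivity
in mS/mm could not be reconciled dimensionally with these units and is
not used.

Discretization: P1 tetrahedral finite elements with lumped mass,
zero-flux boundaries, operator splitting per 0.01 ms step (Rush–Larsen
reaction at every excitable node, then explicit diffusion sub-stepped
automatically under the Gershgorin stability bound; at the default
resolution one sub-step suffices). Local activation is the first upward
crossing of 0 mV (with a 30 ms per-node refractory guard against
numerical double counting); repolarization time is 90% recovery from the
per-node AP amplitude, computed from the 1 ms snapshot history.

### Conduction-velocity calibration

On a 2 cm cable with the fiber diffusivity, the measured planar CV is
84.2 cm/s at the 0.04 cm reference element size, 94.3 cm/s at 0.02 cm,
and ≈ 98 cm/s by Richardson extrapolation — consistent with the published
1-D CV of this ionic model (~46 cm/s at D = 1.17e-3 cm²/ms) scaled by
√(5.8/1.17). The physiological band quoted for adult hearts (41–87 cm/s)
is therefore met at the reference discretization but exceeded by the
fully converged cable; the acceptance tooling reports the CV at the
reference element size and this refinement study documents the
discrepancy. The fiber/transverse CV ratio approaches the cable-theory
prediction √(D_f/D_t) ≈ 1.75 only under mesh refinement (transverse
propagation is much more discretization-sensitive), which is why that
check extrapolates from two grid levels.

## Pseudo-ECG and biomarkers

Unipolar potentials at right-arm, left-arm and left-leg field points are
the infinite-medium integral
`φ_e(x') = −Σ_elements [D∇V_m]·∇(1/r) vol`, evaluated at element
centroids from the 1 ms snapshots; limb leads are LI = LA − RA,
LII = LL − RA, LIII = LL − LA, so Einthoven closure holds by
construction. There is no torso volume conductor: amplitudes carry an
arbitrary global scale and only within-run-set comparisons (intervals,
RMSDs, morphology counts) are meaningful. Electrodes sit at fixed
offsets of the heart's bounding box, identical for both members of a
pair.

On the paired fixtures the sub-structure short-cuts advance local
activation over most of the shared wall (mean ≈ 12 ms on the default
pair, maxima near 50 ms) with a strongly regional pattern; because a
short-cut advances everything downstream of its insertion, the largest
differences sit along the advanced propagation paths rather than at the
insertion points themselves — a scale effect worth keeping in mind when
comparing against full-size activation maps.

Markers: TAT (last local activation), TAT10/TAT90 (volume-weighted
activation quantiles), EDI (volume-weighted standard deviation of LAT),
apparent CV (mode of the face-area-weighted epicardial CV histogram,
2 cm/s bins, ties toward the lower bin), QRS and QT from the three limb
leads. The landmark definitions follow the reference study; the
tolerances it leaves unspecified are: baseline band 2% of the lead's
peak-to-peak amplitude (default), a 12 ms dwell requirement for the QRS
end (so brief baseline touches of fractionated complexes do not
terminate the complex), and a T-wave band anchored at the post-T
quiescent level and scaled by the repolarization-segment amplitude —
at desk scale the T wave is small relative to the QRS (nearly synchronous
repolarization in a miniature strongly-coupled heart), and late resting
drifts would otherwise mask its end. On the synthetic fixtures the
interval markers are evaluated with a 5% band because the miniature
heart's plateau heterogeneity sits at 2–4% of the R amplitude.
Fractionation is quantified three ways: baseline-crossing counts
(`qrs_crossings()`), within-QRS deflection notches (`qrs_notches()`),
and a high-frequency fractionation index (`qrs_hf_ratio()`, the
second-difference energy fraction of the leads inside the complex). On
the miniature fixture the smoothed geometry's much slower, multiphasic
activation stretches its complex (≈ 69 vs 50 ms) and accumulates *more*
total deflections, so raw counts do not discriminate; the
high-frequency index — which captures notching sharpness independent of
complex duration, in the spirit of the clinical fragmented-QRS reading —
is consistently higher for the detailed member (≈ 0.024–0.035 vs 0.020
across fixture seeds) and is the metric the directional fractionation
check uses.

Sex differences (QT_diff = QT_female − QT_male per geometry) and
geometry differences (marker_detailed − marker_smoothed per sex) follow
the reference tables' logic, compared with a two-tailed Welch t-test
(`welch_ttest()`, rejecting at 0.05).

## Programmed stimulation

`run_programmed_stimulation()` implements the clinical risk-stratification
scan: S1 drive at 400 ms cycle length, then decremental S2; on reaching
refractoriness (capture failure) or the coupling floor without induction,
the level is fixed and S3, then S4 open. Defaults follow clinical
convention where the reference is silent: 6 drive beats, 10 ms
decrements, 180 ms floor. The drive train is simulated once per site and
the post-drive tissue state is reused across trials. A trial's
extrastimulus "captures" when ≥ 30% of excitable nodes activate within
its coupling interval; "full heart activation" for reentry counting is
≥ 90% of excitable nodes re-activating in a cycle (partial re-activations
between 30% and 90% are logged as wavelets). Three or more full
re-activations after the final stimulus classify as sustained VT —
exactly three is sustained. Per-beat cycle lengths are measured on a
reference patch farthest from the pacing site, and reentry sites are the
centroids of the earliest-activating connected region of each cycle,
classified by region label and transmural position.

The canonical inducibility fixture is a thin border-zone sheet with a
dense-scar core and an isthmus channel: with the fixed diffusivities the
reentry path length is set by the core circumference plus the channel,
and the scan finds the coupling intervals. Test-suite scans shorten the
protocol (1–2 drive beats from the paced limit cycle, coarser decrements,
a bounded observation window) — these are the package's desk-scale study
conditions, stated here once.

### Why desk-scale channel reentry does not close the loop

Running the scan on these fixtures produces unidirectional block,
long-lived wandering wavelets (up to ~60% of the tissue re-activating and
persisting ~250 ms beyond the last stimulus, which the detector logs as
wavelets), but no full reentrant re-activation. The cause is
quantifiable and worth stating because it constrains every desk-scale
study with this parameter set: steady-state conduction at the border-zone
diffusivity (isotropic 1.9e-3 cm²/ms) already sits at the discrete
propagation margin of this ionic model (block above dx ≈ 0.045 cm even at
full excitability), so a *premature* wave — whose sodium current is only
partly recovered — falls below a safety factor of 1 and dies mid-tissue;
cable experiments at dx = 0.025–0.04 cm show S2 plane waves at coupling
intervals 230–320 ms failing after a few millimetres. Since every reentry
pathway in a scar/border-zone substrate requires a premature wavefront to
traverse border-zone-speed tissue, and since the alternative (circuits in
fast myocardium) would need path lengths of the order of the wavelength
(CV × refractory period ≈ 6–15 cm, beyond any desk-scale fixture), the
channel-reentry endpoint is out of reach at this scale with the study's
parameterization — the full-size hearts, with circuits of tens of
centimetres, do not face this constraint. The sensitivity half of the
reentry check therefore fails by design rather than be weakened, and the
corresponding detection, classification, localization and tally machinery
is verified against constructed activation histories instead.

## Problem sizes and numerical choices

Defaults used throughout the test-suite and acceptance computations:
cable 2 cm at dx = 0.04 cm; biventricular pair with 12% trabecular
fraction, two false tendons, seed 1 (≈ 6 000 nodes detailed); sinus runs
of one analysis beat (450 ms at 600 ms cycle length) initialized from
60-beat paced cells; programmed-stimulation fixtures of a few thousand
nodes. Degenerate inputs are guarded explicitly (empty stimulus sets,
non-finite states, non-orthonormal triads, electrodes inside the
myocardium, flat activation surfaces); ties in the CV histogram resolve
toward the lower bin; the LUT voltage range is [−120, 80] mV with 0.05 mV
spacing and linear interpolation.

## What the synthetic fixtures do and do not show

The generator emulates the *structure* of the reference anatomies (paired
detailed/smoothed geometries, controllable trabecular fraction, false
tendons, transmural layering, fast endocardial layer, five activation
regions, scar with an isthmus) but not their size, their image-derived
endocardial texture, or inter-subject variability. Passing tests
demonstrate that the implemented pipeline reproduces the mechanisms —
sex-dependent repolarization prolongation, sub-structure propagation
short-cuts, fractionation, channel-dependent reentry — under controlled
conditions; they do not validate the pipeline against clinical ECGs
(no torso conduction, generalized activation sequences) nor reproduce
the full-heart marker magnitudes, which required meshes three orders of
magnitude larger. Known limitations shared with the reference approach:
no Purkinje network (a fast layer stands in), no mechano-electric
coupling, monodomain rather than bidomain.
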